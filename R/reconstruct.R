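# Response reconstruction: turn one row of estimated response distances
# d_hat (to the Kr response anchors with responses t_k) into a scalar
# response prediction.

#' RBF-weighted response reconstruction
#'
#' Weighted average of anchor responses with Gaussian radial-basis weights
#' `u_k = exp(-gamma * max(0, d_hat_k)^2)`. The result is always inside
#' `[min t_k, max t_k]` — the reconstruction cannot extrapolate beyond the
#' anchor response range.
#'
#' @param d_hat Estimated response distances (length Kr).
#' @param anchor_responses Anchor responses `t_k` (length Kr).
#' @param gamma RBF bandwidth, default 1.
#' @return The reconstructed scalar response.
#' @export
rbf_reconstruct <- function(d_hat, anchor_responses, gamma = 1) {
  stopifnot(length(d_hat) == length(anchor_responses),
            length(d_hat) >= 1, all(is.finite(anchor_responses)))
  check_scalar_number(gamma, "gamma", lower = 0)
  u <- exp(-gamma * pmax(0, d_hat)^2)
  if (sum(u) == 0) {
    rlang::warn("all RBF weights underflowed to 0; falling back to the nearest anchor response.")
    return(anchor_responses[which.min(d_hat)])
  }
  sum(u * anchor_responses) / sum(u)
}

# Objective of the optimization-based reconstruction:
# sum_k (max(0, d_hat_k) - |t - t_k|)^2.
reconstruction_objective <- function(t, d_hat, anchor_responses) {
  d <- pmax(0, d_hat)
  sum((d - abs(t - anchor_responses))^2)
}

# Exact global minimizer: between consecutive sorted anchor responses the
# sign pattern s_k = sign(t - t_k) is fixed, so the objective is a quadratic
# sum_k (c_k - s_k (t - t_k))^2 with unconstrained minimizer
# t* = mean(s_k c_k + t_k); clamp to the segment and take the best segment.
# Exact ties go to the smaller t (segments scanned left to right).
exact_reconstruct <- function(d_hat, anchor_responses) {
  c_k <- pmax(0, d_hat)
  tk <- anchor_responses
  bp <- sort(unique(tk))
  lo <- c(-Inf, bp)
  hi <- c(bp, Inf)
  best_t <- NA_real_
  best_f <- Inf
  for (seg in seq_along(lo)) {
    mid <- if (is.infinite(lo[seg])) hi[seg] - 1
           else if (is.infinite(hi[seg])) lo[seg] + 1
           else (lo[seg] + hi[seg]) / 2
    s <- ifelse(mid >= tk, 1, -1)
    t_star <- mean(s * c_k + tk)
    t_star <- min(max(t_star, lo[seg]), hi[seg])
    f <- reconstruction_objective(t_star, c_k, tk)
    tol <- if (is.finite(best_f)) 1e-15 * max(1, abs(best_f)) else 0
    if (f < best_f - tol) {
      best_f <- f
      best_t <- t_star
    }
  }
  best_t
}

#' Optimization-based response reconstruction
#'
#' Returns the scalar response minimizing
#' `sum_k (max(0, d_hat_k) - |t - t_k|)^2`, so every distance estimate —
#' including large ones — informs the prediction, and the minimizer may lie
#' outside the anchor response range (extrapolation). `solver = "exact"`
#' minimizes each piecewise-quadratic segment between consecutive sorted
#' anchor responses in closed form and is the reference; `"nelder_mead"`
#' runs the simplex method from the best of the anchor responses and the
#' RBF estimate. With several global minima the exact solver returns the
#' smallest `t`; Nelder-Mead may return any of them.
#'
#' @inheritParams rbf_reconstruct
#' @param solver `"exact"` (default) or `"nelder_mead"`.
#' @param gamma RBF bandwidth used only for the Nelder-Mead starting point.
#' @return The reconstructed scalar response.
#' @export
optimization_reconstruct <- function(d_hat, anchor_responses,
                                     solver = c("exact", "nelder_mead"),
                                     gamma = 1) {
  solver <- match.arg(solver)
  stopifnot(length(d_hat) == length(anchor_responses),
            length(d_hat) >= 1, all(is.finite(anchor_responses)))
  if (solver == "exact") {
    return(exact_reconstruct(d_hat, anchor_responses))
  }
  # the objective is piecewise quadratic with up to one local minimum per
  # segment, so the simplex search is restarted from every anchor response,
  # the two outer rays and the RBF estimate, and the best result kept
  reach <- max(pmax(0, d_hat))
  starts <- unique(c(anchor_responses,
                     min(anchor_responses) - reach,
                     max(anchor_responses) + reach,
                     suppressWarnings(
                       rbf_reconstruct(d_hat, anchor_responses, gamma))))
  best <- Inf; best_t <- starts[1]
  for (s in starts) {
    fit <- suppressWarnings(stats::optim(
      s, reconstruction_objective,
      d_hat = d_hat, anchor_responses = anchor_responses,
      method = "Nelder-Mead",
      control = list(maxit = 200, reltol = 1e-12)
    ))
    if (fit$value < best) {
      best <- fit$value
      best_t <- fit$par
    }
  }
  best_t
}

#' Reconstruct responses for a matrix of distance estimates
#'
#' Applies [rbf_reconstruct()] or [optimization_reconstruct()] to each row
#' of an n x Kr matrix of estimated response distances.
#'
#' @param d_hat_matrix n x Kr matrix of estimated response distances.
#' @param anchor_responses Length-Kr anchor responses.
#' @param method `"optimization"` or `"rbf"`.
#' @param gamma RBF bandwidth.
#' @param solver Solver for the optimization method.
#' @return A numeric vector of n reconstructed responses.
#' @export
reconstruct_responses <- function(d_hat_matrix, anchor_responses,
                                  method = c("optimization", "rbf"),
                                  gamma = 1,
                                  solver = c("exact", "nelder_mead")) {
  method <- match.arg(method)
  solver <- match.arg(solver)
  d_hat_matrix <- as.matrix(d_hat_matrix)
  apply(d_hat_matrix, 1, function(d) {
    if (method == "rbf") {
      rbf_reconstruct(d, anchor_responses, gamma)
    } else {
      optimization_reconstruct(d, anchor_responses, solver, gamma)
    }
  })
}
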