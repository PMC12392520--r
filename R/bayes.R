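# Monte-Carlo verification of the Bayesian hierarchy behind the
# optimization-based reconstruction: a Normal-Exponential scale mixture
# whose marginal is Laplace, and the Normal full conditional of the latent
# response t_n.

#' Sample from the Normal-Exponential scale mixture
#'
#' Draws `tau2 ~ Exponential(rate = d^2 / 2)` and then
#' `t | tau2 ~ Normal(t_n, tau2)`. Marginally over `tau2`, `t` follows
#' `Laplace(t_n, scale = 1/d)` — the distributional identity that links the
#' squared-distance mismatch objective to a coherent hierarchical model.
#'
#' @param t_n Location (the latent response).
#' @param d Response distance, `> 0`; the Laplace scale is `1/d`.
#' @param n_draws Number of draws.
#' @param seed Seed.
#' @return Numeric vector of `n_draws` samples.
#' @export
sample_t_marginal <- function(t_n, d, n_draws, seed = 1) {
  check_scalar_number(d, "d", lower = 1e-300)
  stopifnot(n_draws >= 1)
  with_seed(sub_seed(seed, "laplace_mixture"), {
    tau2 <- stats::rexp(n_draws, rate = d^2 / 2)
    stats::rnorm(n_draws, mean = t_n, sd = sqrt(tau2))
  })
}

#' Laplace cumulative distribution function
#'
#' @param q Quantiles.
#' @param location,scale Laplace parameters (`scale > 0`).
#' @return `P(X <= q)`.
#' @export
plaplace <- function(q, location = 0, scale = 1) {
  z <- (q - location) / scale
  ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
}

#' Normal full conditional of the latent response
#'
#' Under anchor observations `t_k ~ Normal(t_n, tau2_k)` and a
#' `Normal(0, sigma2)` prior on `t_n`, the full conditional of `t_n` is
#' Normal with variance `v* = (1/sigma2 + sum(1/tau2_k))^-1` (precisions
#' add) and mean `u* = v* * sum(t_k / tau2_k)` — the precision-weighted
#' anchor average, shrunk towards 0 by the prior.
#'
#' @param t_vec Anchor responses `t_k`.
#' @param tau2_vec Latent variances `tau2_k`, all `> 0`.
#' @param sigma2 Prior variance of `t_n`, `> 0`.
#' @return A list with `u_star` (posterior mean / point estimate) and
#'   `v_star` (posterior variance).
#' @export
posterior_t <- function(t_vec, tau2_vec, sigma2) {
  stopifnot(length(t_vec) == length(tau2_vec))
  if (any(tau2_vec <= 0) || sigma2 <= 0) {
    rlang::abort("all variances must be positive.")
  }
  v_star <- 1 / (1 / sigma2 + sum(1 / tau2_vec))
  u_star <- v_star * sum(t_vec / tau2_vec)
  list(u_star = u_star, v_star = v_star)
}

#' Compare the optimization reconstruction with the posterior point estimate
#'
#' Diagnostic report putting the distance-mismatch minimizer next to the
#' posterior mean `u*` obtained when each latent variance `tau2_k` is set to
#' its conditional mean `2 / d_hat_k^2`. Zero distance estimates are
#' floored at `eps` so the implied precision stays finite.
#'
#' @param d_hat Estimated response distances.
#' @param anchor_responses Anchor responses `t_k`.
#' @param sigma2 Prior variance of the latent response; default `1e6`
#'   (essentially flat).
#' @param eps Floor applied to `max(0, d_hat)`; default `1e-6`.
#' @return A one-row tibble: `optimization_estimate`, `posterior_mean`,
#'   `posterior_variance`, `difference`.
#' @export
reconstruction_vs_posterior_demo <- function(d_hat, anchor_responses,
                                             sigma2 = 1e6, eps = 1e-6) {
  stopifnot(length(d_hat) == length(anchor_responses))
  d <- pmax(pmax(0, d_hat), eps)
  tau2 <- 2 / d^2
  post <- posterior_t(anchor_responses, tau2, sigma2)
  opt <- optimization_reconstruct(d_hat, anchor_responses, solver = "exact")
  tibble::tibble(
    optimization_estimate = opt,
    posterior_mean = post$u_star,
    posterior_variance = post$v_star,
    difference = opt - post$u_star
  )
}

ks_distance <- function(samples, cdf) {
  x <- sort(samples)
  n <- length(x)
  F_x <- cdf(x)
  max(abs(seq_len(n) / n - F_x), abs((seq_len(n) - 1) / n - F_x))
}

# Quadrature oracle for the posterior of t_n: normalizes the product density
# N(t_k; t_n, tau2_k) * N(t_n; 0, sigma2) on a fine grid.
posterior_t_quadrature <- function(t_vec, tau2_vec, sigma2, n_grid = 20001) {
  prec <- 1 / sigma2 + sum(1 / tau2_vec)
  center <- sum(t_vec / tau2_vec) / prec
  half <- 12 / sqrt(prec)
  grid <- seq(center - half, center + half, length.out = n_grid)
  loglik <- -0.5 * grid^2 / sigma2
  for (k in seq_along(t_vec)) {
    loglik <- loglik - 0.5 * (t_vec[k] - grid)^2 / tau2_vec[k]
  }
  w <- exp(loglik - max(loglik))
  w <- w / sum(w)
  u <- sum(w * grid)
  v <- sum(w * (grid - u)^2)
  list(u_star = u, v_star = v)
}

#' Monte-Carlo verification of the Bayesian hierarchy
#'
#' Runs the package's distributional checks and returns a pass/fail table:
#' * the Normal-Exponential mixture marginal matches the Laplace
#'   distribution (Kolmogorov-Smirnov distance over a grid of locations
#'   and distances);
#' * Laplace moments (mean `t_n`, sd `sqrt(2)/d`);
#' * the full-conditional `(u*, v*)` matches a quadrature oracle;
#' * posterior precisions add exactly.
#'
#' @param seed Seed.
#' @param n_draws Draws per Kolmogorov-Smirnov check; default `1e5`.
#' @param ks_threshold Pass threshold on the KS distance; default 0.01.
#' @return A tibble with columns `check`, `statistic`, `threshold`, `pass`.
#' @export
bayes_check <- function(seed = 1, n_draws = 1e5, ks_threshold = 0.01) {
  rows <- list()
  grid <- expand.grid(t_n = c(-2, 0, 3), d = c(0.5, 1, 2))
  for (g in seq_len(nrow(grid))) {
    t_n <- grid$t_n[g]; d <- grid$d[g]
    s <- sample_t_marginal(t_n, d, n_draws, seed = seed + g)
    ks <- ks_distance(s, function(x) plaplace(x, t_n, 1 / d))
    rows[[length(rows) + 1]] <- tibble::tibble(
      check = sprintf("laplace marginal KS (t_n=%g, d=%g)", t_n, d),
      statistic = ks, threshold = ks_threshold, pass = ks < ks_threshold)
  }
  s <- sample_t_marginal(0, 1, n_draws, seed = seed)
  rows[[length(rows) + 1]] <- tibble::tibble(
    check = "laplace mean (t_n=0, d=1)", statistic = abs(mean(s)),
    threshold = 0.02, pass = abs(mean(s)) < 0.02)
  rows[[length(rows) + 1]] <- tibble::tibble(
    check = "laplace sd (t_n=0, d=1)", statistic = abs(stats::sd(s) - sqrt(2)),
    threshold = 0.03, pass = abs(stats::sd(s) - sqrt(2)) < 0.03)

  qcheck <- with_seed(sub_seed(seed, "posterior_cases"), {
    errs <- numeric(5)
    for (i in 1:5) {
      k <- sample(3:12, 1)
      t_vec <- stats::runif(k, -5, 5)
      tau2 <- stats::runif(k, 0.1, 4)
      sigma2 <- stats::runif(1, 0.5, 100)
      a <- posterior_t(t_vec, tau2, sigma2)
      b <- posterior_t_quadrature(t_vec, tau2, sigma2)
      errs[i] <- max(abs(a$u_star - b$u_star), abs(a$v_star - b$v_star))
    }
    max(errs)
  })
  rows[[length(rows) + 1]] <- tibble::tibble(
    check = "full conditional vs quadrature oracle", statistic = qcheck,
    threshold = 1e-6, pass = qcheck < 1e-6)

  dplyr::bind_rows(rows)
}
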