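# Independent oracle: iterative minimization of the penalized objective
# ||Dr - Ds* W*||^2 + lambda ||W*||_F^2 over the stacked coefficient vector.
iterative_ridge <- function(Ds, Dr, lambda) {
  X <- cbind(1, Ds)
  p <- ncol(X); q <- ncol(Dr)
  obj <- function(w) {
    W <- matrix(w, p, q)
    sum((Dr - X %*% W)^2) + lambda * sum(W^2)
  }
  grad <- function(w) {
    W <- matrix(w, p, q)
    as.numeric(2 * (crossprod(X, X %*% W - Dr) + lambda * W))
  }
  fit <- optim(rep(0, p * q), obj, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  matrix(fit$par, p, q)
}

test_that("least squares recovers exact linear structure", {
  set.seed(42)
  Ds <- matrix(runif(30 * 5), 30)
  W0 <- rbind(rnorm(3), matrix(rnorm(15), 5))
  Dr <- cbind(1, Ds) %*% W0
  m <- fit_distance_regression(Ds, Dr, lambda = 0)
  expect_equal(rbind(m$beta, m$W), W0, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a huge penalty shrinks the coefficients towards zero", {
  set.seed(1)
  Ds <- matrix(runif(40 * 6), 40)
  Dr <- matrix(runif(40 * 2), 40)
  big <- fit_distance_regression(Ds, Dr, lambda = 1e9)
  ref <- fit_distance_regression(Ds, Dr, lambda = 0.05)
  norm_of <- function(m) sqrt(sum(rbind(m$beta, m$W)^2))
  expect_lt(norm_of(big), 1e-3 * norm_of(ref))
})

test_that("closed form matches an iterative minimizer of the objective", {
  set.seed(7)
  for (i in 1:5) {
    Ds <- matrix(runif(20 * 5), 20)
    Dr <- matrix(runif(20 * 3), 20)
    m <- fit_distance_regression(Ds, Dr, lambda = 0.05)
    Wit <- iterative_ridge(Ds, Dr, 0.05)
    expect_equal(rbind(m$beta, m$W), Wit, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("normal equations hold across the lambda range", {
  set.seed(9)
  Ds <- matrix(runif(25 * 4), 25)
  Dr <- matrix(runif(25 * 3), 25)
  X <- cbind(1, Ds)
  for (lambda in c(0, 0.05, 1, 100)) {
    m <- fit_distance_regression(Ds, Dr, lambda = lambda)
    Wstar <- rbind(m$beta, m$W)
    lhs <- (crossprod(X) + lambda * diag(5)) %*% Wstar
    expect_equal(lhs, crossprod(X, Dr), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("training residuals are orthogonal to the design at lambda 0", {
  set.seed(11)
  Ds <- matrix(runif(30 * 4), 30)
  Dr <- matrix(runif(30 * 2), 30)
  m <- fit_distance_regression(Ds, Dr, lambda = 0)
  fitted <- predict_response_distances(m, Ds)
  expect_lt(max(abs(crossprod(cbind(1, Ds), Dr - fitted))), 1e-8)
})

test_that("collinear designs fail at lambda 0 but fit under ridge", {
  set.seed(5)
  base <- matrix(runif(20 * 3), 20)
  Ds <- cbind(base, base[, 1])           # exact duplicate column
  Dr <- matrix(runif(20 * 2), 20)
  expect_error(fit_distance_regression(Ds, Dr, lambda = 0), "lambda > 0")
  m <- fit_distance_regression(Ds, Dr, lambda = 0.05)
  expect_true(all(is.finite(m$W)))
  # ridge keeps the solve well-conditioned: solution satisfies its normal
  # equations even on the degenerate design
  Wstar <- rbind(m$beta, m$W)
  lhs <- (crossprod(cbind(1, Ds)) + 0.05 * diag(5)) %*% Wstar
  expect_equal(lhs, crossprod(cbind(1, Ds), Dr), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("ridge converges to least squares as lambda vanishes", {
  set.seed(13)
  Ds <- matrix(runif(30 * 4), 30)
  Dr <- matrix(runif(30 * 2), 30)
  ols <- fit_distance_regression(Ds, Dr, lambda = 0)
  small <- fit_distance_regression(Ds, Dr, lambda = 1e-10)
  expect_equal(small$W, ols$W, tolerance = 1e-6)
})

test_that("predicted distances honour intercepts and clipping", {
  m <- fake_tr_model(matrix(0, 3, 2), beta = c(0.7, -0.3))$model
  D <- predict_response_distances(m, matrix(0, 4, 3))
  expect_equal(unique(as.numeric(D)), c(0.7, -0.3))
  expect_equal(unique(as.numeric(
    predict_response_distances(m, matrix(0, 4, 3), clip = "abs"))),
    c(0.7, 0.3))
  expect_equal(unique(as.numeric(
    predict_response_distances(m, matrix(0, 4, 3), clip = "nonneg"))),
    c(0.7, 0))
  bad <- matrix(0, 4, 3, dimnames = list(NULL, c("X", "Y", "Z")))
  expect_error(predict_response_distances(m, bad), "do not match")
  expect_error(predict_response_distances(m, matrix(0, 4, 5)), "wrong number")
})

test_that("model archives round-trip exactly", {
  d <- small_qsar(60)
  m <- adaptor_fit(d, steps = 2, seed = 3)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(m$model$W, back$model$W)
  expect_identical(predict(m, d[1:5, ]), predict(back, d[1:5, ]))
})

test_that("tidy and glance expose the fitted weights", {
  d <- small_qsar(60)
  m <- adaptor_fit(d, steps = 1, seed = 3)
  td <- tidy(m)
  expect_equal(nrow(td), (nrow(m$model$W) + 1) * ncol(m$model$W))
  expect_equal(td$weight[td$structure_anchor == "(intercept)"],
               unname(m$model$beta))
  g <- glance(m)
  expect_equal(g$lambda, 0.05)
  expect_equal(g$steps, 1L)
})
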