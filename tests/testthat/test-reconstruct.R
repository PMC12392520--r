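test_that("RBF reconstruction is a bounded weighted average", {
  # equal distances -> unweighted mean
  expect_equal(rbf_reconstruct(rep(2, 4), c(4, 5, 6, 8)), mean(c(4, 5, 6, 8)))
  # a dominant (zero-distance) anchor wins
  expect_equal(rbf_reconstruct(c(0, 10, 10, 10), c(4, 5, 6, 8)), 4,
               tolerance = 1e-4)
  # never outside the anchor response range
  set.seed(2)
  for (i in 1:50) {
    t_k <- runif(6, 4, 8)
    est <- rbf_reconstruct(rnorm(6, 1, 2), t_k, gamma = runif(1, 0.1, 5))
    expect_gte(est, min(t_k)); expect_lte(est, max(t_k))
  }
  # total underflow falls back to the nearest anchor, with a warning
  expect_warning(out <- rbf_reconstruct(c(40, 50), c(4, 8), gamma = 1),
                 "underflow")
  expect_equal(out, 4)
})

test_that("optimization reconstruction solves the toy geometry exactly", {
  est <- optimization_reconstruct(c(3, 2, 1, 1), c(4, 5, 6, 8))
  expect_equal(est, 7, tolerance = 1e-8)
  expect_equal(topreg:::reconstruction_objective(est, c(3, 2, 1, 1),
                                                 c(4, 5, 6, 8)), 0)
  expect_equal(optimization_reconstruct(0, 5), 5)
  # negative distance estimates behave as zero
  expect_equal(optimization_reconstruct(c(-1, 2), c(5, 7)),
               optimization_reconstruct(c(0, 2), c(5, 7)))
})

test_that("both solvers agree with independent oracles on random instances", {
  set.seed(31)
  for (i in 1:50) {
    t_k <- sort(runif(10, 4, 8))
    d_hat <- abs(rnorm(10, 1, 1.5))
    exact <- optimization_reconstruct(d_hat, t_k, solver = "exact")
    nm <- optimization_reconstruct(d_hat, t_k, solver = "nelder_mead")
    f <- function(t) topreg:::reconstruction_objective(t, d_hat, t_k)
    expect_lt(abs(f(nm) - f(exact)), 1e-4)
    # exact solver against a brute-force grid oracle
    expect_lt(f(exact), f(grid_reconstruct(d_hat, t_k)) + 1e-6)
    # global optimality against every anchor and the RBF estimate
    expect_true(all(f(exact) <= vapply(t_k, f, numeric(1)) + 1e-12))
    expect_lte(f(exact), f(rbf_reconstruct(d_hat, t_k)) + 1e-12)
  }
})

test_that("consistent distances are inverted exactly", {
  set.seed(5)
  for (i in 1:20) {
    t_k <- runif(8, 4, 8)
    t0 <- runif(1, 2, 10)
    est <- optimization_reconstruct(abs(t0 - t_k), t_k, solver = "exact")
    expect_equal(est, t0, tolerance = 1e-10)
  }
})

test_that("the optimization path extrapolates where the RBF path cannot", {
  # anchors clustered, all distances large: the minimizer must leave the
  # anchor range
  t_k <- c(5, 5.2, 5.4)
  d_hat <- c(3, 2.8, 2.6)
  est <- optimization_reconstruct(d_hat, t_k, solver = "exact")
  expect_true(est < min(t_k) || est > max(t_k))
  rbf <- rbf_reconstruct(d_hat, t_k)
  expect_true(rbf >= min(t_k) && rbf <= max(t_k))
})

test_that("degenerate single-anchor problems return the smaller minimum", {
  # objective (d - |t - t1|)^2 has global minima at t1 - d and t1 + d
  expect_equal(optimization_reconstruct(2, 5, solver = "exact"), 3)
})

test_that("batch reconstruction matches per-row calls", {
  set.seed(9)
  D <- matrix(abs(rnorm(12)), 4)
  t_k <- c(4, 6, 7)
  out <- reconstruct_responses(D, t_k, method = "optimization")
  expect_equal(out, apply(D, 1, optimization_reconstruct,
                          anchor_responses = t_k))
  out_rbf <- reconstruct_responses(D, t_k, method = "rbf", gamma = 2)
  expect_equal(out_rbf, apply(D, 1, rbf_reconstruct,
                              anchor_responses = t_k, gamma = 2))
})

test_that("under distance noise the optimization path beats RBF on average", {
  errs <- vapply(1:400, function(s) {
    toy <- make_toy_example(noise_sd = 0.5, seed = s)
    c(abs(optimization_reconstruct(toy$d_hat, toy$anchor_responses) -
            toy$true_response),
      abs(rbf_reconstruct(toy$d_hat, toy$anchor_responses) -
            toy$true_response))
  }, numeric(2))
  expect_lte(mean(errs[1, ]), mean(errs[2, ]))
})
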