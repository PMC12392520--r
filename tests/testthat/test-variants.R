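test_that("ensemble fractions stay in bounds and the mean is exact", {
  d <- small_qsar(100)
  ens <- ensemble_fit(d, n_models = 8, seed = 4)
  expect_true(all(ens$fractions >= 0.3 & ens$fractions <= 0.9))
  expect_length(ens$members, 8)
  test <- small_qsar(100)[1:20, ]
  P <- vapply(ens$members, function(m) predict(m, test)$.pred, numeric(20))
  expect_equal(predict(ens, test)$.pred, rowMeans(P))
  expect_error(ensemble_fit(d, n_models = 0), "at least 1")
})

test_that("a one-member ensemble is just that member", {
  d <- small_qsar(100)
  ens <- ensemble_fit(d, n_models = 1, seed = 9)
  test <- d[1:15, ]
  expect_equal(predict(ens, test)$.pred,
               predict(ens$members[[1]], test)$.pred)
})

test_that("stacking weights favour a member that fits the holdout", {
  d <- small_qsar(200, seed = 13)
  # a member that predicts the holdout perfectly vs two pure-noise members
  perfect <- function(nd) nd$response
  noise_a <- function(nd) topreg:::with_seed(101, rnorm(nrow(nd), 6, 1))
  noise_b <- function(nd) topreg:::with_seed(202, rnorm(nrow(nd), 6, 1))
  st <- stack_fit(d, list(perfect, noise_a, noise_b),
                  val_fraction = 0.25, seed = 2)
  expect_gt(st$weights[2], abs(st$weights[3]))
  expect_gt(st$weights[2], abs(st$weights[4]))
  expect_equal(st$weights[2], 1, tolerance = 1e-6)
  test <- d[1:10, ]
  expect_equal(predict(st, test)$.pred, test$response, tolerance = 1e-6)
})

test_that("identical members collapse to a single-member stack", {
  d <- small_qsar(120)
  m <- adaptor_fit(d, steps = 1, seed = 5)
  st2 <- stack_fit(d, list(m, m), val_fraction = 0.3, seed = 7)
  test <- d[1:10, ]
  # duplicated members receive zero extra weight, so predictions equal the
  # affine recalibration of the single member on the holdout
  p1 <- predict(m, test)$.pred
  expect_equal(predict(st2, test)$.pred,
               st2$weights[1] + st2$weights[2] * p1)
  expect_equal(st2$weights[3], 0)
})

test_that("stack holdout sizing is validated and reproducible", {
  d <- small_qsar(100)
  m <- adaptor_fit(d, steps = 1, seed = 5)
  expect_error(stack_fit(d, list(m), val_fraction = 0.5), "at least 2")
  expect_error(stack_fit(d, list(m, m, m), val_fraction = 0.02),
               "cannot identify")
  s1 <- stack_fit(d, list(m, m), val_fraction = 0.5, seed = 3)
  s2 <- stack_fit(d, list(m, m), val_fraction = 0.5, seed = 3)
  expect_identical(s1$validation_ids, s2$validation_ids)
  expect_length(s1$validation_ids, 50)
})

test_that("step-model ensembling matches its definition and the final model", {
  d <- make_synthetic_qsar(300, seed = 29)
  test_ids <- d$id[251:300]
  test <- d[d$id %in% test_ids, ]
  train <- d[!(d$id %in% test_ids), ]
  m <- adaptor_fit(train, steps = 4, seed = 29)
  P <- vapply(step_models(m), function(s) predict(s, test)$.pred,
              numeric(nrow(test)))
  ens <- adaptive_ensemble_predict(m, test, mode = "ensemble")
  expect_equal(ens$.pred, rowMeans(P))
  # averaging over steps does not change performance materially
  nrmse_final <- compute_metrics(test$response, predict(m, test)$.pred)$nrmse
  nrmse_ens <- compute_metrics(test$response, ens$.pred)$nrmse
  expect_lt(abs(nrmse_ens - nrmse_final), 0.05)
  # stacking over steps needs validation data
  expect_error(adaptive_ensemble_predict(m, test, mode = "stack"),
               "validation")
  st <- adaptive_ensemble_predict(m, test, mode = "stack",
                                  validation = train[1:60, ], seed = 1)
  expect_equal(nrow(st), nrow(test))
  # a single-step history degenerates to the lone model
  m1 <- adaptor_fit(train, steps = 1, seed = 29)
  expect_equal(adaptive_ensemble_predict(m1, test, mode = "ensemble")$.pred,
               predict(m1, test)$.pred)
})
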