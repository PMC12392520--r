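test_that("k-means response anchors cover the response space", {
  # ten distinct responses, ten anchors: every sample selected
  d10 <- tibble::tibble(id = sprintf("m%02d", 1:10),
                        response = as.numeric(1:10))
  expect_setequal(select_response_anchors(d10, kr = 10, seed = 1), d10$id)

  # two well-separated blobs -> one anchor per blob
  d2 <- tibble::tibble(id = sprintf("m%02d", 1:10),
                       response = rep(c(0, 10), each = 5))
  picked <- select_response_anchors(d2, kr = 2, seed = 1)
  expect_setequal(d2$response[match(picked, d2$id)], c(0, 10))

  # uniform responses on [4, 8]: the 10 anchors span >= 80% of the range
  set.seed(21)
  du <- tibble::tibble(id = sprintf("m%03d", 1:200),
                       response = runif(200, 4, 8))
  anchors <- select_response_anchors(du, kr = 10, seed = 2)
  vals <- du$response[match(anchors, du$id)]
  expect_gte(diff(range(vals)), 0.8 * diff(range(du$response)))

  expect_error(select_response_anchors(d10, kr = 11), "exceeds")
})

test_that("random structure anchors obey size and determinism contracts", {
  ids <- sprintf("m%03d", 1:500)
  a <- select_initial_structure_anchors(ids, round(0.15 * 500), seed = 4)
  expect_length(a, 75)
  expect_identical(a, select_initial_structure_anchors(ids, 75, seed = 4))
  expect_false(identical(a, select_initial_structure_anchors(ids, 75, seed = 5)))
  expect_setequal(select_initial_structure_anchors(ids, 500, seed = 1), ids)
  expect_error(select_initial_structure_anchors(ids, 501, seed = 1), "exceeds")
  # vanilla TR budget: 60% of the training samples
  expect_length(select_tr_anchors(sprintf("x%d", 1:100), seed = 1), 60)
})

test_that("early stopping requires consecutive stalled improvements", {
  expect_false(early_stop_check(c(0.9, 0.7, 0.5), 0.01, 2))
  expect_true(early_stop_check(c(0.7, 0.699, 0.6989), 0.01, 2))
  expect_false(early_stop_check(0.5, 0.01, 2))
  expect_false(early_stop_check(c(0.9, 0.7), 0.01, 2))       # one stall short
  expect_true(early_stop_check(c(0.9, 0.7, 0.7001, 0.7), 0.01, 2))
})

test_that("a single adaptive step equals a plain random-anchor fit", {
  d <- small_qsar(80)
  m1 <- adaptor_fit(d, steps = 1, seed = 6)
  ids <- sort(select_initial_structure_anchors(d$id, round(0.15 * 80), seed = 6))
  expect_identical(sort(m1$structure_anchors$id), ids)
  anchors <- d[match(ids, d$id), ]
  ra <- d[match(select_response_anchors(d, 10, seed = 6), d$id), ]
  direct <- fit_distance_regression(
    build_distance_matrix(anchors, anchors, "structure"),
    build_distance_matrix(anchors, ra, "response"), lambda = 0.05)
  expect_equal(m1$model$W, direct$W, ignore_attr = TRUE)
})

test_that("anchor sets grow by Ka, stay nested and disjoint from their additions", {
  d <- small_qsar(120)
  m <- adaptor_fit(d, steps = 4, anchor_fraction = 0.15, seed = 8)
  ka <- round(0.15 * 120)
  sizes <- vapply(m$anchor_sets, length, integer(1))
  expect_equal(sizes, (1:4) * ka)
  for (p in 2:4) {
    expect_true(all(m$anchor_sets[[p - 1]] %in% m$anchor_sets[[p]]))
    expect_length(intersect(m$anchor_star_sets[[p - 1]],
                            m$anchor_sets[[p - 1]]), 0)
  }
  # default fraction 0.15 with 4 steps reproduces the vanilla 60% budget
  expect_equal(sizes[4], round(0.6 * 120))
  # determinism: identical reruns
  m2 <- adaptor_fit(d, steps = 4, anchor_fraction = 0.15, seed = 8)
  expect_identical(m$anchor_sets, m2$anchor_sets)
  expect_identical(m$model$W, m2$model$W)
})

test_that("adaptive selection repairs the regions the first model got wrong", {
  d <- make_synthetic_qsar(300, seed = 17)
  m <- adaptor_fit(d, steps = 2, seed = 17)
  star1 <- d[d$id %in% m$anchor_star_sets[[1]], ]
  models <- step_models(m)
  err1 <- mean(abs(star1$response - predict(models[[1]], star1)$.pred))
  err2 <- mean(abs(star1$response - predict(models[[2]], star1)$.pred))
  expect_lt(err2, err1)
})

test_that("infeasible adaptive configurations fail before any fitting", {
  d <- small_qsar(40)
  expect_error(adaptor_fit(d, anchor_fraction = 0.3, steps = 4),
               "infeasible")
  expect_error(adaptor_fit(d[1:21, ], early_stopping = TRUE,
                           val_fraction = 0.01),
               "validation")
})

test_that("early stopping halts on a stalled validation trace", {
  d <- small_qsar(200, seed = 3)
  m <- adaptor_fit(d, steps = 4, early_stopping = TRUE, min_delta = 10,
                   patience = 2, seed = 3)
  # an absurdly large min_delta means no step counts as progress:
  # the loop must stop after patience + 1 evaluations
  expect_true(m$early_stopped)
  expect_equal(length(m$steps), 3)
  expect_length(m$val_history, 3)
  expect_length(m$validation_ids, 20)
})
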