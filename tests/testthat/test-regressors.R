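test_that("median regression stores and predicts the exact training median", {
  train <- tiny_class(n = 3)
  train$pic50 <- c(5, 7, 9)
  m <- fit_potency_model(train, "MR")
  expect_identical(m$median, 7)
  train2 <- tiny_class(n = 2)
  train2$pic50 <- c(6, 8)
  expect_identical(fit_potency_model(train2, "MR")$median, 7)

  test <- tiny_class(n = 5, seed = 55)
  m2 <- fit_potency_model(dplyr::mutate(tiny_class(n = 9), pic50 = rep(7.4, 9)), "MR")
  p <- predict(m2, test)
  expect_identical(p$y_pred, rep(7.4, 5))
  # MR training-set MAE equals mean absolute deviation from the median
  tr <- tiny_class(n = 20)
  mr <- fit_potency_model(tr, "MR")
  p_tr <- predict(mr, tr)
  expect_equal(mae(p_tr$y_true, p_tr$y_pred),
               mean(abs(tr$pic50 - median(tr$pic50))))
})

test_that("nearest-neighbour predictions follow Tanimoto similarity exactly", {
  train <- tiny_class(n = 8)
  test <- train[3, ]
  test$compound_id <- "probe"
  m1 <- fit_potency_model(train, "1NN")
  expect_equal(predict(m1, test)$y_pred, train$pic50[3])

  # three equally most-similar neighbours with potencies 6, 7, 8 average to 7
  fp_a <- c(rep(1L, 8), rep(0L, 8))
  mk <- function(id, fp, y) {
    tibble::tibble(compound_id = id, class_id = "K", pic50 = y,
                   subrange = assign_subrange(y), fingerprint = list(fp))
  }
  shared <- replace(fp_a, 9, 1L)  # same overlap with fp_a for all three
  train3 <- dplyr::bind_rows(mk("a", replace(fp_a, 9L, 1L), 6),
                             mk("b", replace(fp_a, 10L, 1L), 7),
                             mk("c", replace(fp_a, 11L, 1L), 8))
  probe <- mk("p", fp_a, 7)
  m3 <- fit_potency_model(train3, "3NN")
  expect_equal(predict(m3, probe)$y_pred, 7)

  # 1NN and 3NN agree when the nearest neighbour is replicated three times
  trainrep <- dplyr::bind_rows(mk("a1", fp_a, 6.5), mk("a2", fp_a, 6.5),
                               mk("a3", fp_a, 6.5),
                               mk("far", c(rep(0L, 8), rep(1L, 8)), 10))
  p1 <- predict(fit_potency_model(trainrep, "1NN"), probe)
  p3 <- predict(fit_potency_model(trainrep, "3NN"), probe)
  expect_equal(p1$y_pred, p3$y_pred)
  expect_error(fit_potency_model(train[1:2, ], "3NN"), "at least 3")
})

test_that("SVR selects C from the grid and drives training error down on clean SAR", {
  cfg <- synth_config(n_compounds = 200L, noise_sd = 0,
                      min_per_subrange = 20L, seed = 12L)
  cls <- generate_activity_class(cfg)
  m <- fit_potency_model(cls, "SVR", seed = 2L)
  expect_true(m$params$C %in% c(1, 10, 100, 1000))
  expect_equal(nrow(tidy(m)), 4L)
  # on noise-free, fingerprint-determined potencies the big-C training fit
  # is much tighter than the small-C fit
  strong <- fit_potency_model(cls, "SVR", grid = default_grid(svr_C = 1000),
                              seed = 2L)
  weak <- fit_potency_model(cls, "SVR", grid = default_grid(svr_C = 0.01),
                            seed = 2L)
  p_strong <- predict(strong, cls)
  p_weak <- predict(weak, cls)
  expect_lt(mae(p_strong$y_true, p_strong$y_pred), 0.2)
  expect_lt(mae(p_strong$y_true, p_strong$y_pred),
            mae(p_weak$y_true, p_weak$y_pred))
})

test_that("model fitting and prediction are reproducible under a fixed seed", {
  cls <- generate_activity_class(synth_config(n_compounds = 250L,
                                              min_per_subrange = 30L, seed = 4L))
  train <- cls[1:150, ]
  test <- cls[151:200, ]
  for (method in c("SVR", "RFR", "1NN", "MR")) {
    grid <- reduced_grid()
    a <- predict(fit_potency_model(train, method, grid = grid, seed = 9L), test)
    b <- predict(fit_potency_model(train, method, grid = grid, seed = 9L), test)
    expect_identical(a, b)
  }
})

test_that("RFR searches the stated tree grid and predicts sensibly", {
  cls <- generate_activity_class(synth_config(n_compounds = 220L,
                                              min_per_subrange = 25L, seed = 8L))
  plan <- random_5050_splits(cls, n_trials = 1, seed = 8)
  train <- cls[match(plan$train_ids[[1]], cls$compound_id), ]
  test <- cls[match(plan$test_ids[[1]], cls$compound_id), ]
  grid <- default_grid(rfr_num_trees = c(50L, 100L),
                       rfr_min_node_size = c(2L, 5L),
                       rfr_min_bucket = 1L, rfr_max_features = "sqrt")
  m <- fit_potency_model(train, "RFR", grid = grid, seed = 3L)
  expect_equal(nrow(tidy(m)), 4L)
  expect_true(m$params$num_trees %in% c(50L, 100L))
  p <- predict(m, test)
  p_mr <- predict(fit_potency_model(train, "MR"), test)
  expect_lt(mae(p$y_true, p$y_pred), mae(p_mr$y_true, p_mr$y_pred))
  g <- glance(m)
  expect_equal(g$method, "RFR")
  expect_equal(g$n_train, nrow(train))
})

test_that("cost selection supports the coefficient-of-determination control", {
  cls <- generate_activity_class(synth_config(n_compounds = 200L,
                                              min_per_subrange = 20L, seed = 14L))
  m <- fit_potency_model(cls[1:120, ], "SVR", cost = "R2", seed = 5L)
  expect_true(m$params$C %in% c(1, 10, 100, 1000))
  expect_equal(m$cost, "R2")
})

test_that("degenerate inputs are rejected or handled", {
  expect_error(fit_potency_model(tiny_class(0), "MR"), "empty")
  # tiny training sets fall back to a single validation split instead of CV
  small <- tiny_class(n = 5)
  m <- fit_potency_model(small, "SVR", seed = 1L)
  expect_true(m$params$C %in% c(1, 10, 100, 1000))
  # empty test set gives an empty result
  p <- predict(m, tiny_class(12)[0, ])
  expect_equal(nrow(p), 0L)
})
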