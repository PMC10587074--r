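test_that("error metrics match hand-computed values", {
  expect_equal(mae(c(5, 7, 9), c(5, 7, 9)), 0)
  expect_equal(mae(c(5, 7, 9), c(6, 7, 8)), 2 / 3)
  expect_equal(mae(c(5, 9), c(7, 7)), 2)
  expect_equal(rmse(c(5, 7, 9), c(5, 7, 9)), 0)
  expect_equal(rmse(c(5, 9), c(7, 7)), 2)  # equal residuals: RMSE = MAE
  expect_equal(rmse(c(5, 7, 9), c(6, 7, 8)), sqrt(2 / 3))
  expect_equal(r2_pearson(1:3, 2 * (1:3) + 1), 1)
  expect_equal(r2_pearson(c(1, 2, 3), c(1, 3, 2)), 0.25)
  expect_warning(r2c <- r2_pearson(1:5, rep(7.4, 5)), "constant")
  expect_true(is.na(r2c))
  expect_equal(r2_determination(c(5, 7, 9), c(5, 7, 9)), 1)
  expect_equal(r2_determination(c(5, 7, 9), rep(7, 3)), 0)
  expect_equal(r2_determination(c(5, 7, 9), c(6, 7, 8)), 0.75)
  expect_error(mae(1:3, 1:2), "lengths")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(r2_determination(c(7, 7), c(6, 8)), "constant")
})

test_that("metrics agree with brute-force loops to 1e-12 on random vectors", {
  withr::with_seed(31, {
    for (i in 1:100) {
      n <- sample(3:40, 1)
      y <- runif(n, 5, 11)
      yhat <- y + rnorm(n, 0, 0.7)
      s_abs <- 0
      s_sq <- 0
      for (j in seq_len(n)) {
        s_abs <- s_abs + abs(y[j] - yhat[j])
        s_sq <- s_sq + (y[j] - yhat[j])^2
      }
      expect_equal(mae(y, yhat), s_abs / n, tolerance = 1e-12)
      expect_equal(rmse(y, yhat), sqrt(s_sq / n), tolerance = 1e-12)
      mx <- sum(y) / n
      my <- sum(yhat) / n
      num <- sum((y - mx) * (yhat - my))
      den <- sqrt(sum((y - mx)^2) * sum((yhat - my)^2))
      expect_equal(r2_pearson(y, yhat), (num / den)^2, tolerance = 1e-12)
      expect_equal(r2_determination(y, yhat),
                   1 - s_sq / sum((y - mx)^2), tolerance = 1e-12)
      expect_gte(rmse(y, yhat), mae(y, yhat))  # power-mean inequality
    }
  })
})

test_that("sub-range decomposition conserves counts and weights global MAE", {
  withr::with_seed(8, {
    y <- runif(60, 5, 11)
    pred <- tibble::tibble(
      compound_id = as.character(1:60), y_true = y,
      y_pred = y + rnorm(60, 0, 1), subrange = assign_subrange(y),
      method = "X", class_id = "C", trial = 0L)
    out <- decompose_by_subrange(pred)
    expect_equal(nrow(out), 4L)
    glob <- out[out$scope == "GLOBAL", ]
    subs <- out[out$scope != "GLOBAL", ]
    expect_equal(sum(subs$n), glob$n)
    expect_equal(sum(subs$n * subs$mae) / sum(subs$n), glob$mae)
  })
})

test_that("decomposition flags empty sub-ranges and keeps GLOBAL equal to the only populated one", {
  pred <- tibble::tibble(y_true = c(7.2, 8.1, 8.8), y_pred = c(7.0, 8.0, 9.0),
                         subrange = assign_subrange(c(7.2, 8.1, 8.8)))
  out <- decompose_by_subrange(pred)
  expect_equal(out$n[out$scope == "LOW"], 0L)
  expect_equal(out$n[out$scope == "HIGH"], 0L)
  expect_true(is.na(out$mae[out$scope == "LOW"]))
  expect_equal(out$mae[out$scope == "GLOBAL"], out$mae[out$scope == "MID"])
})

test_that("median-regression sub-range errors reproduce the 2.0-unit mechanism", {
  # training median 7.5; test compounds at 5.5 / 7.5 / 9.5: the constant
  # predictor is exact mid-range and off by 2 in the outer sub-ranges
  pred <- tibble::tibble(y_true = c(5.5, 7.5, 9.5), y_pred = rep(7.5, 3),
                         subrange = assign_subrange(c(5.5, 7.5, 9.5)))
  out <- decompose_by_subrange(pred)
  expect_equal(out$mae[match(c("LOW", "MID", "HIGH"), out$scope)],
               c(2, 0, 2))
})

test_that("signed-rank p-values match full enumeration on random paired lists", {
  withr::with_seed(77, {
    for (i in 1:20) {
      n <- 10
      x <- runif(n)
      y <- x + rnorm(n, sd = sample(c(0.2, 1, 3), 1)) *
        sample(c(0.5, 1), 1)
      scores <- tibble::tibble(
        method = rep(c("A", "B"), each = n), trial = rep(1:n, 2),
        value = c(x, y))
      p_pkg <- wilcoxon_pairwise(scores)$p_value
      expect_equal(p_pkg, signed_rank_enum_p(x, y), tolerance = 1e-12)
    }
  })
})

test_that("wilcoxon_pairwise yields one result per unordered pair and handles ties", {
  withr::with_seed(5, {
    scores <- tidyr::expand_grid(method = c("SVR", "RFR", "1NN", "3NN", "MR"),
                                 trial = 0:9) |>
      dplyr::mutate(value = runif(dplyr::n()))
    out <- wilcoxon_pairwise(scores)
    expect_equal(nrow(out), choose(5, 2))
    expect_equal(out$alpha, rep(0.005, 10))
    # identical lists: all differences zero -> p = 1, not significant
    same <- tibble::tibble(method = rep(c("A", "B"), each = 10),
                           trial = rep(1:10, 2), value = rep(1:10, 2))
    res <- wilcoxon_pairwise(same)
    expect_equal(res$p_value, 1)
    expect_false(res$significant)
    # constant shift of 1 across 10 trials is maximally significant
    shift <- tibble::tibble(method = rep(c("A", "B"), each = 10),
                            trial = rep(1:10, 2),
                            value = c(1:10, 2:11 + 0.001 * runif(10)))
    expect_lt(wilcoxon_pairwise(shift)$p_value, 0.005)
    expect_true(wilcoxon_pairwise(shift)$significant)
  })
})
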