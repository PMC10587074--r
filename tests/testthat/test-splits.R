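test_that("the ladder size sequence and per-sub-range counts are exact", {
  expect_identical(ladder_sizes(), c(6L, 12L, 18L, 30L, 48L, 78L, 126L, 204L, 330L))
  expect_equal(ladder_sizes()[1] / 3, 2)
  expect_equal(ladder_sizes()[2] / 3, 4)
  expect_true(all(ladder_sizes() %% 3 == 0))
})

test_that("random 50/50 splits partition each class and are replayable", {
  cls <- tiny_class(n = 100)
  plans <- random_5050_splits(cls, n_trials = 10, seed = 5)
  expect_equal(nrow(plans), 10L)
  for (i in seq_len(nrow(plans))) {
    tr <- plans$train_ids[[i]]
    te <- plans$test_ids[[i]]
    expect_length(tr, 50L)
    expect_length(te, 50L)
    expect_length(intersect(tr, te), 0L)
    expect_setequal(c(tr, te), cls$compound_id)
  }
  # different trials differ; same master seed replays identically
  expect_false(identical(plans$train_ids[[1]], plans$train_ids[[2]]))
  expect_identical(plans, random_5050_splits(cls, n_trials = 10, seed = 5))
  # odd class size: training set gets the extra compound
  odd <- random_5050_splits(tiny_class(n = 11), n_trials = 1, seed = 1)
  expect_length(odd$train_ids[[1]], 6L)
  expect_length(odd$test_ids[[1]], 5L)
  expect_error(random_5050_splits(tiny_class(n = 1)), "fewer than 2")
})

test_that("balanced ladders have exact per-sub-range counts, nesting, and a HIGH-keyed test set", {
  # class with sub-range counts (300, 400, 150): test set should take
  # 150 - 110 = 40 compounds from every sub-range
  withr::with_seed(21, {
    pic <- c(runif(300, 5, 6.9), runif(400, 7, 8.9), runif(150, 9, 11))
    cls <- tibble::tibble(class_id = "L", compound_id = as.character(seq_along(pic)),
                          pic50 = pic, subrange = assign_subrange(pic))
  })
  plans <- balanced_ladder_splits(cls, n_trials = 2, seed = 13)
  expect_equal(nrow(plans), 2L * 9L)
  sub_of <- setNames(as.character(cls$subrange), cls$compound_id)
  for (i in seq_len(nrow(plans))) {
    tr <- plans$train_ids[[i]]
    te <- plans$test_ids[[i]]
    expect_length(intersect(tr, te), 0L)
    counts <- table(sub_of[tr])
    expect_true(all(counts == plans$ladder_size[i] / 3))
    expect_true(all(table(sub_of[te]) == 40L))
  }
  # nesting within a trial; fixed test set across sizes
  t0 <- plans[plans$trial == 0, ]
  for (k in 2:9) {
    expect_true(all(t0$train_ids[[k - 1]] %in% t0$train_ids[[k]]))
    expect_identical(t0$test_ids[[k]], t0$test_ids[[1]])
  }
  expect_identical(plans, balanced_ladder_splits(cls, n_trials = 2, seed = 13))
})

test_that("balanced ladders refuse under-populated sub-ranges, naming them", {
  withr::with_seed(4, {
    pic <- c(runif(200, 5, 6.9), runif(200, 7, 8.9), runif(100, 9, 11))
    cls <- tibble::tibble(class_id = "S", compound_id = as.character(seq_along(pic)),
                          pic50 = pic, subrange = assign_subrange(pic))
  })
  expect_error(balanced_ladder_splits(cls), "HIGH")
})

test_that("imbalanced ladders sample whole-class proportions without quotas", {
  cls <- generate_activity_class(synth_config(n_compounds = 500L,
                                              min_per_subrange = 0L, seed = 6L))
  plans <- imbalanced_ladder_splits(cls, n_trials = 2, seed = 3)
  expect_equal(unique(plans$ladder_size), ladder_sizes())
  sub_of <- setNames(as.character(cls$subrange), cls$compound_id)
  big <- plans[plans$ladder_size == 330L & plans$trial == 0, ]
  expect_length(intersect(big$train_ids[[1]], big$test_ids[[1]]), 0L)
  # large-sample sub-range proportions track the class proportions
  prop_class <- prop.table(table(cls$subrange))
  prop_train <- prop.table(table(factor(sub_of[big$train_ids[[1]]],
                                        levels = names(prop_class))))
  suppressWarnings(
    chi <- chisq.test(table(factor(sub_of[big$train_ids[[1]]],
                                   levels = names(prop_class))),
                      p = as.numeric(prop_class))
  )
  expect_gt(chi$p.value, 0.001)
  expect_lt(max(abs(prop_train - prop_class)), 0.1)
})

test_that("split plans round-trip through JSON for exact replay", {
  cls <- tiny_class(n = 40)
  plans <- random_5050_splits(cls, n_trials = 2, seed = 19)
  f <- withr::local_tempfile(fileext = ".json")
  write_split_plans(plans, f)
  back <- read_split_plans(f)
  expect_equal(back, plans)
})
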