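# Orchestration of the three experiment families: distribution diagnostics,
# the global + sub-range benchmark on random 50/50 splits, and the
# balanced/imbalanced training-set ladders.

lookup_rows <- function(cls, ids) {
  cls[match(ids, cls$compound_id), , drop = FALSE]
}

# Fit one method on one plan's training rows and score its predictions on
# the plan's test rows, decomposed by sub-range.
run_plan_method <- function(cls, plan_row, method, grid, cost, seed,
                            keep_predictions = FALSE) {
  train <- lookup_rows(cls, plan_row$train_ids[[1L]])
  test <- lookup_rows(cls, plan_row$test_ids[[1L]])
  fit_seed <- derive_seed(seed, plan_row$class_id, plan_row$protocol,
                          plan_row$trial,
                          ifelse(is.na(plan_row$ladder_size), 0L,
                                 plan_row$ladder_size), method)
  model <- fit_potency_model(train, method, grid = grid, cost = cost,
                             seed = fit_seed)
  pred <- predict(model, test)
  pred$class_id <- plan_row$class_id
  pred$trial <- plan_row$trial
  pred$protocol <- plan_row$protocol
  pred$ladder_size <- plan_row$ladder_size
  metrics <- decompose_by_subrange(pred)
  list(metrics = metrics, predictions = if (keep_predictions) pred)
}

run_plans <- function(classes, plans, methods, grid, cost, seed,
                      keep_predictions = FALSE) {
  by_class <- split(classes, classes$class_id)
  out <- purrr::map(seq_len(nrow(plans)), function(i) {
    plan_row <- plans[i, , drop = FALSE]
    cls <- by_class[[plan_row$class_id]]
    purrr::map(methods, function(m) {
      run_plan_method(cls, plan_row, m, grid, cost, seed,
                      keep_predictions = keep_predictions)
    })
  })
  flat <- unlist(out, recursive = FALSE)
  list(
    metrics = dplyr::bind_rows(purrr::map(flat, "metrics")),
    predictions = if (keep_predictions) {
      dplyr::bind_rows(purrr::map(flat, "predictions"))
    }
  )
}

#' Potency distribution and similarity diagnostics
#'
#' Per-class summaries of the potency value distribution (median, quartiles,
#' per-sub-range counts, qualification) and of the pairwise Tanimoto
#' similarity of compounds within each potency sub-range — the structural
#' diagnostics that frame a benchmark run. Sub-ranges with fewer than two
#' compounds yield an empty similarity summary (`n_pairs = 0`, `NA`
#' statistics).
#'
#' @param classes Compound tibble with `class_id`, `pic50`, `subrange`,
#'   `fingerprint`.
#' @param min_per_subrange Qualification threshold (default 75).
#' @return A list of two tibbles: `class_summary` and `subrange_similarity`
#'   (per class and sub-range: `n`, `n_pairs`, similarity mean, median,
#'   quartiles).
#' @export
distribution_report <- function(classes, min_per_subrange = 75L) {
  check_columns(classes, c("class_id", "pic50", "subrange", "fingerprint"),
                "classes")
  qual <- qualify_classes(classes, min_per_subrange)
  summary <- classes |>
    dplyr::group_by(.data$class_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_pic50 = stats::median(.data$pic50),
      q25_pic50 = stats::quantile(.data$pic50, 0.25)[[1]],
      q75_pic50 = stats::quantile(.data$pic50, 0.75)[[1]],
      .groups = "drop"
    ) |>
    dplyr::left_join(qual[, c("class_id", "n_low", "n_mid", "n_high",
                              "qualified")], by = "class_id")
  sim <- classes |>
    dplyr::group_by(.data$class_id, .data$subrange) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      n <- nrow(g)
      if (n < 2L) {
        return(tibble::tibble(class_id = g$class_id[1], subrange = g$subrange[1],
                              n = n, n_pairs = 0L, mean_sim = NA_real_,
                              median_sim = NA_real_, q25_sim = NA_real_,
                              q75_sim = NA_real_))
      }
      S <- tanimoto_matrix(g)
      vals <- S[upper.tri(S)]
      tibble::tibble(class_id = g$class_id[1], subrange = g$subrange[1],
                     n = n, n_pairs = length(vals), mean_sim = mean(vals),
                     median_sim = stats::median(vals),
                     q25_sim = stats::quantile(vals, 0.25)[[1]],
                     q75_sim = stats::quantile(vals, 0.75)[[1]])
    }) |>
    dplyr::bind_rows()
  list(class_summary = summary, subrange_similarity = sim)
}

#' Run the global + sub-range potency prediction benchmark
#'
#' For each class: 10 (by default) independent random 50/50 train/test
#' splits; for each split and method: fit (with grid-search model selection),
#' predict the test set, and score globally and per potency sub-range. Then
#' compare methods pairwise per class and metric with the Wilcoxon
#' signed-rank test over the per-trial metric values.
#'
#' @param classes Compound tibble (one or more qualified classes).
#' @param methods Methods to run (default all five).
#' @param n_trials Trials per class (default 10).
#' @param seed Master seed; every derived stage seed comes from it.
#' @param grid Hyperparameter grid (default [default_grid()]).
#' @param cost Model-selection cost, `"MAE"` or `"R2"`.
#' @param keep_predictions Keep per-compound predictions in the result.
#' @param alpha,n_correction Significance threshold parameters passed to
#'   [wilcoxon_pairwise()].
#' @return A list: `metrics` (per method x class x trial x scope),
#'   `significance` (per class x metric x method pair), `plans`, and
#'   optionally `predictions`.
#' @export
#' @examples
#' \donttest{
#' suite <- generate_benchmark_suite(2, synth_config(n_compounds = 300,
#'                                                   min_per_subrange = 40))
#' bench <- run_benchmark(suite, methods = c("1NN", "MR"), n_trials = 3,
#'                        seed = 7)
#' }
run_benchmark <- function(classes, methods = c("SVR", "RFR", "1NN", "3NN", "MR"),
                          n_trials = 10L, seed = 1L, grid = default_grid(),
                          cost = c("MAE", "R2"), keep_predictions = FALSE,
                          alpha = 0.005, n_correction = 10L) {
  cost <- match.arg(cost)
  plans <- random_5050_splits(classes, n_trials = n_trials, seed = seed)
  res <- run_plans(classes, plans, methods, grid, cost, seed,
                   keep_predictions = keep_predictions)
  significance <- res$metrics |>
    dplyr::filter(.data$scope == "GLOBAL") |>
    tidyr::pivot_longer(cols = c("mae", "rmse", "r2"), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$class_id, .data$metric) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      out <- wilcoxon_pairwise(g, alpha = alpha, n_correction = n_correction)
      out$class_id <- g$class_id[1]
      out$metric <- g$metric[1]
      out
    }) |>
    dplyr::bind_rows() |>
    dplyr::relocate(dplyr::all_of(c("class_id", "metric")))
  list(metrics = res$metrics, significance = significance, plans = plans,
       predictions = res$predictions)
}

#' Run the training-set ladder experiment
#'
#' For each class and trial: nested sub-range-balanced (or imbalanced
#' control) training sets of increasing size, one fixed test set per trial,
#' all methods fitted at every size and scored per potency sub-range. This
#' is the experiment that separates sub-range behaviour: MID-sub-range error
#' stays at the median-regression level at all sizes while LOW/HIGH error
#' falls with training-set size for the learning methods.
#'
#' @inheritParams run_benchmark
#' @param protocol `"balanced"` (default) or `"imbalanced"`.
#' @param sizes Ladder sizes (default [ladder_sizes()]).
#' @return A list: `metrics` (per method x class x trial x size x scope),
#'   `plans`, and optionally `predictions`.
#' @export
run_ladder <- function(classes, methods = c("SVR", "RFR", "1NN", "3NN", "MR"),
                       protocol = c("balanced", "imbalanced"), n_trials = 10L,
                       seed = 1L, grid = default_grid(), cost = c("MAE", "R2"),
                       sizes = ladder_sizes(), keep_predictions = FALSE) {
  protocol <- match.arg(protocol)
  cost <- match.arg(cost)
  plans <- if (protocol == "balanced") {
    balanced_ladder_splits(classes, n_trials = n_trials, seed = seed,
                           sizes = sizes)
  } else {
    imbalanced_ladder_splits(classes, n_trials = n_trials, seed = seed,
                             sizes = sizes)
  }
  res <- run_plans(classes, plans, methods, grid, cost, seed,
                   keep_predictions = keep_predictions)
  list(metrics = res$metrics, plans = plans, predictions = res$predictions)
}

#' Write metric records as tidy TSV
#'
#' @param metrics Metric tibble (from [run_benchmark()] or [run_ladder()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  readr::write_tsv(metrics, path)
  invisible(path)
}
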