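#' Regression error metrics
#'
#' Mean absolute error, root mean squared error, squared Pearson correlation,
#' and the coefficient of determination, as used to score potency
#' predictions. `r2_pearson` is undefined (returned as `NA` with a warning)
#' when either vector is constant — the median-regression control always
#' triggers this. `r2_determination` (`1 - SS_res / SS_tot`) can be negative
#' and is used only as an alternative model-selection cost.
#'
#' @param y Observed values.
#' @param yhat,x Predicted values / second vector.
#' @return A single number (`NA` for undefined `r2_pearson`).
#' @export
#' @examples
#' mae(c(5, 7, 9), c(6, 7, 8))
#' rmse(c(5, 7, 9), c(6, 7, 8))
mae <- function(y, yhat) {
  check_metric_input(y, yhat)
  mean(abs(y - yhat))
}

#' @rdname mae
#' @export
rmse <- function(y, yhat) {
  check_metric_input(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' @rdname mae
#' @export
r2_pearson <- function(x, y) {
  check_metric_input(x, y)
  if (length(x) < 2L) {
    stop("r2_pearson needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: squared Pearson correlation is undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' @rdname mae
#' @export
r2_determination <- function(y, yhat) {
  check_metric_input(y, yhat)
  if (length(y) < 2L) {
    stop("r2_determination needs at least 2 observations", call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("constant observed vector: coefficient of determination is undefined",
         call. = FALSE)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

check_metric_input <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop("vectors have different lengths", call. = FALSE)
  }
  if (length(y) == 0L) {
    stop("empty input", call. = FALSE)
  }
  invisible(NULL)
}

#' Decompose prediction errors by potency sub-range
#'
#' Scores a prediction table globally and separately over the test compounds
#' whose *observed* potency falls into each sub-range (experimental potency
#' defines sub-range membership). Empty sub-ranges yield a row with `n = 0`
#' and `NA` metrics.
#'
#' @param result Prediction tibble with columns `y_true`, `y_pred`,
#'   `subrange`, and any identifying columns (`method`, `class_id`, `trial`,
#'   `ladder_size`), which are carried through.
#' @return A tibble with one row per scope (`GLOBAL`, `LOW`, `MID`, `HIGH`)
#'   per identifying group: `n`, `mae`, `rmse`, `r2` (squared Pearson
#'   correlation of observed vs predicted, `NA` when undefined).
#' @export
#' @examples
#' pred <- tibble::tibble(y_true = c(5.5, 7.5, 9.5), y_pred = 7.5,
#'                        subrange = assign_subrange(c(5.5, 7.5, 9.5)))
#' decompose_by_subrange(pred)
decompose_by_subrange <- function(result) {
  check_columns(result, c("y_true", "y_pred", "subrange"), "result")
  id_cols <- intersect(c("method", "class_id", "trial", "protocol",
                         "ladder_size"), names(result))
  score <- function(df, scope, ids) {
    if (nrow(df) == 0L) {
      return(dplyr::bind_cols(ids, tibble::tibble(
        scope = scope, n = 0L, mae = NA_real_, rmse = NA_real_, r2 = NA_real_)))
    }
    r2 <- if (nrow(df) >= 2L && stats::sd(df$y_true) > 0 &&
              stats::sd(df$y_pred) > 0) {
      stats::cor(df$y_true, df$y_pred)^2
    } else {
      NA_real_
    }
    dplyr::bind_cols(ids, tibble::tibble(
      scope = scope, n = nrow(df),
      mae = mae(df$y_true, df$y_pred),
      rmse = rmse(df$y_true, df$y_pred),
      r2 = r2))
  }
  groups <- if (length(id_cols) > 0L) {
    result |> dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
      dplyr::group_split()
  } else {
    list(result)
  }
  purrr::map(groups, function(g) {
    ids <- if (length(id_cols) > 0L) {
      tibble::as_tibble(g[1, id_cols, drop = FALSE])
    } else {
      tibble::tibble(.rows = 1L)
    }
    dplyr::bind_rows(
      score(g, "GLOBAL", ids),
      score(g[g$subrange == "LOW", , drop = FALSE], "LOW", ids),
      score(g[g$subrange == "MID", , drop = FALSE], "MID", ids),
      score(g[g$subrange == "HIGH", , drop = FALSE], "HIGH", ids)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(scope = factor(.data$scope,
                                 levels = c("GLOBAL", "LOW", "MID", "HIGH")))
}

# Exact two-sided Wilcoxon signed-rank p-value with the zero-discard
# convention; exact null (stats::psignrank) when |differences| are untied,
# normal approximation with tie correction otherwise.
signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(1)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (!any(duplicated(abs(d)))) {
    p <- 2 * min(stats::psignrank(W, n), 1 - stats::psignrank(W - 1, n))
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(ties^3 - ties) / 48)
  if (sigma == 0) {
    return(1)
  }
  min(1, 2 * stats::pnorm(-abs(W - mu) / sigma))
}

#' Pairwise Wilcoxon signed-rank comparison of methods
#'
#' Compares per-trial metric values of every unordered method pair with a
#' two-sided Wilcoxon signed-rank test (exact null distribution, zeros
#' discarded) and flags significance against a Bonferroni-style threshold:
#' with 5 methods there are exactly `C(5,2) = 10` pairs, and `p < alpha`
#' with `alpha = 0.005` corresponds to a familywise 0.05 level corrected for
#' `n_correction = 10` comparisons.
#'
#' @param scores Tibble with columns `method`, `trial`, `value` (one metric
#'   value per method and trial; trials must match across methods).
#' @param alpha Corrected significance threshold (default 0.005).
#' @param n_correction Number of comparisons the threshold corrects for
#'   (default 10; recorded in the output).
#' @return A tibble with one row per method pair: `method_a`, `method_b`,
#'   `p_value`, `alpha`, `n_correction`, `significant`.
#' @export
#' @examples
#' scores <- tidyr::expand_grid(method = c("SVR", "MR"), trial = 0:9) |>
#'   dplyr::mutate(value = ifelse(method == "SVR", 0.5, 1.0) + trial / 100)
#' wilcoxon_pairwise(scores)
wilcoxon_pairwise <- function(scores, alpha = 0.005, n_correction = 10L) {
  check_columns(scores, c("method", "trial", "value"), "scores")
  wide <- scores |>
    dplyr::select(dplyr::all_of(c("method", "trial", "value"))) |>
    tidyr::pivot_wider(names_from = "method", values_from = "value") |>
    dplyr::arrange(.data$trial)
  methods <- setdiff(names(wide), "trial")
  if (length(methods) < 2L) {
    stop("need at least two methods to compare", call. = FALSE)
  }
  pairs <- utils::combn(methods, 2L)
  purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- wide[[pairs[1, j]]]
    b <- wide[[pairs[2, j]]]
    keep <- !is.na(a) & !is.na(b)
    p <- if (sum(keep) == 0L) NA_real_ else signed_rank_p(a[keep], b[keep])
    tibble::tibble(method_a = pairs[1, j], method_b = pairs[2, j],
                   n_trials = sum(keep), p_value = p, alpha = alpha,
                   n_correction = as.integer(n_correction),
                   significant = !is.na(p) & p < alpha)
  }) |>
    dplyr::bind_rows()
}
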