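#' Potency sub-range labels
#'
#' The three pIC50 bands used to stratify activity classes: LOW `[5, 7)`,
#' MID `[7, 9)`, HIGH `[9, 11]`. Half-open intervals cover the continuum
#' without gaps; the band edges are configurable for sensitivity checks.
#'
#' @param pic50 Numeric vector of pIC50 values, all inside `[5, 11]`.
#' @param breaks Interior band boundaries, default `c(7, 9)`.
#' @return A factor with levels `LOW`, `MID`, `HIGH`.
#' @export
#' @examples
#' assign_subrange(c(5, 6.9, 7, 8.9, 9, 11))
assign_subrange <- function(pic50, breaks = c(7, 9)) {
  stopifnot(is.numeric(pic50), length(breaks) == 2L, breaks[1] < breaks[2])
  bad <- which(!is.na(pic50) & (pic50 < 5 | pic50 > 11))
  if (length(bad) > 0L) {
    stop(sprintf("pIC50 outside [5, 11] at position(s) %s (value(s) %s)",
                 paste(utils::head(bad, 5), collapse = ", "),
                 paste(utils::head(pic50[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  lab <- ifelse(pic50 < breaks[1], "LOW", ifelse(pic50 < breaks[2], "MID", "HIGH"))
  factor(lab, levels = c("LOW", "MID", "HIGH"))
}

#' Curate raw compound records
#'
#' Applies the compound-level filters used to build benchmark activity
#' classes: keep pIC50 inside `[5, 11]`, drop compounds with a known
#' molecular mass above `mass_max` (records without a mass are retained), and
#' label each survivor with its potency sub-range. Rows with a non-numeric
#' potency are skipped with a warning naming the rows. Input order of
#' survivors is preserved, and curation is idempotent.
#'
#' ChEMBL-specific extraction filters (target relationship and confidence,
#' measurement-error flags) are assumed applied upstream; an assay
#' interference filter can be supplied as a hook but defaults to
#' pass-through.
#'
#' @param records Data frame with at least a `pic50` column; optional
#'   `mol_mass` (Da), and any identifier/fingerprint columns, which pass
#'   through untouched.
#' @param mass_max Maximum retained molecular mass in Da (default 1000).
#' @param interference_filter Optional function taking the curated tibble and
#'   returning a logical keep-vector (hook for assay-interference screens).
#' @return A tibble of surviving records with a `subrange` column.
#' @export
#' @examples
#' raw <- data.frame(compound_id = c("a", "b", "c"), pic50 = c(4.9, 6.2, 9.5))
#' curate(raw)
curate <- function(records, mass_max = 1000, interference_filter = NULL) {
  check_columns(records, "pic50", "records")
  out <- tibble::as_tibble(records)
  pic <- suppressWarnings(as.numeric(out$pic50))
  bad <- which(is.na(pic) & !is.na(out$pic50))
  if (length(bad) > 0L) {
    warning(sprintf("skipping %d row(s) with non-numeric potency: row(s) %s",
                    length(bad), paste(utils::head(bad, 10), collapse = ", ")))
  }
  out$pic50 <- pic
  keep <- !is.na(pic) & pic >= 5 & pic <= 11
  if ("mol_mass" %in% names(out)) {
    keep <- keep & (is.na(out$mol_mass) | out$mol_mass <= mass_max)
  }
  out <- out[keep, , drop = FALSE]
  out$subrange <- assign_subrange(out$pic50)
  if (!is.null(interference_filter)) {
    out <- out[interference_filter(out), , drop = FALSE]
  }
  out
}

#' Qualify a single activity class for benchmarking
#'
#' A class qualifies when every potency sub-range holds at least
#' `min_per_subrange` compounds.
#'
#' @param cls Curated class tibble with a `subrange` column.
#' @param min_per_subrange Minimum compounds per sub-range (default 75).
#' @return `TRUE` or `FALSE`.
#' @export
qualify_class <- function(cls, min_per_subrange = 75L) {
  if (nrow(cls) == 0L) {
    return(FALSE)
  }
  check_columns(cls, "subrange", "cls")
  counts <- table(factor(cls$subrange, levels = c("LOW", "MID", "HIGH")))
  all(counts >= min_per_subrange)
}

#' Summarise and qualify activity classes
#'
#' @param classes Curated compound tibble with `class_id` and `subrange`
#'   columns (one or several classes).
#' @param min_per_subrange Minimum compounds per sub-range (default 75).
#' @return A tibble with one row per class: total and per-sub-range counts,
#'   median pIC50, and the `qualified` flag.
#' @export
#' @examples
#' suite <- generate_benchmark_suite(2, synth_config(n_compounds = 400), seed = 7)
#' qualify_classes(suite)
qualify_classes <- function(classes, min_per_subrange = 75L) {
  check_columns(classes, c("class_id", "pic50", "subrange"), "classes")
  classes |>
    dplyr::group_by(.data$class_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_low = sum(.data$subrange == "LOW"),
      n_mid = sum(.data$subrange == "MID"),
      n_high = sum(.data$subrange == "HIGH"),
      median_pic50 = stats::median(.data$pic50),
      .groups = "drop"
    ) |>
    dplyr::mutate(qualified = pmin(.data$n_low, .data$n_mid, .data$n_high) >=
                    min_per_subrange)
}
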