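#' Fingerprint / hex-string conversion
#'
#' Fingerprints are serialised in CSV files as hex strings, four bits per
#' character, most significant bit first, so a 2048-bit fingerprint is 512
#' characters. `hex_to_fp` inverts `fp_to_hex` exactly.
#'
#' @param fp Integer/logical 0/1 vector whose length is a multiple of 4.
#' @param hex Hex string.
#' @return `fp_to_hex`: a hex string; `hex_to_fp`: an integer 0/1 vector.
#' @export
#' @examples
#' fp_to_hex(c(1, 0, 1, 0, 1, 1, 1, 1))
#' hex_to_fp("af")
fp_to_hex <- function(fp) {
  fp <- as.integer(fp)
  if (length(fp) %% 4L != 0L) {
    stop("fingerprint length must be a multiple of 4", call. = FALSE)
  }
  nib <- matrix(fp, nrow = 4L)
  vals <- as.integer(c(8, 4, 2, 1) %*% nib)
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[vals + 1L], collapse = "")
}

#' @rdname fp_to_hex
#' @export
hex_to_fp <- function(hex) {
  chars <- strsplit(tolower(hex), "", fixed = TRUE)[[1L]]
  vals <- strtoi(chars, base = 16L)
  if (anyNA(vals)) {
    stop("malformed fingerprint hex string", call. = FALSE)
  }
  as.integer(rbind(vals %/% 8L %% 2L, vals %/% 4L %% 2L,
                   vals %/% 2L %% 2L, vals %% 2L))
}

#' Write / read an activity class as CSV
#'
#' One row per compound with columns `compound_id`, `smiles`, `pIC50`,
#' `fingerprint_hex`, `series_id` (and `class_id` when present). pIC50 values
#' are written with a round-trip-exact decimal representation, so
#' `read_class_csv(write_class_csv(cls))` reproduces the class
#' field-for-field. On read, potencies outside `[5, 11]` and malformed rows
#' are rejected with the offending row number; a missing potency column is a
#' schema error.
#'
#' @param cls Activity-class tibble (as from [generate_activity_class()] or
#'   [curate()]).
#' @param path File path.
#' @param class_id Class id assigned on read when the file has no `class_id`
#'   column; defaults to the file name without extension.
#' @return `write_class_csv` returns `path` invisibly; `read_class_csv`
#'   returns the class tibble.
#' @export
#' @examples
#' cls <- generate_activity_class(synth_config(n_compounds = 50,
#'                                             min_per_subrange = 0))
#' f <- tempfile(fileext = ".csv")
#' write_class_csv(cls, f)
#' cls2 <- read_class_csv(f)
write_class_csv <- function(cls, path) {
  check_columns(cls, c("compound_id", "pic50", "fingerprint"), "cls")
  flat <- tibble::tibble(
    compound_id = cls$compound_id,
    class_id = if ("class_id" %in% names(cls)) cls$class_id else NA_character_,
    smiles = if ("smiles" %in% names(cls)) cls$smiles else NA_character_,
    pIC50 = format(cls$pic50, digits = 17, trim = TRUE, scientific = FALSE),
    fingerprint_hex = vapply(cls$fingerprint, fp_to_hex, character(1)),
    series_id = if ("series_id" %in% names(cls)) cls$series_id else NA_integer_
  )
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' @rdname write_class_csv
#' @export
read_class_csv <- function(path, class_id = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character())
  names(raw)[tolower(names(raw)) %in% c("pic50", "pic_50")] <- "pIC50"
  required <- c("compound_id", "pIC50", "fingerprint_hex")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop(sprintf("class CSV '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pic <- suppressWarnings(as.numeric(raw$pIC50))
  bad <- which(is.na(pic) | pic < 5 | pic > 11)
  if (length(bad) > 0L) {
    stop(sprintf("invalid pIC50 (missing, non-numeric, or outside [5, 11]) at data row(s) %s of '%s'",
                 paste(utils::head(bad, 10), collapse = ", "), path),
         call. = FALSE)
  }
  fps <- lapply(seq_along(raw$fingerprint_hex), function(i) {
    tryCatch(hex_to_fp(raw$fingerprint_hex[[i]]),
             error = function(e) {
               stop(sprintf("malformed fingerprint at data row %d of '%s'", i, path),
                    call. = FALSE)
             })
  })
  lens <- lengths(fps)
  if (length(unique(lens)) > 1L) {
    stop(sprintf("inconsistent fingerprint lengths in '%s'", path), call. = FALSE)
  }
  cid <- if ("class_id" %in% names(raw) && any(nzchar(raw$class_id))) {
    raw$class_id
  } else if (!is.null(class_id)) {
    class_id
  } else {
    sub("\\.[^.]*$", "", basename(path))
  }
  tibble::tibble(
    compound_id = raw$compound_id,
    class_id = cid,
    smiles = if ("smiles" %in% names(raw)) dplyr::na_if(raw$smiles, "") else NA_character_,
    pic50 = pic,
    subrange = assign_subrange(pic),
    series_id = if ("series_id" %in% names(raw)) {
      suppressWarnings(as.integer(raw$series_id))
    } else {
      NA_integer_
    },
    fingerprint = fps
  )
}
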