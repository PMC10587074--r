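# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
# RNG kind is pinned so the same seed gives the same draws on any platform.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Derive a reproducible sub-seed
#'
#' Hashes a master seed together with an arbitrary set of labels (class id,
#' trial index, protocol, ladder size, ...) into a positive integer seed, so
#' that every stage of an experiment draws from an independent, replayable
#' stream. FNV-1a over the label string, reduced modulo 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param ... Labels (coerced to character) identifying the consumer.
#' @return A single integer in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(42, "CHEMBL204", 3, "RANDOM_5050")
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "\x1f")
  bytes <- utf8ToInt(key)
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(h, b)
    # FNV prime 16777619, kept in double precision below 2^53
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646L) + 1L
}

# Assert that a data frame has the columns a pipeline stage needs.
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Stack a list-column of equal-length bit vectors into an integer matrix.
fp_matrix <- function(x) {
  fps <- if (is.data.frame(x)) x$fingerprint else x
  if (is.matrix(fps)) {
    return(fps)
  }
  if (length(fps) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 0L))
  }
  lens <- lengths(fps)
  if (length(unique(lens)) != 1L) {
    stop("fingerprints have unequal lengths", call. = FALSE)
  }
  matrix(as.integer(unlist(fps, use.names = FALSE)),
         nrow = length(fps), ncol = lens[[1L]], byrow = TRUE)
}
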