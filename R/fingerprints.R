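#' Folded ECFP4 fingerprints from SMILES
#'
#' Computes extended-connectivity fingerprints of bond diameter 4 (radius 2)
#' with OpenBabel (via \pkg{ChemmineOB}) and folds them by bitwise OR to a
#' fixed length. The same SMILES always yields the same bits within a toolkit
#' version; bit assignments are not comparable across toolkit versions.
#'
#' @param smiles Character vector of SMILES strings.
#' @param n_bits Folded fingerprint length (default 2048).
#' @return A list of integer 0/1 vectors of length `n_bits`, one per input.
#' @export
#' @examples
#' \dontrun{
#' fps <- ecfp4(c("CCO", "c1ccccc1"))
#' tanimoto(fps[[1]], fps[[2]])
#' }
ecfp4 <- function(smiles, n_bits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L, n_bits >= 1L)
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("ecfp4() requires the ChemmineOB package", call. = FALSE)
  }
  lapply(smiles, function(s) {
    raw_fp <- tryCatch(
      ChemmineOB::forEachMol("SMILES", s, function(mol) {
        ChemmineOB::fingerprint_OB(list(mol), "ECFP4")
      })[[1L]],
      error = function(e) {
        stop(sprintf("cannot parse SMILES '%s': %s", s, conditionMessage(e)),
             call. = FALSE)
      }
    )
    bits <- as.integer(raw_fp)
    if (sum(bits) == 0L) {
      stop(sprintf("SMILES '%s' produced an empty fingerprint", s),
           call. = FALSE)
    }
    folded <- integer(n_bits)
    folded[unique((which(bits == 1L) - 1L) %% n_bits) + 1L] <- 1L
    folded
  })
}

#' Tanimoto similarity between two binary fingerprints
#'
#' `|a AND b| / |a OR b|` over set bits. Symmetric, bounded in \[0, 1\], and 1
#' exactly for identical non-empty bit sets. The similarity of two all-zero
#' fingerprints is undefined set arithmetic; by convention it is reported as
#' `all_zero` (default 1, the identical-object reading) with a warning.
#'
#' @param a,b Integer/logical 0/1 vectors of equal length.
#' @param all_zero Value returned when both fingerprints are empty.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' tanimoto(c(1, 1, 0, 1), c(1, 0, 1, 1))
tanimoto <- function(a, b, all_zero = 1) {
  if (length(a) != length(b)) {
    stop("fingerprint lengths differ", call. = FALSE)
  }
  a <- as.logical(a)
  b <- as.logical(b)
  union_n <- sum(a | b)
  if (union_n == 0L) {
    warning("both fingerprints are all-zero; returning the configured convention value")
    return(all_zero)
  }
  sum(a & b) / union_n
}

#' Pairwise Tanimoto similarity matrix
#'
#' Computes all pairwise Tanimoto similarities between two fingerprint sets.
#' `tanimoto_matrix(A, A)` is the Tanimoto kernel: symmetric, unit diagonal,
#' and positive semidefinite, as required for kernel support vector
#' regression.
#'
#' @param A,B Lists of 0/1 vectors (or 0/1 matrices, one fingerprint per row)
#'   of a common length. `B` defaults to `A`.
#' @param all_zero Similarity assigned when both fingerprints are empty.
#' @return A `length(A)` by `length(B)` numeric matrix.
#' @export
#' @examples
#' fps <- list(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
#' tanimoto_matrix(fps)
tanimoto_matrix <- function(A, B = A, all_zero = 1) {
  MA <- fp_matrix(A)
  MB <- fp_matrix(B)
  if (nrow(MA) == 0L || nrow(MB) == 0L) {
    return(matrix(numeric(0), nrow = nrow(MA), ncol = nrow(MB)))
  }
  if (ncol(MA) != ncol(MB)) {
    stop("fingerprint lengths differ between the two sets", call. = FALSE)
  }
  inter <- MA %*% t(MB)
  union <- outer(rowSums(MA), rowSums(MB), "+") - inter
  out <- inter / union
  if (any(union == 0)) {
    warning("all-zero fingerprint pair(s); using the configured convention value")
    out[union == 0] <- all_zero
  }
  out
}
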