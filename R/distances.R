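## Pairwise CDR3 distance ---------------------------------------------------

#' Normalized edit distance between CDR3 amino-acid sequences
#'
#' Global-alignment edit distance with unit mismatch and unit gap costs
#' (Levenshtein), divided by the longer sequence length, so values lie in
#' `[0, 1]` with 0 on the diagonal. This replaces multiple alignment +
#' maximum-likelihood trees as the substrate for neighbor joining.
#'
#' @param sequences character vector of CDR3 amino-acid sequences; names are
#'   used as labels, defaulting to the sequences themselves (which must then
#'   be unique)
#' @return symmetric numeric matrix with zero diagonal and the labels as
#'   dimnames
#' @export
pairwise_cdr3_distance <- function(sequences) {
  if (length(sequences) == 0) stop("validation error: no sequences given")
  check_aa(sequences)
  labels <- names(sequences)
  if (is.null(labels)) labels <- sequences
  if (anyDuplicated(labels)) {
    stop("validation error: duplicated sequence labels")
  }
  raw <- utils::adist(sequences)  # unit-cost global alignment, in C
  L <- nchar(sequences)
  denom <- outer(L, L, pmax)
  d <- raw / denom
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  d
}

#' Validate a labeled distance matrix
#'
#' Checks squareness, labeling, symmetry (within `tol`), a zero diagonal and
#' non-negativity; errors otherwise.
#'
#' @param d matrix to check
#' @param tol symmetry tolerance
#' @return `TRUE`, invisibly
#' @export
validate_distance_matrix <- function(d, tol = 1e-12) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) stop("distance matrix must be labeled")
  if (any(abs(d - t(d)) > tol)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  invisible(TRUE)
}
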