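#' Zero replacement and closure of a count table
#'
#' Adds a uniform pseudocount to every entry of a sample-by-ASV count matrix
#' and closes each row to proportions summing to one. Compositional analyses
#' (notably the centered log-ratio transform) require strictly positive
#' parts; sequencing count tables are sparse, so a small uniform offset is
#' applied before closure. The offset is deliberately simple and
#' reproducible rather than tied to detection-limit heuristics.
#'
#' @param counts non-negative numeric matrix, samples in rows, ASVs in
#'   columns.
#' @param pseudocount positive offset added to every count before closure
#'   (default 1).
#' @return matrix of strictly positive proportions; each row sums to 1.
#' @seealso [clr_transform()]
#' @export
replace_zeros <- function(counts, pseudocount = 1) {
  counts <- as_weight_matrix(counts)
  check_nonnegative_matrix(counts, "count table")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stopf("pseudocount must be a single positive number")
  zero_rows <- rowSums(counts) == 0
  if (any(zero_rows)) {
    ids <- rownames(counts)[zero_rows]
    if (is.null(ids)) ids <- which(zero_rows)
    stopf("all-zero sample row(s): %s", paste(ids, collapse = ", "))
  }
  x <- counts + pseudocount
  x / rowSums(x)
}

#' Centered log-ratio transform
#'
#' Maps each row of a strictly positive composition to
#' `clr(x)_i = ln(x_i / g(x))`, where `g(x)` is the row geometric mean. The
#' transform is scale-invariant (multiplying a sample by any positive
#' constant, e.g. its sequencing depth, leaves it unchanged) and every
#' transformed row sums to zero.
#'
#' @param prop strictly positive matrix (rows are samples); typically the
#'   output of [replace_zeros()].
#' @return matrix of clr values with the same dimnames; rows sum to 0.
#' @export
clr_transform <- function(prop) {
  prop <- as_weight_matrix(prop)
  if (anyNA(prop) || any(prop <= 0))
    stopf("clr transform requires strictly positive entries")
  lx <- log(prop)
  lx - rowMeans(lx)
}
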