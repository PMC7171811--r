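#' Shannon entropy of one alignment column
#'
#' Entropy in bits of the state frequencies of a column, across all
#' sequences of the alignment (not just query + reference). By default the
#' five informative states A, C, G, T and gap are counted and N (missing
#' information) is excluded with frequencies renormalized, since N carries
#' no state information; a column that is entirely N has entropy 0. With
#' `include_missing = TRUE`, N is counted as a sixth state instead.
#'
#' Values lie in `[0, log2(5)]` (or `[0, log2(6)]` with missing included):
#' 0 for a uniform column, maximal only when all counted states are equally
#' frequent.
#'
#' @param aln A [sig_alignment()].
#' @param position 1-based column index.
#' @param include_missing Count N as a state instead of excluding it.
#' @return Entropy in bits.
#' @export
column_entropy <- function(aln, position, include_missing = FALSE) {
  stopifnot(inherits(aln, "sig_alignment"))
  position <- .check_position(aln, position)
  col <- unclass(aln)[, position]
  if (!include_missing) col <- col[col != "N"]
  if (length(col) == 0L) return(0)
  f <- table(col) / length(col)
  f <- as.numeric(f)
  -sum(f * log2(f))
}

#' Entropy profile of an alignment
#'
#' [column_entropy()] applied to every column in order. Peaks mark variable
#' regions of the alignment, troughs conserved regions; plotted alongside
#' the signature characters it shows which sequence context a diagnostic
#' position sits in.
#'
#' @inheritParams column_entropy
#' @return Numeric vector of per-column entropies (bits), length equal to
#'   the alignment length.
#' @export
#' @examples
#' wx <- generate_worked_example()
#' entropy_profile(wx$alignment)[5]  # variable column: G,G,G,A,A,T,T
entropy_profile <- function(aln, include_missing = FALSE) {
  vapply(seq_len(alignment_length(aln)), function(p) {
    column_entropy(aln, p, include_missing = include_missing)
  }, numeric(1))
}
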