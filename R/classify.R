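#' Is a position a candidate character?
#'
#' A position qualifies as a candidate character when the query group is
#' uniform there (query rank 1) and carries no missing information (the N
#' count is 0). Only candidate characters are suitable for inclusion in a
#' taxon diagnosis; all other positions are reported but left unclassified.
#'
#' For pair state vectors the same rule applies with "N" read as "either
#' member of the pair is N".
#'
#' @param Q Query state vector (6-dimensional, or 36-dimensional for pairs).
#' @return Logical.
#' @export
is_candidate <- function(Q) {
  n_dims <- grepl("N", names(Q), fixed = TRUE)
  vector_rank(Q) == 1L && sum(unclass(Q)[n_dims]) == 0L
}

.sig_classes <- c("binary", "asymmetric", "noisy", "conserved", "non_candidate")

#' Classify a candidate character from its two state vectors
#'
#' Non-candidate positions (query not uniform, or query contains N) get the
#' label `non_candidate`. Candidate positions are classified by the exact
#' metric thresholds:
#'
#' | class      | d-power | q-rank | r-rank |
#' |------------|---------|--------|--------|
#' | binary     | 1       | 1      | 1      |
#' | asymmetric | 1       | 1      | >1     |
#' | noisy      | <1      | 1      | >1     |
#' | conserved  | <1      | 1      | 1      |
#'
#' The `d-power = 1` test is implemented as the exact integer condition
#' "the vector supports are disjoint" (equivalent by the L1 identity), never
#' as a floating-point comparison.
#'
#' @param Q,R State vectors over the same ordered state list, positive L1
#'   norms.
#' @return One of `"binary"`, `"asymmetric"`, `"noisy"`, `"conserved"`,
#'   `"non_candidate"`.
#' @export
classify <- function(Q, R) {
  .check_vec_pair(Q, R)
  if (sum(Q) == 0L || sum(R) == 0L) {
    stop("classification is undefined for an all-zero state vector",
         call. = FALSE)
  }
  if (!is_candidate(Q)) return("non_candidate")
  disjoint <- !any(unclass(Q) > 0L & unclass(R) > 0L)  # d-power == 1, exactly
  r_rank <- vector_rank(R)
  if (disjoint) {
    if (r_rank == 1L) "binary" else "asymmetric"
  } else {
    if (r_rank > 1L) "noisy" else "conserved"
  }
}

#' Is a classified position a signature character?
#'
#' A candidate character is a signature character exactly when its
#' discriminative power is 1, i.e. when its class is binary or asymmetric.
#' Signature characters separate every member of the query group from every
#' member of the reference group.
#'
#' @param m A one-row position metrics data frame (from
#'   [compute_position_metrics()]), a full metrics table, or a character
#'   vector of class labels.
#' @return Logical vector.
#' @export
is_signature <- function(m) {
  cls <- if (is.data.frame(m)) m$char_class else m
  cls %in% c("binary", "asymmetric")
}

#' Compute all ranking metrics for one alignment position
#'
#' Builds the query and reference state vectors at `position` and assembles
#' discriminative power, query rank, reference rank, consensus states, the
#' class label and the signature flag. `ref_has_missing` records whether the
#' reference group carries any N at the position: such Ns inflate the
#' reference rank and can never match a candidate query state, so asymmetric
#' calls at these positions deserve scrutiny.
#'
#' @param aln A [sig_alignment()].
#' @param part A partition from [resolve_groups()].
#' @param position 1-based column index.
#' @return One-row data frame with columns `position`, `d_power`, `q_rank`,
#'   `r_rank`, `query_state`, `query_uniform`, `reference_state`,
#'   `reference_uniform`, `char_class`, `is_signature`, `ref_has_missing`.
#' @export
compute_position_metrics <- function(aln, part, position) {
  stopifnot(inherits(part, "sig_partition"))
  Q <- build_state_vector(aln, part$query, position)
  R <- build_state_vector(aln, part$reference, position)
  cq <- consensus_state(Q)
  cr <- consensus_state(R)
  cls <- classify(Q, R)
  data.frame(
    position = as.integer(position),
    d_power = discriminative_power(Q, R),
    q_rank = vector_rank(Q),
    r_rank = vector_rank(R),
    query_state = cq$state,
    query_uniform = cq$is_uniform,
    reference_state = cr$state,
    reference_uniform = cr$is_uniform,
    char_class = cls,
    is_signature = is_signature(cls),
    ref_has_missing = unclass(R)[["N"]] > 0L,
    stringsAsFactors = FALSE
  )
}

#' Metrics for every alignment position
#'
#' [compute_position_metrics()] applied to every column, in positional
#' order (unranked).
#'
#' @inheritParams compute_position_metrics
#' @return Data frame with one row per alignment position.
#' @export
position_metrics <- function(aln, part) {
  rows <- lapply(seq_len(alignment_length(aln)), function(p) {
    compute_position_metrics(aln, part, p)
  })
  do.call(rbind, rows)
}

#' Diagnostic relevance ranking
#'
#' Orders position metrics lexicographically by discriminative power
#' (descending), query rank (ascending) and reference rank (ascending), so
#' that the most diagnostically relevant positions are listed first.
#' Remaining ties are broken by position ascending, for determinism. Every
#' alignment position appears exactly once; non-candidate positions are
#' ranked too, they are simply never classified.
#'
#' @param rows Metrics data frame from [position_metrics()], one row per
#'   position.
#' @return The same data frame, reordered, with a leading `rank` column and
#'   class `sig_ranked_table`.
#' @export
#' @examples
#' wx <- generate_worked_example()
#' ranked <- rank_positions(position_metrics(wx$alignment, wx$partition))
#' head(ranked[, c("rank", "position", "d_power", "char_class")])
rank_positions <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  if (anyDuplicated(rows$position)) {
    stop("duplicate position(s) in metrics table: ",
         paste(unique(rows$position[duplicated(rows$position)]),
               collapse = ", "), call. = FALSE)
  }
  ord <- order(-rows$d_power, rows$q_rank, rows$r_rank, rows$position)
  out <- rows[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("sig_ranked_table", "data.frame")
  out
}

#' @export
print.sig_ranked_table <- function(x, n = 10L, ...) {
  cat("diagnostic relevance ranking: ", nrow(x), " position(s), ",
      sum(x$is_signature), " signature character(s)\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more row(s)\n", sep = "")
  invisible(x)
}
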