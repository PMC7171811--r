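#' Enumerate position pairs inside a k-window
#'
#' All pairs `(i, j)` with `i < j` drawn from a sorted list of positions and
#' `j - i < k`, in lexicographic order. With `k = 1` no pair qualifies; with
#' `k` at least the alignment length the enumeration is unwindowed.
#'
#' @param noisy_positions Strictly increasing vector of 1-based positions
#'   (in practice, the noisy candidate characters of a ranking).
#' @param k Window size, integer >= 1.
#' @return Integer matrix with columns `i` and `j` (zero rows if none).
#' @export
#' @examples
#' enumerate_pairs(c(8, 19, 20, 23), k = 5)
enumerate_pairs <- function(noisy_positions, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 ||
      k != as.integer(k)) {
    stop("k must be a single integer >= 1", call. = FALSE)
  }
  p <- as.integer(noisy_positions)
  if (is.unsorted(p, strictly = TRUE)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  empty <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  if (length(p) < 2L) return(empty)
  pairs <- t(utils::combn(p, 2L))
  keep <- (pairs[, 2L] - pairs[, 1L]) < k
  pairs <- pairs[keep, , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

#' Build the pair state vector of a group at two positions
#'
#' Each sequence of the group contributes its ordered state pair (state at
#' `i`, state at `j`) to a 36-dimensional count vector indexed by
#' [sig_pair_states()]. As for single positions, the L1 norm equals the
#' group size.
#'
#' @param aln A [sig_alignment()].
#' @param ids Non-empty subset of sequence ids.
#' @param i,j 1-based column indices.
#' @return Named integer vector over the 36 pair states, class
#'   `sig_state_vector`.
#' @export
build_pair_vector <- function(aln, ids, i, j) {
  stopifnot(inherits(aln, "sig_alignment"))
  i <- .check_position(aln, i)
  j <- .check_position(aln, j)
  ids <- .check_ids(aln, ids)
  m <- unclass(aln)
  pairs <- paste0(m[ids, i], m[ids, j])
  states <- sig_pair_states()
  .state_vector(tabulate(match(pairs, states), nbins = length(states)), states)
}

#' Classify a combined character from its pair state vectors
#'
#' The same metrics and class thresholds as for single positions, applied
#' to the 36-dimensional pair vectors: discriminative power is the
#' normalized L1 distance, the ranks count distinct observed pairs, and the
#' class follows the binary/asymmetric/noisy/conserved table. A combined
#' character is jointly diagnostic when its discriminative power is 1
#' (class asymmetric, or binary in the degenerate uniform-reference case).
#'
#' @param Q2,R2 Pair state vectors over [sig_pair_states()].
#' @return List with `d_power`, `q_rank`, `r_rank`, `query_pair`,
#'   `char_class`.
#' @export
classify_pair <- function(Q2, R2) {
  .check_vec_pair(Q2, R2)
  if (length(Q2) != length(sig_pair_states())) {
    stop("pair vectors must be indexed by the 36 ordered state pairs",
         call. = FALSE)
  }
  list(
    d_power = discriminative_power(Q2, R2),
    q_rank = vector_rank(Q2),
    r_rank = vector_rank(R2),
    query_pair = consensus_state(Q2)$state,
    char_class = classify(Q2, R2)
  )
}

#' Find combined characters among noisy candidates
#'
#' Many candidate characters come out noisy and cannot alone distinguish
#' the groups; yet two noisy columns may jointly be diagnostic when no
#' reference sequence carries the query's state combination. This searches
#' all pairs of noisy candidate positions within the k-window, classifies
#' each pair on its 36-dimensional pair vectors and returns all of them
#' (diagnostic and near-diagnostic alike), sorted by the same lexicographic
#' relevance order as single positions.
#'
#' @param aln A [sig_alignment()].
#' @param part A `sig_partition`.
#' @param ranked A ranking from [rank_positions()] (its noisy rows seed the
#'   pair enumeration).
#' @param k Window size, integer >= 1; positions pair only if `|i - j| < k`.
#' @return Data frame with columns `i`, `j`, `d_power`, `q_rank`, `r_rank`,
#'   `query_pair`, `char_class`, `is_signature`, sorted by (`d_power` desc,
#'   `q_rank` asc, `r_rank` asc, `i`, `j`).
#' @export
#' @examples
#' wx <- generate_worked_example()
#' ranked <- rank_positions(position_metrics(wx$alignment, wx$partition))
#' find_combined_characters(wx$alignment, wx$partition, ranked, k = 5)
find_combined_characters <- function(aln, part, ranked, k) {
  stopifnot(inherits(part, "sig_partition"), is.data.frame(ranked))
  noisy <- sort(ranked$position[ranked$char_class == "noisy"])
  pairs <- enumerate_pairs(noisy, k)
  out <- .empty_combined()
  if (nrow(pairs) == 0L) return(out)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, "i"]
    j <- pairs[r, "j"]
    Q2 <- build_pair_vector(aln, part$query, i, j)
    R2 <- build_pair_vector(aln, part$reference, i, j)
    cls <- classify_pair(Q2, R2)
    data.frame(i = i, j = j, d_power = cls$d_power, q_rank = cls$q_rank,
               r_rank = cls$r_rank, query_pair = cls$query_pair,
               char_class = cls$char_class,
               is_signature = is_signature(cls$char_class),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$d_power, out$q_rank, out$r_rank, out$i, out$j), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_combined <- function() {
  data.frame(i = integer(0), j = integer(0), d_power = numeric(0),
             q_rank = integer(0), r_rank = integer(0),
             query_pair = character(0), char_class = character(0),
             is_signature = logical(0), stringsAsFactors = FALSE)
}
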