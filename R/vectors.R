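#' Build the character state vector of a group at one position
#'
#' Counts, for each state of the ordered alphabet `A, C, G, T, -, N`, how
#' many sequences of `ids` carry that state at `position`. The resulting
#' count vector is the basic object of the method: its L1 norm always equals
#' the group size.
#'
#' @param aln A [sig_alignment()].
#' @param ids Non-empty subset of the alignment's sequence ids.
#' @param position 1-based column index.
#' @return Named integer vector over [sig_states()] with class
#'   `sig_state_vector`.
#' @export
#' @examples
#' wx <- generate_worked_example()
#' build_state_vector(wx$alignment, wx$partition$query, 5)     # <0,0,3,0,0,0>
#' build_state_vector(wx$alignment, wx$partition$reference, 5) # <2,0,0,2,0,0>
build_state_vector <- function(aln, ids, position) {
  stopifnot(inherits(aln, "sig_alignment"))
  position <- .check_position(aln, position)
  ids <- .check_ids(aln, ids)
  col <- unclass(aln)[ids, position]
  .state_vector(tabulate(match(col, sig_states()), nbins = 6L), sig_states())
}

.state_vector <- function(counts, states) {
  structure(as.integer(counts), names = states, class = "sig_state_vector")
}

#' @export
print.sig_state_vector <- function(x, ...) {
  cat("<", paste(unclass(x)[unclass(x) != 0 | seq_along(x) <= 6],
                 collapse = ","), ">", sep = "")
  if (length(x) > 6L) {
    nz <- which(unclass(x) != 0)
    cat("  [", paste0(names(x)[nz], ":", unclass(x)[nz], collapse = " "), "]",
        sep = "")
  } else {
    cat("  (", paste(names(x), collapse = ","), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

.check_vec_pair <- function(Q, R) {
  if (length(Q) != length(R) ||
      !identical(names(Q), names(R))) {
    stop("state vectors are indexed by different state lists", call. = FALSE)
  }
}

#' Discriminative power of a position
#'
#' The normalized L1 distance between the query and reference state
#' vectors, `sum(|q_i - r_i|) / (sum(q_i) + sum(r_i))`. It lies in `[0, 1]`;
#' it equals 1 exactly when the two groups share no character state at the
#' position (disjoint vector supports), and 0 exactly when the vectors are
#' identical. Computed from integer counts, so the extremes are exact.
#'
#' @param Q,R State vectors over the same ordered state list, each with
#'   positive L1 norm.
#' @return Numeric in `[0, 1]`.
#' @export
discriminative_power <- function(Q, R) {
  .check_vec_pair(Q, R)
  nq <- sum(Q)
  nr <- sum(R)
  if (nq == 0L || nr == 0L) {
    stop("discriminative power is undefined for an all-zero state vector",
         call. = FALSE)
  }
  sum(abs(unclass(Q) - unclass(R))) / (nq + nr)
}

#' Rank of a state vector
#'
#' Number of non-zero dimensions, i.e. the number of distinct states the
#' group exhibits. Applied to the query vector this is the query rank
#' (q-rank); to the reference vector, the reference rank (r-rank).
#'
#' @param v A state vector.
#' @return Non-negative integer count of non-zero dimensions.
#' @export
vector_rank <- function(v) {
  sum(unclass(v) > 0L)
}

#' Uniform or prevalent state of a group
#'
#' The state with the maximal count. The column is uniform when exactly one
#' dimension is non-zero; otherwise the returned state is the prevalent one,
#' with ties broken deterministically by state-list order (earliest wins).
#' Display-level information only: classification never depends on it.
#'
#' @param v A state vector with positive L1 norm.
#' @return List with `state` (symbol or symbol pair) and `is_uniform`.
#' @export
consensus_state <- function(v) {
  if (sum(v) == 0L) {
    stop("consensus state is undefined for an all-zero state vector",
         call. = FALSE)
  }
  idx <- which.max(unclass(v))  # first maximum = earliest state on ties
  structure(list(state = names(v)[idx], is_uniform = vector_rank(v) == 1L),
            class = "sig_consensus")
}

#' @export
print.sig_consensus <- function(x, ...) {
  cat(x$state, if (x$is_uniform) "(uniform)" else "(prevalent)", "\n")
  invisible(x)
}
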