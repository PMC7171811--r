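#' Resolve query and reference group specifications into a checked partition
#'
#' Each group specification is either a comma-separated string of sequence
#' ids (or an already-split character vector of ids), or a [tree_node()]
#' selector naming a clade of `tree`. When `reference` is `NULL`, the
#' reference group defaults to the complement of the query group within the
#' alignment ids. Ids are matched by exact string equality after whitespace
#' trimming.
#'
#' Sequences in the alignment that end up in neither group take no part in
#' state-vector computations; they still contribute to the entropy profile,
#' which describes the whole input alignment.
#'
#' @param aln A [sig_alignment()].
#' @param query Query group specification.
#' @param reference Reference group specification, or `NULL` for the
#'   complement of the query group.
#' @param tree Optional `phylo` tree; required when either specification is
#'   a [tree_node()].
#' @return A `sig_partition`: list with character vectors `query` and
#'   `reference`, disjoint, non-empty, both subsets of the alignment ids.
#' @export
#' @examples
#' wx <- generate_worked_example()
#' resolve_groups(wx$alignment, "q1,q2,q3")
resolve_groups <- function(aln, query, reference = NULL, tree = NULL) {
  stopifnot(inherits(aln, "sig_alignment"))
  ids <- alignment_ids(aln)
  q <- .resolve_one(query, tree, "query")
  r <- if (is.null(reference)) setdiff(ids, q) else {
    .resolve_one(reference, tree, "reference")
  }
  unknown <- setdiff(c(q, r), ids)
  if (length(unknown) > 0L) {
    stop("id(s) not in alignment: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  overlap <- intersect(q, r)
  if (length(overlap) > 0L) {
    stop("query and reference groups overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (length(q) == 0L) stop("query group is empty", call. = FALSE)
  if (length(r) == 0L) stop("reference group is empty", call. = FALSE)
  structure(list(query = q, reference = r), class = "sig_partition")
}

.resolve_one <- function(spec, tree, what) {
  if (inherits(spec, "sig_node_selector")) {
    if (is.null(tree)) {
      stop(what, " group uses a tree node selector but no tree was given",
           call. = FALSE)
    }
    return(.node_leaves(tree, spec$label))
  }
  if (!is.character(spec) || length(spec) < 1L) {
    stop(what, " group spec must be a character vector or tree_node()",
         call. = FALSE)
  }
  out <- trimws(unlist(strsplit(spec, ",", fixed = TRUE), use.names = FALSE))
  out <- out[nzchar(out)]
  if (length(out) == 0L) stop(what, " group spec is empty", call. = FALSE)
  if (anyDuplicated(out)) out <- unique(out)
  out
}

#' @export
print.sig_partition <- function(x, ...) {
  cat("group partition\n")
  cat("  query     (", length(x$query), "): ",
      paste(x$query, collapse = ", "), "\n", sep = "")
  cat("  reference (", length(x$reference), "): ",
      paste(x$reference, collapse = ", "), "\n", sep = "")
  invisible(x)
}
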