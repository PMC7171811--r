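#' Read a Newick tree for group selection
#'
#' Parses a Newick file with \pkg{ape} and validates it for use as a group
#' selector: leaf labels must be unique. Branch lengths and support values
#' are ignored downstream; the tree is used only to resolve clades into sets
#' of sequence ids.
#'
#' @param path Path to a Newick file.
#' @return An \pkg{ape} `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("not parseable as Newick: ", path, .newick_offset_hint(txt),
         call. = FALSE)
  }
  tree$tip.label <- trimws(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- trimws(tree$node.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label(s) in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  tree
}

# Best-effort character offset of the first structural problem, for error
# messages (ape does not report one).
.newick_offset_hint <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(paste0(" (unmatched ')' at character ", i, ")"))
    }
  }
  if (depth > 0L) {
    return(paste0(" (", depth, " unclosed '(' at end of input, character ",
                  length(chars), ")"))
  }
  ""
}

#' Select a tree node as a group specifier
#'
#' Marks a label as naming a tree node rather than a sequence id list, for
#' use as the `query`/`reference` argument of [resolve_groups()]. The label
#' may name an internal node (the group is all leaves of that clade) or a
#' single leaf.
#'
#' @param label Node or leaf label in the tree.
#' @return A `sig_node_selector` object.
#' @export
#' @examples
#' tree_node("cladeA")
tree_node <- function(label) {
  if (!is.character(label) || length(label) != 1L || !nzchar(trimws(label))) {
    stop("tree_node() needs a single non-empty label", call. = FALSE)
  }
  structure(list(label = trimws(label)), class = "sig_node_selector")
}

#' @export
print.sig_node_selector <- function(x, ...) {
  cat("tree node selector: '", x$label, "'\n", sep = "")
  invisible(x)
}

# Resolve a node selector to the leaf labels of its clade.
.node_leaves <- function(tree, label) {
  if (label %in% tree$tip.label) return(label)
  ntip <- length(tree$tip.label)
  if (!is.null(tree$node.label)) {
    hit <- which(tree$node.label == label)
    if (length(hit) == 1L) {
      clade <- ape::extract.clade(tree, ntip + hit)
      return(clade$tip.label)
    }
    if (length(hit) > 1L) {
      stop("tree node label '", label, "' is not unique", call. = FALSE)
    }
  }
  stop("no tree node or leaf labelled '", label, "'", call. = FALSE)
}
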