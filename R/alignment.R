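#' Construct an alignment object from a character matrix
#'
#' Internal constructor shared by [read_alignment()] and the fixture
#' generators. Rows are sequences (rownames are the sequence ids), columns
#' are alignment positions; every cell must already be one of the six
#' alphabet states.
#'
#' @param mat Character matrix with unique non-empty rownames.
#' @return A `sig_alignment` object (a classed character matrix).
#' @export
sig_alignment <- function(mat) {
  if (!is.matrix(mat) || !is.character(mat)) {
    stop("alignment must be a character matrix", call. = FALSE)
  }
  if (nrow(mat) < 1L || ncol(mat) < 1L) {
    stop("alignment needs at least one sequence and one column", call. = FALSE)
  }
  ids <- rownames(mat)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("alignment rows must be named by non-empty sequence ids", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  bad <- !(mat %in% sig_states())
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("unrecognized character '", mat[idx[1], idx[2]], "' at position ",
         idx[2], " of sequence '", ids[idx[1]], "'", call. = FALSE)
  }
  structure(mat, class = c("sig_alignment", "matrix", "array"))
}

#' Read an aligned FASTA file
#'
#' Parses a multi-record FASTA file of equal-length nucleotide sequences and
#' normalizes all states to the fixed alphabet `A, C, G, T, -, N` (see
#' [normalize_states()] for the normalization and ambiguity-code policy).
#' Record order is preserved. The sequence id is the first
#' whitespace-delimited token of the header line, the convention used by
#' alignment and tree tools throughout the field.
#'
#' @param path Path to a FASTA file.
#' @param ambiguity How to treat IUPAC degeneracy codes: `"mask"` (to N,
#'   with a warning) or `"strict"` (error).
#' @return A [sig_alignment()] object.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "acgu"), fa)
#' aln <- read_alignment(fa)
#' alignment_length(aln)
read_alignment <- function(path, ambiguity = c("mask", "strict")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- vapply(strsplit(trimws(names(set)), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("empty sequence id in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  lens <- Biostrings::width(set)
  if (length(unique(lens)) != 1L) {
    ref_len <- lens[1]
    off <- ids[lens != ref_len]
    stop("alignment rows differ in length (first row has ", ref_len,
         "); offending id(s): ", paste(off, collapse = ", "), call. = FALSE)
  }
  rows <- strsplit(as.character(set), "", fixed = TRUE)
  rows <- mapply(normalize_states, rows, id = ids,
                 MoreArgs = list(ambiguity = ambiguity), SIMPLIFY = FALSE)
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  sig_alignment(mat)
}

#' Write an alignment to FASTA
#'
#' Inverse of [read_alignment()] for normalized alignments: re-reading the
#' written file yields identical records.
#'
#' @param aln A `sig_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "sig_alignment"))
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- rownames(aln)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Alignment sequence ids, in file order
#' @param aln A `sig_alignment`.
#' @return Character vector of ids.
#' @export
alignment_ids <- function(aln) rownames(aln)

#' Number of alignment columns
#' @param aln A `sig_alignment`.
#' @return Integer alignment length.
#' @export
alignment_length <- function(aln) ncol(aln)

#' @export
print.sig_alignment <- function(x, ...) {
  cat("sig_alignment: ", nrow(x), " sequence(s) x ", ncol(x), " column(s)\n",
      sep = "")
  ids <- utils::head(rownames(x), 6L)
  for (id in ids) {
    s <- paste(x[id, seq_len(min(60L, ncol(x)))], collapse = "")
    if (ncol(x) > 60L) s <- paste0(s, "...")
    cat(format(id, width = max(nchar(ids)) + 2L), s, "\n")
  }
  if (nrow(x) > 6L) cat("  ... ", nrow(x) - 6L, " more\n", sep = "")
  invisible(x)
}

.check_position <- function(aln, position) {
  if (!is.numeric(position) || length(position) != 1L || is.na(position) ||
      position != as.integer(position)) {
    stop("position must be a single integer", call. = FALSE)
  }
  if (position < 1L || position > ncol(aln)) {
    stop("position ", position, " out of range [1, ", ncol(aln), "]",
         call. = FALSE)
  }
  as.integer(position)
}

.check_ids <- function(aln, ids) {
  if (length(ids) == 0L) stop("id set is empty", call. = FALSE)
  missing <- setdiff(ids, rownames(aln))
  if (length(missing) > 0L) {
    stop("unknown sequence id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ids
}
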