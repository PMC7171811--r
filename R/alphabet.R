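#' The ordered character state alphabet
#'
#' All state vectors are indexed by this fixed ordered list: the four
#' nucleotides, the gap (deletion) state and N (missing information). The
#' order is part of the public contract so that printed vectors are
#' bit-comparable across runs and tools.
#'
#' @return Character vector `c("A","C","G","T","-","N")`.
#' @export
#' @examples
#' sig_states()
sig_states <- function() c("A", "C", "G", "T", "-", "N")

#' Ordered pair states for combined characters
#'
#' The 36 ordered state pairs, first position major: `AA, AC, ..., NN`.
#' Pair state vectors for combined characters are indexed by this list.
#'
#' @return Character vector of length 36.
#' @export
sig_pair_states <- function() {
  b <- sig_states()
  paste0(rep(b, each = length(b)), rep(b, times = length(b)))
}

# IUPAC degeneracy codes that the 6-state alphabet cannot represent.
.sig_iupac_ambig <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Normalize raw sequence characters to the 6-state alphabet
#'
#' Uppercases, maps RNA `U` to `T` and the alternative gap symbol `.` to
#' `-`. IUPAC degeneracy codes (R, Y, S, W, K, M, B, D, H, V) carry partial
#' information the 6-state model cannot hold; under policy `"mask"` they are
#' replaced by `N` with a warning, under `"strict"` they raise an error. Any
#' other character is always an error.
#'
#' Normalization is idempotent: applying it to already-normalized states is
#' the identity.
#'
#' @param x Character vector of single characters (one alignment column or
#'   sequence, split).
#' @param ambiguity `"mask"` (default) or `"strict"`.
#' @param id Sequence id used in messages.
#' @return Character vector over `sig_states()`.
#' @export
normalize_states <- function(x, ambiguity = c("mask", "strict"), id = "<sequence>") {
  ambiguity <- match.arg(ambiguity)
  x <- toupper(x)
  x[x == "U"] <- "T"
  x[x == "."] <- "-"
  amb <- x %in% .sig_iupac_ambig
  if (any(amb)) {
    pos <- which(amb)
    shown <- paste0(x[pos[1]], "@", pos[1])
    if (ambiguity == "strict") {
      stop("IUPAC ambiguity code in sequence '", id, "' (first: ", shown,
           "); rerun with ambiguity = \"mask\" to replace with N", call. = FALSE)
    }
    warning("masked ", length(pos), " IUPAC ambiguity code(s) to N in sequence '",
            id, "' (first: ", shown, ")", call. = FALSE)
    x[amb] <- "N"
  }
  bad <- !(x %in% sig_states())
  if (any(bad)) {
    p <- which(bad)[1]
    stop("unrecognized character '", x[p], "' at position ", p,
         " of sequence '", id, "'", call. = FALSE)
  }
  x
}
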