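# Independent set-based classifier used as an oracle against the
# vector-metric implementation. Works directly on the raw column symbols:
#   candidate  iff the query has exactly one distinct state and it is not N
#   binary     iff reference disjoint from query and uniform
#   asymmetric iff reference disjoint from query and not uniform
#   conserved  iff reference states == query states
#   noisy      otherwise
oracle_classify <- function(q_chars, r_chars) {
  SQ <- unique(q_chars)
  SR <- unique(r_chars)
  if (length(SQ) != 1L || "N" %in% SQ) return("non_candidate")
  if (length(intersect(SQ, SR)) == 0L) {
    if (length(SR) == 1L) "binary" else "asymmetric"
  } else if (setequal(SR, SQ)) {
    "conserved"
  } else {
    "noisy"
  }
}

# Build a state vector directly from integer counts (bypasses alignments).
sv <- function(counts, states = sig_states()) {
  structure(as.integer(counts), names = states, class = "sig_state_vector")
}

# One-column alignment from raw query/reference characters.
column_alignment <- function(q_chars, r_chars) {
  n_q <- length(q_chars)
  ids <- c(paste0("q", seq_len(n_q)), paste0("r", seq_along(r_chars)))
  mat <- cbind(c(q_chars, r_chars))
  rownames(mat) <- ids
  aln <- sig_alignment(mat)
  list(alignment = aln,
       partition = resolve_groups(aln, paste(ids[seq_len(n_q)],
                                             collapse = ",")))
}

# Write the worked example to temp FASTA/Newick files; returns the paths.
worked_example_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  wx <- generate_worked_example()
  fa <- file.path(dir, "worked.fasta")
  nw <- file.path(dir, "worked.nwk")
  write_alignment(wx$alignment, fa)
  ape::write.tree(wx$tree, nw)
  list(fasta = fa, newick = nw, wx = wx)
}
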