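#' Assemble an analysis configuration
#'
#' Bundles and validates all parameters of a run. Exactly one of `query` /
#' `query_node` is required; `reference` / `reference_node` are optional
#' (default: the complement of the query group). `k` switches the combined
#' character search on; leaving it `NULL` skips that step.
#'
#' @param alignment_path Path to the aligned FASTA file.
#' @param tree_path Optional path to a Newick tree (required when groups
#'   are selected by tree node).
#' @param query Comma-separated sequence ids (or character vector).
#' @param query_node Tree node label selecting the query clade.
#' @param reference,reference_node Same, for the reference group.
#' @param k Optional k-window size (integer >= 1) for combined characters.
#' @param ambiguity IUPAC ambiguity policy, `"mask"` or `"strict"`.
#' @param entropy_include_missing Count N as an entropy state.
#' @return A `sig_config` list.
#' @export
analysis_config <- function(alignment_path, tree_path = NULL,
                            query = NULL, query_node = NULL,
                            reference = NULL, reference_node = NULL,
                            k = NULL, ambiguity = c("mask", "strict"),
                            entropy_include_missing = FALSE) {
  ambiguity <- match.arg(ambiguity)
  if (is.null(query) == is.null(query_node)) {
    stop("give exactly one of query / query_node", call. = FALSE)
  }
  if (!is.null(reference) && !is.null(reference_node)) {
    stop("give at most one of reference / reference_node", call. = FALSE)
  }
  if (!is.null(k)) {
    if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 ||
        k != as.integer(k)) {
      stop("k must be a single integer >= 1", call. = FALSE)
    }
    k <- as.integer(k)
  }
  if ((!is.null(query_node) || !is.null(reference_node)) &&
      is.null(tree_path)) {
    stop("tree node selection requires tree_path", call. = FALSE)
  }
  structure(list(
    alignment_path = alignment_path, tree_path = tree_path,
    query = query, query_node = query_node,
    reference = reference, reference_node = reference_node,
    k = k, ambiguity = ambiguity,
    entropy_include_missing = isTRUE(entropy_include_missing)
  ), class = "sig_config")
}

#' Run the full signature character analysis
#'
#' Reads the alignment (and tree, if any), resolves the groups, computes
#' the diagnostic relevance ranking of all positions, extracts the
#' signature characters, optionally searches combined characters within
#' the k-window, and computes the entropy profile of the whole input
#' alignment. The result is deterministic for fixed inputs.
#'
#' @param cfg A configuration from [analysis_config()].
#' @return A `sig_analysis` list: `ranked` (the [rank_positions()] table),
#'   `signature_positions` (positions of binary/asymmetric rows, in ranked
#'   order), `combined` (combined character table, zero rows when `k` is
#'   absent), `entropy` (per-column bits), `partition`, and `run_metadata`
#'   (parameters, input md5 digests, timestamp, package version).
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "sig_config"))
  aln <- read_alignment(cfg$alignment_path, ambiguity = cfg$ambiguity)
  tree <- if (!is.null(cfg$tree_path)) read_tree(cfg$tree_path) else NULL
  qspec <- if (!is.null(cfg$query_node)) tree_node(cfg$query_node) else cfg$query
  rspec <- if (!is.null(cfg$reference_node)) {
    tree_node(cfg$reference_node)
  } else {
    cfg$reference
  }
  part <- resolve_groups(aln, qspec, rspec, tree)

  ranked <- rank_positions(position_metrics(aln, part))
  combined <- if (!is.null(cfg$k)) {
    find_combined_characters(aln, part, ranked, cfg$k)
  } else {
    .empty_combined()
  }
  entropy <- entropy_profile(aln, include_missing = cfg$entropy_include_missing)

  n_ref_missing <- sum(ranked$ref_has_missing)
  if (n_ref_missing > 0L) {
    message("note: ", n_ref_missing, " position(s) have missing data (N) in ",
            "the reference group; their reference ranks include N")
  }

  inputs <- c(alignment = unname(tools::md5sum(cfg$alignment_path)),
              tree = if (!is.null(cfg$tree_path))
                unname(tools::md5sum(cfg$tree_path)) else NA_character_)
  structure(list(
    ranked = ranked,
    signature_positions = ranked$position[ranked$is_signature],
    combined = combined,
    entropy = entropy,
    partition = part,
    run_metadata = list(
      parameters = cfg[!vapply(cfg, is.null, logical(1))],
      input_md5 = as.list(inputs[!is.na(inputs)]),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      version = as.character(utils::packageVersion("sigchar"))
    )
  ), class = "sig_analysis")
}

#' @export
print.sig_analysis <- function(x, ...) {
  cat("signature character analysis\n")
  cat("  positions ranked:     ", nrow(x$ranked), "\n")
  cat("  candidate characters: ",
      sum(x$ranked$char_class != "non_candidate"), "\n")
  cat("  signature characters: ", length(x$signature_positions),
      if (length(x$signature_positions) > 0L) {
        paste0(" (positions ",
               paste(sort(x$signature_positions), collapse = ", "), ")")
      } else "", "\n", sep = "")
  cat("  combined characters:  ", nrow(x$combined), " evaluated, ",
      sum(x$combined$is_signature), " diagnostic\n", sep = "")
  invisible(x)
}

#' Write analysis reports to a directory
#'
#' Serializes a [run_analysis()] result: `ranked_table.tsv` (the full
#' diagnostic relevance ranking, `d_power` printed with 4 decimals),
#' `combined.tsv`, `entropy.tsv` (position, entropy_bits), a plain-text
#' `signatures.txt` summary and a machine-readable `run_metadata.json`
#' sidecar. With `plots = TRUE`, PNG images of the signature bar and of the
#' entropy profile are also written (never required by any downstream
#' step). Re-running on identical inputs reproduces the TSVs byte for byte;
#' only the metadata timestamp differs.
#'
#' @param res A `sig_analysis` result.
#' @param out_dir Output directory (created if needed).
#' @param plots Also write PNG plots.
#' @return Character vector of the written file paths, invisibly.
#' @export
write_reports <- function(res, out_dir, plots = FALSE) {
  stopifnot(inherits(res, "sig_analysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  w <- function(name) file.path(out_dir, name)

  ranked <- as.data.frame(res$ranked)
  ranked$d_power <- sprintf("%.4f", ranked$d_power)
  f <- w("ranked_table.tsv")
  utils::write.table(ranked, f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)

  combined <- res$combined
  combined$d_power <- sprintf("%.4f", combined$d_power)
  f <- w("combined.tsv")
  utils::write.table(combined, f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)

  f <- w("entropy.tsv")
  utils::write.table(
    data.frame(position = seq_along(res$entropy),
               entropy_bits = sprintf("%.6f", res$entropy)),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)

  sig <- res$ranked[res$ranked$is_signature, , drop = FALSE]
  f <- w("signatures.txt")
  lines <- c(
    paste0("signature characters: ", nrow(sig)),
    if (nrow(sig) > 0L) {
      paste0("position ", sig$position, "\t", sig$char_class,
             "\tquery=", sig$query_state, "\treference=", sig$reference_state)
    },
    paste0("diagnostic combined characters: ", sum(res$combined$is_signature)),
    if (any(res$combined$is_signature)) {
      cs <- res$combined[res$combined$is_signature, , drop = FALSE]
      paste0("positions (", cs$i, ",", cs$j, ")\t", cs$char_class,
             "\tquery pair=", cs$query_pair)
    }
  )
  writeLines(lines, f)
  written <- c(written, f)

  f <- w("run_metadata.json")
  jsonlite::write_json(res$run_metadata, f, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, f)

  if (isTRUE(plots)) {
    written <- c(written, .plot_reports(res, out_dir))
  }
  invisible(written)
}

.plot_reports <- function(res, out_dir) {
  files <- character(0)
  cls_col <- c(binary = "#1b9e77", asymmetric = "#7570b3", noisy = "#d95f02")
  f <- file.path(out_dir, "signature_bar.png")
  grDevices::png(f, width = 900, height = 220)
  tab <- res$ranked[res$ranked$char_class %in% names(cls_col), , drop = FALSE]
  plot(NULL, xlim = c(0.5, max(res$ranked$position) + 0.5), ylim = c(0, 1),
       xlab = "alignment position", ylab = "", yaxt = "n",
       main = "candidate characters")
  if (nrow(tab) > 0L) {
    graphics::segments(tab$position, 0, tab$position, 1,
                       col = cls_col[tab$char_class], lwd = 3)
  }
  graphics::legend("topright", legend = names(cls_col), col = cls_col,
                   lwd = 3, bty = "n", horiz = TRUE)
  grDevices::dev.off()
  files <- c(files, f)

  f <- file.path(out_dir, "entropy.png")
  grDevices::png(f, width = 900, height = 300)
  plot(seq_along(res$entropy), res$entropy, type = "l",
       xlab = "alignment position", ylab = "entropy (bits)",
       main = "entropy profile")
  grDevices::dev.off()
  c(files, f)
}
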