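#' Deterministic worked-example alignment
#'
#' Builds the small demonstration dataset used throughout the documentation
#' and tests: 7 sequences (query q1-q3, reference r1-r4) by 24 columns,
#' together with a 7-leaf tree separating the two groups (internal node
#' labels `query` and `reference`) and the corresponding partition.
#'
#' The diagnostically meaningful columns are fixed by construction:
#'
#' * position 1: binary (query uniform A vs reference uniform G);
#' * position 5: asymmetric (query GGG vs reference AATT; vectors
#'   `<0,0,3,0,0,0>` and `<2,0,0,2,0,0>`);
#' * position 13: asymmetric (query TTT vs reference CCGG);
#' * positions 8, 19, 20, 23: noisy (the query state recurs in the
#'   reference group);
#' * positions 15-17: conserved (both groups uniform C / G / T);
#' * positions 19+20 jointly: query pairs CA,CA,CA vs reference pairs
#'   GA,GA,CT,CT -- a diagnostic combined character;
#' * positions 19+23 and 20+23: pairs CT resp. AT occur in both groups, so
#'   these combinations stay noisy.
#'
#' All remaining columns are deterministic filler with a non-uniform query
#' (hence non-candidates), cycling through three fixed column patterns.
#'
#' @return List with elements `alignment` ([sig_alignment()]), `tree`
#'   (`phylo`) and `partition` (`sig_partition`).
#' @export
#' @examples
#' wx <- generate_worked_example()
#' wx$alignment
generate_worked_example <- function() {
  ids <- c("q1", "q2", "q3", "r1", "r2", "r3", "r4")
  mat <- matrix("", nrow = 7L, ncol = 24L, dimnames = list(ids, NULL))

  set_col <- function(p, q, r) mat[, p] <<- c(q, r)

  set_col(1L, c("A", "A", "A"), c("G", "G", "G", "G"))   # binary
  set_col(5L, c("G", "G", "G"), c("A", "A", "T", "T"))   # asymmetric
  set_col(8L, c("A", "A", "A"), c("A", "A", "G", "G"))   # noisy
  set_col(13L, c("T", "T", "T"), c("C", "C", "G", "G"))  # asymmetric
  set_col(15L, c("C", "C", "C"), c("C", "C", "C", "C"))  # conserved
  set_col(16L, c("G", "G", "G"), c("G", "G", "G", "G"))  # conserved
  set_col(17L, c("T", "T", "T"), c("T", "T", "T", "T"))  # conserved
  set_col(19L, c("C", "C", "C"), c("G", "G", "C", "C"))  # noisy
  set_col(20L, c("A", "A", "A"), c("A", "A", "T", "T"))  # noisy
  set_col(23L, c("T", "T", "T"), c("T", "G", "T", "G"))  # noisy

  # filler columns: non-uniform query => non-candidate; three fixed
  # patterns cycled so the entropy profile shows some texture
  fillers <- list(
    list(q = c("A", "C", "A"), r = c("G", "G", "T", "T")),
    list(q = c("C", "T", "C"), r = c("C", "C", "A", "A")),
    list(q = c("G", "A", "G"), r = c("T", "T", "G", "G"))
  )
  free <- setdiff(seq_len(24L), c(1L, 5L, 8L, 13L, 15L, 16L, 17L, 19L, 20L, 23L))
  for (n in seq_along(free)) {
    f <- fillers[[(n - 1L) %% length(fillers) + 1L]]
    set_col(free[n], f$q, f$r)
  }

  aln <- sig_alignment(mat)
  tree <- ape::read.tree(
    text = "((q1,q2,q3)query,(r1,r2,r3,r4)reference);")
  part <- resolve_groups(aln, c("q1", "q2", "q3"))
  list(alignment = aln, tree = tree, partition = part)
}

#' Seeded random alignment with planted column classes
#'
#' Generates a reproducible alignment in which chosen columns provably
#' realize a requested candidate class, for property testing (planted-class
#' recovery). Each planted column is constructed directly from the
#' set-based class definitions: binary = uniform query state vs a different
#' uniform reference state; asymmetric = uniform query vs >= 2 reference
#' states, none equal to the query's; noisy = uniform query whose state
#' recurs in a non-uniform reference; conserved = one state everywhere.
#' Unplanned columns are randomized non-candidates (non-uniform query, or a
#' query N when the query group has a single sequence).
#'
#' States are drawn from the five informative states A, C, G, T, gap; N
#' appears only where needed to force non-candidacy.
#'
#' @param n_query,n_reference Group sizes (>= 1; asymmetric and noisy
#'   columns additionally need `n_reference >= 2`, non-uniform fillers need
#'   `n_query >= 2` or fall back to a query N).
#' @param length Number of alignment columns.
#' @param class_plan Named character vector: names are 1-based positions,
#'   values in `c("binary","asymmetric","noisy","conserved","non_candidate")`.
#' @param seed Integer seed; identical arguments give identical output.
#' @return List with `alignment`, `partition` and `classes` (the expected
#'   class label of every column, `non_candidate` where unplanned).
#' @export
#' @examples
#' fx <- generate_random_fixture(3, 4, 30, c("3" = "binary", "7" = "noisy"),
#'                               seed = 42)
#' fx$classes[c(3, 7)]
generate_random_fixture <- function(n_query, n_reference, length, class_plan,
                                    seed) {
  stopifnot(n_query >= 1L, n_reference >= 1L, length >= 1L)
  plan_pos <- as.integer(names(class_plan))
  if (length(class_plan) > 0L) {
    if (anyNA(plan_pos) || any(plan_pos < 1L) || any(plan_pos > length)) {
      stop("class_plan positions must be integers within the alignment length",
           call. = FALSE)
    }
    if (anyDuplicated(plan_pos)) {
      stop("class_plan positions must be unique", call. = FALSE)
    }
    bad <- setdiff(class_plan, .sig_classes)
    if (length(bad) > 0L) {
      stop("unknown class(es) in plan: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (n_reference < 2L && any(class_plan %in% c("asymmetric", "noisy"))) {
      stop("asymmetric and noisy columns need n_reference >= 2",
           call. = FALSE)
    }
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))

  informative <- c("A", "C", "G", "T", "-")
  make_col <- function(class) {
    switch(class,
      conserved = {
        s <- sample(informative, 1L)
        c(rep(s, n_query), rep(s, n_reference))
      },
      binary = {
        s <- sample(informative, 2L)
        c(rep(s[1], n_query), rep(s[2], n_reference))
      },
      asymmetric = {
        s <- sample(informative, 3L)
        ref <- sample(s[2:3], n_reference, replace = TRUE)
        ref[1:2] <- s[2:3]  # both alternative states guaranteed present
        c(rep(s[1], n_query), ref)
      },
      noisy = {
        s <- sample(informative, 2L)
        ref <- sample(s, n_reference, replace = TRUE)
        ref[1:2] <- s  # query state recurs AND a second state is present
        c(rep(s[1], n_query), ref)
      },
      non_candidate = {
        ref <- sample(informative, n_reference, replace = TRUE)
        if (n_query >= 2L) {
          s <- sample(informative, 2L)
          qry <- sample(s, n_query, replace = TRUE)
          qry[1:2] <- s  # query provably non-uniform
        } else {
          qry <- "N"  # single-sequence query: N forces non-candidacy
        }
        c(qry, ref)
      },
      stop("unreachable class ", class)
    )
  }

  classes <- rep("non_candidate", length)
  classes[plan_pos] <- unname(class_plan)
  mat <- vapply(classes, make_col, character(n_query + n_reference))
  ids <- c(paste0("q", seq_len(n_query)), paste0("r", seq_len(n_reference)))
  rownames(mat) <- ids
  aln <- sig_alignment(mat)
  part <- resolve_groups(aln, paste(ids[seq_len(n_query)], collapse = ","))
  list(alignment = aln, partition = part, classes = classes)
}
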