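---
title: "Detecting diagnostic signature characters in nucleotide alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diagnostic signature characters in nucleotide alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigchar)
```

## The problem

A taxon diagnosis names characters that separate a taxon of interest (the
*query group*) from its relatives (the *reference group*). With gene
sequence data, every column of a multiple alignment is a potential
molecular character, and the question becomes: at which positions does
every query sequence carry a state that no reference sequence carries?
`sigchar` answers this with a ranking and classification of *all*
alignment positions, so that the user can audit near-diagnostic positions
as well as the unequivocal ones.

## Model and metrics

The state space is the fixed ordered list `⟨A, C, G, T, -, N⟩`: four
nucleotides, the gap (a deletion is a legitimate, inheritable character
state) and N for missing information. At each position `p`, each group is
reduced to a *character state vector* of counts over this list, `Q_p` for
the query and `R_p` for the reference group. The L1 norm of each vector
equals its group size, an invariant the tests enforce everywhere.

Three per-position metrics drive everything:

* **discriminative power** `d = ||Q_p − R_p||₁ / (||Q_p||₁ + ||R_p||₁)`.
  Writing the L1 identity out dimension-wise shows `d = 1` exactly when no
  state is counted in both vectors, and `d = 0` exactly when the vectors
  coincide. Because the counts are integers, the package implements the
  `d = 1` decision as the exact support-disjointness test, never as a
  floating-point comparison; `d` itself is exported as a double for
  display and sorting only.
* **query rank** and **reference rank**: the number of non-zero
  dimensions, i.e. how many distinct states each group exhibits.

The *diagnostic relevance ranking* orders all positions lexicographically
by d-power (descending), q-rank (ascending), r-rank (ascending). Beyond
these three keys the order is unspecified in the underlying method; the
package breaks remaining ties by position ascending so that runs are
deterministic and tables byte-reproducible.

A position is a *candidate character* when the query group is uniform and
N-free there (`q-rank = 1`, query N count 0): only such positions can be
written into a diagnosis. Candidates fall into four classes — binary
`(d, q, r) = (1, 1, 1)`, asymmetric `(1, 1, >1)`, noisy `(<1, 1, >1)` and
conserved `(<1, 1, 1)` — and the binary and asymmetric ones (`d = 1`) are
*signature characters*: they separate every query member from every
reference member. Non-candidate positions remain in the ranked table
(ranking covers all positions) but carry the label `non_candidate` and are
never classified further.

An equivalent set-based formulation — compare the set of distinct query
states with the set of distinct reference states — is implemented
independently in the test suite and checked against the vector-metric
implementation on tens of thousands of random columns.

## Combined characters

Noisy candidates are individually useless for diagnosis (the query's state
recurs in the reference group), but two noisy positions `i < j` may be
*jointly* diagnostic: no reference sequence need carry the query's state
*combination*. `sigchar` evaluates all pairs of noisy candidates within a
user-chosen *k-window* (`j − i < k`, distance in alignment columns,
gap columns included) on 36-dimensional pair state vectors indexed by the
ordered state pairs, with the identical metrics and class thresholds.
Because each paired position has a uniform query, the pair's query rank is
always 1 — a property the tests assert on generated fixtures. Pairs that
remain noisy are reported with their class rather than discarded, so
near-diagnostic combinations can be audited. Combinations of more than two
positions are out of scope; the pair machinery (ordered tuples of
positions) extends naturally should that change.

## Entropy profile

The per-column Shannon entropy (bits) of the **whole input alignment** —
including sequences assigned to neither group — provides sequence context:
peaks mark variable regions, troughs conserved ones. The formula for the
profile is a package choice (the method this follows cites an external
tool without reprinting a formula): frequencies are taken over the five
informative states `A, C, G, T, -`, N is excluded and the remaining
frequencies renormalized, because N carries no state information; a column
of pure N has entropy 0. The gap is kept as an informative state since
indel patterns mark variable regions. Setting
`entropy_include_missing = TRUE` (CLI `--entropy-include-missing`) counts
N as a sixth state instead. Exported values are never smoothed; values lie
in `[0, log2(5)]` (or `log2(6)` with N included).

## Input handling and parameters

* **States** are normalized on read: lowercase to uppercase, `U → T`,
  `. → -`. IUPAC degeneracy codes (R, Y, S, W, K, M, B, D, H, V) encode
  partial information the 6-state model cannot hold; the default policy
  `mask` replaces them with N and warns (N is the model's catch-all for
  non-informative states), `strict` refuses the file. Anything else is an
  error naming the sequence and offset.
* **Groups** come as comma-separated id lists or as a labelled node of an
  optional Newick tree (the clade's leaves form the group; a leaf label
  selects a singleton). An absent reference group defaults to the
  complement of the query group. Matching is exact string equality after
  whitespace trimming; the FASTA id is the first whitespace-delimited
  header token. Groups must be disjoint, non-empty subsets of the
  alignment ids. Sequences in neither group are excluded from all state
  vectors but included in the entropy profile.
* **Reference-group N states** are counted literally: they inflate the
  reference rank and, since candidates exclude N, can turn a would-be
  binary position asymmetric. Rather than special-casing the vector math,
  each table row carries `ref_has_missing` so users can discount
  asymmetric calls driven by missing data.
* **k** (integer ≥ 1, default off) is the only search parameter; `k = 1`
  pairs nothing, `k ≥` alignment length is an unwindowed all-pairs search
  over the noisy candidates.
* **Consensus display**: each row shows the group's uniform or prevalent
  state; ties between equally frequent states go to the earliest state in
  alphabet order. Display only — classification never reads it.

## The fixture generators

`generate_worked_example()` rebuilds the small demonstration dataset used
in all documentation: 7 sequences × 24 columns. Ten columns are fixed by
the constraints the method's worked examples state (one binary, two
asymmetric, four noisy, three conserved, with positions 19/20 forming a
diagnostic pair and 19/23, 20/23 sharing pairs across groups); the 14
unconstrained columns are deterministic filler cycling three fixed
non-candidate patterns (non-uniform query), chosen so the entropy profile
shows texture. It emulates a tiny, gap-free, clean alignment; real data
with gaps, missing stretches and larger groups will exercise the same
code paths but green tests on the fixture establish correctness of the
metrics and classes, not robustness to alignment error — an alignment
with misaligned homology will produce confidently wrong characters.

`generate_random_fixture()` plants requested classes column-by-column
directly from the set-based class definitions (e.g. noisy = uniform query
state that provably recurs in a non-uniform reference) under a fixed seed,
drawing states from the five informative symbols; N appears only to force
non-candidacy when a single-sequence query cannot be made non-uniform.
Planted columns are recovered with 100% label agreement by construction —
that property tests the classifier, not the generator's realism: columns
are independent, with no phylogenetic correlation, rate variation or
indel structure.

## Numerical and degenerate-input choices

* All classification decisions are integer tests (support disjointness,
  rank counts); no tolerance parameters exist anywhere.
* Zero state vectors (empty groups) are rejected, not defaulted.
* Positions are 1-based in every public interface.
* TSV output prints d-power with 4 decimals; `run_metadata.json` records
  parameters, input MD5 digests, timestamp and package version. Re-runs
  on identical inputs reproduce every TSV byte-for-byte.

## Known limitations

* Nucleotide alphabet only; no amino acids, no unaligned input.
* Group sizes are taken at face value: a single-sequence query makes every
  non-N column "uniform", so candidate calls from tiny groups are weak
  evidence.
* The entropy profile is descriptive context, not a test statistic, and
  is not numerically comparable to other entropy tools.
* At most two positions combine; the reported combined characters are not
  corrected for the number of pairs examined.
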