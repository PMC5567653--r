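---
title: "Detecting conserved signature indels in protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved signature indels in protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csindel)
```

## The model behind the scanner

A conserved signature indel (CSI) is a discrete molecular marker: an
insertion or deletion that arose once, in the common ancestor of a group of
homologs, and was then vertically inherited.  Three observable properties
follow from that generative story, and each becomes one stage of the
scanner:

1. **The indel is a gap-run difference between sequences.**
   `find_gap_runs()` extracts maximal per-row gap runs; runs touching either
   alignment end are discarded because ragged termini reflect fragment
   boundaries (database truncations, domain excisions), not indel events.
   `cluster_loci()` merges runs whose column intervals overlap
   (single-linkage) into one locus whose interval is the union hull — this
   is what lets two groups carry indels of different lengths *at the same
   position* appear as a single locus.

2. **The indel sits in a conserved neighbourhood.**  A locus passes
   `assess_flanks()` when at least `min_conserved` columns in the `window`
   columns on each side are conserved.  "Conserved" is operationalised as:
   consensus residue fraction at least `threshold` over the evaluated rows,
   with a *gap-veto* — a column containing any gap can never count.  The
   veto prevents a neighbouring indel from supplying its own flank evidence.
   The classical criterion for signature indels is 5–6 conserved residues
   within the neighbouring 30–40 positions on each side; we take the
   permissive ends as defaults (`min_conserved = 5`, `window = 30`,
   `threshold = 0.8`) and expose all three as parameters.

3. **The indel state is group-uniform.**  `classify_specificity()` scores
   each row by its residue count within the locus hull and partitions
   groups into a residue-bearing side and a fully-gapped side.  The
   *signature side* is the minority side (fewer groups; ties resolved
   toward the gapped, deletion-relative reading).  One signature group
   gives `group_specific`; several with one common length,
   `shared_by_groups`; several, each internally uniform but with different
   lengths, `paired_lengths`; anything mixed is `unclassified` and dropped
   by default.  `exceptions` (default 0) allows a stated number of
   contradicting rows, because "specifically present" is read as
   exceptionless within a curated set.

Two modelling caveats are deliberately baked in.  *Polarity is relative*:
with no outgroup available for a family-specific domain, no ancestral state
can be inferred, so calls say `insert_relative`/`deletion_relative`, never
"insertion event"/"deletion event".  *Positions are fuzzy*: when compared
groups are highly diverged, the exact placement of an indel inside a
conserved region can shift by a few residues between equally defensible
alignments, so truth-matching in the tests accepts a ±3-column shift
(`score_calls(tol = 3)`), and reported reference coordinates
(`map_reference()`, e.g. against a human DGK-ε row) should be read with the
same tolerance.  For deletion-relative calls the gapped length must be
uniform; insert-relative calls may carry a length *range* (e.g. 16–24)
because secondary expansion events inside the signature group are legal and
observed.

## The phylogeny the signatures are read against

Signature interpretation needs a tree.  The package builds a desk-scale,
fully deterministic one: pairwise maximum-likelihood distances under the
JTT amino-acid model, neighbour joining, column bootstrap, midpoint rooting.

* `jtt_model()` assembles the rate matrix from the embedded published
  exchangeabilities and equilibrium frequencies, normalised to one expected
  substitution per site per unit time; the unit tests assert zero row sums,
  detailed balance and the unit rate.
* `jtt_distance()` maximises the two-sequence likelihood
  $\prod_c \pi_{a_c} P_{a_c b_c}(t)$ over $t \in [10^{-8}, 10]$ by bounded
  scalar optimisation with pairwise gap deletion; the count table is
  symmetrised, which leaves the likelihood unchanged (reversibility) and
  makes the estimate exactly direction-independent.  Saturated pairs are
  capped at $t = 10$ with a warning.  Ambiguity codes (X/B/Z/U) are treated
  as missing.
* `bootstrap_supports()` resamples columns with replacement, rebuilds
  distances and the NJ tree per replicate, and counts bipartitions; support
  for *any* tip set can be queried afterwards with `clade_support()`,
  whether or not the point tree contains it.  Complete-column gap deletion
  (`strip_gap_columns()`) is required first, which mirrors the usual
  practice for distance and likelihood computations on gapped protein
  alignments.
* `tree_log_likelihood()` is a plain Felsenstein pruning likelihood (site
  independence, no rate heterogeneity), intended for *relative* comparison
  of candidate topologies; it is checked against brute-force summation over
  internal states on three-leaf trees to 1e-10.

A full maximum-likelihood tree search is intentionally out of scope: the
reproducible surface of such an analysis is the topology-level structure
(which groups are monophyletic, which associations are weak), not a
particular search engine's log likelihood, and NJ on ML distances recovers
that structure deterministically in seconds.

## What the simulator emulates — and what it does not

`simulate_family()` evolves a root sequence (drawn from JTT equilibrium)
along a given guide tree by exact stochastic simulation of the substitution
process (so per-branch event counts are available and are tested for
Poisson consistency).  Indels are then *planted*, deterministically, on the
stem branch of their clade: every clade member and only clade members carry
the event, inserts open gap columns in all other rows, and invariant flank
masks are excluded from substitution.  A truth table records each planted
locus in final alignment coordinates.

This is a benchmark generator, not an indel-process model: indel lengths
and positions are specified, not drawn from an empirical length
distribution; alignment error is not simulated (the input to the scanner is
assumed to be a *curated* alignment); and flank masks make conservation
explicit rather than emergent.  Consequently, perfect scanner
precision/recall on these fixtures demonstrates that the detection logic is
exact under the CSI generative assumptions — it does not certify
performance on poorly aligned or unalignable regions of real data.  One
realism concession: residues inside planted inserts evolve along the whole
tree like any other column, so within-clade insert variation arises
naturally.

### The DGK-like fixtures

`make_dgk_like_fixture()` and `make_full_domain_fixture()` instantiate the
study conditions of the vertebrate diacylglycerol kinase catalytic-domain
analysis: ten isozymes in five classes (three representatives each —
mammal, bird, fish; 30 sequences), with the published signature inventory
planted at known loci.  `make_full_domain_fixture()` is a synthetic
stand-in for an edited 364-column catalytic-domain alignment (no curated
sequences are redistributed; every residue is simulated): ragged terminal ends
(30 columns) and non-clade-consistent decoy gap runs (21 columns) are added
so that, together with the planted signature gaps (53 columns), exactly 260
of the 364 columns are gap-free.  The decoys exercise the scanner's
precision: they are gap runs spread across unrelated classes, so they must
be rejected as `unclassified`.

Fixture design choices worth stating explicitly:

* **Guide-tree geometry.**  Class stems (0.20–0.25 substitutions/site) are
  long enough that the five classes are recovered as monophyletic with
  ~100% bootstrap support; the ε stem (0.70) and θ stem (0.45) are the two
  longest, so midpoint rooting places those clades outermost; the κ and ζ
  tips are split across two clusters inside their classes (κ with δ and
  with η; ζ around the ι clade), reproducing the polyphyletic branching
  reported for those isozymes.
* **The weak class I + class IV association.**  The I+IV stem is nearly
  zero: one masked diagnostic column (Q in classes I and IV, E elsewhere)
  plus a 0.002 stem.  This was calibrated so that the association is
  recovered but with weak bootstrap support, targeting the ~50% regime the
  study design implies; support for a signal this small is intrinsically
  variable between simulated datasets (roughly 15–95% across seeds), which
  is itself a faithful property of weak associations.  The acceptance test
  therefore averages the support over three replicate analyses instead of
  asserting on one draw.
* **ATP-binding motif.**  The kinase motif G-X-G-X-X-G is planted as fixed
  columns (GAGTLG), with the mammalian κ row carrying S in place of the
  final G — the one deviation `check_atp_motif()` should flag.  Flank-mask
  columns are drawn from the equilibrium distribution *excluding glycine*
  so the planted motif window is unambiguous.
* **Masked-column load.**  Flank masks are 6 columns per side per locus.
  Wider masks make flank detection trivial but freeze so much of the
  alignment that pairwise distances compress and the deep tree structure
  degrades; 6 columns satisfies the ≥5 rule with the smallest invariant
  footprint.

## Numerical and degenerate-input choices

* Columns are 1-based and intervals closed, matching residue-numbering
  conventions in signature figures.
* Consensus ties break alphabetically; NJ inherits `ape::nj` tie-breaking;
  negative NJ branch lengths are clamped to zero.
* `column_profile()` excludes gaps from frequency denominators and never
  counts X/B/Z/U toward a consensus.
* Empty alignments, ragged rows, duplicate ids, unknown ids/groups,
  all-gap columns, <3 taxa for NJ, all-zero branch lengths for midpoint
  rooting, and out-of-vocabulary isozyme names are all hard errors with
  named offenders.
* Smith–Waterman scores use the classical empty-alignment floor: when the
  best local alignment is negative the score is 0 and the alignment empty.
* Classifier thresholds are fractions of the query self-score
  (`s_min = 0.4`, `m_min = 0.05`); there is no principled universal value
  for either, so both are exposed and documented as heuristics.
* All stochastic entry points take explicit seeds; a fixed seed makes every
  artifact byte-identical, and the pipeline keeps timestamps out of all
  outputs except the log.

## Problem sizes used in the tests

The shipped test-and-acceptance runs use the 30-sequence × 364-column
fixtures (bootstraps of 100 replicates), twenty independent simulated
families for the scanner benchmark, pairwise simulations of 10⁴ columns for
distance-estimator calibration, and 100-branch star trees for the Poisson
check — sizes chosen so the whole suite completes in minutes on a single
CPU while leaving each statistical check enough power to fail visibly if
the implementation drifts.

## Known limitations

* Paired deletions of different lengths at one locus (as opposed to paired
  inserts) are classified from the residue-bearing perspective and may be
  reported as a specific deletion of the deeper-gapped group rather than as
  a pair; paired inserts are the canonical and tested case.
* The scanner consumes one alignment; it does not attempt to reconcile
  alternative alignments of the same family (two readings of nearby 1 aa
  deletions in different input alignments are reported as-is, unmerged).
* No rate heterogeneity across sites in distances or likelihoods.
* `exceptions > 0` relaxes group uniformity globally per locus, not per
  group.
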