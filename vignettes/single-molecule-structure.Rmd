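---
title: "Single-molecule RNA structure analysis with smstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule RNA structure analysis with smstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smstruct)
```

## The measurement model

`smstruct` analyzes chemical probing experiments read out on single
molecules. A reagent such as DEPC marks accessible (unpaired) adenosines;
native sequencing of the probed molecules yields, per read and per base, a
continuous statistic comparing the treated signal to an untreated control,
on a `[0, 1]` scale where low values indicate modification. The package
takes those statistics as its starting point — the signal-level comparison
that produces them is upstream and out of scope — and treats each read as a
noisy snapshot of one molecule's conformation:

* a base that is open in the molecule's structure is modified with some
  probability `p_open` (well below 1: single hits per site, partial
  reactivity);
* a paired base is still *called* modified at a floor rate `p_closed`,
  combining true transient opening ("breathing") with false calls of the
  signal comparison;
* the statistic is missing near the 3' end of every read, because the
  signal model emits nothing for the last bases.

Everything downstream is built to be honest about this noise: calibration
measures the false-call floor empirically, and the pairwise statistics are
chance- and distance-corrected so that structure, not noise, drives them.

## Threshold calibration

On control material known to be unmodified, every call is false, so the
fraction of control statistics below a threshold *t* is the empirical FDR
of calling at *t*. `fdr_curve()` evaluates this on a grid (default step
0.05) and `select_threshold()` returns the largest grid threshold whose FDR
does not exceed the target (default 0.15). Grid selection without
interpolation is deliberate: the FDR–threshold relation is close to linear
in the relevant range, so interpolation would add model assumptions without
changing the operating point. Calls use a strict inequality
(`statistic < threshold`); boundary values count as unmodified. With the
default control model (15% of null mass below 0.2) the selected threshold
is 0.2 — though on a finite control sample the empirical FDR at that grid
point sits on either side of 0.15 with nearly equal probability, in which
case the next grid point down is returned; this is sampling variation, not
an error.

`corrected_rate()` removes the false-call fraction from an observed rate
(`rate × (1 − fdr)`): at an observed 31% and FDR 0.15 the corrected
estimate is 26%. `filter_reads()` drops under- and over-modified reads; the
default window (4–18 modifications, inclusive) is calibrated for a short
hairpin construct and must be re-chosen per molecule.

## Pairwise co-dependencies

For positions *U* and *V*, joint modification counts are taken over the
reads covering both; pairs with fewer than 10 such reads are ineligible
(`min_reads`, configurable). Mutual information uses natural logarithms
throughout — the convention of the reference adjusted-mutual-information
implementations — and the chance term E[MI] is the exact expectation over
all 2×2 tables with the observed margins under the hypergeometric
(permutation) distribution, summed in closed form rather than sampled.
The adjusted score is `(MI − E[MI]) / (avg(H(U), H(V)) − E[MI])`; when the
denominator would vanish it is clamped away from zero at machine epsilon,
mirroring the reference implementation, and a pair in which either column
is constant scores 0 by convention — zero observed variation carries zero
information, and such pairs are excluded from distance normalization
entirely rather than entering it as exact zeros.

Because the pore reads several bases at once, nearby positions share signal
for purely technical reasons. All pairwise statistics are therefore
z-scored within each distance class |i−j|, using the population standard
deviation (the full finite population of pairs at that distance is in
hand, so the n−1 correction would be wrong). Distance classes with fewer
than `min_pairs_per_distance` (default 2) eligible pairs, or zero spread,
map to 0. No additional proximity mask is applied: normalization, not
exclusion, handles the short-range dependence.

Co-openness is implemented symmetrically as n₁₁/(n₁₁+n₁₀+n₀₁) — the
probability both bases are modified given at least one is. The prose
definition of "one modified given the other is" is directional, but the
quantity is displayed as a symmetric heatmap, so the symmetric realization
is the default and the two directional conditionals are exposed via
`co_openness(..., directional = TRUE)`.

## Structural heterogeneity

`constrained_fold()` folds a sequence with a set of banned positions that
may not pair — the in-silico counterpart of treating called modifications
as hard constraints. The builtin engine maximizes base-pair count
(Watson–Crick plus GU wobble, minimum hairpin loop of 3 unpaired bases) by
dynamic programming and reports `energy_score = −pairs`. It is a
combinatorial, not thermodynamic, model: adequate for counting and ranking
structure groups on short constructs, and exactly testable against
exhaustive enumeration. Ties in the dynamic program are broken
deterministically — the smallest opening index pairs first, with its
smallest admissible partner — so identical inputs give identical
structures. A thermodynamic folder can be plugged in through
`sms_external_engine()` (FASTA plus a constraint line on stdin, dot-bracket
on stdout); its output is checked post-hoc and rejected if it pairs a
banned position.

`group_reads_by_structure()` folds each read with its modified positions
banned (distinct constraint sets are folded once and reused) and pools
identical dot-brackets. `assign_reads()` clusters reads to candidate
structures by the binary distance `1 − |M∩O| / |M∪O|` between the read's
modified set M and the structure's open set O, restricted by default to the
probed adenosines (all-positions comparison is a flag; the probed-base
default reflects that unprobed bases carry no evidence either way). Two
empty sets give distance 0; ties in assignment go to the lowest structure
index. `structure_permutation_test()` shuffles each structure's open/paired
labels across positions — independently per structure and per permutation,
preserving open-set size, the minimal label-randomization null — and
compares per-read minimum distances to true versus permuted structures with
a Welch t-test (no variance-equality assumption). The exact p-value is
reported rather than a floor.

## Differential accessibility and transcript features

`differential_scan()` compares two conditions position by position.
Replicates are the strata of a Cochran–Mantel–Haenszel test — the only
stratification variable available in a replicated two-condition design —
computed without continuity correction, so a single stratum reduces to
(N−1)/N times the Pearson chi-square. Effect size is a log2 fold change
with a Haldane–Anscombe pseudocount of 0.5, keeping zero-count positions
finite. P-values are Benjamini–Hochberg-adjusted across the positions of
one scan (one transcript), and positions with `q < 0.1` are flagged.

One property of this design is worth stating plainly: BH controls the
*expected proportion* of false flags at q, so in a scan where nothing is
truly different, the probability of at least one (spurious) flag is itself
approximately q. Across many null scans at q = 0.1, roughly one in ten will
show a stray flag; and in a scan with real effects, an occasional extra
position riding along at q just under 0.1 is within the contract of FDR
control, not a defect. Users who need family-wise control should lower
`q_cut` or apply a Bonferroni-style correction externally.

Metaprofiles z-score each gene's rate profile against its own covered
positions (population sd; a flat profile maps to zeros so a constant gene
contributes no artefactual shape), align profiles at an anchor (translation
start or stop), and average per offset across genes, dropping offsets
covered by fewer than `min_genes` (default 10). Windows default to ±100 nt;
both are configurable. Stop-codon groups (UAA/UGA/UAG) are profiled
separately; motif windows average the raw rate 50 nt upstream to 20 nt
downstream of each motif start, truncating at profile boundaries; gene
ranking averages over all probed, non-missing cells with ties broken
stably by gene id.

## The synthetic-data generator

`ensemble_spec()` describes a weighted mixture of structures with
modification probabilities `p_open` and `p_closed` (scalars or per-position
vectors), a probed-position mask (default: adenosines), statistic emission
distributions, and a trailing window of `missing_tail = 13` positions with
no statistic (ten bases the signal model never emits plus three lost to its
context smoothing). Defaults are calibrated to the assay the package
models: `p_closed = 0.15` matches the empirical false-call floor, and the
null statistic distribution places 15% of its mass below 0.2 so that
threshold calibration on simulated controls lands at the same operating
point; the alternative places 95% below 0.2. These are assay-calibrated
defaults, not universal constants. Modification events are independent
across positions given the structure — dependence enters only through which
structure a read samples, which is exactly the signal the dAMI analysis is
designed to detect. The generator has a per-position probability hook but
no sequence-context (k-mer) miscall model, no sequencing-error or alignment
simulation, and no signal-level simulation; passing tests therefore
demonstrate correctness of the statistics under the stated noise model, not
robustness to context-dependent miscalls present in real nanopore data.

Bundled fixtures: `fixture_hairpin()` (12 bp stem, 8 nt A-rich loop,
unstructured A/C linker, 60 nt; the sequence is designed so the builtin
engine's unconstrained fold is exactly the reference hairpin, which the
test-suite asserts), `fixture_two_domain()` (a riboswitch-like construct
whose aptamer domain is open in one conformation and paired in the other,
with exactly 10 probed aptamer adenosines; `bound = TRUE` drops their
accessibility to 0.1, emulating ligand occlusion), `fixture_stem_flip()`
(hairpin stem either fully formed or fully molten, all positions probed —
the textbook joint-flip co-dependency signal) and
`fixture_transcriptome()` (mRNA-like genes with UTR/CDS annotation,
planted open windows upstream of start and stop anchors, UGA-specific
closing at the 3'UTR start, and an accessible polyadenylation-motif
window; all positions probed as a dense-probing idealization).

## Conventions and numerical choices

* Positions are 1-based and inclusive everywhere — matrices, structures,
  annotations, reports — the native R convention; the BED-like annotation
  format is 0-based half-open on disk and converted at the boundary.
* Missing values are `NA` in memory and the literal string `NA` in the TSV
  dialect; writers and readers round-trip matrices exactly.
* ROC AUC is the probability a random positive outranks a random negative
  with ties at half credit (midrank formula), identical to trapezoidal
  integration of the curve.
* Seeds are explicit arguments of every stochastic function and are
  recorded in results and CLI run manifests; a missing CLI seed is drawn
  and recorded rather than left implicit.

## Problem sizes in the test-suite

The packaged tests run the analyses at sizes chosen to make their
statistical assertions sharp but quick: calibration on 500 × 60 null
matrices; calling performance on 3000 reads; oracle equivalence of the
adjusted-MI on 200 random column pairs (N up to 500) and of the folder on
100 random sequences up to length 14 against exhaustive enumeration;
clustering of 600 reads to three disjoint-open-set structures with a
10,000-fold permutation null; and 100 repeated null differential scans of
2 × 200 reads. The whole suite completes in a few minutes on one CPU.

## Limitations

The builtin folder ranks structures by pair count, not free energy, so its
`energy_score` is a proxy; use an external thermodynamic engine where
energies matter. The simulator's independence-given-structure assumption
understates the blocky, context-dependent noise of real signal-level
calls. The CMH stratification assumes replicates are exchangeable strata;
batch structure beyond replicates is not modeled. And the probed-base mask
restricts all structural inference to adenosines when the reagent is
A-specific — stems poor in adenosines are simply invisible, which is a
property of the assay, not the implementation.
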