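---
title: "Models and methods: 4DTv dating, RIL filtering, and gene-family statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: 4DTv dating, RIL filtering, and gene-family statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milletevol)
```

This vignette is the package's own account of the models it implements, the
defaults it ships, and the choices made where the underlying procedures are
conventionally under-specified. Every empirical statement here is one the
test suite or `scripts/acceptance.R` computes; nothing is quoted from
external analyses.

## The 4DTv statistic

For two aligned coding sequences, a codon column is a *fourfold-degenerate
site* when neither codon carries a gap or `N`, both codons agree at their
first two positions, and that shared prefix is one of the eight fourfold
families of the standard genetic code. The 4DTv distance is the fraction of
those sites whose third positions differ by a transversion
(purine ↔ pyrimidine). Because transversions at fourfold sites are
selectively near-neutral and accumulate slowly, the statistic resists
saturation and separates duplication cohorts of very different ages in one
distribution.

Three conventions deserve explicit statement, since published descriptions
rarely fix them:

* **Strict intersection.** The site must be fourfold degenerate in *both*
  sequences simultaneously (identical two-base prefix). This is the
  conservative reading when a method description is silent; a
  single-sequence convention would admit columns whose degeneracy status
  differs between the two genes.
* **No multiple-hit correction by default.** `fourdtv()` reports the raw
  transversion proportion. A corrected distance
  `-log(1 - 2q)/2` — the closed-form inverse of the lumped
  purine/pyrimidine two-state chain, HKY-style — is available via
  `corrected = TRUE` but is not used by any default, because mode *positions*
  of the raw statistic are what the dating anchor is expressed in.
* **`N`-containing codons are excluded**, never treated as matches.

`dedup_tandem()` implements the rule that tandemly duplicated genes matched
to the same homeolog are counted once. "Tandem" is taken as genes on one
chromosome within a rank window (default **5 gene ranks**, transitively
closed); the retained representative is the result with the most scored
fourfold sites, with ties broken by the lexicographically smallest gene
identifier and then pair id. The window size and keep-rule are not dictated
by any published convention; the defaults make the operation deterministic
and conservative (clusters merge only nearby genes). Synteny anchors pass
through the standard collinear-block size rule: blocks with fewer than five
anchor pairs are dropped.

## Dating WGD peaks

`kde_modes()` estimates the density of a 4DTv sample with a Gaussian kernel
on a regular grid over [0, 1] (step **0.001**). `bandwidth = "auto"` is
Silverman's rule of thumb (`stats::bw.nrd0`); modes are grid points strictly
greater than both neighbours with density at least **5%** of the global
maximum (suppressing boundary ripples). Fewer than 10 finite values is an
error rather than a silent estimate. With finite samples a single true peak
can ripple into two adjacent local maxima under a near-optimal bandwidth, so
`run_dating_pipeline()` flags each class's highest-density mode
(`is_major`) as the headline estimate while still reporting all modes.

Dating is strict linear molecular-clock scaling through the origin:
`time = location × anchor_time / anchor_4dtv`, with the grass rho WGD
(4DTv 0.38, ~70 MY) as the default anchor. Nothing richer (rate
heterogeneity, mixture deconvolution, confidence intervals) is attempted —
the linear anchor is the only model the input statistic supports, and the
resulting dates should be read as order-of-magnitude placements. Note that
a peak at 0.032 under this anchor dates to 0.032 × 70 / 0.38 ≈ 5.9 MY;
published roundings of the same arithmetic vary between ~5.6 and ~5.8 MY,
which is within the uncertainty this method can claim.

Pairs with zero scorable fourfold sites are excluded before density
estimation with a logged count; classes with fewer than 10 pairs are
omitted with a warning.

## The substitution simulator

The generator's null model is deliberately minimal: a Kimura two-parameter
process applied *only to third positions of fourfold codons*. Ancestral
codons are drawn uniformly from the 61 sense codons; first and second
positions and non-fourfold codons are held fixed. Consequences: the
fourfold-site set of each pair is known exactly (ground truth travels with
the output), no stop codons can arise, and the observed transversion
proportion at a fourfold site after time *t* on both lineages has the
closed form

> E[4DTv] = ½ (1 − e^(−8βt)),

where β is the rate toward *each* transversion neighbour per site per
million years per lineage. Because the jump process's total rate α + 2β
does not depend on the current base, the exact exponential-waiting-time
realisation is equivalent to drawing a Poisson number of events and
applying them sequentially, which is how `simulate_codon_pairs()`
vectorises it. The test suite checks the closed form against an
independent numerically-powered two-state chain and against the simulator
at three divergence times.

`simulate_wgd_genome()` emits three cohorts mirroring an allotetraploid
grass genome: homeologs from the recent tetraploidization (default
t = 5.8 MY, expected 4DTv 0.032), cross-species orthologs (t = 18 MY,
0.081), and the deep rho background (t = 70 MY, 0.38). A single (α, β)
clock cannot place expected 4DTv at both 0.032 for t = 5.8 and 0.38 for
t = 70 — the curve through the first point saturates near 0.27 by 70 MY —
so by default each cohort's β is derived by inverting the closed form for
its (d, t) pair (`k2p_beta_for()`), with α = 2β. This per-cohort rate
heterogeneity is a deliberate device to make the simulated distribution
match the observed peak geometry; a user wanting a strict single clock can
pass `params = substitution_params(...)`. Default cohort sizes are 500
pairs of 400 codons — the order of a real WGD anchor-pair set, and enough
that kernel mode estimates are stable — and five tandem triplets are
planted as adjacent-rank extra copies matched to the same homeolog.

What the generator does *not* emulate: codon-usage bias, selection,
alignment error, GC heterogeneity, and gene conversion between homeologs.
Passing tests therefore demonstrate correctness of the statistics and the
recovery machinery under a clean null, not robustness to those real-data
complications.

## RIL marker filtering

Under single-seed-descent selfing from a fully heterozygous F1, marker
heterozygosity halves each generation: `p_het = (1/2)^(g−1)`, homozygote
classes equal. At F6 this is 31:2:31. `segregation_test()` is Pearson's
chi-squared with df = 2 and no continuity correction, with expected counts
taken from the **non-missing** total (the natural denominator when the
missing-rate criterion is assessed separately; the alternative — the full
line count — would conflate the two criteria). For df = 2 the upper tail
has the identity p = e^(−χ²/2), which the tests assert to 1e−12.

The three filter criteria follow their stated wording exactly: missing
fraction **strictly below** 0.20 (denominator = progeny lines only,
parents excluded), segregation p **strictly above** 1e−5, and QUAL
**≥ 999 inclusive**. Biallelic means exactly one single-base ALT and a
single-base REF. Markers whose progeny calls are all missing are
untestable by the chi-squared criterion; they are tallied separately and
fail through the missing-rate criterion rather than being charged to the
segregation tally.

The simulator overlays, in order: distortion (markers redrawn from an
alternative genotype distribution — a testing device for power, not a
genetic model), symmetric miscalls (relabel to each other state with
probability `error_rate/2`), then missingness. The optional `linkage`
option is a stationary mixing Markov chain — keep the previous genotype
with probability 1 − min(1, 2r), else redraw from the marginal — which
preserves the F_g marginal exactly while inducing the qualitative
correlation structure; it is not the true two-locus RIL distribution,
which is out of scope because only the per-marker filter consumes the
output. `haldane_r()` converts map distances for users who think in
Morgans.

## Expression diversity and enrichment

Per-gene tissue specificity is the Shannon entropy, in bits, of the gene's
expression proportions across tissues (base 2 is a display choice; all
comparative statements are base-invariant). Family summaries average
per-gene entropies within a family — not the entropy of the family-summed
profile — because the scientific question is whether *members* diversified
their patterns. Zero-expression genes are undefined and tallied, not
averaged.

The expression generator draws each profile from a symmetric Dirichlet
with concentration = `specificity` (small → tissue-specific, large →
uniform; the mean entropy is monotone in it), scaled by a log-normal
magnitude. Configuring specificity to decrease with family copy number
reproduces the qualitative copy-number/entropy trend; configuring it
constant removes the trend, which is what makes the relationship testable
rather than built-in.

`two_proportion_test()` is the pooled z test; the default applies a
Yates-style continuity correction of `(1/n1 + 1/n2)/2`, the variant whose
two-tailed p on the published transcription-factor expansion counts
(899/1313 vs 11,773/20,374) lands at 3.3e−14 — the uncorrected variant is
available and differs by ~20% in log-p, and only order-of-magnitude
agreement should ever be claimed for such a value. `fisher_exact2()` uses
the standard exact two-sided convention (sum of all same-margin table
probabilities not exceeding the observed table's, with the customary
1 + 1e−7 relative guard against floating-point ties); it is computed
directly from hypergeometric mass so that exhaustive enumeration checks
over all small tables are feasible, and it is cross-checked against
`stats::fisher.test` in the unit tests. BH adjustment delegates to
`stats::p.adjust(method = "BH")` and is verified against the brute-force
step-up definition.

## BTB domain architectures

Classification is generative rather than whitelist-based: the subgroup
label is the hyphen-joined sequence of recognised domains in start-coordinate
order (ties by end, then label) with consecutive duplicates collapsed —
two tandem BTB domains still read "BTB", since subgroup names conventionally
encode identity and order, not copy counts. Unrecognised labels map to
`other` and any such architecture reports as `BTB-other`, keeping the label
space closed. Strict order is used (MATH-BTB ≠ BTB-MATH); a
presence/absence reading would merge subgroups that differ biologically in
domain arrangement. Hits are filtered at E ≤ 1e−5 (inclusive), overlapping
same-domain hits merge to their union interval, and proteins without a
qualifying BTB hit are dropped with a logged count. The expansion flag on
`copy_number_table()` fires when the focal species' count is at least
`fold` (default 2) times the maximum among the other species and at least
1; when all other species have zero copies any focal copy flags, which is
the documented edge reading of "at least twofold".

## Problem sizes and numerical tolerances

The shipped tests exercise: 200 random alignments (≤ 300 codons) against a
literal 64-entry degeneracy-table oracle, exact equality; 500 pairs × ~500
fourfold sites per divergence time for the K2P closed form, within 3
standard errors; 20 seeded end-to-end WGD scenarios (500 pairs per cohort,
400 codons) requiring the dated age within 20% of truth in ≥ 18; 50 null
RIL simulations of 10,000 markers × 132 lines for filter calibration
(criterion-(b) failure < 1e−3 per run) and one fully distorted set for
power (≥ 99% failure); 1000 random p-vectors for BH; and every 2×2 table
with grand total ≤ 60 for the Fisher enumeration (equality to 1e−12).
These sizes keep each property statistically decisive while the whole
suite runs in minutes on one core.

## Known limitations

* The dating model is a single linear anchor; overlapping WGD peaks, rate
  variation between paralog classes, and uncertainty quantification are
  out of scope.
* The sequence null model mutates only fourfold third positions; it cannot
  probe the scorer's behaviour under alignment error or non-stationary
  composition.
* The RIL linkage option approximates correlation structure only; do not
  use it to benchmark map-construction algorithms.
* Synteny block *detection* is consumed as input, never inferred.
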