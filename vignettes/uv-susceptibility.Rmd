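---
title: "Methods: UV lesion susceptibility analysis with suscept"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UV lesion susceptibility analysis with suscept}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suscept)
```

# Scope and model

`suscept` analyzes the genomic distribution of UV-induced cyclobutane
pyrimidine dimer (CPD) lesions measured by immunoprecipitation sequencing,
and the mutational consequences visible in melanoma cohorts. The package
assumes upstream processing (alignment, deduplication, peak calling) has
already happened: its inputs are aligned-fragment intervals, binned signal
tracks, labeled segmentations (chromatin states, A/B compartments, repeat
families, genes), MAF-like mutation tables, reads, and Cq tables.

All coordinates are 0-based half-open (BED convention), because every
external format the package touches is BED-family. Telomeres are modeled
as the two anchor positions of a chromosome (0 and its length), not as
intervals: the subtelomeric definition (a fixed window proximal to each
end) needs only the ends. The centromere body is excluded from the
pericentric definition — "pericentric" means the two ±1 Mb flanks — since
lesion quantification inside the unassembled centromere is not meaningful;
this is a deliberate reading where the underlying convention is ambiguous.

## Binned tracks

A `binned_track` holds one value per fixed-width bin per chromosome; the
last bin of a chromosome may be partial and is retained. Fragments are
counted into the bin containing their midpoint, which makes the
conservation law exact (`sum(bins) == n_fragments`) and treats a lesion
IP fragment as the point event it marks; base-pair-overlap coverage could
be added later but is not the default. Fold-change tracks are

    log2((a/s_a + pc) / (b/s_b + pc))

with `s` the genome-wide library totals divided by 1e6 under `scale =
"cpm"` (or 1 under `scale = "none"`) and pseudocount `pc = 1` by default.
The pseudocount is added after scaling, so swapping numerator and
denominator negates every value exactly. On purely synthetic fragments,
generated at absolute per-bin rates rather than at a fixed sequencing
depth, `scale = "none"` is the appropriate setting: cpm scaling would
deflate a region-specific rate multiplier by exactly the library-size
shift that the multiplier itself induces. The package's own recovery
analyses therefore measure the pericentric log2(KO/WT) on raw counts.

Bins meet sub-bin segmentations by majority coverage: a bin is assigned to
the label covering most of it, ties going to the label whose interval
starts first. Quantile selections take exactly `round(f * n_nonmissing)`
bins, with ties at the threshold broken by genome order so results are
reproducible.

# Random-region enrichment tests

The landmark-region analysis asks whether the 100-kb bins overlapping the
pericentric or subtelomeric regions carry systematically different signal.
The observed statistic is the median value over those bins. The null is
built from `n_groups` (default 1,000) groups of random regions, each group
containing one region per template region with exactly the template's
length; chromosomes are drawn with probability proportional to the number
of feasible start positions, starts uniformly so the region fits, and
placements overlapping an exclusion set (by default the template itself)
are rejection-sampled with a cap of 10,000 tries. Everything is
deterministic given a seed.

Two p-values are reported. The Mann–Whitney p compares the selected bin
values against the pooled null bin values; it overstates the effective
sample size because pooled bins are not independent across groups, and is
reported for continuity with common practice. The primary, resampling-
honest p-value is empirical on the group medians with an add-one
correction. Two-sidedness is implemented symmetrically around the null
center `c` (the mean of the group medians):

    p = (1 + #{ |m_g - c| >= |m_obs - c| }) / (n_groups + 1)

This convention has three properties that a one-tailed add-one count and a
doubled min-tail count cannot deliver simultaneously: a constant track
gives p = 1; an observation more extreme than every group gives the
attainable minimum `1/(n_groups + 1)`; and under a homogeneous Poisson
null its rejection rate at a nominal level is close to nominal. The
direction (enriched/depleted) is reported separately.

## Bin-aligned sampling

The analysis unit is the bin: landmark regions enter as "the bins
overlapping them", and the landmark boundaries in practice coincide with
bin boundaries. A control region sampled at base-pair resolution almost
always straddles one extra bin, so its group median averages over a
slightly larger sample than the observed statistic — a small but
systematic narrowing of the null. `sample_random_groups(align_to =
bin_size)` restricts starts to the bin grid, matching control and observed
bin counts; the bin-based analyses in this package use it, while the
default remains unrestricted base-pair sampling.

## A known small-genome limitation

All group medians are computed on the *same realized track*. When the
selected regions cover a substantial fraction of the genome (pericentric
regions cover 20% of the package's 2 × 10 Mb test genome), each null group
subsamples a large share of a small finite population, which narrows the
group-median distribution relative to true replication variance and makes
the empirical p anti-conservative. The package's null-calibration
analysis therefore uses the subtelomeric template (4 of 200 bins, a
fraction comparable to landmark regions on a real genome, where this
finite-population effect is negligible). On genuinely small genomes, or
with very large selected fractions, empirical p-values near the threshold
should be interpreted cautiously.

# Compartment metaprofiles

Adjacent same-label A/B compartments are merged into a dense alternating
track (across gaps, since the goal is a dense track). Each compartment is
rescaled onto 50 meta-bins: the compartment is split into 50 equal-width
sub-intervals and each meta-bin takes the *median* of the track bins whose
midpoints fall inside it; empty meta-bins are filled from the nearest
nonempty neighbor and flagged. Every closed (B) compartment with an open
(A) compartment on both sides forms an A–B–A triple contributing a
150-position vector; chromosome-terminal compartments without both flanks
are dropped. The profile line is the positionwise *mean* over triples —
the median-within, mean-across mixture is retained deliberately — and the
95% band is the positionwise 2.5/97.5 percentile of means over R = 1,000
bootstrap resamples of triples (percentile rather than BCa: it matches
the stated resampling scheme with the fewest assumptions).

Two caveats follow from this construction. Adjacent triples share a
flanking A compartment, so triples are not fully independent and the
bootstrap slightly understates flank variance. And with a few dozen
triples the percentile bootstrap shows its usual small-sample
undercoverage: the package's coverage analysis at its test scale (39
triples, R = 200) sits near 0.93 rather than 0.95. With hundreds of
triples, as on a real genome, both effects shrink.

# Repeat families

Multi-mapping is handled by fractional assignment: a read mapping to k
families adds 1/k to each (equal division, since no weighting scheme is
given by the quantification convention), conserving read mass exactly.
The package consumes a read-to-candidate-families map; pseudogenome
alignment is out of scope. Family-level differences between paired
replicate groups use the paired Wilcoxon signed-rank test plus a
permutation test that flips pair signs on the centered signed-rank
statistic — enumerated exhaustively when `2^n_pairs <= 1024`, otherwise
10,000 random flips with an add-one p — followed by Benjamini–Hochberg
correction across families. This chain replaces a count-model dispersion
analysis; numeric concordance with count-model results is not claimed.

# Mutation cohort statistics

The solar signature keeps (C→T) and (G→A) records only. Gene mutation
rates are mutations per C+G base per donor; the C+G content of a gene's
territory is an explicit input, since territory conventions vary. Genic
features (promoter, exon, ...) are taken from the input annotation —
no promoter window is imposed. Donor exclusion (e.g., non-UV acral
melanomas) is an explicit donor list, not a classifier.

Co-occurrence uses the donor × gene binary matrix: per pair, the 2×2
table, `log2 OR` with a Haldane–Anscombe 0.5 added to every cell only when
some cell is zero (flagged), a two-sided Fisher exact p by hypergeometric
tail summation (all tables with probability not exceeding the observed,
with the customary `1 + 1e-7` relative slack against floating-point
ties), and BH across the requested pair list — not across all possible
pairs, matching how small driver-gene panels are analyzed. Calls:
co-occurring iff `log2 OR > 0` and `q < 0.05`; mutually exclusive iff
`log2 OR < 0` and `q < 0.05`.

# Telomere content and qPCR calculators

A read is telomeric iff it contains at least 7 consecutive exact copies of
TTAGGG or its reverse complement; no mismatch tolerance, no variant
repeats (a simplification relative to variant-aware tools). GC-normalized
content divides by the number of reads with GC fraction in a configurable
window, default 0.48–0.52, bracketing the 50% GC of the repeat unit.

The ΔΔCq fold change is `2^(-ΔΔCq)`; UV interference is
`(1 - 2^(-X)) * 100` with `X = D(-UV) - D(+UV)` and
`D(c) = Cq(control, c) - Cq(target, c)`. The sign convention makes
UV-induced polymerase blocking at the target yield `X > 0` and positive
inhibition (X = 1 is 50%, X = 2 is 75%). Standard errors assume
independent cells: the four cell SEMs add in quadrature into `SE(ΔΔCq)`
or `SE(X)`, then the first-order delta method maps through the
exponential.

# The synthetic-data generators

Every pipeline input can be generated with known ground truth, so
calibration and recovery are testable without sequencing data. The
generators are pure functions of (config, seed) — byte-identical on rerun
— and each emits a truth sidecar.

* **Lesion fragments.** Per 100-kb bin, counts are Poisson with mean
  `base rate × region-class multipliers`; fragments are placed uniformly
  and entirely within their bin so midpoint-count truth is exact. Poisson
  rather than negative binomial by default: calibration needs a clean
  null first, and an overdispersed model can be layered on by the user.
  Default study conditions: 2 chromosomes × 10 Mb, 100-kb bins, base rate
  50 fragments/bin, centromeres of 200 kb at mid-chromosome, and a KO
  pericentric multiplier of 1.5.
* **Compartments.** Alternating fixed-width A/B compartments with Poisson
  track counts at rate `base` in A and `base × ba_ratio` in B. The
  metaprofile analyses use 1 chromosome × 20 Mb with 250-kb compartments
  and 50-kb track bins, giving 39 A–B–A triples — enough for the
  percentile bootstrap to be in its operating range while keeping a
  thousand-dataset coverage simulation inexpensive.
* **Cohorts.** For each targeted gene pair, donor indicators are drawn
  from the bivariate Bernoulli whose cell probabilities are solved
  exactly from the marginals and target odds ratio (the standard
  quadratic); untargeted genes are independent. Exactness is what makes
  tight recovery tolerances meaningful. Each mutated donor-gene yields
  one record, solar-signature with probability 0.8 by default.
* **Telomere reads, Cq panels.** Reads are pure repeat runs or random
  background at GC ≈ 0.5 (so the GC window has a denominator); Cq
  replicates are truth + Gaussian noise (SD 0.1 cycles, 3 replicates —
  typical technical-replicate scatter).

What the generators do **not** emulate: mappability and GC bias,
overdispersion, fragment-length distributions, sequencing errors, variant
telomere repeats, linkage between neighboring bins, and real hg19
coordinates. Passing recovery tests therefore demonstrates correctness of
the statistical machinery under its stated model, not robustness to every
artifact of real sequencing data.

# Numerical and reproducibility choices

* Dinucleotide windows containing N are excluded from numerator and
  denominator; length-≤1 sequences give missing frequencies, not zero.
  Dipyrimidine counting is double-stranded (a pyrimidine dinucleotide or
  its reverse complement), since CPDs form on either strand.
* Degenerate inputs error early and specifically: fragments on unknown
  chromosomes, ragged bedGraph bins, quantile selections of zero bins,
  regions overlapping no bins, metaprofiles with fewer than two triples,
  empty strata, zero-length genes.
* `run_pipeline` derives one seed per stage from the global seed by a
  counter-based affine map recorded in the manifest, avoiding hidden
  coupling between stages; the manifest lists every output with its MD5
  digest, and reruns with the same seed are byte-identical.
* Test and calibration problem sizes (500 null genomes, 50 effect
  replicates, 100 cohorts, 1,000 coverage datasets with R = 200) were
  chosen so the whole suite completes in a few minutes on one core while
  keeping Monte-Carlo error well inside the tolerance bands.

# Known limitations

* The random-region null is length-matched only — no GC or mappability
  matching.
* The empirical p is anti-conservative when selected regions cover a
  large fraction of a small genome (see above).
* The percentile bootstrap band undercovers slightly at a few dozen
  triples; with ~0.93 observed at the package's own test scale this is a
  property of the method at that sample size, not a defect of the
  implementation.
* The repeat differential chain is a rank/permutation substitute for
  count-model inference and will differ numerically from it.
* Fisher's exact test convention (two-sided by probability mass) matches
  R's `fisher.test`; other tools' conventions (e.g., doubling the
  one-sided p) can differ near ties.
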