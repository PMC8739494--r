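# suscept: genome-wide UV lesion susceptibility analysis

Ultraviolet light damages DNA mostly by crosslinking adjacent pyrimidines
into cyclobutane pyrimidine dimers (CPDs). How many lesions a genomic
region acquires immediately after exposure — its *UV susceptibility* — is
not uniform: heterochromatin, repeat-dense regions, and the neighborhoods
of centromeres and telomeres behave differently from gene-rich
euchromatin, and loss of the RB1 tumor suppressor redistributes this
susceptibility. `suscept` implements the downstream statistical analysis
of CPD immunoprecipitation sequencing experiments of that kind, for
computational biologists working from aligned fragments, binned signal
tracks, segmentations and mutation tables:

* **Binned susceptibility maps** — fragment midpoint counts in fixed
  100-kb bins, library-size-normalized log2(KO/WT) fold-change tracks,
  top/bottom quantile selections, Spearman track correlations, and
  per-chromatin-state aggregation with Mann–Whitney tests against the
  genome-wide distribution.
* **Landmark-region enrichment** — pericentric (±1 Mb around the
  centromere) and subtelomeric (100 kb from each chromosome end) regions
  are scored against a null of 1,000 groups of random length-matched
  regions. The observed statistic is the median over the 100-kb bins
  overlapping the regions; the null distribution is the same statistic per
  random group; the primary p-value is empirical with an add-one
  correction, `p = (1 + #{|m_g - c| >= |m_obs - c|}) / (n_groups + 1)`,
  with `c` the null mean. A chi-squared observed/expected test quantifies
  peak overlap with quantile-selected bins.
* **TAD compartment metaprofiles** — same-label A/B Hi-C compartments are
  merged, each compartment rescaled to 50 bins (median per bin), every
  closed (B) compartment aligned centrally with its two open (A) flanks,
  and the mean profile bracketed by a positionwise 95% percentile
  bootstrap band (R = 1,000 resamples of A–B–A triples).
* **Repeat families** — reads mapping to k families contribute 1/k to
  each; per-family cpm log2 fold changes; paired Wilcoxon plus exhaustive
  sign-flip permutation tests with Benjamini–Hochberg correction.
* **Melanoma cohort statistics** — solar-signature (C>T / G>A) filtering,
  mutation rates per C+G base per donor, RB1-pathway stratification
  (RB1, CCND1, CCNE1, CDKN1A/1B/2A/2B), per-genic-feature mutation
  fractions, distance of genes to the nearest centromere or telomere, and
  pairwise co-occurrence/mutual exclusivity: for each gene pair a 2×2
  donor table, `log2 OR = log2((both · neither) / (A-only · B-only))`
  (Haldane–Anscombe 0.5 correction when a cell is empty), a two-sided
  Fisher exact test by hypergeometric tail summation, and BH q-values.
* **Telomere content and qPCR** — reads containing ≥7 consecutive exact
  TTAGGG (or CCCTAA) repeats, optionally normalized per million reads of
  comparable GC content; ΔΔCq fold changes `2^(−ΔΔCq)` and UV
  interference percent inhibition `(1 − 2^(−X)) · 100`, both with
  first-order error propagation.
* **Synthetic data** — seed-deterministic generators for every input the
  pipeline consumes (Poisson lesion fragments with region-class rate
  multipliers, alternating A/B compartments, per-state ChIP enrichment,
  bivariate-Bernoulli mutation cohorts with exact target odds ratios,
  telomeric read mixtures, replicated Cq panels), each with a
  machine-readable ground-truth sidecar.

## Worked example

A complete synthetic experiment: simulate wild-type and RB1-KO lesion
fragments on a 2 × 10 Mb genome in which the KO pericentric lesion rate is
1.5× the base rate, then test pericentric enrichment, build the
compartment metaprofile, and score mutation co-occurrence.

```r
library(suscept)
cfg <- sim_config()                      # 2 x 10 Mb genome, KO pericentric x1.5
lay <- generate_layout(cfg)

wt <- generate_lesion_fragments(cfg, lay, "WT", seed = 1)
ko <- generate_lesion_fragments(cfg, lay, "KO", seed = 2)
fc <- normalize_and_ratio(bin_coverage(ko$fragments, lay, 1e5),
                          bin_coverage(wt$fragments, lay, 1e5),
                          scale = "none")
fc
#> binned_track: bin_size 1e+05 bp; 200 bins ( 0 missing ); range -1.078 .. 1.186

peri <- define_pericentric(lay)
null <- sample_random_groups(lay, peri, n_groups = 200, seed = 3,
                             align_to = 1e5)
region_enrichment_test(fc, peri, null)
#> enrichment_result: observed 0.566 vs null -0.07719 +/- 0.02887 (200 groups)
#>   direction enriched; empirical p = 0.004975; Mann-Whitney p = 1.379e-23

comp <- generate_compartments(cfg, lay, seed = 4)
build_metaprofile(comp$track, comp$compartments, R = 200, seed = 5)
#> metaprofile: 18 A-B-A triples, 150 positions, R = 200
#>   flank A mean 49.94; central B mean 75.56

coh <- generate_cohort(cfg, seed = 6)
cm  <- cohort_matrix(coh$records, donors = coh$donors,
                     genes = names(cfg$gene_marginals))
cooccurrence(cm, data.frame(geneA = "TERT", geneB = "TPTE"))
#>   geneA geneB n11 n10 n01 n00   log2or corrected            p            q
#> 1  TERT  TPTE  82 118 121 679 1.963313     FALSE 2.490735e-14 2.490735e-14
#>           call
#> 1 co-occurring
```

Reading the output: the median pericentric log2(KO/WT) of 0.566 recovers
the simulated log2(1.5) ≈ 0.585 effect and sits outside every one of the
200 random-region null medians (empirical p = 1/201); the metaprofile's
central B positions recover the simulated B/A rate step (75.6 vs 49.9,
ratio ≈ 1.51); and the cohort's estimated log2 odds ratio of 1.96 recovers
the simulated target of 2 with a co-occurring call at q < 0.05.

`run_pipeline(out_dir, config, seed)` chains all of the above end to end,
writes every stage output as plain text (BED, bedGraph, TSV, FASTA), and
records an MD5 manifest; the same seed reproduces every file byte for
byte.

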