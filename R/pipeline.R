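#' Run the end-to-end synthetic reproduction pipeline
#'
#' Chains the full analysis on generated data: simulate a genome, WT and
#' RB1-KO lesion fragments, compartments, a mutation cohort, telomere
#' reads, and a Cq panel; then bin the fragments, form the KO/WT log2
#' ratio, run the pericentric and subtelomeric random-region enrichment
#' tests, build the A-B-A compartment metaprofile, compute co-occurrence
#' statistics, count telomeric reads, and evaluate the qPCR calculators.
#' All stage outputs are written under `out_dir` as plain-text files and a
#' manifest lists every output with its MD5 digest. One global seed fans
#' out to per-stage seeds through a counter-based derivation recorded in
#' the manifest, so a rerun with the same seed reproduces every output
#' byte-for-byte (the manifest's timestamp aside).
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param seed global integer seed.
#' @param n_groups random-region groups for the enrichment tests
#'   (default 200).
#' @param R bootstrap resamples for the metaprofile (default 200).
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest` (data.frame file/md5).
#' @export
run_pipeline <- function(out_dir, config = sim_config(), seed = 1,
                         n_groups = 200, R = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  seeds <- stats::setNames(
    vapply(1:8, derive_seed, integer(1), seed = seed),
    c("wt", "ko", "compartments", "cohort", "telomere", "cq",
      "null_peri", "null_subtelo"))

  layout <- generate_layout(config)
  write_genome_layout(layout, path("layout.tsv"))

  wt <- generate_lesion_fragments(config, layout, "WT", seed = seeds[["wt"]])
  ko <- generate_lesion_fragments(config, layout, "KO", seed = seeds[["ko"]])
  write_bed(wt$fragments, path("fragments_WT.bed"))
  write_bed(ko$fragments, path("fragments_KO.bed"))

  wt_track <- bin_coverage(wt$fragments, layout, config$bin_size)
  ko_track <- bin_coverage(ko$fragments, layout, config$bin_size)
  fc <- normalize_and_ratio(ko_track, wt_track, scale = "none")
  write_bedgraph(fc, path("log2fc_KO_WT.bedGraph"))

  peri <- suppressWarnings(
    define_pericentric(layout, config$pericentric_flank))
  subtelo <- suppressWarnings(
    define_subtelomeric(layout, config$subtelomeric_flank))
  tests <- list(
    pericentric = region_enrichment_test(
      fc, peri, sample_random_groups(layout, peri, n_groups,
                                     seed = seeds[["null_peri"]])),
    subtelomeric = region_enrichment_test(
      fc, subtelo, sample_random_groups(layout, subtelo, n_groups,
                                        seed = seeds[["null_subtelo"]])))
  enrich_tab <- do.call(rbind, lapply(names(tests), function(nm) {
    r <- tests[[nm]]
    data.frame(region_class = nm, observed = r$observed_stat,
               null_mean = mean(r$null_stats),
               null_sd = stats::sd(r$null_stats),
               mw_p = r$mw_p, empirical_p = r$empirical_p,
               direction = r$direction)
  }))
  write_tsv(enrich_tab, path("region_enrichment.tsv"))

  comp <- generate_compartments(config, layout,
                                seed = seeds[["compartments"]])
  write_bed(comp$compartments, path("compartments.bed"))
  write_bedgraph(comp$track, path("compartment_signal.bedGraph"))
  mp <- build_metaprofile(comp$track, comp$compartments, R = R,
                          seed = seeds[["compartments"]])
  write_tsv(data.frame(position = seq_along(mp$mean), mean = mp$mean,
                       ci_low = mp$ci_low, ci_high = mp$ci_high),
            path("metaprofile.tsv"))

  cohort_sim <- generate_cohort(config, seed = seeds[["cohort"]])
  write_tsv(cohort_sim$records, path("cohort.tsv"))
  # co-occurrence uses all mutations; the solar-signature filter applies to
  # the rate analyses, not to the donor-level indicators
  cohort <- cohort_matrix(cohort_sim$records, donors = cohort_sim$donors,
                          genes = names(config$gene_marginals))
  cooc <- cooccurrence(cohort, config$pair_log2or[c("geneA", "geneB")])
  write_tsv(as.data.frame(cooc), path("cooccurrence.tsv"))

  telo <- generate_telomere_reads(config, seed = seeds[["telomere"]])
  write_sequences(telo$reads, path("reads.fasta"))
  telo_est <- gc_normalized_content(telo$reads)
  write_tsv(data.frame(telomeric = telo_est$telomeric_read_count,
                       total = telo_est$total_reads,
                       gc_window = telo_est$gc_window_read_count,
                       per_million = telo_est$content_per_million),
            path("telomere_content.tsv"))

  cq <- generate_cq_table(config, seed = seeds[["cq"]])
  write_tsv(cq$panel, path("cq.tsv"))
  inh <- percent_inhibition(cq$panel, target = "TERT")
  write_tsv(data.frame(percent_inhibition = inh$percent_inhibition,
                       se = inh$se, X = inh$X, X_se = inh$X_se),
            path("percent_inhibition.tsv"))

  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  write_tsv(cbind(manifest,
                  seed = seed, timestamp = format(Sys.time(), "%FT%T")),
            path("manifest.tsv"))
  invisible(list(layout = layout, fold_change = fc, enrichment = tests,
                 metaprofile = mp, cooccurrence = cooc,
                 telomere = telo_est, inhibition = inh,
                 manifest = manifest, seeds = seeds))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
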