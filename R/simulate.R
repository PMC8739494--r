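#' Simulation configuration
#'
#' Central parameter object for the synthetic-data generators that emulate
#' every input of the pipeline with known ground truth. Defaults are the
#' desk-scale study conditions used throughout the package's tests: a small
#' genome of 100-kb-binned chromosomes, Poisson lesion counts with
#' region-class rate multipliers, alternating A/B compartments, a melanoma
#' cohort with configurable marginal rates and pairwise odds ratios,
#' telomeric read fractions, and replicated Cq measurements with Gaussian
#' noise.
#'
#' @param n_chromosomes number of chromosomes (default 2).
#' @param chrom_length length of each chromosome in bp (default 10 Mb).
#' @param centromere_fraction centromere midpoint as a fraction of the
#'   chromosome (default 0.5).
#' @param centromere_width centromere width in bp (default 200 kb).
#' @param bin_size lesion-track bin width (default 100 kb).
#' @param lesion_base_rate Poisson mean fragment count per bin (default 50).
#' @param lesion_multipliers named list per condition of named region-class
#'   multipliers, e.g. `list(KO = c(pericentric = 1.5))`.
#' @param fragment_length lesion/ChIP fragment length in bp (default 150).
#' @param pericentric_flank,subtelomeric_flank landmark flanks (defaults
#'   1 Mb / 100 kb).
#' @param chip_enrichment named list per mark of named per-state
#'   multipliers applied to the IP track over a flat input.
#' @param compartment_length A/B compartment width in bp (default 500 kb).
#' @param compartment_track_bin bin width of the compartment signal track
#'   (default 50 kb).
#' @param ba_ratio B/A Poisson rate ratio (default 1.5).
#' @param compartment_base_rate Poisson mean per compartment-track bin in A
#'   (default 50).
#' @param n_donors cohort size (default 1000).
#' @param gene_marginals named vector of per-gene marginal mutation
#'   probabilities.
#' @param pair_log2or data.frame (geneA, geneB, log2or) of targeted
#'   pairwise associations; genes not listed are independent.
#' @param solar_fraction fraction of generated records carrying the
#'   C>T / G>A solar signature (default 0.8).
#' @param n_reads,read_length,telomeric_fraction telomere read model
#'   (defaults 5000, 100, 0.01).
#' @param cq_truth data.frame (target, group, true_cq) of underlying Cq
#'   values.
#' @param cq_sd,cq_replicates Gaussian replicate noise SD and count
#'   (defaults 0.1, 3).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2, chrom_length = 1e7,
                       centromere_fraction = 0.5, centromere_width = 2e5,
                       bin_size = 1e5, lesion_base_rate = 50,
                       lesion_multipliers = list(
                         WT = c(), KO = c(pericentric = 1.5)),
                       fragment_length = 150,
                       pericentric_flank = 1e6, subtelomeric_flank = 1e5,
                       chip_enrichment = list(
                         H3K9me3 = c(Het = 4, Quies = 1.5),
                         H3K27me3 = c(ReprPC = 4, Biv = 2)),
                       compartment_length = 5e5,
                       compartment_track_bin = 5e4,
                       ba_ratio = 1.5, compartment_base_rate = 50,
                       n_donors = 1000,
                       gene_marginals = c(TERT = 0.2, TPTE = 0.2,
                                          RB1 = 0.1, CDKN2A = 0.15),
                       pair_log2or = data.frame(
                         geneA = "TERT", geneB = "TPTE", log2or = 2),
                       solar_fraction = 0.8,
                       n_reads = 5000, read_length = 100,
                       telomeric_fraction = 0.01,
                       cq_truth = NULL, cq_sd = 0.1, cq_replicates = 3) {
  cfg <- as.list(environment())
  stopifnot(cfg$lesion_base_rate >= 0, cfg$n_donors >= 2,
            all(cfg$gene_marginals >= 0 & cfg$gene_marginals <= 1),
            cfg$telomeric_fraction >= 0, cfg$telomeric_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a genome layout
#'
#' Chromosomes chr1..chrN of the configured length, each with a centromere
#' of the configured width centered at `centromere_fraction` of the
#' chromosome.
#'
#' @param config a [sim_config()].
#' @return A [genome_layout()].
#' @export
generate_layout <- function(config) {
  n <- config$n_chromosomes
  len <- rep(config$chrom_length, n)
  mid <- len * config$centromere_fraction
  genome_layout(paste0("chr", seq_len(n)), len,
                cen_start = mid - config$centromere_width / 2,
                cen_end = mid + config$centromere_width / 2)
}

# per-bin Poisson rates for a condition, applying region-class multipliers
lesion_truth_rates <- function(config, layout, condition) {
  bs <- config$bin_size
  rate <- lapply(n_bins(layout, bs), function(n)
    rep(config$lesion_base_rate, n))
  mult <- config$lesion_multipliers[[condition]]
  classes <- list(
    pericentric = suppressWarnings(
      define_pericentric(layout, config$pericentric_flank)),
    subtelomeric = suppressWarnings(
      define_subtelomeric(layout, config$subtelomeric_flank)))
  for (cls in names(mult)) {
    if (!cls %in% names(classes))
      stop("unknown region class in multipliers: ", cls)
    sel <- bins_overlapping(layout, bs, classes[[cls]])
    for (i in seq_len(nrow(sel)))
      rate[[sel$chrom[i]]][sel$bin[i]] <-
        rate[[sel$chrom[i]]][sel$bin[i]] * mult[[cls]]
  }
  rate
}

#' Generate UV lesion fragments for one condition
#'
#' Per bin the fragment count is Poisson with mean `base rate x` the
#' product of the applicable region-class multipliers for the condition;
#' fragments are placed uniformly (and entirely) within their bin, so the
#' midpoint-count truth is exact. Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param layout a [genome_layout()] from [generate_layout()].
#' @param condition `"WT"` or `"KO"` (a name of
#'   `config$lesion_multipliers`).
#' @param seed integer seed.
#' @return list with `fragments` (data.frame chrom/start/end) and `truth`
#'   (data.frame chrom/bin/rate).
#' @export
generate_lesion_fragments <- function(config, layout, condition, seed = NULL) {
  rates <- lesion_truth_rates(config, layout, condition)
  bs <- config$bin_size
  frag_len <- config$fragment_length
  out <- with_seed(seed, {
    pieces <- lapply(layout$chrom, function(ch) {
      r <- rates[[ch]]
      cnt <- stats::rpois(length(r), r)
      bin <- rep(seq_along(r), cnt)
      bin_start <- (bin - 1) * bs
      bin_end <- pmin(bin * bs, layout$length[[ch]])
      slack <- pmax(bin_end - bin_start - frag_len, 0)
      start <- bin_start + floor(stats::runif(length(bin)) * (slack + 1))
      data.frame(chrom = ch, start = start,
                 end = pmin(start + frag_len, bin_end),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  truth <- data.frame(
    chrom = rep(layout$chrom, times = lengths(rates)),
    bin = unlist(lapply(rates, seq_along), use.names = FALSE),
    rate = unlist(rates, use.names = FALSE))
  list(fragments = out, truth = truth)
}

#' Generate alternating A/B compartments and a matching signal track
#'
#' Compartments of fixed width alternate A, B, A, ... along each
#' chromosome; the signal track has Poisson counts with mean
#' `compartment_base_rate` in A bins and `compartment_base_rate * ba_ratio`
#' in B bins (bin membership by midpoint). Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param layout a [genome_layout()].
#' @param seed integer seed.
#' @return list with `compartments` (labeled intervals), `track`
#'   ([binned_track()]), and `truth` (per-bin expected rate track).
#' @export
generate_compartments <- function(config, layout, seed = NULL) {
  cl <- config$compartment_length
  comp <- do.call(rbind, lapply(layout$chrom, function(ch) {
    n <- floor(layout$length[[ch]] / cl)
    data.frame(chrom = ch, start = (seq_len(n) - 1) * cl,
               end = seq_len(n) * cl,
               label = rep(c("A", "B"), length.out = n),
               stringsAsFactors = FALSE)
  }))
  bs <- config$compartment_track_bin
  nb <- n_bins(layout, bs)
  rate <- lapply(layout$chrom, function(ch) {
    mids <- (seq_len(nb[[ch]]) - 0.5) * bs
    ci <- floor(mids / cl)  # compartment index, 0-based
    in_b <- ci %% 2 == 1 & ci < floor(layout$length[[ch]] / cl)
    r <- rep(config$compartment_base_rate, nb[[ch]])
    r[in_b] <- r[in_b] * config$ba_ratio
    r
  })
  names(rate) <- layout$chrom
  values <- with_seed(seed, lapply(rate, function(r)
    as.numeric(stats::rpois(length(r), r))))
  list(compartments = comp,
       track = binned_track(layout, bs, values),
       truth = binned_track(layout, bs, rate))
}

#' Generate ChIP and input fragments with per-state enrichment
#'
#' The input track is flat Poisson; the IP track multiplies the base rate
#' by the mark's configured multiplier in bins assigned to each chromatin
#' state. States are laid out as fixed-width blocks cycling through the
#' state universe along each chromosome.
#'
#' @param config a [sim_config()].
#' @param layout a [genome_layout()].
#' @param mark a name of `config$chip_enrichment` (e.g. "H3K9me3").
#' @param states optional labeled segmentation; defaults to cycling
#'   2-bin-wide blocks over the mark's states plus a neutral "Other".
#' @param seed integer seed.
#' @return list with `states`, `ip`, `input` (fragment data.frames), and
#'   `truth` (per-bin IP rate).
#' @export
generate_chip_fragments <- function(config, layout, mark, states = NULL,
                                    seed = NULL) {
  enrich <- config$chip_enrichment[[mark]]
  if (is.null(enrich)) stop("unknown mark: ", mark)
  bs <- config$bin_size
  if (is.null(states)) {
    universe <- c(names(enrich), "Other")
    block <- 2 * bs
    states <- do.call(rbind, lapply(layout$chrom, function(ch) {
      n <- ceiling(layout$length[[ch]] / block)
      data.frame(chrom = ch, start = (seq_len(n) - 1) * block,
                 end = pmin(seq_len(n) * block, layout$length[[ch]]),
                 label = rep(universe, length.out = n),
                 stringsAsFactors = FALSE)
    }))
  }
  nb <- n_bins(layout, bs)
  assign <- assign_bins_to_labels(layout, bs, states)
  rate <- lapply(layout$chrom, function(ch) rep(config$lesion_base_rate,
                                                nb[[ch]]))
  names(rate) <- layout$chrom
  for (i in seq_len(nrow(assign))) {
    m <- enrich[assign$label[i]]  # NA for states without a multiplier
    if (!is.na(m))
      rate[[assign$chrom[i]]][assign$bin[i]] <-
        rate[[assign$chrom[i]]][assign$bin[i]] * unname(m)
  }
  sample_frags <- function(rates, s) with_seed(s, {
    pieces <- lapply(layout$chrom, function(ch) {
      cnt <- stats::rpois(length(rates[[ch]]), rates[[ch]])
      bin <- rep(seq_along(cnt), cnt)
      bin_start <- (bin - 1) * bs
      bin_end <- pmin(bin * bs, layout$length[[ch]])
      slack <- pmax(bin_end - bin_start - config$fragment_length, 0)
      start <- bin_start + floor(stats::runif(length(bin)) * (slack + 1))
      data.frame(chrom = ch, start = start,
                 end = pmin(start + config$fragment_length, bin_end),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  flat <- lapply(rate, function(r) rep(config$lesion_base_rate, length(r)))
  list(states = states,
       ip = sample_frags(rate, seed),
       input = sample_frags(flat, if (is.null(seed)) NULL else seed + 1L),
       truth = binned_track(layout, bs, rate))
}

# solve the 2x2 cell probability p11 from marginals and odds ratio
solve_p11 <- function(pa, pb, or) {
  lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
  if (or == 1) {
    p11 <- pa * pb
  } else {
    s <- 1 + (pa + pb) * (or - 1)
    disc <- s^2 - 4 * or * (or - 1) * pa * pb
    if (disc < 0) stop("infeasible (odds ratio, marginals) combination")
    p11 <- (s - sqrt(disc)) / (2 * (or - 1))
  }
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12)
    stop("infeasible (odds ratio, marginals) combination")
  min(max(p11, lo), hi)
}

#' Generate a synthetic melanoma mutation cohort
#'
#' Donor x gene indicators: each pair listed in `config$pair_log2or` is
#' drawn from the bivariate Bernoulli with the configured marginals and
#' odds ratio (cell probabilities solved exactly from (p_A, p_B, OR));
#' remaining genes are independent Bernoulli. Every mutated donor-gene
#' receives one MAF-like record whose ref/alt is a solar-signature
#' substitution (C>T or G>A, equal odds) with probability
#' `solar_fraction`, otherwise a non-solar substitution; genic features are
#' drawn uniformly. Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `records` (MAF-like data.frame), `donors`, and
#'   `truth` (marginals and targeted pairwise log2 odds ratios).
#' @export
generate_cohort <- function(config, seed = NULL) {
  marg <- config$gene_marginals
  pairs <- config$pair_log2or
  genes <- names(marg)
  n <- config$n_donors
  # validate feasibility before sampling
  for (i in seq_len(nrow(pairs)))
    solve_p11(marg[[pairs$geneA[i]]], marg[[pairs$geneB[i]]],
              2^pairs$log2or[i])
  with_seed(seed, {
    m <- matrix(0L, n, length(genes),
                dimnames = list(sprintf("donor%04d", seq_len(n)), genes))
    paired_genes <- character(0)
    for (i in seq_len(nrow(pairs))) {
      ga <- pairs$geneA[i]; gb <- pairs$geneB[i]
      p11 <- solve_p11(marg[[ga]], marg[[gb]], 2^pairs$log2or[i])
      p10 <- marg[[ga]] - p11; p01 <- marg[[gb]] - p11
      cell <- sample.int(4L, n, replace = TRUE,
                         prob = c(p11, p10, p01, 1 - p11 - p10 - p01))
      m[, ga] <- as.integer(cell %in% c(1L, 2L))
      m[, gb] <- as.integer(cell %in% c(1L, 3L))
      paired_genes <- c(paired_genes, ga, gb)
    }
    for (g in setdiff(genes, paired_genes))
      m[, g] <- stats::rbinom(n, 1L, marg[[g]])
    idx <- which(m == 1L, arr.ind = TRUE)
    n_rec <- nrow(idx)
    solar <- stats::runif(n_rec) < config$solar_fraction
    strand <- stats::runif(n_rec) < 0.5
    ref <- ifelse(solar, ifelse(strand, "C", "G"), "T")
    alt <- ifelse(solar, ifelse(strand, "T", "A"), "G")
    records <- data.frame(
      donor_id = rownames(m)[idx[, 1]],
      gene = colnames(m)[idx[, 2]],
      chrom = "chr1",
      pos = floor(stats::runif(n_rec, 0, 1e6)),
      ref = ref, alt = alt,
      genic_feature = sample(c("promoter", "exon", "intron", "UTR5",
                               "UTR3", "upstream", "downstream"),
                             n_rec, replace = TRUE),
      stringsAsFactors = FALSE)
    records <- records[order(records$donor_id, records$gene), , drop = FALSE]
    rownames(records) <- NULL
    list(records = records, donors = rownames(m),
         truth = list(marginals = marg, pair_log2or = pairs))
  })
}

#' Generate telomere-sequencing reads
#'
#' Each read is telomeric with probability `telomeric_fraction` (a run of
#' exact TTAGGG repeats filling the read, on either strand) or background
#' (iid bases with per-read GC probability drawn from a narrow normal
#' around 0.5, so GC-window normalization has a denominator).
#' Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `reads` (named character vector) and `truth`
#'   (n_telomeric).
#' @export
generate_telomere_reads <- function(config, seed = NULL) {
  with_seed(seed, {
    n <- config$n_reads
    len <- config$read_length
    telo <- stats::runif(n) < config$telomeric_fraction
    motif <- strrep("TTAGGG", ceiling(len / 6))
    rc <- strrep("CCCTAA", ceiling(len / 6))
    reads <- character(n)
    for (i in which(telo))
      reads[i] <- substr(if (stats::runif(1) < 0.5) motif else rc, 1, len)
    for (i in which(!telo)) {
      gc <- min(max(stats::rnorm(1, 0.5, 0.05), 0.2), 0.8)
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      reads[i] <- paste(sample(names(p), len, replace = TRUE, prob = p),
                        collapse = "")
    }
    names(reads) <- sprintf("read%05d", seq_len(n))
    list(reads = reads, truth = list(n_telomeric = sum(telo)))
  })
}

#' Generate a replicated Cq table
#'
#' Replicate Cq values are the configured true cell means plus Gaussian
#' noise. When `config$cq_truth` is NULL a default TERT/GAPDH +/-UV panel
#' with a true X of 1 cycle is used.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `panel` (data.frame target/condition/replicate/cq)
#'   and `truth` (the cell-mean table).
#' @export
generate_cq_table <- function(config, seed = NULL) {
  truth <- config$cq_truth
  if (is.null(truth))
    truth <- data.frame(
      target = c("GAPDH", "TERT", "GAPDH", "TERT"),
      condition = c("-UV", "-UV", "+UV", "+UV"),
      true_cq = c(20, 24, 20, 25))  # X = (20-24) - (20-25) = 1
  with_seed(seed, {
    reps <- config$cq_replicates
    panel <- truth[rep(seq_len(nrow(truth)), each = reps), , drop = FALSE]
    panel$replicate <- rep(seq_len(reps), times = nrow(truth))
    panel$cq <- panel$true_cq + stats::rnorm(nrow(panel), 0, config$cq_sd)
    panel$true_cq <- NULL
    rownames(panel) <- NULL
    list(panel = panel, truth = truth)
  })
}
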