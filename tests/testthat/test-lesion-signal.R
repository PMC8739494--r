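test_that("bin_coverage follows the midpoint rule and conserves counts", {
  lay <- genome_layout("chr1", 1e3)
  fr <- data.frame(chrom = "chr1", start = c(0, 150), end = c(100, 250))
  tr <- bin_coverage(fr, lay, 100)
  expect_equal(tr$values$chr1, c(1, 0, 1, rep(0, 7)))  # midpoints 50, 200

  empty <- bin_coverage(fr[0, ], lay, 100)
  expect_true(all(unlist(empty$values) == 0))

  expect_error(bin_coverage(data.frame(chrom = "chrX", start = 0, end = 10),
                            lay, 100), "chrX")
})

test_that("bin_coverage equals the brute-force midpoint histogram", {
  lay <- tiny_layout()
  set.seed(5)
  fr <- random_regions(lay, 10000, min_len = 50, max_len = 500)
  tr <- bin_coverage(fr, lay, 1e5)
  expect_equal(sum(unlist(tr$values)), nrow(fr))
  for (ch in lay$chrom) {
    mids <- floor((fr$start + fr$end) / 2)[fr$chrom == ch]
    oracle <- tabulate(floor(mids / 1e5) + 1L,
                       nbins = ceiling(lay$length[[ch]] / 1e5))
    expect_equal(tr$values[[ch]], as.numeric(oracle))
  }
})

test_that("normalize_and_ratio reproduces the per-bin formula", {
  lay <- tiny_layout()
  a <- value_track(lay, seed = 1)
  expect_true(all(unlist(normalize_and_ratio(a, a)$values) == 0))

  c4 <- binned_track(lay, 1e5, fill = 4)
  c1 <- binned_track(lay, 1e5, fill = 1)
  r <- normalize_and_ratio(c4, c1, pseudocount = 0, scale = "none")
  expect_true(all(unlist(r$values) == 2))

  b <- value_track(lay, seed = 2)
  for (sc in c("cpm", "none")) {
    got <- normalize_and_ratio(a, b, pseudocount = 1, scale = sc)
    for (ch in lay$chrom) {
      av <- a$values[[ch]]; bv <- b$values[[ch]]
      if (sc == "cpm") {
        av <- av / (sum(unlist(a$values)) / 1e6)
        bv <- bv / (sum(unlist(b$values)) / 1e6)
      }
      expect_equal(got$values[[ch]], log2((av + 1) / (bv + 1)),
                   tolerance = 1e-12)
    }
    # antisymmetry under numerator/denominator swap
    rev <- normalize_and_ratio(b, a, pseudocount = 1, scale = sc)
    expect_equal(unlist(rev$values), -unlist(got$values), tolerance = 1e-12)
  }

  short <- binned_track(genome_layout("chr1", 5e5), 1e5)
  expect_error(normalize_and_ratio(a, short), "mismatch")
})

test_that("ratio is missing where either input is missing", {
  lay <- tiny_layout()
  a <- value_track(lay, seed = 1); b <- value_track(lay, seed = 2)
  a$values$chr1[2] <- NA; b$values$chr2[3] <- NA
  r <- normalize_and_ratio(a, b)
  expect_true(is.na(r$values$chr1[2]))
  expect_true(is.na(r$values$chr2[3]))
  expect_equal(sum(is.na(unlist(r$values))), 2)
})

test_that("quantile bin selection is exact and deterministically tied", {
  lay <- genome_layout("chr1", 1e6)
  tr <- binned_track(lay, 1e5, list(chr1 = as.numeric(1:10)))
  top <- select_quantile_bins(tr, 0.1, "top")
  expect_equal(top$bin, 10L)
  bottom <- select_quantile_bins(tr, 0.1, "bottom")
  expect_equal(bottom$bin, 1L)

  # all equal: genome-order tie break
  tie <- binned_track(lay, 1e5, fill = 7)
  expect_equal(select_quantile_bins(tie, 0.2, "top")$bin, c(1L, 2L))

  expect_error(select_quantile_bins(tr, 0.01, "top"), "0 bins")
  expect_error(select_quantile_bins(tr, 1.2, "top"))
})

test_that("quantile selection matches sort-and-slice and tails are disjoint", {
  lay <- tiny_layout()
  set.seed(8)
  tr <- value_track(lay, seed = 8)
  for (f in c(0.1, 0.25, 0.5)) {
    top <- select_quantile_bins(tr, f, "top")
    df <- suscept:::track_frame(tr)
    k <- round(f * nrow(df))
    oracle <- sort(df$value, decreasing = TRUE)[seq_len(k)]
    expect_equal(sort(top$value, decreasing = TRUE), oracle)
    bottom <- select_quantile_bins(tr, f, "bottom")
    if (f <= 0.5)
      expect_equal(nrow(merge(top[1:2], bottom[1:2])), 0)
  }
})

test_that("state aggregation partitions bins and flags shifted states", {
  lay <- genome_layout("chr1", 6e6)
  states <- data.frame(chrom = "chr1",
                       start = c(0, 1.2e6, 1.8e6),
                       end = c(1.2e6, 1.8e6, 6e6),
                       label = c("Quies", "Het", "Tss"))
  uniform <- binned_track(lay, 1e5, fill = 3)
  agg <- aggregate_by_state(uniform, states)
  expect_equal(sum(agg$n), 60L)
  expect_true(all(agg$median == attr(agg, "genome_median")))
  expect_true(all(agg$p_mw > 0.9))

  vals <- rep(3, 60); vals[13:18] <- 4  # the Het bins shifted by +1
  shifted <- binned_track(lay, 1e5, list(chr1 = vals))
  agg2 <- aggregate_by_state(shifted, states)
  # the flagging convention is P < 0.001 against the genome distribution
  expect_equal(agg2$median[agg2$label == "Het"], 4)
  expect_lt(agg2$p_mw[agg2$label == "Het"], 0.001)
  expect_gt(min(agg2$p_mw[agg2$label != "Het"]), 0.001)
})

test_that("majority-coverage assignment matches brute-force grouping", {
  lay <- tiny_layout()
  set.seed(13)
  # random segmentation: tile each chromosome with random-width labeled runs
  segs <- do.call(rbind, lapply(lay$chrom, function(ch) {
    cuts <- sort(sample(seq(1e4, lay$length[[ch]] - 1e4, by = 1e4), 8))
    bounds <- c(0, cuts, lay$length[[ch]])
    data.frame(chrom = ch, start = bounds[-length(bounds)],
               end = bounds[-1],
               label = sample(c("a", "b", "c"), length(bounds) - 1,
                              replace = TRUE))
  }))
  tr <- value_track(lay, seed = 13)
  agg <- aggregate_by_state(tr, segs)
  assign <- attr(agg, "assignment")
  expect_equal(sum(agg$n), nrow(assign))
  # per-label medians against direct grouping of the assignment table
  for (lb in agg$label[agg$n > 0]) {
    v <- assign$value[assign$label == lb]
    expect_equal(agg$median[agg$label == lb], median(v))
  }
  # brute-force majority label for a handful of bins
  for (i in sample(nrow(assign), 10)) {
    ch <- assign$chrom[i]; b <- assign$bin[i]
    bs <- (b - 1) * 1e5; be <- min(b * 1e5, lay$length[[ch]])
    ov <- segs[segs$chrom == ch, ]
    bp <- tapply(pmax(0, pmin(ov$end, be) - pmax(ov$start, bs)), ov$label,
                 sum)
    expect_equal(assign$label[i], names(which.max(bp)))
  }
})

test_that("track correlation is Spearman over complete pairs", {
  lay <- tiny_layout()
  a <- value_track(lay, seed = 21)
  b <- a; b$values <- lapply(a$values, exp)
  expect_equal(correlate_tracks(a, b)$rho, 1)
  neg <- a; neg$values <- lapply(a$values, function(v) -v)
  expect_equal(correlate_tracks(a, neg)$rho, -1)

  set.seed(22)
  b2 <- value_track(lay, seed = 22)
  got <- correlate_tracks(a, b2)
  x <- unlist(a$values); y <- unlist(b2$values)
  expect_equal(got$rho, cor(rank(x), rank(y)), tolerance = 1e-12)

  sparse <- a
  sparse$values <- lapply(sparse$values, function(v) {
    v[] <- NA; v })
  sparse$values$chr1[1:2] <- 1:2
  expect_error(correlate_tracks(a, sparse), "3")
})

test_that("gene overlap filter applies the strict 10% rule", {
  lay <- genome_layout("chr1", 1e6)
  sel <- data.frame(chrom = "chr1", bin = 2L)  # [100k, 200k)
  genes <- data.frame(chrom = "chr1",
                      start = c(5e4, 1e5, 0),
                      end = c(5e4 + 1000, 2e5, 1e6),
                      label = c("g_outside", "g_inside", "g_boundary"))
  # g_boundary: 1e5 / 1e6 = exactly 10% -> excluded by strict inequality
  kept <- select_genes_by_overlap(genes, sel, lay, 1e5)
  expect_equal(kept$label, "g_inside")

  # 150/1000 = 15% > 10% kept
  g <- data.frame(chrom = "chr1", start = 199850, end = 200850, label = "g")
  expect_equal(nrow(select_genes_by_overlap(g, sel, lay, 1e5)), 1)

  expect_error(select_genes_by_overlap(
    data.frame(chrom = "chr1", start = 10, end = 10, label = "z"),
    sel, lay, 1e5), "zero-length")
})

test_that("gene overlap fractions match the brute-force bp oracle", {
  lay <- tiny_layout()
  set.seed(31)
  genes <- random_regions(lay, 100, min_len = 1000, max_len = 4e5)
  genes$label <- paste0("g", seq_len(nrow(genes)))
  tr <- value_track(lay)
  sel <- select_quantile_bins(tr, 0.3, "top")[c("chrom", "bin")]
  kept <- select_genes_by_overlap(genes, sel, lay, 1e5)
  oracle_frac <- vapply(seq_len(nrow(genes)), function(i) {
    bp <- 0
    for (j in seq_len(nrow(sel))) {
      if (sel$chrom[j] != genes$chrom[i]) next
      bs <- (sel$bin[j] - 1) * 1e5
      be <- min(sel$bin[j] * 1e5, lay$length[[sel$chrom[j]]])
      bp <- bp + max(0, min(genes$end[i], be) - max(genes$start[i], bs))
    }
    bp / (genes$end[i] - genes$start[i])
  }, numeric(1))
  expect_equal(kept$label, genes$label[oracle_frac > 0.10])
  expect_equal(kept$overlap_fraction, oracle_frac[oracle_frac > 0.10])
})
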