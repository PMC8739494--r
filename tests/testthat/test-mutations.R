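mk_records <- function(ref, alt, donor = NULL, gene = "TERT",
                       feature = "exon") {
  n <- length(ref)
  data.frame(donor_id = donor %||% paste0("d", seq_len(n)), gene = gene,
             chrom = "chr1", pos = seq_len(n), ref = ref, alt = alt,
             genic_feature = feature, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("solar-signature filter keeps exactly C>T and G>A", {
  rec <- mk_records(c("C", "G", "C", "T"), c("T", "A", "A", "C"))
  kept <- filter_solar_signature(rec)
  expect_equal(nrow(kept), 2)
  expect_true(all(paste0(kept$ref, kept$alt) %in% c("CT", "GA")))
  expect_equal(nrow(filter_solar_signature(rec[0, ])), 0)

  set.seed(41)
  bases <- c("A", "C", "G", "T")
  big <- mk_records(sample(bases, 500, TRUE), sample(bases, 500, TRUE))
  big <- big[big$ref != big$alt, ]
  oracle <- (big$ref == "C" & big$alt == "T") |
    (big$ref == "G" & big$alt == "A")
  expect_equal(filter_solar_signature(big)$pos, big$pos[oracle])
})

test_that("gene mutation rate normalizes by CG content and cohort size", {
  rec <- mk_records(c("C", "C"), c("T", "T"), donor = c("d1", "d1"))
  cm <- cohort_matrix(rec, donors = "d1", cg_content = c(TERT = 10))
  expect_equal(gene_mutation_rate(cm, "TERT"), 2 / (10 * 1))

  cm5 <- cohort_matrix(rec, donors = paste0("d", 1:5),
                       cg_content = c(TERT = 10))
  expect_equal(gene_mutation_rate(cm5, "TERT"), 2 / (10 * 5))

  none <- cohort_matrix(rec[0, ], donors = "d1", genes = "TERT",
                        cg_content = c(TERT = 10))
  expect_equal(gene_mutation_rate(none, "TERT"), 0)

  bad <- cohort_matrix(rec, donors = "d1", cg_content = c(TERT = 0))
  expect_warning(r <- gene_mutation_rate(bad, "TERT"), "CG")
  expect_true(is.na(r))
})

test_that("pathway stratification is an exhaustive disjoint any-column OR", {
  set.seed(43)
  genes <- c("RB1", "CDKN2A", "TERT", "BRAF")
  m <- matrix(rbinom(200 * 4, 1, 0.2), 200, 4,
              dimnames = list(paste0("d", 1:200), genes))
  cm <- structure(list(matrix = m, records = NULL), class = "cohort_matrix")
  expect_warning(s <- stratify_by_pathway(cm), "absent")
  oracle <- rowSums(m[, c("RB1", "CDKN2A")]) > 0
  expect_setequal(s$mutated, rownames(m)[oracle])
  expect_setequal(s$not_mutated, rownames(m)[!oracle])
  expect_length(intersect(s$mutated, s$not_mutated), 0)
  expect_equal(length(s$mutated) + length(s$not_mutated), 200)

  # donor with only CDKN2A is in the mutated group
  m2 <- matrix(0L, 2, 4, dimnames = list(c("a", "b"), genes))
  m2["a", "CDKN2A"] <- 1L
  cm2 <- structure(list(matrix = m2), class = "cohort_matrix")
  expect_warning(s2 <- stratify_by_pathway(cm2), "absent")
  expect_equal(s2$mutated, "a")
  expect_equal(s2$not_mutated, "b")
})

test_that("per-feature fractions tally donors within strata", {
  rec <- rbind(
    mk_records(rep("C", 3), rep("T", 3), donor = c("d1", "d2", "d3"),
               feature = "promoter"),
    mk_records("C", "T", donor = "d8", feature = "exon"))
  cm <- cohort_matrix(rec, donors = paste0("d", 1:20))
  strata <- list(mutated = paste0("d", 1:10),
                 not_mutated = paste0("d", 11:20))
  fr <- feature_mutation_fraction(cm, "TERT", strata)
  expect_equal(fr$fraction_mutated[fr$feature == "promoter"], 0.3)
  expect_equal(fr$fraction_not_mutated[fr$feature == "promoter"], 0)
  expect_equal(fr$fraction_mutated[fr$feature == "exon"], 0.1)

  # identical strata composition gives Fisher p = 1
  sym <- list(mutated = c("d1", "d11"), not_mutated = c("d2", "d12"))
  rec2 <- mk_records(c("C", "C"), c("T", "T"), donor = c("d1", "d2"),
                     feature = "promoter")
  cm2 <- cohort_matrix(rec2, donors = c("d1", "d2", "d11", "d12"))
  fr2 <- feature_mutation_fraction(cm2, "TERT", sym)
  expect_equal(fr2$fisher_p, 1)

  expect_error(feature_mutation_fraction(cm, "TERT",
                                         list(mutated = character(),
                                              not_mutated = "d1")),
               "empty")
})

test_that("co-occurrence reproduces the closed-form odds ratio", {
  # donors: 30 both, 10 A-only, 10 B-only, 50 neither
  donors <- paste0("d", 1:100)
  rec <- rbind(
    mk_records(rep("C", 40), rep("T", 40), donor = donors[1:40],
               gene = "A"),
    mk_records(rep("C", 40), rep("T", 40),
               donor = donors[c(1:30, 41:50)], gene = "B"))
  cm <- cohort_matrix(rec, donors = donors)
  cc <- cooccurrence(cm, data.frame(geneA = "A", geneB = "B"))
  expect_equal(c(cc$n11, cc$n10, cc$n01, cc$n00), c(30, 10, 10, 50))
  expect_equal(cc$n11 + cc$n10 + cc$n01 + cc$n00, 100)
  expect_equal(cc$log2or, log2(15))
  expect_false(cc$corrected)
  expect_equal(cc$call, "co-occurring")
  expect_equal(cc$p, fisher.test(matrix(c(30, 10, 10, 50), 2))$p.value,
               tolerance = 1e-12)
})

test_that("odds ratio sign flips under single swap, survives double swap", {
  or_of <- function(m) {
    cm <- structure(list(matrix = m), class = "cohort_matrix")
    cooccurrence(cm, data.frame(geneA = "A", geneB = "B"))$log2or
  }
  set.seed(47)
  m <- cbind(A = rbinom(60, 1, 0.4), B = rbinom(60, 1, 0.4))
  rownames(m) <- paste0("d", 1:60)
  base <- or_of(m)
  swapped_one <- or_of(cbind(A = 1L - m[, "A"], B = m[, "B"]))
  swapped_both <- or_of(cbind(A = 1L - m[, "A"], B = 1L - m[, "B"]))
  expect_equal(swapped_one, -base, tolerance = 1e-12)
  expect_equal(swapped_both, base, tolerance = 1e-12)
})

test_that("zero cells trigger the Haldane correction; degenerate columns p = 1", {
  m <- cbind(A = c(1L, 1L, 0L, 0L), B = c(1L, 1L, 0L, 0L))
  rownames(m) <- paste0("d", 1:4)
  cm <- structure(list(matrix = m), class = "cohort_matrix")
  cc <- cooccurrence(cm, data.frame(geneA = "A", geneB = "B"))
  expect_true(cc$corrected)
  expect_equal(cc$log2or, log2((2.5 * 2.5) / (0.5 * 0.5)))

  m2 <- cbind(A = rep(1L, 4), B = c(1L, 0L, 1L, 0L))
  rownames(m2) <- paste0("d", 1:4)
  cm2 <- structure(list(matrix = m2), class = "cohort_matrix")
  cc2 <- cooccurrence(cm2, data.frame(geneA = "A", geneB = "B"))
  expect_true(is.na(cc2$log2or))
  expect_equal(cc2$p, 1)
  expect_equal(cc2$call, "none")
})

test_that("Fisher p equals fisher.test and BH spans the pair list", {
  set.seed(48)
  n <- 80
  m <- matrix(rbinom(n * 4, 1, c(0.3, 0.25, 0.4, 0.2)), n, 4,
              dimnames = list(paste0("d", 1:n), c("w", "x", "y", "z")))
  cm <- structure(list(matrix = m), class = "cohort_matrix")
  pairs <- data.frame(geneA = c("w", "w", "x"), geneB = c("x", "y", "z"))
  cc <- cooccurrence(cm, pairs)
  for (i in 1:3) {
    tab <- matrix(c(cc$n11[i], cc$n01[i], cc$n10[i], cc$n00[i]), 2)
    expect_equal(cc$p[i], fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_equal(cc$q, oracle_bh(cc$p))
})

test_that("distance to landmark takes the minimum over all anchors", {
  lay <- genome_layout("chr1", 1e8, cen_start = 5e7, cen_end = 5.1e7)
  g <- data.frame(chrom = "chr1", start = 5e6, end = 5.01e6)
  expect_equal(distance_to_landmark(g, lay)$distance, 5e6)

  # overlapping the centromere: distance 0
  g0 <- data.frame(chrom = "chr1", start = 5.05e7, end = 5.06e7)
  expect_equal(distance_to_landmark(g0, lay)$distance, 0)

  # nearer the centromere edge than either end
  g2 <- data.frame(chrom = "chr1", start = 5.2e7, end = 5.21e7)
  expect_equal(distance_to_landmark(g2, lay)$distance, 5.2e7 - 5.1e7)

  expect_error(distance_to_landmark(
    data.frame(chrom = "chrZ", start = 0, end = 10), lay), "chrZ")

  # random genes against a brute-force min over anchors
  set.seed(49)
  lay2 <- tiny_layout()
  genes <- random_regions(lay2, 50, min_len = 100, max_len = 5e4)
  got <- distance_to_landmark(genes, lay2)$distance
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    cen <- lay2$centromeres[lay2$centromeres$chrom == ch, ]
    dcen <- if (genes$end[i] <= cen$start) cen$start - genes$end[i]
      else if (genes$start[i] >= cen$end) genes$start[i] - cen$end
      else 0
    expect_equal(got[i], min(genes$start[i],
                             lay2$length[[ch]] - genes$end[i], dcen))
  }
})

test_that("rate comparison uses the exact Mann-Whitney null when possible", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  r <- compare_rate_distributions(a, a + 0)
  expect_gt(r$p, 0.9)

  set.seed(50)
  x <- runif(10); y <- runif(10) + 2
  r2 <- compare_rate_distributions(x, y)
  expect_true(r2$U %in% c(0, 100))

  # exact enumeration oracle for n <= 8 (tie-free)
  x3 <- c(0.1, 0.9, 1.7); y3 <- c(0.4, 1.1)
  perms <- combn(5, 3)
  pooled <- c(x3, y3)
  u_of <- function(idx) sum(rank(pooled)[idx]) - 3 * 4 / 2
  obs <- u_of(1:3)
  null_u <- apply(perms, 2, u_of)
  # two-sided exact p: fraction of assignments at least as extreme
  mu <- 3 * 2 / 2
  p_oracle <- mean(abs(null_u - mu) >= abs(obs - mu) - 1e-12)
  expect_equal(compare_rate_distributions(x3, y3)$p, p_oracle)
})

test_that("mutation tables read and validate; exclusion list honored", {
  rec <- mk_records(c("C", "G"), c("T", "A"), donor = c("d1", "d2"))
  f <- tempfile(fileext = ".tsv")
  write.table(rec, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_mutations(f), rec)

  bad <- rec; bad$alt[1] <- "C"
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutations(f), "invalid")

  cm <- cohort_matrix(rec, donors = c("d1", "d2", "d3"),
                      exclude_donors = "d2")
  expect_equal(rownames(cm$matrix), c("d1", "d3"))
})
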