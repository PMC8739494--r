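#' Keep only solar-signature substitutions
#'
#' UV mutagenesis leaves C>T transitions (G>A on the opposite strand); only
#' records with (ref = C, alt = T) or (ref = G, alt = A) are retained.
#'
#' @param records MAF-like data.frame with at least `ref` and `alt`
#'   columns.
#' @return The qualifying subset of `records`.
#' @export
filter_solar_signature <- function(records) {
  keep <- (records$ref == "C" & records$alt == "T") |
    (records$ref == "G" & records$alt == "A")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a donor x gene binary cohort matrix
#'
#' @param records MAF-like data.frame with `donor_id` and `gene` columns
#'   (pre-filter with [filter_solar_signature()] if desired).
#' @param donors optional full donor universe (so donors without qualifying
#'   mutations keep all-zero rows).
#' @param genes optional gene universe.
#' @param cg_content optional named numeric vector: count of C+G bases in
#'   each gene's territory (used by [gene_mutation_rate()]).
#' @param exclude_donors optional donor ids to drop (e.g. acral melanomas).
#' @return An object of class `cohort_matrix`: list with `matrix` (binary,
#'   donors x genes), `records`, `cg_content`.
#' @export
cohort_matrix <- function(records, donors = NULL, genes = NULL,
                          cg_content = NULL, exclude_donors = NULL) {
  if (!is.null(exclude_donors)) {
    records <- records[!(records$donor_id %in% exclude_donors), ,
                       drop = FALSE]
    donors <- setdiff(donors, exclude_donors)
  }
  if (is.null(donors)) donors <- sort(unique(records$donor_id))
  if (is.null(genes)) genes <- sort(unique(records$gene))
  m <- matrix(0L, length(donors), length(genes),
              dimnames = list(donors, genes))
  hit <- records$donor_id %in% donors & records$gene %in% genes
  m[cbind(records$donor_id[hit], records$gene[hit])] <- 1L
  structure(list(matrix = m, records = records, cg_content = cg_content),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("cohort_matrix:", nrow(x$matrix), "donors x", ncol(x$matrix),
      "genes;", sum(x$matrix), "mutated donor-gene entries\n")
  invisible(x)
}

#' C+G-normalized gene mutation rate
#'
#' Mutations per C+G base per donor:
#' `(# qualifying records in the gene) / (CG content * n donors)`.
#' Assumes `cohort$records` has already been restricted to the solar
#' signature when that is the intended numerator.
#'
#' @param cohort a [cohort_matrix()] carrying `cg_content`.
#' @param gene gene symbol.
#' @return rate (numeric), or `NA` with a warning if the CG content is 0 or
#'   unknown.
#' @export
gene_mutation_rate <- function(cohort, gene) {
  cg <- cohort$cg_content[[gene]]
  if (is.null(cg) || is.na(cg) || cg == 0) {
    warning("CG content missing or zero for ", gene)
    return(NA_real_)
  }
  n_mut <- sum(cohort$records$gene == gene)
  n_mut / (cg * nrow(cohort$matrix))
}

#' Stratify donors by RB1-pathway mutation status
#'
#' @param cohort a [cohort_matrix()].
#' @param pathway_genes gene symbols whose union defines the "mutated"
#'   stratum; defaults to RB1 and its cyclin/CDK-inhibitor regulators.
#' @return list with `mutated` and `not_mutated` donor id vectors
#'   (exhaustive, disjoint).
#' @export
stratify_by_pathway <- function(cohort,
                                pathway_genes = c("RB1", "CCND1", "CCNE1",
                                                  "CDKN1A", "CDKN1B",
                                                  "CDKN2A", "CDKN2B")) {
  absent <- setdiff(pathway_genes, colnames(cohort$matrix))
  if (length(absent))
    warning("pathway gene(s) absent from cohort (treated as unmutated): ",
            paste(absent, collapse = ", "))
  present <- intersect(pathway_genes, colnames(cohort$matrix))
  hit <- if (length(present))
    rowSums(cohort$matrix[, present, drop = FALSE]) > 0
  else rep(FALSE, nrow(cohort$matrix))
  list(mutated = rownames(cohort$matrix)[hit],
       not_mutated = rownames(cohort$matrix)[!hit])
}

#' Per-genic-feature mutation fractions by pathway stratum
#'
#' For one gene, the fraction of donors in each stratum carrying at least
#' one qualifying record in each genic feature, with a per-feature Fisher
#' exact comparison of the two strata.
#'
#' @param cohort a [cohort_matrix()].
#' @param gene gene symbol.
#' @param strata list(mutated=, not_mutated=) from
#'   [stratify_by_pathway()].
#' @return data.frame per feature: fraction_mutated, fraction_not_mutated,
#'   fisher_p.
#' @export
feature_mutation_fraction <- function(cohort, gene, strata) {
  if (length(strata$mutated) == 0 || length(strata$not_mutated) == 0)
    stop("empty stratum")
  rec <- cohort$records[cohort$records$gene == gene, , drop = FALSE]
  feats <- sort(unique(rec$genic_feature))
  rows <- lapply(feats, function(f) {
    donors_f <- unique(rec$donor_id[rec$genic_feature == f])
    a <- sum(strata$mutated %in% donors_f)
    b <- sum(strata$not_mutated %in% donors_f)
    n1 <- length(strata$mutated); n2 <- length(strata$not_mutated)
    p <- fisher_exact_p(a, n1 - a, b, n2 - b)
    data.frame(feature = f, fraction_mutated = a / n1,
               fraction_not_mutated = b / n2, fisher_p = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise mutation co-occurrence / mutual exclusivity
#'
#' For each requested gene pair the donor x gene matrix yields a 2x2 table
#' (both, A-only, B-only, neither). The log2 odds ratio
#' `log2((both * neither) / (A-only * B-only))` uses a Haldane-Anscombe
#' correction (`zero_cell` added to every cell) only when some cell is 0;
#' significance is a two-sided Fisher exact test (hypergeometric tail
#' summation), BH-adjusted across the requested pairs. Calls:
#' co-occurring iff log2OR > 0 and q < `q_threshold`; mutually exclusive
#' iff log2OR < 0 and q < `q_threshold`.
#'
#' @param cohort a [cohort_matrix()].
#' @param gene_pairs data.frame or 2-column matrix of gene symbol pairs.
#' @param q_threshold BH q cutoff for calls (default 0.05).
#' @param zero_cell Haldane-Anscombe constant (default 0.5).
#' @return An object of class `cooccurrence`: data.frame per pair with
#'   n11, n10, n01, n00, log2or, corrected flag, p, q, call.
#' @export
cooccurrence <- function(cohort, gene_pairs, q_threshold = 0.05,
                         zero_cell = 0.5) {
  gene_pairs <- as.matrix(gene_pairs)
  m <- cohort$matrix
  rows <- lapply(seq_len(nrow(gene_pairs)), function(i) {
    ga <- gene_pairs[i, 1]; gb <- gene_pairs[i, 2]
    if (!all(c(ga, gb) %in% colnames(m)))
      stop("gene pair not in cohort: ", ga, " / ", gb)
    a <- m[, ga]; b <- m[, gb]
    n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
    n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
    degenerate <- length(unique(a)) == 1 || length(unique(b)) == 1
    if (degenerate) {
      log2or <- NA_real_; corrected <- FALSE; p <- 1
    } else {
      cells <- c(n11, n10, n01, n00)
      corrected <- any(cells == 0)
      if (corrected) cells <- cells + zero_cell
      log2or <- log2((cells[1] * cells[4]) / (cells[2] * cells[3]))
      p <- fisher_exact_p(n11, n10, n01, n00)
    }
    data.frame(geneA = ga, geneB = gb, n11 = n11, n10 = n10, n01 = n01,
               n00 = n00, log2or = log2or, corrected = corrected, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$call <- "none"
  out$call[!is.na(out$log2or) & out$log2or > 0 &
             out$q < q_threshold] <- "co-occurring"
  out$call[!is.na(out$log2or) & out$log2or < 0 &
             out$q < q_threshold] <- "mutually exclusive"
  rownames(out) <- NULL
  class(out) <- c("cooccurrence", "data.frame")
  out
}

# two-sided Fisher exact p for the 2x2 table (n11 n10 / n01 n00) by
# hypergeometric tail summation: sum of P(table) over all tables with the
# observed margins whose probability does not exceed the observed one
# (standard 1 + 1e-7 relative slack against floating-point ties)
fisher_exact_p <- function(n11, n10, n01, n00) {
  rowA <- n11 + n10
  colA <- n11 + n01
  n <- n11 + n10 + n01 + n00
  support <- max(0, rowA + colA - n):min(rowA, colA)
  probs <- stats::dhyper(support, colA, n - colA, rowA)
  obs <- probs[support == n11]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Distance from genes to the nearest centromere or telomere
#'
#' Per gene, the minimum over: gap from the gene's nearest edge to the
#' nearer centromere boundary, to the p-telomere anchor (position 0), and
#' to the q-telomere anchor (chromosome end); 0 when the gene overlaps the
#' landmark.
#'
#' @param genes data.frame of gene intervals (chrom/start/end, optional
#'   label).
#' @param layout a [genome_layout()].
#' @return `genes` with an added `distance` column (bp).
#' @export
distance_to_landmark <- function(genes, layout) {
  unknown <- setdiff(genes$chrom, layout$chrom)
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  cen <- layout$centromeres
  d <- vapply(seq_len(nrow(genes)), function(i) {
    ch <- genes$chrom[i]; s <- genes$start[i]; e <- genes$end[i]
    cand <- c(s, layout$length[[ch]] - e)  # p and q telomere anchors
    j <- which(cen$chrom == ch)
    if (length(j)) {
      cs <- cen$start[j[1]]; ce <- cen$end[j[1]]
      cand <- c(cand, if (e <= cs) cs - e else if (s >= ce) s - ce else 0)
    }
    min(cand)
  }, numeric(1))
  genes$distance <- d
  genes
}

#' Compare two mutation-rate distributions
#'
#' Standard two-sided Mann-Whitney U (Wilcoxon rank-sum): exact null for
#' small tie-free samples, normal approximation with tie correction
#' otherwise.
#'
#' @param rates_a,rates_b numeric vectors.
#' @return list with `p` and `U` (statistic for `rates_a`).
#' @export
compare_rate_distributions <- function(rates_a, rates_b) {
  wt <- suppressWarnings(stats::wilcox.test(rates_a, rates_b))
  list(p = wt$p.value, U = unname(wt$statistic))
}

#' Read a MAF-like mutation table
#'
#' TSV with header columns donor_id, gene, chrom, pos, ref, alt,
#' genic_feature.
#'
#' @param path file path.
#' @return data.frame of mutation records.
#' @export
read_mutations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("donor_id", "gene", "chrom", "pos", "ref", "alt",
            "genic_feature")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("mutation table lacks column(s): ", paste(missing, collapse = ", "))
  bad <- tab$ref == tab$alt | !(tab$ref %in% c("A", "C", "G", "T")) |
    !(tab$alt %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("invalid ref/alt in ", sum(bad), " record(s)")
  tab
}
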