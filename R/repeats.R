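#' Fractional assignment of reads to repeat families
#'
#' A read mapping to k candidate families contributes 1/k to each; uniquely
#' mapping reads contribute 1; reads with no candidate family accumulate in
#' `unassigned`. Read mass is conserved exactly:
#' sum(counts) + unassigned = number of reads.
#'
#' @param read_family_map list of character vectors (candidate families per
#'   read), or a data.frame with columns `read_id` and `families`
#'   (comma-separated labels, empty string = unassigned).
#' @return An object of class `family_counts`: list with `counts` (named
#'   numeric), `unassigned`, `total_reads`.
#' @export
assign_fractional <- function(read_family_map) {
  if (is.data.frame(read_family_map)) {
    read_family_map <- strsplit(read_family_map$families, ",", fixed = TRUE)
    read_family_map <- lapply(read_family_map,
                              function(f) f[nzchar(f)])
  }
  total <- length(read_family_map)
  k <- lengths(read_family_map)
  unassigned <- sum(k == 0)
  fam <- unlist(read_family_map, use.names = FALSE)
  w <- rep(1 / pmax(k, 1L), k)
  counts <- if (length(fam)) {
    tapply(w, fam, sum)
  } else {
    numeric(0)
  }
  structure(list(counts = stats::setNames(as.numeric(counts), names(counts)),
                 unassigned = as.numeric(unassigned),
                 total_reads = total),
            class = "family_counts")
}

#' @export
print.family_counts <- function(x, ...) {
  cat("family_counts:", length(x$counts), "families,",
      x$total_reads, "reads (", x$unassigned, "unassigned )\n")
  invisible(x)
}

#' Per-family log2 fold change of IP over input
#'
#' Both count vectors are normalized to counts-per-million of their total
#' read count, then `log2((ip + pc) / (input + pc))` is taken per family.
#' Families absent from one vector are treated as zero there.
#'
#' @param ip,input [assign_fractional()] results.
#' @param pseudocount added after cpm scaling (default 1).
#' @return Named numeric vector of log2 fold changes over the union of
#'   family universes.
#' @export
family_log2fc <- function(ip, input, pseudocount = 1) {
  fams <- sort(union(names(ip$counts), names(input$counts)))
  get_cpm <- function(fc) {
    v <- fc$counts[fams]
    v[is.na(v)] <- 0
    names(v) <- fams
    v / (fc$total_reads / 1e6)
  }
  log2((get_cpm(ip) + pseudocount) / (get_cpm(input) + pseudocount))
}

#' Family-level differential test: paired Wilcoxon + sign-flip permutation
#'
#' For each repeat family, paired values across replicate groups (e.g. KO
#' vs WT log2 fold changes per replicate) are compared with a paired
#' Wilcoxon signed-rank test and a sign-flip permutation test on the
#' centered signed-rank statistic; p-values are Benjamini-Hochberg adjusted
#' across families. With `n` pairs the permutation null is enumerated
#' exhaustively when `2^n <= 1024` (then the p-value is the exact fraction
#' of flips with `|statistic| >= observed`); otherwise `n_perm` random sign
#' flips are used with the add-one correction.
#'
#' @param x,y numeric matrices (families x replicates) of paired
#'   observations; rownames are family labels.
#' @param n_perm number of random permutations when enumeration is not
#'   exhaustive (default 10000).
#' @param seed integer seed for the random-permutation path.
#' @return data.frame per family: mean_diff, p_wilcoxon, p_perm, q (BH on
#'   p_perm), exhaustive flag.
#' @export
family_differential <- function(x, y, n_perm = 10000, seed = NULL) {
  if (!identical(dim(x), dim(y))) stop("x and y must have matching shape")
  if (ncol(x) < 2) stop("need >= 2 paired observations per family")
  fams <- rownames(x)
  if (is.null(fams)) fams <- paste0("family", seq_len(nrow(x)))
  res <- with_seed(seed, {
    rows <- lapply(seq_len(nrow(x)), function(i) {
      d <- x[i, ] - y[i, ]
      if (all(d == 0)) {
        return(data.frame(family = fams[i], mean_diff = 0,
                          p_wilcoxon = 1, p_perm = 1, exhaustive = TRUE))
      }
      pw <- suppressWarnings(
        stats::wilcox.test(x[i, ], y[i, ], paired = TRUE,
                           exact = FALSE)$p.value)
      pp <- sign_flip_p(d, n_perm)
      data.frame(family = fams[i], mean_diff = mean(d), p_wilcoxon = pw,
                 p_perm = pp$p, exhaustive = pp$exhaustive)
    })
    do.call(rbind, rows)
  })
  res$q <- stats::p.adjust(res$p_perm, method = "BH")
  rownames(res) <- NULL
  res
}

# centered signed-rank statistic: V - n(n+1)/4 computed on nonzero diffs
signed_rank_stat <- function(d) {
  d <- d[d != 0]
  if (length(d) == 0) return(0)
  r <- rank(abs(d))
  sum(r[d > 0]) - length(d) * (length(d) + 1) / 4
}

sign_flip_p <- function(d, n_perm) {
  obs <- abs(signed_rank_stat(d))
  n <- sum(d != 0)
  if (n == 0) return(list(p = 1, exhaustive = TRUE))
  if (2^n <= 1024) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    dn <- d[d != 0]
    stat <- apply(signs, 1L, function(s) abs(signed_rank_stat(dn * s)))
    list(p = mean(stat >= obs - 1e-12), exhaustive = TRUE)
  } else {
    dn <- d[d != 0]
    stat <- vapply(seq_len(n_perm), function(j) {
      abs(signed_rank_stat(dn * sample(c(-1, 1), n, replace = TRUE)))
    }, numeric(1))
    list(p = (1 + sum(stat >= obs - 1e-12)) / (n_perm + 1),
         exhaustive = FALSE)
  }
}
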