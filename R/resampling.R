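#' Sample length-matched random region groups
#'
#' Builds the resampling null used by the landmark-region enrichment tests:
#' `n_groups` groups, each containing one random region per template region
#' with exactly the template's length. For each placement a chromosome is
#' drawn with probability proportional to the number of feasible start
#' positions, then a start is drawn uniformly so that the region fits;
#' placements overlapping the exclusion set are rejection-sampled (cap
#' 10,000 tries per region slot). Deterministic given `seed`.
#'
#' @param layout a [genome_layout()].
#' @param template data.frame of intervals whose count and lengths the null
#'   groups match.
#' @param n_groups number of groups (default 1000).
#' @param seed integer seed.
#' @param exclusion interval set the samples must avoid; defaults to the
#'   template regions themselves (`NULL` disables exclusion).
#' @param align_to optional grid width in bp. When set, sampled starts are
#'   restricted to multiples of the grid (uniform over feasible grid
#'   slots). Use the analysis bin size here when the downstream statistic
#'   is bin-based, so control regions cover the same number of bins as the
#'   equally bin-aligned landmark regions instead of straddling one extra
#'   bin.
#' @return An object of class `random_region_null`: list with `groups`
#'   (data.frame group/chrom/start/end), `n_groups`, `seed`, `exclusion`.
#' @export
sample_random_groups <- function(layout, template, n_groups = 1000,
                                 seed = NULL, exclusion = template,
                                 align_to = NULL) {
  if (nrow(template) == 0) stop("template is empty")
  lens <- template$end - template$start
  chrom_len <- layout$length
  groups <- with_seed(seed, {
    total <- n_groups * length(lens)
    L <- rep(lens, times = n_groups)
    chrom <- character(total)
    start <- numeric(total)
    pending <- seq_len(total)
    tries <- 0L
    while (length(pending)) {
      tries <- tries + 1L
      if (tries > 10000L)
        stop("could not place region of length ", L[pending[1]],
             " after 10,000 tries")
      # draw chromosomes (prob ~ feasible starts) and starts, batched by
      # template length
      for (Lu in unique(L[pending])) {
        slot <- pending[L[pending] == Lu]
        usable <- if (is.null(align_to)) pmax(chrom_len - Lu + 1, 0)
          else pmax(floor((chrom_len - Lu) / align_to) + 1, 0)
        if (sum(usable) == 0)
          stop("region of length ", Lu, " fits on no chromosome")
        ch <- layout$chrom[sample.int(length(usable), length(slot),
                                      replace = TRUE, prob = usable)]
        chrom[slot] <- ch
        s <- floor(stats::runif(length(slot)) * usable[ch])
        start[slot] <- if (is.null(align_to)) s else s * align_to
      }
      # reject placements overlapping the exclusion set
      if (!is.null(exclusion) && nrow(exclusion)) {
        bad <- vapply(pending, function(i) {
          sel <- exclusion$chrom == chrom[i]
          any(exclusion$start[sel] < start[i] + L[i] &
                exclusion$end[sel] > start[i])
        }, logical(1))
        pending <- pending[bad]
      } else {
        pending <- integer(0)
      }
    }
    data.frame(group = rep(seq_len(n_groups), each = length(lens)),
               chrom = chrom, start = start, end = start + L,
               stringsAsFactors = FALSE)
  })
  structure(list(groups = groups, n_groups = n_groups, seed = seed,
                 exclusion = exclusion, template_lengths = lens),
            class = "random_region_null")
}

#' @export
print.random_region_null <- function(x, ...) {
  cat("random_region_null:", x$n_groups, "groups x",
      length(x$template_lengths), "regions (seed",
      if (is.null(x$seed)) "none" else x$seed, ")\n")
  invisible(x)
}

#' Region enrichment test against a random-region null
#'
#' The observed statistic is the median track value over bins overlapping
#' the query regions; the null distribution is the same statistic over each
#' random group. Two p-values are reported: a Mann-Whitney U p of the
#' selected bin values against the pooled null bin values, and the primary
#' empirical p from the group-statistic null distribution. The empirical p
#' is two-sided and add-one corrected:
#' `(1 + #\{|null - c| >= |obs - c|\}) / (n_groups + 1)` with `c` the null
#' mean, so it is never 0 and equals `1/(n_groups + 1)` when the observed
#' median is more extreme than every group.
#'
#' @param track a [binned_track()].
#' @param regions data.frame of query intervals.
#' @param null a [sample_random_groups()] result on the same layout.
#' @return An object of class `enrichment_result`: list with
#'   `observed_stat`, `null_stats`, `mw_p`, `empirical_p`, `direction`,
#'   `n_selected_bins`.
#' @export
region_enrichment_test <- function(track, regions, null) {
  layout <- track$layout
  sel_bins <- bins_overlapping(layout, track$bin_size, regions)
  sel_values <- track_values_at(track, sel_bins)
  sel_values <- sel_values[!is.na(sel_values)]
  if (length(sel_values) == 0) stop("no bins overlap the query regions")
  g <- null$groups
  # flat genome-order indexing: offset[chrom] + bin
  nb <- n_bins(layout, track$bin_size)
  offset <- stats::setNames(cumsum(c(0L, unname(nb)))[seq_along(nb)],
                            names(nb))
  flat <- unlist(track$values[names(nb)], use.names = FALSE)
  first <- floor(g$start / track$bin_size) + 1L
  last <- pmin(floor((g$end - 1) / track$bin_size) + 1L,
               unname(nb[g$chrom]))
  first <- pmax(first, 1L)
  cnt <- last - first + 1L
  idx_all <- sequence(cnt) - 1L + rep(first + offset[g$chrom], cnt)
  grp_all <- rep(g$group, cnt)
  # drop duplicate bins within each group
  dup <- duplicated(grp_all * (length(flat) + 1) + idx_all)
  idx_all <- idx_all[!dup]; grp_all <- grp_all[!dup]
  v_all <- flat[idx_all]
  null_stats <- vapply(split(v_all, grp_all),
                       stats::median, numeric(1), na.rm = TRUE)
  pooled <- v_all[!is.na(v_all)]
  observed <- stats::median(sel_values)
  mw_p <- suppressWarnings(
    stats::wilcox.test(sel_values, pooled, exact = FALSE)$p.value)
  centre <- mean(null_stats)
  empirical_p <- (1 + sum(abs(null_stats - centre) >=
                            abs(observed - centre))) / (null$n_groups + 1)
  structure(list(observed_stat = observed, null_stats = unname(null_stats),
                 mw_p = mw_p, empirical_p = empirical_p,
                 direction = if (observed >= stats::median(null_stats))
                   "enriched" else "depleted",
                 n_selected_bins = length(sel_values)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: observed %.4g vs null %.4g +/- %.4g (%d groups)\n",
    x$observed_stat, mean(x$null_stats), stats::sd(x$null_stats),
    length(x$null_stats)))
  cat(sprintf("  direction %s; empirical p = %.4g; Mann-Whitney p = %.4g\n",
              x$direction, x$empirical_p, x$mw_p))
  invisible(x)
}

#' Observed versus expected peak overlap (chi-squared)
#'
#' Tests whether peaks fall inside a bin selection (e.g. the top 10% most
#' UV-susceptible bins) more or less often than expected under the null
#' hypothesis of no association: expected in-selection count =
#' `n_peaks * |selected| / |all|`. One-degree-of-freedom chi-squared on the
#' (in, out) observed vs expected cells. Peaks map to bins by midpoint.
#'
#' @param peaks data.frame of peak intervals.
#' @param selected_bins,all_bins data.frames (chrom, bin); `selected_bins`
#'   must be a subset of `all_bins`.
#' @param bin_size bin width in bp.
#' @return list with `chisq`, `p`, `df`, and `table` (observed/expected per
#'   cell).
#' @export
observed_expected_overlap <- function(peaks, selected_bins, all_bins,
                                      bin_size) {
  if (nrow(peaks) == 0) stop("no peaks supplied")
  key <- function(df) paste(df$chrom, df$bin)
  if (!all(key(selected_bins) %in% key(all_bins)))
    stop("selected_bins must be a subset of all_bins")
  mid <- floor((peaks$start + peaks$end) / 2)
  peak_key <- paste(peaks$chrom, floor(mid / bin_size) + 1L)
  in_universe <- peak_key %in% key(all_bins)
  n <- sum(in_universe)
  if (n == 0) stop("no peaks fall in the bin universe")
  obs_in <- sum(peak_key[in_universe] %in% key(selected_bins))
  exp_in <- n * nrow(selected_bins) / nrow(all_bins)
  obs <- c(inside = obs_in, outside = n - obs_in)
  expd <- c(inside = exp_in, outside = n - exp_in)
  if (any(expd < 1))
    warning("expected cell < 1; chi-squared approximation is suspect")
  chisq <- sum((obs - expd)^2 / expd)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       df = 1L,
       table = data.frame(cell = names(obs), observed = unname(obs),
                          expected = unname(expd)))
}

#' Cumulative repair enrichment across XR-seq timepoints
#'
#' Replicate (and strand) tracks within each timepoint are averaged, the
#' averaged tracks are prefix-summed across timepoints (each cumulative
#' track is the sum of its timepoint and all earlier ones), and
#' [region_enrichment_test()] is applied to each cumulative track.
#'
#' @param timepoint_tracks ordered list; each element is a
#'   [binned_track()] or a list of replicate tracks to average.
#' @param regions query intervals.
#' @param null a [sample_random_groups()] result.
#' @return list with `cumulative_tracks` and `results` (one
#'   `enrichment_result` per timepoint).
#' @export
cumulative_repair_profile <- function(timepoint_tracks, regions, null) {
  avg <- lapply(timepoint_tracks, function(tp) {
    if (inherits(tp, "binned_track")) return(tp)
    ref <- tp[[1]]
    for (t in tp[-1]) if (!same_bin_structure(ref, t))
      stop("inconsistent bin structures within a timepoint")
    vals <- lapply(names(ref$values), function(ch) {
      Reduce(`+`, lapply(tp, function(t) t$values[[ch]])) / length(tp)
    })
    binned_track(ref$layout, ref$bin_size, stats::setNames(vals, names(ref$values)))
  })
  ref <- avg[[1]]
  for (t in avg[-1]) if (!same_bin_structure(ref, t))
    stop("inconsistent bin structures across timepoints")
  cumulative <- vector("list", length(avg))
  running <- lapply(ref$values, function(v) v * 0)
  for (i in seq_along(avg)) {
    running <- stats::setNames(lapply(names(running), function(ch)
      running[[ch]] + avg[[i]]$values[[ch]]), names(running))
    cumulative[[i]] <- binned_track(ref$layout, ref$bin_size, running)
  }
  list(cumulative_tracks = cumulative,
       results = lapply(cumulative, region_enrichment_test,
                        regions = regions, null = null))
}
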