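#' Fixed-width binned signal track
#'
#' One numeric vector per chromosome, one value per bin; the last bin may be
#' partial (it covers `[(n-1) * bin_size, length)`). `NA` marks unmappable /
#' missing bins.
#'
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp.
#' @param values named list of numeric vectors, one per chromosome, each of
#'   length `ceiling(length / bin_size)`. Omitted with `fill` to build a
#'   constant track.
#' @param fill scalar used when `values` is NULL (default 0).
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(layout, bin_size, values = NULL, fill = 0) {
  nb <- n_bins(layout, bin_size)
  if (is.null(values)) {
    values <- lapply(nb, function(n) rep(as.numeric(fill), n))
  } else {
    if (!setequal(names(values), layout$chrom))
      stop("values must be named by the layout's chromosomes")
    values <- values[layout$chrom]
    ok <- vapply(layout$chrom,
                 function(ch) length(values[[ch]]) == nb[[ch]], logical(1))
    if (!all(ok))
      stop("bin count mismatch on: ",
           paste(layout$chrom[!ok], collapse = ", "))
    values <- lapply(values, as.numeric)
  }
  structure(list(layout = layout, bin_size = bin_size, values = values),
            class = "binned_track")
}

n_bins <- function(layout, bin_size) {
  stats::setNames(as.integer(ceiling(layout$length / bin_size)), layout$chrom)
}

#' @export
print.binned_track <- function(x, ...) {
  v <- unlist(x$values, use.names = FALSE)
  cat("binned_track: bin_size", format(x$bin_size, big.mark = ","),
      "bp;", length(v), "bins (", sum(is.na(v)), "missing );",
      "range", paste(signif(range(v, na.rm = TRUE), 4), collapse = " .. "),
      "\n")
  invisible(x)
}

# flatten a track to a data.frame in genome order
track_frame <- function(track) {
  nb <- lengths(track$values)
  data.frame(chrom = rep(names(track$values), nb),
             bin = unlist(lapply(nb, seq_len), use.names = FALSE),
             value = unlist(track$values, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# values at a (chrom, bin) selection
track_values_at <- function(track, bins) {
  vapply(seq_len(nrow(bins)),
         function(i) track$values[[bins$chrom[i]]][bins$bin[i]],
         numeric(1))
}

same_bin_structure <- function(a, b) {
  a$bin_size == b$bin_size &&
    identical(names(a$values), names(b$values)) &&
    identical(lengths(a$values), lengths(b$values))
}

#' Count fragment midpoints per bin
#'
#' Each aligned fragment contributes one count to the bin containing its
#' midpoint `floor((start + end) / 2)`; the per-bin totals are raw integers,
#' so the track conserves the fragment count.
#'
#' @param fragments data.frame of intervals (chrom/start/end).
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp.
#' @return A [binned_track()] of counts.
#' @export
bin_coverage <- function(fragments, layout, bin_size) {
  unknown <- setdiff(fragments$chrom, layout$chrom)
  if (length(unknown))
    stop("fragments on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  nb <- n_bins(layout, bin_size)
  values <- lapply(nb, function(n) numeric(n))
  if (nrow(fragments)) {
    mid <- floor((fragments$start + fragments$end) / 2)
    bin <- floor(mid / bin_size) + 1L
    for (ch in unique(fragments$chrom)) {
      values[[ch]] <- values[[ch]] +
        tabulate(bin[fragments$chrom == ch], nbins = nb[[ch]])
    }
  }
  binned_track(layout, bin_size, values)
}

#' Log2 ratio of two binned tracks
#'
#' `log2((a_norm + pseudocount) / (b_norm + pseudocount))` per bin, where
#' `cpm` scaling first divides each track by its nonmissing total / 1e6.
#' Missing wherever either input is missing.
#'
#' @param numerator,denominator [binned_track()]s with identical bin
#'   structure.
#' @param pseudocount added to both scaled values (default 1).
#' @param scale `"cpm"` for counts-per-million library-size normalization or
#'   `"none"`.
#' @return A [binned_track()] of log2 ratios, with the parameters attached as
#'   attributes `pseudocount` and `scale`.
#' @export
normalize_and_ratio <- function(numerator, denominator, pseudocount = 1,
                                scale = c("cpm", "none")) {
  scale <- match.arg(scale)
  if (!same_bin_structure(numerator, denominator))
    stop("tracks have mismatched bin structure")
  # library sizes are genome-wide totals
  num_total <- sum(unlist(numerator$values), na.rm = TRUE)
  den_total <- sum(unlist(denominator$values), na.rm = TRUE)
  values <- mapply(function(a, b) {
    if (scale == "cpm") {
      a <- a / (num_total / 1e6)
      b <- b / (den_total / 1e6)
    }
    r <- log2((a + pseudocount) / (b + pseudocount))
    r[is.na(a) | is.na(b)] <- NA_real_
    r
  }, numerator$values, denominator$values, SIMPLIFY = FALSE)
  out <- binned_track(numerator$layout, numerator$bin_size, values)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "scale") <- scale
  out
}

#' Select the top or bottom quantile of bins
#'
#' Returns exactly `round(fraction * n_nonmissing)` bins. Ties at the
#' threshold are broken deterministically by genome order (chromosome order,
#' then bin index).
#'
#' @param track a [binned_track()].
#' @param fraction in (0, 1).
#' @param tail `"top"` or `"bottom"`.
#' @return data.frame with columns chrom, bin, value.
#' @export
select_quantile_bins <- function(track, fraction, tail = c("top", "bottom")) {
  tail <- match.arg(tail)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  df <- track_frame(track)
  df <- df[!is.na(df$value), , drop = FALSE]
  k <- round(fraction * nrow(df))
  if (k < 1) stop("fraction selects 0 bins")
  key <- if (tail == "top") -df$value else df$value
  ord <- order(key, match(df$chrom, track$layout$chrom), df$bin)
  out <- df[ord[seq_len(k)], , drop = FALSE]
  out <- out[order(match(out$chrom, track$layout$chrom), out$bin), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate a track by chromatin state (or any labeled segmentation)
#'
#' Each bin is assigned to the label covering the majority of the bin (ties
#' go to the label whose interval starts first); per label the distribution
#' of assigned bin values is summarized and compared against all nonmissing
#' genome bins with a two-sided Mann-Whitney U test.
#'
#' @param track a [binned_track()].
#' @param states data.frame of labeled intervals (chrom/start/end/label).
#' @return An object of class `state_aggregate`: data.frame with one row per
#'   label (n, median, q25, q75, p_mw, scaled_median) plus attributes
#'   `genome_median` and `assignment` (the per-bin label table).
#' @export
aggregate_by_state <- function(track, states) {
  if (is.null(states$label)) stop("states need a 'label' column")
  assign <- assign_bins_to_labels(track$layout, track$bin_size, states)
  assign$value <- track_values_at(track, assign)
  assign <- assign[!is.na(assign$value), , drop = FALSE]
  genome_values <- unlist(track$values, use.names = FALSE)
  genome_values <- genome_values[!is.na(genome_values)]
  gmed <- stats::median(genome_values)
  labels <- sort(unique(states$label))
  rows <- lapply(labels, function(lb) {
    v <- assign$value[assign$label == lb]
    if (length(v) == 0)
      return(data.frame(label = lb, n = 0L, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_, p_mw = NA_real_))
    p <- suppressWarnings(
      stats::wilcox.test(v, genome_values, exact = FALSE)$p.value)
    if (is.na(p)) p <- 1  # every value tied: no evidence of difference
    data.frame(label = lb, n = length(v), median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)), p_mw = p)
  })
  out <- do.call(rbind, rows)
  rng <- range(out$median, na.rm = TRUE)
  out$scaled_median <- if (diff(rng) > 0)
    (out$median - rng[1]) / diff(rng) else rep(0.5, nrow(out))
  attr(out, "genome_median") <- gmed
  attr(out, "assignment") <- assign
  class(out) <- c("state_aggregate", "data.frame")
  out
}

# majority-coverage assignment of bins to segmentation labels
assign_bins_to_labels <- function(layout, bin_size, states) {
  pieces <- lapply(seq_len(nrow(states)), function(i) {
    ch <- states$chrom[i]
    s <- states$start[i]; e <- states$end[i]
    first <- floor(s / bin_size) + 1L
    last <- floor((e - 1) / bin_size) + 1L
    bin <- seq.int(first, last)
    bs <- (bin - 1) * bin_size
    be <- pmin(bin * bin_size, layout$length[[ch]])
    data.frame(chrom = ch, bin = bin,
               bp = pmin(e, be) - pmax(s, bs),
               seg_start = s, label = states$label[i],
               stringsAsFactors = FALSE)
  })
  cov <- do.call(rbind, pieces)
  cov <- cov[cov$bp > 0, , drop = FALSE]
  # total bp per (bin, label), keeping the earliest segment start for ties
  key <- paste(cov$chrom, cov$bin, cov$label, sep = "\r")
  bp <- rowsum(cov$bp, key)
  min_start <- tapply(cov$seg_start, key, min)
  parts <- do.call(rbind, strsplit(rownames(bp), "\r", fixed = TRUE))
  agg <- data.frame(chrom = parts[, 1], bin = as.integer(parts[, 2]),
                    label = parts[, 3], bp = bp[, 1],
                    seg_start = as.numeric(min_start[rownames(bp)]),
                    stringsAsFactors = FALSE)
  agg <- agg[order(agg$chrom, agg$bin, -agg$bp, agg$seg_start), , drop = FALSE]
  winner <- !duplicated(agg[c("chrom", "bin")])
  out <- agg[winner, c("chrom", "bin", "label"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.state_aggregate <- function(x, ...) {
  cat("state_aggregate over", nrow(x), "labels; genome median",
      signif(attr(x, "genome_median"), 4), "\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Spearman correlation between two tracks
#'
#' Computed over pairwise-nonmissing bins.
#'
#' @param a,b [binned_track()]s with identical bin structure.
#' @return list with `rho` and `p` (two-sided).
#' @export
correlate_tracks <- function(a, b) {
  if (!same_bin_structure(a, b))
    stop("tracks have mismatched bin structure")
  x <- unlist(a$values, use.names = FALSE)
  y <- unlist(b$values, use.names = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("fewer than 3 complete bin pairs")
  ct <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Filter genes by fractional overlap with a bin selection
#'
#' A gene is kept iff the fraction of its length covered by the selected
#' bins strictly exceeds `min_fraction`.
#'
#' @param genes data.frame of labeled intervals (chrom/start/end/label =
#'   gene symbol).
#' @param selected_bins data.frame (chrom, bin) as returned by
#'   [select_quantile_bins()] or [bins_overlapping()].
#' @param layout a [genome_layout()].
#' @param bin_size bin width used for `selected_bins`.
#' @param min_fraction strict lower bound on overlap fraction (default 0.10).
#' @return The subset of `genes`, with an added `overlap_fraction` column.
#' @export
select_genes_by_overlap <- function(genes, selected_bins, layout, bin_size,
                                    min_fraction = 0.10) {
  if (any(genes$end <= genes$start)) stop("zero-length gene")
  frac <- vapply(seq_len(nrow(genes)), function(i) {
    ch <- genes$chrom[i]
    s <- genes$start[i]; e <- genes$end[i]
    sel <- selected_bins$bin[selected_bins$chrom == ch]
    if (length(sel) == 0) return(0)
    bs <- (sel - 1) * bin_size
    be <- pmin(sel * bin_size, layout$length[[ch]])
    sum(pmax(0, pmin(e, be) - pmax(s, bs))) / (e - s)
  }, numeric(1))
  out <- genes[frac > min_fraction, , drop = FALSE]
  out$overlap_fraction <- frac[frac > min_fraction]
  rownames(out) <- NULL
  out
}
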