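#' Merge adjacent same-label compartments
#'
#' Consecutive compartments with the same label on a chromosome are merged
#' into one spanning interval (whether touching or separated by a gap),
#' producing the dense alternating A/B track the metaprofile needs.
#' Idempotent.
#'
#' @param compartments data.frame of labeled intervals with labels in
#'   \{A, B\}, sorted and non-overlapping per chromosome.
#' @return data.frame of merged labeled intervals.
#' @export
merge_adjacent <- function(compartments) {
  bad <- setdiff(unique(compartments$label), c("A", "B"))
  if (length(bad))
    stop("labels outside {A, B}: ", paste(bad, collapse = ", "))
  out <- lapply(split(compartments, compartments$chrom), function(df) {
    df <- df[order(df$start), , drop = FALSE]
    r <- rle(df$label)
    last <- cumsum(r$lengths)
    first <- last - r$lengths + 1L
    data.frame(chrom = df$chrom[1], start = df$start[first],
               end = df$end[last], label = r$values,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescale one compartment onto a fixed number of meta-bins
#'
#' The compartment is split into `n_bins` equal-width sub-intervals; each
#' meta-bin takes the median of the track bins whose midpoints fall inside
#' it. Meta-bins containing no track-bin midpoint are filled from the
#' nearest nonempty meta-bin (left wins ties) and flagged.
#'
#' @param track a [binned_track()].
#' @param compartment one interval (list or single-row data.frame with
#'   chrom, start, end).
#' @return list with `values` (length `n_bins`) and `filled` (logical flag
#'   per meta-bin).
#' @param n_bins number of meta-bins (default 50).
#' @export
rescale_compartment <- function(track, compartment, n_bins = 50) {
  ch <- compartment$chrom[1]
  s <- compartment$start[1]; e <- compartment$end[1]
  bs <- track$bin_size
  v <- track$values[[ch]]
  # track bins whose midpoints lie inside the compartment
  first <- floor(s / bs) + 1L
  last <- min(floor((e - 1) / bs) + 1L, length(v))
  cand <- seq.int(max(first, 1L), last)
  mids <- (cand - 0.5) * bs
  mids <- pmin(mids, track$layout$length[[ch]] - 0.5)  # partial last bin
  inside <- mids >= s & mids < e
  if (!any(inside)) stop("compartment overlaps no track bins")
  cand <- cand[inside]; mids <- mids[inside]
  meta <- pmin(floor((mids - s) / (e - s) * n_bins) + 1L, n_bins)
  med <- tapply(v[cand], meta, stats::median, na.rm = TRUE)
  values <- rep(NA_real_, n_bins)
  values[as.integer(names(med))] <- as.numeric(med)
  filled <- is.na(values)
  if (any(filled)) {
    nonempty <- which(!filled)
    for (i in which(filled)) {
      nearest <- nonempty[which.min(abs(nonempty - i))]
      values[i] <- values[nearest]
    }
  }
  list(values = values, filled = filled)
}

#' A-B-A compartment metaprofile with bootstrap confidence band
#'
#' Every B compartment flanked by an A on both sides forms a triple; each
#' triple contributes a concatenated vector (left A, B, right A), each part
#' rescaled to `n_bins` meta-bins, aligning the closed (B) compartment in
#' the middle. The profile is the positionwise mean over triples; the 95%
#' band is the positionwise 2.5/97.5 percentile of means over `R` bootstrap
#' resamples of triples (with replacement). Deterministic given `seed`.
#'
#' @param track a [binned_track()].
#' @param compartments labeled A/B intervals (merged with
#'   [merge_adjacent()] if needed).
#' @param n_bins meta-bins per compartment (default 50).
#' @param R bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return An object of class `metaprofile`: list with `mean`, `ci_low`,
#'   `ci_high` (length `3 * n_bins`), `n_triples`, `triples` (matrix), `R`,
#'   `seed`, `n_bins_per_compartment`.
#' @export
build_metaprofile <- function(track, compartments, n_bins = 50, R = 1000,
                              seed = NULL) {
  merged <- merge_adjacent(compartments)
  triples <- list()
  for (df in split(merged, merged$chrom)) {
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) < 3) next
    for (i in seq(2, nrow(df) - 1)) {
      if (df$label[i] == "B" && df$label[i - 1] == "A" &&
          df$label[i + 1] == "A") {
        vec <- c(rescale_compartment(track, df[i - 1, ], n_bins)$values,
                 rescale_compartment(track, df[i, ], n_bins)$values,
                 rescale_compartment(track, df[i + 1, ], n_bins)$values)
        triples[[length(triples) + 1L]] <- vec
      }
    }
  }
  m <- do.call(rbind, triples)
  if (is.null(m) || nrow(m) < 2)
    stop("fewer than 2 A-B-A triples; confidence band undefined")
  prof_mean <- colMeans(m)
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(nrow(m), nrow(m) * R, replace = TRUE),
                  nrow = R)
    t(apply(idx, 1L, function(j) colMeans(m[j, , drop = FALSE])))
  })
  ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  structure(list(mean = prof_mean,
                 ci_low = pmin(ci[1, ], prof_mean),
                 ci_high = pmax(ci[2, ], prof_mean),
                 n_triples = nrow(m), triples = m, R = R, seed = seed,
                 n_bins_per_compartment = n_bins),
            class = "metaprofile")
}

#' @export
print.metaprofile <- function(x, ...) {
  nb <- x$n_bins_per_compartment
  cat("metaprofile:", x$n_triples, "A-B-A triples,", 3 * nb,
      "positions, R =", x$R, "\n")
  cat(sprintf("  flank A mean %.4g; central B mean %.4g\n",
              mean(x$mean[c(1:nb, (2 * nb + 1):(3 * nb))]),
              mean(x$mean[(nb + 1):(2 * nb)])))
  invisible(x)
}

#' @export
plot.metaprofile <- function(x, ...) {
  nb <- x$n_bins_per_compartment
  pos <- seq_along(x$mean)
  graphics::plot(pos, x$mean, type = "n",
                 ylim = range(c(x$ci_low, x$ci_high)),
                 xlab = "meta-position (A | B | A)", ylab = "signal", ...)
  graphics::rect(nb + 0.5, graphics::par("usr")[3], 2 * nb + 0.5,
                 graphics::par("usr")[4],
                 col = grDevices::adjustcolor("red", 0.12), border = NA)
  graphics::polygon(c(pos, rev(pos)), c(x$ci_low, rev(x$ci_high)),
                    col = "grey80", border = NA)
  graphics::lines(pos, x$mean, col = "black", lwd = 2)
  invisible(x)
}
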