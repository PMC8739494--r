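# shared fixtures built in code

tiny_layout <- function() {
  genome_layout(c("chr1", "chr2"), c(1e6, 8e5),
                cen_start = c(4e5, 3e5), cen_end = c(5e5, 4e5))
}

# a track with deterministic pseudo-random values
value_track <- function(layout = tiny_layout(), bin_size = 1e5, seed = 42) {
  set.seed(seed)
  vals <- lapply(stats::setNames(nm = layout$chrom), function(ch)
    round(stats::runif(ceiling(layout$length[[ch]] / bin_size), 0, 100), 3))
  binned_track(layout, bin_size, vals)
}

# brute-force overlap oracle: does bin i on chrom overlap any region?
oracle_bins_overlapping <- function(layout, bin_size, regions) {
  out <- list()
  for (ch in layout$chrom) {
    nb <- ceiling(layout$length[[ch]] / bin_size)
    for (i in seq_len(nb)) {
      bs <- (i - 1) * bin_size
      be <- min(i * bin_size, layout$length[[ch]])
      sel <- regions$chrom == ch
      if (any(regions$start[sel] < be & regions$end[sel] > bs))
        out[[length(out) + 1L]] <- data.frame(chrom = ch, bin = i)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), bin = integer()))
  do.call(rbind, out)
}

random_regions <- function(layout, n, min_len = 1, max_len = 3e5) {
  chrom <- sample(layout$chrom, n, replace = TRUE)
  len <- sample(seq(min_len, max_len), n, replace = TRUE)
  len <- pmin(len, layout$length[chrom])
  start <- floor(runif(n) * (layout$length[chrom] - len + 1))
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# brute-force BH step-up q-values
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  q[o] <- rev(cummin(rev(sorted)))
  pmin(q, 1)
}
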