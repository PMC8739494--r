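#' Dipyrimidine content of sequences
#'
#' CPDs form between adjacent pyrimidines on either strand, so each
#' pyrimidine dinucleotide is counted double-stranded: plus-strand
#' occurrences of the dinucleotide plus occurrences of its reverse
#' complement (TT with AA, TC with GA, CT with AG, CC with GG). The
#' denominator is the number of valid dinucleotide windows per strand
#' contribution, i.e. `2 * (#windows without N)`; windows containing N are
#' excluded from numerator and denominator alike.
#'
#' @param sequences character vector of uppercase ACGTN strings, one per
#'   region.
#' @return data.frame with one row per sequence and columns `TT`, `TC`,
#'   `CT`, `CC` (frequencies in \[0, 1\]) plus `n_windows` (valid windows on
#'   one strand). Sequences with no valid window get `NA` frequencies.
#' @examples
#' dipyrimidine_content("TTAA")  # TpT frequency 2/6
#' @export
dipyrimidine_content <- function(sequences) {
  pairs <- c(TT = "AA", TC = "GA", CT = "AG", CC = "GG")
  rows <- lapply(sequences, function(s) {
    counts <- dinucleotide_counts(s)
    nw <- sum(counts)
    if (nw == 0)
      return(data.frame(TT = NA_real_, TC = NA_real_, CT = NA_real_,
                        CC = NA_real_, n_windows = 0L))
    freq <- vapply(names(pairs), function(d) {
      (counts[[d]] + counts[[pairs[[d]]]]) / (2 * nw)
    }, numeric(1))
    data.frame(TT = freq[["TT"]], TC = freq[["TC"]], CT = freq[["CT"]],
               CC = freq[["CC"]], n_windows = nw)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# counts of all 16 ACGT dinucleotides over windows free of N
dinucleotide_counts <- function(s) {
  n <- nchar(s)
  counts <- stats::setNames(
    integer(16),
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)))
  if (n < 2) return(counts)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  a <- chars[-n]; b <- chars[-1]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) return(counts)
  tab <- table(paste0(a[ok], b[ok]))
  counts[names(tab)] <- as.integer(tab)
  counts
}
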