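#' Genome layout: chromosome lengths, centromeres, telomere anchors
#'
#' The coordinate frame shared by every analysis in the package. All
#' coordinates are 0-based half-open (BED convention). Telomeres are modeled
#' as the two anchor positions of each chromosome (p-end = 0, q-end = length)
#' rather than intervals; the subtelomeric definition used downstream only
#' needs the ends.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length numeric vector of chromosome lengths in bp (> 0).
#' @param cen_start,cen_end optional numeric vectors giving the centromere
#'   interval per chromosome (0-based half-open); `NA` for chromosomes
#'   without an annotated centromere.
#' @return An object of class `genome_layout`: a list with `chrom`, `length`
#'   (named), and `centromeres` (data.frame chrom/start/end, annotated
#'   chromosomes only).
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e7, 8e6),
#'               cen_start = c(4.9e6, 3.9e6), cen_end = c(5.1e6, 4.1e6))
#' @export
genome_layout <- function(chrom, length, cen_start = NULL, cen_end = NULL) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  if (is.null(cen_start)) cen_start <- rep(NA_real_, base::length(chrom))
  if (is.null(cen_end)) cen_end <- rep(NA_real_, base::length(chrom))
  has_cen <- !is.na(cen_start) & !is.na(cen_end)
  if (any(has_cen & (cen_start < 0 | cen_end > length | cen_start >= cen_end)))
    stop("centromere interval must satisfy 0 <= start < end <= length")
  layout <- list(
    chrom = chrom,
    length = stats::setNames(length, chrom),
    centromeres = data.frame(
      chrom = chrom[has_cen],
      start = as.numeric(cen_start[has_cen]),
      end = as.numeric(cen_end[has_cen]),
      stringsAsFactors = FALSE
    )
  )
  class(layout) <- "genome_layout"
  layout
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom), "chromosomes,",
      format(sum(x$length), big.mark = ","), "bp total;",
      nrow(x$centromeres), "centromeres annotated\n")
  invisible(x)
}

#' Read a genome layout from a TSV file
#'
#' Expects a header line with columns `chrom`, `length`, and optionally
#' `cen_start`, `cen_end`.
#'
#' @param path file path.
#' @return A [genome_layout()] object.
#' @export
read_genome_layout <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(tab)))
    stop("layout file needs 'chrom' and 'length' columns")
  genome_layout(tab$chrom, tab$length,
                cen_start = if ("cen_start" %in% names(tab)) tab$cen_start,
                cen_end = if ("cen_end" %in% names(tab)) tab$cen_end)
}

#' Write a genome layout to a TSV file
#'
#' @param layout a [genome_layout()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_genome_layout <- function(layout, path) {
  cen <- layout$centromeres
  idx <- match(layout$chrom, cen$chrom)
  tab <- data.frame(chrom = layout$chrom,
                    length = unname(layout$length),
                    cen_start = cen$start[idx],
                    cen_end = cen$end[idx])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated set of genomic intervals
#'
#' Intervals are 0-based half-open. When a `layout` is supplied each interval
#' is checked against its chromosome bounds.
#'
#' @param chrom character vector.
#' @param start,end numeric vectors, `0 <= start < end`.
#' @param label optional per-interval label (chromatin state, compartment,
#'   repeat family, gene symbol).
#' @param layout optional [genome_layout()] for bounds checking.
#' @return A data.frame with columns chrom/start/end (and label).
#' @export
genomic_intervals <- function(chrom, start, end, label = NULL, layout = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- as.character(label)
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("intervals must satisfy 0 <= start < end")
  if (!is.null(layout)) {
    unknown <- setdiff(df$chrom, layout$chrom)
    if (length(unknown))
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(df$end > layout$length[df$chrom]))
      stop("interval end exceeds chromosome length")
  }
  df
}

#' Pericentric regions: centromere flanks
#'
#' For each annotated centromere `[s, e)` returns the two flanking intervals
#' `[max(0, s - flank), s)` and `[e, min(len, e + flank))`, clipped to
#' chromosome bounds. The centromere body itself is excluded. Chromosomes
#' without a centromere entry are skipped with a warning.
#'
#' @param layout a [genome_layout()].
#' @param flank flank width in bp (default 1 Mb).
#' @return data.frame of intervals (chrom/start/end).
#' @export
define_pericentric <- function(layout, flank = 1e6) {
  missing_cen <- setdiff(layout$chrom, layout$centromeres$chrom)
  if (length(missing_cen))
    warning("no centromere entry, skipping: ",
            paste(missing_cen, collapse = ", "))
  if (flank <= 0 || nrow(layout$centromeres) == 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  cen <- layout$centromeres
  len <- layout$length[cen$chrom]
  out <- data.frame(
    chrom = rep(cen$chrom, 2L),
    start = c(pmax(0, cen$start - flank), cen$end),
    end = c(cen$start, pmin(unname(len), cen$end + flank)),
    stringsAsFactors = FALSE
  )
  out <- out[out$start < out$end, , drop = FALSE]
  out <- out[order(match(out$chrom, layout$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtelomeric regions: chromosome-end windows
#'
#' Per chromosome: `[0, min(flank, len))` and `[max(0, len - flank), len)`.
#' On chromosomes shorter than `2 * flank` the two windows overlap; both are
#' kept and a warning is emitted.
#'
#' @param layout a [genome_layout()].
#' @param flank window width in bp (default 100 kb).
#' @return data.frame of intervals (chrom/start/end).
#' @export
define_subtelomeric <- function(layout, flank = 1e5) {
  if (flank <= 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  len <- unname(layout$length)
  short <- layout$chrom[len < 2 * flank]
  if (length(short))
    warning("subtelomeric windows overlap on: ",
            paste(short, collapse = ", "))
  out <- data.frame(
    chrom = rep(layout$chrom, each = 2L),
    start = as.numeric(rbind(0, pmax(0, len - flank))),
    end = as.numeric(rbind(pmin(flank, len), len)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Bins overlapping a region set
#'
#' A bin is selected iff its half-open interval overlaps any region by at
#' least 1 bp. Bin `i` (1-based) covers
#' `[(i-1) * bin_size, min(i * bin_size, length))`.
#'
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp.
#' @param regions data.frame of intervals (chrom/start/end).
#' @return data.frame with columns `chrom`, `bin` (1-based bin index),
#'   one row per selected bin, unique, in genome order.
#' @export
bins_overlapping <- function(layout, bin_size, regions) {
  if (nrow(regions) == 0)
    return(data.frame(chrom = character(), bin = integer(),
                      stringsAsFactors = FALSE))
  unknown <- setdiff(regions$chrom, layout$chrom)
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  first <- floor(regions$start / bin_size) + 1L
  last <- floor((regions$end - 1) / bin_size) + 1L
  n <- last - first + 1L
  chrom <- rep(regions$chrom, n)
  bin <- unlist(lapply(seq_len(nrow(regions)),
                       function(i) seq.int(first[i], last[i])),
                use.names = FALSE)
  # clip to the number of bins actually present on each chromosome
  nb <- ceiling(layout$length[chrom] / bin_size)
  keep <- bin >= 1L & bin <= nb
  out <- unique(data.frame(chrom = chrom[keep], bin = as.integer(bin[keep]),
                           stringsAsFactors = FALSE))
  out <- out[order(match(out$chrom, layout$chrom), out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}
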