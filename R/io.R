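#' Read BED3/BED4 intervals
#'
#' Coordinates are kept 0-based half-open as in the file. A fourth column, if
#' present, becomes the `label`.
#'
#' @param path file path.
#' @param layout optional [genome_layout()] for validation.
#' @return data.frame chrom/start/end (and label).
#' @export
read_bed <- function(path, layout = NULL) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "label",
                                         "score", "strand")[1:count_fields(path)],
                           fill = TRUE)
  genomic_intervals(tab$chrom, tab$start, tab$end,
                    label = if ("label" %in% names(tab)) tab$label,
                    layout = layout)
}

count_fields <- function(path) {
  max(utils::count.fields(path, sep = "\t"))
}

#' Write intervals as BED
#'
#' @param intervals data.frame chrom/start/end, optional label.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "label"), names(intervals))
  tab <- intervals[cols]
  tab$start <- format(tab$start, scientific = FALSE, trim = TRUE)
  tab$end <- format(tab$end, scientific = FALSE, trim = TRUE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fixed-width bedGraph into a binned track
#'
#' Every record must span exactly one bin of the stated width (the last bin
#' of a chromosome may be shorter); ragged intervals are an error. Bins not
#' present in the file are missing (`NA`).
#'
#' @param path file path.
#' @param layout a [genome_layout()].
#' @param bin_size expected bin width in bp.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, layout, bin_size) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "value"))
  unknown <- setdiff(tab$chrom, layout$chrom)
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  exp_end <- pmin(tab$start + bin_size, layout$length[tab$chrom])
  if (any(tab$start %% bin_size != 0) || any(tab$end != exp_end))
    stop("ragged intervals: file is not a fixed ", bin_size, "-bp bedGraph")
  track <- binned_track(layout, bin_size, fill = NA_real_)
  for (ch in unique(tab$chrom)) {
    sel <- tab$chrom == ch
    track$values[[ch]][tab$start[sel] / bin_size + 1L] <- tab$value[sel]
  }
  track
}

#' Write a binned track as bedGraph
#'
#' Missing bins are omitted from the file.
#'
#' @param track a [binned_track()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- track_frame(track)
  df <- df[!is.na(df$value), , drop = FALSE]
  start <- (df$bin - 1) * track$bin_size
  end <- pmin(df$bin * track$bin_size, track$layout$length[df$chrom])
  tab <- data.frame(chrom = df$chrom,
                    start = format(start, scientific = FALSE, trim = TRUE),
                    end = format(end, scientific = FALSE, trim = TRUE),
                    value = format(df$value, digits = 15, trim = TRUE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' @param path file path (gzip supported); format guessed from the
#'   extension.
#' @return Named character vector of uppercase sequences.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, format = "fasta")
  invisible(path)
}
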