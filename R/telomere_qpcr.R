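#' Count telomeric reads by consecutive-motif matching
#'
#' A read is telomeric iff it contains `k` or more consecutive exact copies
#' of the telomere repeat TTAGGG or of its reverse complement CCCTAA as a
#' contiguous substring. No mismatches are tolerated.
#'
#' @param reads character vector of ACGTN sequences (or a FASTA/FASTQ path,
#'   read via [read_sequences()]).
#' @param k minimum number of consecutive motif copies (default 7).
#' @return An object of class `telomere_content`: list with
#'   `telomeric_read_count`, `total_reads`, `method = "motif_count"`.
#' @export
count_telomeric_reads <- function(reads, k = 7) {
  if (length(reads) == 1 && !grepl("[ACGTN]{10}", reads) && file.exists(reads))
    reads <- read_sequences(reads)
  fwd <- strrep("TTAGGG", k)
  rev <- strrep("CCCTAA", k)
  hit <- grepl(fwd, reads, fixed = TRUE) | grepl(rev, reads, fixed = TRUE)
  structure(list(telomeric_read_count = sum(hit),
                 total_reads = length(reads),
                 method = "motif_count"),
            class = "telomere_content")
}

#' GC-normalized telomere content
#'
#' Telomere content per million reads of comparable base composition:
#' `telomeric_read_count / (# reads with GC fraction in gc_window) * 1e6`.
#' GC fraction is (G+C) over the non-N read length.
#'
#' @param reads character vector of ACGTN sequences.
#' @param gc_window inclusive GC-fraction window (default c(0.48, 0.52),
#'   bracketing the ~50% GC of the TTAGGG repeat).
#' @param k minimum consecutive motif copies (default 7).
#' @return An object of class `telomere_content` with
#'   `content_per_million`, `gc_window_read_count`, and the motif-count
#'   fields; `method = "gc_normalized"`.
#' @export
gc_normalized_content <- function(reads, gc_window = c(0.48, 0.52), k = 7) {
  base <- count_telomeric_reads(reads, k = k)
  gc <- gc_fraction(reads)
  in_window <- sum(!is.na(gc) & gc >= gc_window[1] & gc <= gc_window[2])
  if (in_window == 0) stop("no reads fall in the GC window")
  structure(list(telomeric_read_count = base$telomeric_read_count,
                 total_reads = base$total_reads,
                 gc_window_read_count = in_window,
                 content_per_million =
                   base$telomeric_read_count / in_window * 1e6,
                 method = "gc_normalized"),
            class = "telomere_content")
}

gc_fraction <- function(reads) {
  n_gc <- nchar(gsub("[^GC]", "", reads))
  n_valid <- nchar(gsub("[^ACGT]", "", reads))
  ifelse(n_valid > 0, n_gc / n_valid, NA_real_)
}

#' @export
print.telomere_content <- function(x, ...) {
  cat("telomere_content (", x$method, "):", x$telomeric_read_count, "of",
      x$total_reads, "reads telomeric")
  if (!is.null(x$content_per_million))
    cat(";", signif(x$content_per_million, 5), "per million GC-matched reads")
  cat("\n")
  invisible(x)
}

# mean / SEM per (target, group) cell of a Cq panel
cq_cell <- function(panel, target, group, group_col) {
  v <- panel$cq[panel$target == target & panel[[group_col]] == group]
  if (length(v) == 0) stop("missing Cq cell: ", target, " / ", group)
  list(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
}

#' Relative telomere content by qPCR (delta-delta-Cq)
#'
#' `dCq_s = mean Cq(telo, s) - mean Cq(control, s)`;
#' `ddCq = dCq_test - dCq_ref`; fold change `FC = 2^(-ddCq)`. Standard
#' errors propagate assuming independent cells:
#' `SE(ddCq) = sqrt(sum of the four SEM^2)` and, by the delta method,
#' `SE(FC) = FC * ln(2) * SE(ddCq)`.
#'
#' @param panel data.frame with columns target, sample, replicate, cq.
#' @param test_sample,ref_sample sample labels to compare.
#' @param telo_target,control_target target labels (defaults "telo",
#'   "36B4").
#' @return list with fold_change, se, ddcq, ddcq_se.
#' @export
qpcr_telomere_ratio <- function(panel, test_sample, ref_sample,
                                telo_target = "telo",
                                control_target = "36B4") {
  cells <- list(
    tt = cq_cell(panel, telo_target, test_sample, "sample"),
    ct = cq_cell(panel, control_target, test_sample, "sample"),
    tr = cq_cell(panel, telo_target, ref_sample, "sample"),
    cr = cq_cell(panel, control_target, ref_sample, "sample"))
  ddcq <- (cells$tt$mean - cells$ct$mean) - (cells$tr$mean - cells$cr$mean)
  ddcq_se <- sqrt(sum(vapply(cells, function(c) c$sem^2, numeric(1))))
  fc <- 2^(-ddcq)
  list(fold_change = fc, se = fc * log(2) * ddcq_se,
       ddcq = ddcq, ddcq_se = ddcq_se)
}

#' Percent inhibition of amplification by UV lesions
#'
#' UV photoproducts block the polymerase, delaying amplification of a
#' lesion-containing target relative to a control locus. With
#' `D_c = mean Cq(control, c) - mean Cq(target, c)` for conditions
#' c in \{-UV, +UV\} and `X = D_-UV - D_+UV`, percent inhibition is
#' `(1 - 2^(-X)) * 100`, so X = 1 gives 50% and X = 2 gives 75%. The SE of
#' X is the quadrature sum of the four cell SEMs; the delta method gives
#' `SE(inhibition) = 100 * ln(2) * 2^(-X) * SE(X)`.
#'
#' @param panel data.frame with columns target, condition, replicate, cq;
#'   conditions labeled `"-UV"` and `"+UV"`.
#' @param target target locus label (e.g. "TERT").
#' @param control control locus label (default "GAPDH").
#' @return list with percent_inhibition, se, X, X_se.
#' @export
percent_inhibition <- function(panel, target, control = "GAPDH") {
  cells <- list(
    cm = cq_cell(panel, control, "-UV", "condition"),
    tm = cq_cell(panel, target, "-UV", "condition"),
    cp = cq_cell(panel, control, "+UV", "condition"),
    tp = cq_cell(panel, target, "+UV", "condition"))
  X <- (cells$cm$mean - cells$tm$mean) - (cells$cp$mean - cells$tp$mean)
  X_se <- sqrt(sum(vapply(cells, function(c) c$sem^2, numeric(1))))
  inh <- (1 - 2^(-X)) * 100
  list(percent_inhibition = inh,
       se = 100 * log(2) * 2^(-X) * X_se,
       X = X, X_se = X_se)
}

#' Read a Cq table
#'
#' TSV with header; requires `target`, `cq`, and a grouping column
#' (`sample` or `condition`) plus `replicate`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_cq_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("target", "cq") %in% names(tab)))
    stop("Cq table needs 'target' and 'cq' columns")
  if (any(tab$cq <= 0)) stop("Cq values must be positive")
  tab
}
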