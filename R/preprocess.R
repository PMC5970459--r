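#' Trim the 3' sequencing adapter from reads
#'
#' Finds, for each read, the leftmost position at which a prefix of the
#' adapter of length at least `min_overlap` matches the read exactly to the
#' end of the read (a full internal adapter occurrence therefore also
#' matches), and truncates the read and its quality string there.  Reads
#' with no such match are returned unchanged; inserts longer than the
#' maximum miRNA length are removed later by [length_filter()].
#'
#' Matching is exact by default; `max_mismatch = 1` tolerates one mismatch
#' in the overlap.
#'
#' @param read_seq Character vector of read sequences.
#' @param read_quals Character vector of Phred+33 quality strings, same
#'   lengths as `read_seq`, or `NULL`.
#' @param adapter_seq Adapter sequence (DNA, non-empty).
#' @param min_overlap Minimum read/adapter overlap to trigger trimming
#'   (default 8).
#' @param max_mismatch Mismatches tolerated in the overlap (default 0).
#' @return A list with character vectors `seq` and `quals`.
#' @export
trim_adapter <- function(read_seq, read_quals = NULL, adapter_seq,
                         min_overlap = 8L, max_mismatch = 0L) {
  stopifnot(nzchar(adapter_seq), min_overlap >= 1L)
  if (!is.null(read_quals) &&
      any(nchar(read_quals) != nchar(read_seq))) {
    stop("quality string length differs from sequence length")
  }
  # identical reads are trimmed once
  uniq <- unique(read_seq)
  cut <- vapply(uniq, adapter_cut_pos, integer(1L),
                adapter = adapter_seq, min_overlap = as.integer(min_overlap),
                max_mismatch = as.integer(max_mismatch))
  cut_all <- cut[match(read_seq, uniq)]
  keep_len <- ifelse(cut_all < 0L, nchar(read_seq), cut_all)
  list(seq = substr(read_seq, 1L, keep_len),
       quals = if (is.null(read_quals)) NULL else
         substr(read_quals, 1L, keep_len))
}

# 0-based cut position (number of bases kept), or -1 when no adapter found.
adapter_cut_pos <- function(read, adapter, min_overlap, max_mismatch = 0L) {
  L <- nchar(read)
  A <- nchar(adapter)
  if (L < min_overlap) return(-1L)
  rb <- utf8ToInt(read)
  ab <- utf8ToInt(adapter)
  for (p in seq_len(L - min_overlap + 1L)) {
    k <- min(L - p + 1L, A)
    if (k < min_overlap) break
    mism <- sum(rb[p:(p + k - 1L)] != ab[seq_len(k)])
    if (mism <= max_mismatch) return(p - 1L)
  }
  -1L
}

#' Collapse trimmed reads into unique sequences with per-sample counts
#'
#' Aggregates identical sequences within and across samples into one record
#' per unique sequence.  A (sequence, sample) pair is quality-flagged when
#' no supporting read in that sample has all base qualities at or above
#' `qmin`; the flag feeds [quality_filter()].  Reads containing N are
#' discarded (sequence identity is the primary key and N would fragment
#' counts).
#'
#' @param reads_by_sample Named list (names are sample IDs); each element a
#'   list or data.frame with elements `seq` and `quals` (quals may be NULL).
#' @param qmin Minimum per-base Phred quality for a read to count as
#'   high-quality support (default 30).
#' @return An object of class `casmir_collapsed`: a list with `seq`
#'   (character), `counts` (integer matrix, sequences x samples), `lowq`
#'   (logical matrix, same shape) and `sample_totals` (named integer vector
#'   of trimmed reads passing collapse per sample).
#' @export
collapse_reads <- function(reads_by_sample, qmin = 30L) {
  samples <- names(reads_by_sample)
  if (is.null(samples) || any(!nzchar(samples))) {
    stop("reads_by_sample must be a named list of samples")
  }
  per_sample <- lapply(samples, function(sm) {
    rs <- reads_by_sample[[sm]]
    sq <- rs$seq
    ql <- rs$quals
    if (length(sq) == 0L) {
      warning("sample '", sm, "' has no reads")
      return(data.frame(seq = character(), n = integer(),
                        hq = logical(), stringsAsFactors = FALSE))
    }
    keep <- !grepl("[^ACGT]", sq) & nzchar(sq)
    sq <- sq[keep]
    if (!is.null(ql)) ql <- ql[keep]
    hq_read <- if (is.null(ql)) rep(TRUE, length(sq)) else
      read_min_qual(ql) >= qmin
    agg <- tapply(hq_read, sq, function(x) c(length(x), any(x)))
    sqs <- names(agg)
    mat <- do.call(rbind, agg)
    data.frame(seq = sqs, n = as.integer(mat[, 1L]),
               hq = as.logical(mat[, 2L]), stringsAsFactors = FALSE)
  })
  names(per_sample) <- samples
  all_seq <- sort(unique(unlist(lapply(per_sample, `[[`, "seq"))))
  counts <- matrix(0L, nrow = length(all_seq), ncol = length(samples),
                   dimnames = list(all_seq, samples))
  lowq <- matrix(FALSE, nrow = length(all_seq), ncol = length(samples),
                 dimnames = list(all_seq, samples))
  for (sm in samples) {
    ps <- per_sample[[sm]]
    if (nrow(ps) == 0L) next
    idx <- match(ps$seq, all_seq)
    counts[idx, sm] <- ps$n
    lowq[idx, sm] <- !ps$hq
  }
  structure(list(seq = all_seq, counts = counts, lowq = lowq,
                 sample_totals = colSums(counts)),
            class = "casmir_collapsed")
}

# minimum Phred+33 quality per quality string, vectorized over unique strings
read_min_qual <- function(quals) {
  uniq <- unique(quals)
  mn <- vapply(uniq, function(q) min(utf8ToInt(q)) - 33L, integer(1L))
  mn[match(quals, uniq)]
}

#' @export
print.casmir_collapsed <- function(x, ...) {
  cat("Collapsed small RNA sequences\n")
  cat(sprintf("  %d unique sequences x %d samples\n",
              length(x$seq), ncol(x$counts)))
  cat(sprintf("  reads per sample: %s\n",
              paste(sprintf("%s=%d", names(x$sample_totals),
                            x$sample_totals), collapse = ", ")))
  invisible(x)
}

#' Read, trim and collapse FASTQ files for a sample sheet
#'
#' Convenience wrapper: reads each sample's FASTQ (optionally gzipped,
#' Phred+33), trims the adapter with [trim_adapter()] and collapses with
#' [collapse_reads()].
#'
#' @param sample_sheet Data.frame with columns `sample_id`, `group`,
#'   `fastq`.
#' @param adapter_seq Adapter sequence; `NULL` skips trimming.
#' @inheritParams trim_adapter
#' @inheritParams collapse_reads
#' @return A `casmir_collapsed` object; the sample sheet with a
#'   `total_trimmed_reads` column is attached as attribute `"sample_sheet"`.
#' @export
collapse_fastq <- function(sample_sheet, adapter_seq = NULL,
                           min_overlap = 8L, qmin = 30L) {
  stopifnot(all(c("sample_id", "group", "fastq") %in% names(sample_sheet)))
  reads <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    fq <- suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(sample_sheet$fastq[i]))
    r <- list(seq = as.character(fq),
              quals = as.character(Biostrings::quality(fq)))
    if (!is.null(adapter_seq)) {
      r <- trim_adapter(r$seq, r$quals, adapter_seq, min_overlap)
    }
    r
  })
  names(reads) <- sample_sheet$sample_id
  col <- collapse_reads(reads, qmin = qmin)
  ss <- sample_sheet
  ss$total_trimmed_reads <- as.integer(col$sample_totals[ss$sample_id])
  attr(col, "sample_sheet") <- ss
  col
}

#' Remove sequences that are low-quality in too many samples
#'
#' Drops any unique sequence whose low-quality flag (no supporting read in
#' the sample entirely at or above Q30, see [collapse_reads()]) is set in
#' strictly more than `max_lowq_samples` samples.  This removes variants
#' that originate from sequencing artifacts rather than biology.
#'
#' @param collapsed A `casmir_collapsed` object.
#' @param max_lowq_samples Threshold; an integer count, or a fraction in
#'   (0, 1) interpreted relative to the number of samples (the count
#'   default of 10 was calibrated to an 81-sample study).
#' @return The filtered `casmir_collapsed`; number of rows removed attached
#'   as attribute `"n_removed"`.
#' @export
quality_filter <- function(collapsed, max_lowq_samples = 10) {
  thr <- max_lowq_samples
  if (thr > 0 && thr < 1) thr <- thr * ncol(collapsed$counts)
  nlow <- rowSums(collapsed$lowq)
  keep <- nlow <= thr
  out <- subset_collapsed(collapsed, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Keep sequences within the typical mature miRNA size range
#'
#' Inclusive length filter, default 17--25 nt.
#'
#' @param collapsed A `casmir_collapsed` object.
#' @param min_len,max_len Inclusive bounds.
#' @return The filtered `casmir_collapsed`; rows removed in attribute
#'   `"n_removed"`.
#' @export
length_filter <- function(collapsed, min_len = 17L, max_len = 25L) {
  stopifnot(min_len <= max_len)
  len <- nchar(collapsed$seq)
  keep <- len >= min_len & len <= max_len
  out <- subset_collapsed(collapsed, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

subset_collapsed <- function(collapsed, keep) {
  structure(list(seq = collapsed$seq[keep],
                 counts = collapsed$counts[keep, , drop = FALSE],
                 lowq = collapsed$lowq[keep, , drop = FALSE],
                 sample_totals = collapsed$sample_totals),
            class = "casmir_collapsed")
}
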