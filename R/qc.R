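# Read-level quality control.
#
# Three rules, applied in order to every read:
#   1. reads with more than `n_max` N/wildcard bases are discarded;
#   2. the read is scanned 5'->3' with a sliding window of `window` bases and
#      truncated at the first base of the first window whose mean quality is
#      strictly below `min_avg_q` (that base and everything 3' of it is
#      removed);
#   3. reads shorter than `min_len` bases after truncation are discarded.
#
# Window means are compared via integer sums (sum < min_avg_q * window), so
# there is no floating-point ambiguity at the boundary.

#' Quality-filter a single read
#'
#' @param bases nucleotide string over `A,C,G,T,N`.
#' @param quals integer vector of per-base quality scores, same length as
#'   `bases`.
#' @param n_max maximum tolerated count of `N` bases (default 2; more are
#'   discarded).
#' @param window sliding-window width in bases (default 5).
#' @param min_avg_q minimum window mean quality (default 20); a window mean
#'   strictly below this triggers truncation at the window's first base.
#' @param min_len minimum surviving read length (default 35).
#' @return a list with elements `status` (one of `"kept"`, `"truncated"`,
#'   `"discarded_n"`, `"discarded_short"`), `bases` and `quals` (`NULL` when
#'   discarded). Reads shorter than `window` pass the window scan untruncated.
#' @examples
#' qc_filter(strrep("A", 40), rep(40L, 40))$status
#' @export
qc_filter <- function(bases, quals, n_max = 2L, window = 5L,
                      min_avg_q = 20, min_len = 35L) {
  stopifnot(is.character(bases), length(bases) == 1L,
            nchar(bases) == length(quals), all(quals >= 0))
  n <- nchar(bases)
  # rule 1: N count
  n_count <- n - nchar(gsub("N", "", bases, fixed = TRUE))
  if (n_count > n_max) {
    return(list(status = "discarded_n", bases = NULL, quals = NULL))
  }
  # rule 2: sliding-window truncation
  keep_len <- n
  truncated <- FALSE
  if (n >= window) {
    cs <- c(0, cumsum(as.numeric(quals)))
    wsum <- cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]
    bad <- which(wsum < min_avg_q * window)
    if (length(bad)) {
      keep_len <- bad[1L] - 1L
      truncated <- TRUE
    }
  }
  # rule 3: minimum length
  if (keep_len < min_len) {
    return(list(status = "discarded_short", bases = NULL, quals = NULL))
  }
  list(
    status = if (truncated) "truncated" else "kept",
    bases = substr(bases, 1L, keep_len),
    quals = quals[seq_len(keep_len)]
  )
}

#' Quality-filter a table of reads
#'
#' Applies [qc_filter()] to every row of a reads table (as returned by
#' [read_fastq()]).
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (phred+33).
#' @inheritParams qc_filter
#' @return a list with `reads` (the surviving reads table, truncated in
#'   place) and `tally`, a data.frame of per-status counts.
#' @export
qc_filter_reads <- function(reads, n_max = 2L, window = 5L,
                            min_avg_q = 20, min_len = 35L) {
  status <- character(nrow(reads))
  out_seq <- character(nrow(reads))
  out_qual <- character(nrow(reads))
  quals <- phred_to_int(reads$qual)
  for (i in seq_len(nrow(reads))) {
    r <- qc_filter(reads$seq[i], quals[[i]], n_max = n_max, window = window,
                   min_avg_q = min_avg_q, min_len = min_len)
    status[i] <- r$status
    if (!startsWith(r$status, "discarded")) {
      out_seq[i] <- r$bases
      out_qual[i] <- int_to_phred(r$quals)
    }
  }
  keep <- !startsWith(status, "discarded")
  tally <- as.data.frame(table(
    status = factor(status, levels = c("kept", "truncated", "discarded_n",
                                       "discarded_short"))
  ), stringsAsFactors = FALSE)
  names(tally) <- c("status", "n")
  list(
    reads = data.frame(id = reads$id[keep], seq = out_seq[keep],
                       qual = out_qual[keep], stringsAsFactors = FALSE),
    tally = tally
  )
}

#' Quality-filter a FASTQ file
#'
#' File-level wrapper around [qc_filter_reads()]: reads `in_path`, writes the
#' surviving (possibly truncated) reads to `out_path` and a per-status tally
#' to `tally_path`.
#'
#' @param in_path input FASTQ.
#' @param out_path output FASTQ of kept/truncated reads.
#' @param tally_path optional TSV path for the status tally.
#' @inheritParams qc_filter
#' @return the tally data.frame, invisibly.
#' @export
qc_filter_fastq <- function(in_path, out_path, tally_path = NULL,
                            n_max = 2L, window = 5L, min_avg_q = 20,
                            min_len = 35L) {
  reads <- read_fastq(in_path)
  res <- qc_filter_reads(reads, n_max = n_max, window = window,
                         min_avg_q = min_avg_q, min_len = min_len)
  write_fastq(res$reads, out_path)
  if (!is.null(tally_path)) write_tsv(res$tally, tally_path)
  invisible(res$tally)
}
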