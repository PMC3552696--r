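# Read counting and RPKM quantification.
#
# A read counts for a feature when any of its aligned blocks overlaps the
# feature's exonic bases on the same strand; each read counts at most once
# per feature (reads ambiguous between features count for both). RPKM is
# raw_count / (exonic_kb) / (mapped_millions).

#' Count reads per feature and sample
#'
#' @param blocks `GRanges` of aligned read blocks with `read_id` and
#'   `sample_id` metadata columns ([alignment_blocks()]).
#' @param features named `GRangesList` of exon models (single-interval
#'   features are length-1 elements).
#' @param samples character vector of sample ids defining the column order
#'   (default: sorted unique sample ids in `blocks`).
#' @param stranded count only same-strand reads (default `TRUE`); features
#'   with strand `*` accept both.
#' @return integer matrix features x samples of distinct-read counts.
#' @export
count_reads <- function(blocks, features, samples = NULL, stranded = TRUE) {
  if (is.null(samples)) samples <- sort(unique(blocks$sample_id))
  fx <- unlist(features, use.names = FALSE)
  fid <- rep(seq_along(features), lengths(features))
  hits <- GenomicRanges::findOverlaps(fx, blocks, ignore.strand = !stranded)
  q <- fid[S4Vectors::queryHits(hits)]
  s <- S4Vectors::subjectHits(hits)
  keep <- !duplicated(paste(q, blocks$sample_id[s], blocks$read_id[s],
                            sep = "\r"))
  counts <- matrix(0L, nrow = length(features), ncol = length(samples),
                   dimnames = list(names(features), samples))
  if (any(keep)) {
    tab <- table(factor(q[keep], levels = seq_along(features)),
                 factor(blocks$sample_id[s][keep], levels = samples))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' @param raw_count read count (vector or matrix).
#' @param exonic_length feature exonic length in bp (recycled over rows when
#'   `raw_count` is a matrix).
#' @param total_mapped total mapped reads of the library (recycled over
#'   columns when `raw_count` is a matrix).
#' @return RPKM values, same shape as `raw_count`.
#' @export
rpkm <- function(raw_count, exonic_length, total_mapped) {
  stopifnot(all(exonic_length > 0), all(total_mapped > 0))
  if (is.matrix(raw_count)) {
    sweep(sweep(raw_count, 1, exonic_length / 1000, "/"),
          2, total_mapped / 1e6, "/")
  } else {
    raw_count / (exonic_length / 1000) / (total_mapped / 1e6)
  }
}

#' Natural-log reads per million
#'
#' The miRNA abundance covariate of the repression model. Undefined (NA) for
#' zero counts.
#'
#' @param raw_count read count (vector or matrix).
#' @param total_mapped total mapped reads (recycled over columns for a
#'   matrix).
#' @return `ln(raw_count / total_mapped * 1e6)`, `NA` where `raw_count` is 0.
#' @export
ln_rpm <- function(raw_count, total_mapped) {
  x <- if (is.matrix(raw_count)) {
    log(sweep(raw_count, 2, total_mapped, "/") * 1e6)
  } else {
    log(raw_count / total_mapped * 1e6)
  }
  x[!is.finite(x)] <- NA_real_
  x
}

#' Expression-detectability filter
#'
#' Keeps features expressed above `min_rpkm` RPKM in strictly more than
#' `min_samples` samples. With the defaults (0.5 RPKM, more than 15 of 20
#' samples) a feature above threshold in exactly 15 samples is removed and
#' one above it in 16 is kept.
#'
#' @param rpkm_mat RPKM matrix, features x samples.
#' @param min_rpkm RPKM threshold (strict `>`, default 0.5).
#' @param min_samples sample-count threshold (strict `>`, default 15).
#' @return logical vector over rows: `TRUE` for detectable features.
#' @export
detectability_filter <- function(rpkm_mat, min_rpkm = 0.5, min_samples = 15L) {
  rowSums(rpkm_mat > min_rpkm) > min_samples
}
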