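# Truth-table evaluation of pipeline stages.
#
# The generator's truth tables are sufficient to score every downstream
# stage: exact recovery of planted exon structures, recall of planted seed
# sites, and sensitivity/false-discovery of reverse-correlation calls.

#' Exact-recovery rate of planted multi-exon transcripts
#'
#' A planted transcript is recovered when some assembled transcript has
#' exactly its exon coordinates (all starts and ends equal).
#'
#' @param transcripts assembled `GRangesList` ([assemble_transcripts()]).
#' @param truth generator truth ([simulate_genome()]).
#' @return list with `recovered`, `total` (planted multi-exon transcripts)
#'   and `rate`.
#' @export
evaluate_assembly <- function(transcripts, truth) {
  sig <- vapply(seq_along(transcripts), function(i) {
    ex <- transcripts[[i]]
    paste(GenomicRanges::start(ex), GenomicRanges::end(ex),
          sep = "-", collapse = ",")
  }, "")
  tt <- truth$tx_tab
  planted <- split(tt, tt$lincrna_id)
  multi <- Filter(function(d) nrow(d) > 1L, planted)
  hit <- vapply(multi, function(d) {
    d <- d[order(d$start), ]
    paste(d$start, d$end, sep = "-", collapse = ",") %in% sig
  }, logical(1))
  list(recovered = sum(hit), total = length(multi),
       rate = if (length(multi)) mean(hit) else NA_real_)
}

#' Recall of planted 8mer seed sites
#'
#' A planted site is recalled when a predicted 8mer for the same miRNA
#' covers the same genomic positions.
#'
#' @param sites predicted site table (with `mirna_id`, `site_type`,
#'   `genomic_blocks`).
#' @param truth generator truth.
#' @return list with `recalled`, `total`, `rate`.
#' @export
evaluate_sites <- function(sites, truth) {
  ts <- truth$sites
  pred8 <- sites[sites$site_type == "8mer", , drop = FALSE]
  pred_start <- vapply(strsplit(pred8$genomic_blocks, "[,-]"), function(x) {
    min(as.numeric(x))
  }, numeric(1))
  hit <- vapply(seq_len(nrow(ts)), function(i) {
    any(pred8$mirna_id == ts$mirna_id[i] &
          abs(pred_start - ts$gstart[i]) < 0.5)
  }, logical(1))
  list(recalled = sum(hit), total = nrow(ts), rate = mean(hit))
}

#' Sensitivity and empirical FDR of reverse-correlation calls
#'
#' Maps assembled transcript ids back to planted lincRNAs by exact genomic
#' overlap and scores the pair calls against the planted-pair truth.
#'
#' @param pair_calls output of [call_pairs()] (pipeline naming:
#'   `target_id` is the assembled transcript id).
#' @param transcripts assembled `GRangesList`.
#' @param truth generator truth.
#' @return list with `sensitivity` (planted pairs called), `fdr` (called
#'   pairs that are not planted), `n_called`, `n_planted`.
#' @export
evaluate_pairs <- function(pair_calls, transcripts, truth) {
  tt <- truth$tx_tab
  linc_of_tx <- vapply(seq_along(transcripts), function(i) {
    ex <- transcripts[[i]]
    ov <- tt$lincrna_id[tt$start <= GenomicRanges::end(ex)[1] &
                          tt$end >= GenomicRanges::start(ex)[1]]
    if (length(ov)) ov[1] else NA_character_
  }, "")
  names(linc_of_tx) <- names(transcripts)
  planted <- truth$pairs[truth$pairs$planted, ]
  planted_key <- paste(planted$mirna_id, planted$lincrna_id)
  call_key <- paste(pair_calls$mirna_id, linc_of_tx[pair_calls$target_id])
  called <- pair_calls$reverse_correlated
  n_called <- sum(called)
  tp <- sum(called & call_key %in% planted_key)
  list(
    sensitivity = tp / nrow(planted),
    fdr = if (n_called) (n_called - tp) / n_called else 0,
    n_called = n_called, n_planted = nrow(planted)
  )
}
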