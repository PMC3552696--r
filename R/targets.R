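# miRNA seed-match prediction on spliced lincRNA sequences.
#
# Because the whole mature transcript of a noncoding RNA is untranslated,
# sites are predicted over the entire spliced sequence. Site classes follow
# the TargetScan convention, keyed to the miRNA seed (positions 2-7 of the
# mature miRNA, extended seed 2-8):
#   7mer-m8: transcript carries the reverse complement of miRNA positions
#            2-8;
#   7mer-A1: transcript carries the reverse complement of positions 2-7
#            followed by an A;
#   8mer:    both conditions hold.
# Each occurrence is reported once under its most specific class.

#' Load mature miRNA sequences from FASTA
#'
#' @param path FASTA of mature miRNA sequences (RNA or DNA alphabet;
#'   miRBase-style headers accepted, id = first whitespace-separated token).
#' @return data.frame `id`, `mature_seq` (RNA, uppercase).
#' @export
read_mirnas <- function(path) {
  x <- Biostrings::readBStringSet(path)
  data.frame(
    id = vapply(strsplit(names(x), "\\s+"), `[`, "", 1L),
    mature_seq = chartr("Tt", "Uu", toupper(as.character(x))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# seed heptamers as DNA, 5'->3' on the target
seed_site_patterns <- function(mature_seq) {
  dna <- chartr("U", "T", toupper(mature_seq))
  if (nchar(dna) < 8L) stop("mature miRNA must be at least 8 nt")
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))
  )
  list(
    m8 = rc(substr(dna, 2L, 8L)),                 # 7 nt
    a1 = paste0(rc(substr(dna, 2L, 7L)), "A")     # 6 nt + A
  )
}

find_all <- function(text, pattern) {
  hits <- gregexpr(pattern, text, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Predict miRNA seed-match sites on a spliced transcript sequence
#'
#' @param tx_seq spliced transcript sequence, sense strand, DNA alphabet.
#' @param mirnas data.frame `id`, `mature_seq` (see [read_mirnas()]); U/T
#'   are interchangeable.
#' @param lincrna_id transcript id recorded in the output.
#' @param exons optional `GRanges` of the transcript's exons (sorted by
#'   coordinate); when given, together with `strand`, each site is
#'   back-projected to genomic blocks.
#' @param strand transcript strand (`"+"` or `"-"`), used for
#'   back-projection.
#' @return data.frame with one row per site: `mirna_id`, `lincrna_id`,
#'   `site_type` (`8mer`, `7mer-m8`, `7mer-A1`), `transcript_pos` (1-based
#'   start on the spliced sequence), `site_length`, and, when `exons` is
#'   supplied, `chrom`, `genomic_blocks` (comma-separated `start-end` pairs)
#'   and `strand`. Transcripts shorter than 8 nt yield no sites.
#' @export
predict_seed_matches <- function(tx_seq, mirnas, lincrna_id = "lincRNA",
                                 exons = NULL, strand = "+") {
  tx_seq <- chartr("Uu", "Tt", toupper(tx_seq))
  L <- nchar(tx_seq)
  rows <- list()
  if (L >= 8L) {
    for (i in seq_len(nrow(mirnas))) {
      pat <- seed_site_patterns(mirnas$mature_seq[i])
      p_m8 <- find_all(tx_seq, pat$m8)
      is8 <- if (length(p_m8)) {
        p_m8 + 7L <= L & substring(tx_seq, p_m8 + 7L, p_m8 + 7L) == "A"
      } else logical(0)
      p_a1 <- find_all(tx_seq, pat$a1)
      # an A1 heptamer at q sitting inside an 8mer that starts at q-1 is
      # already reported as the 8mer
      inside_8mer <- p_a1 %in% (p_m8[is8] + 1L)
      p_a1 <- p_a1[!inside_8mer]
      if (length(p_m8) + length(p_a1) == 0L) next
      df <- data.frame(
        mirna_id = mirnas$id[i], lincrna_id = lincrna_id,
        site_type = c(ifelse(is8, "8mer", "7mer-m8"),
                      rep("7mer-A1", length(p_a1))),
        transcript_pos = c(p_m8, p_a1),
        stringsAsFactors = FALSE
      )
      df$site_length <- ifelse(df$site_type == "8mer", 8L, 7L)
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), lincrna_id = character(0),
               site_type = character(0), transcript_pos = integer(0),
               site_length = integer(0))
  out <- out[order(out$mirna_id, out$transcript_pos), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(exons) && nrow(out)) {
    bl <- transcript_to_genomic(out$transcript_pos,
                                out$transcript_pos + out$site_length - 1L,
                                exons, strand)
    out$chrom <- as.character(GenomicRanges::seqnames(exons))[1]
    out$genomic_blocks <- bl
    out$strand <- strand
  }
  out
}

#' Map transcript intervals to genomic blocks
#'
#' Projects 1-based closed intervals on the spliced transcript back through
#' the exon map. On the minus strand, transcript position 1 is the genomic
#' 3' end of the last exon.
#'
#' @param from,to integer vectors of transcript coordinates (1-based,
#'   inclusive).
#' @param exons `GRanges` of exons in genomic coordinate order.
#' @param strand `"+"` or `"-"`.
#' @return character vector: comma-separated `start-end` genomic blocks per
#'   interval, in genomic coordinate order.
#' @export
transcript_to_genomic <- function(from, to, exons, strand = "+") {
  w <- GenomicRanges::width(exons)
  L <- sum(w)
  stopifnot(all(from >= 1L), all(to <= L), all(from <= to))
  offs <- cumsum(c(0L, w[-length(w)])) # transcript offset of each exon (+)
  es <- GenomicRanges::start(exons)
  ee <- GenomicRanges::end(exons)
  map1 <- function(tpos) {
    # genomic position of a single transcript position
    if (strand == "-") tpos <- L - tpos + 1L
    i <- findInterval(tpos, offs + 1L)
    es[i] + (tpos - offs[i] - 1L)
  }
  vapply(seq_along(from), function(k) {
    tp <- from[k]:to[k]
    gp <- sort(vapply(tp, map1, numeric(1)))
    runs <- cumsum(c(1L, diff(gp) != 1L))
    blocks <- vapply(split(gp, runs), function(g) {
      paste0(min(g), "-", max(g))
    }, "")
    paste(blocks, collapse = ",")
  }, "")
}

#' Length-matched control intervals upstream of predicted sites
#'
#' For each predicted site, an interval of the same length starting `offset`
#' bases 5' of the site on the transcript. Sites whose control would fall
#' off the transcript are dropped (and counted in attribute `n_dropped`).
#'
#' @param matches site table from [predict_seed_matches()].
#' @param exons,strand exon map for back-projection (optional, as in
#'   [predict_seed_matches()]).
#' @param offset distance upstream on the transcript (default 100 bp).
#' @return data.frame shaped like `matches` with `transcript_pos` shifted
#'   upstream; attribute `n_dropped` counts discarded sites.
#' @export
upstream_control_sites <- function(matches, exons = NULL, strand = "+",
                                   offset = 100L) {
  pos <- matches$transcript_pos - offset
  keep <- pos >= 1L
  out <- matches[keep, , drop = FALSE]
  out$transcript_pos <- pos[keep]
  if (!is.null(exons) && nrow(out)) {
    out$genomic_blocks <- transcript_to_genomic(
      out$transcript_pos, out$transcript_pos + out$site_length - 1L,
      exons, strand
    )
    out$strand <- strand
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Extract the spliced (sense-strand) sequence of a transcript model
#'
#' @param genome `DNAStringSet`.
#' @param exons `GRanges` of exons in genomic coordinate order (one
#'   chromosome).
#' @param strand `"+"` or `"-"`; minus-strand transcripts return the reverse
#'   complement of the concatenated exon sequence.
#' @return the spliced sequence as a character string, 5'->3'.
#' @export
spliced_sequence <- function(genome, exons, strand = "+") {
  chrom <- as.character(GenomicRanges::seqnames(exons))[1]
  seqs <- vapply(seq_along(exons), function(i) {
    as.character(Biostrings::subseq(genome[[chrom]],
                                    GenomicRanges::start(exons)[i],
                                    GenomicRanges::end(exons)[i]))
  }, "")
  s <- paste(seqs, collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}
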