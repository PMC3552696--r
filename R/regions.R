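# Candidate lincRNA region selection.
#
# Candidate regions carrying the K4-K36 chromatin signature (promoter
# H3K4me3 followed by gene-body H3K36me3) from two sources (native and
# lifted-over from a second species) are merged, stripped of anything near or
# overlapping known genes, then filtered by RNA polymerase II occupancy and
# by codon substitution frequency (CSF) coding potential.

#' Merge candidate regions from two sources and drop those near known genes
#'
#' Overlapping intervals from the two sources are merged into single regions
#' (coordinate union). Any merged region overlapping, or closer than
#' `min_gene_distance` bases to, a known gene is removed. A gap of exactly
#' `min_gene_distance` bases is kept.
#'
#' @param human `GRanges` of native candidate regions.
#' @param mouse_lifted `GRanges` of lifted-over candidate regions (already
#'   projected onto the same assembly).
#' @param known_genes `GRanges` of known gene loci.
#' @param min_gene_distance minimum tolerated gap to the nearest gene, in bp
#'   (default 5000).
#' @return a `GRanges` of candidate regions with a `source` metadata column
#'   (`"human"`, `"mouse_lifted"`, or `"human"` when a region merges both).
#' @export
merge_and_exclude <- function(human, mouse_lifted, known_genes,
                              min_gene_distance = 5000L) {
  stopifnot(methods::is(human, "GRanges"), methods::is(mouse_lifted, "GRanges"),
            methods::is(known_genes, "GRanges"), min_gene_distance >= 0)
  pool <- c(GenomicRanges::granges(human), GenomicRanges::granges(mouse_lifted))
  GenomicRanges::strand(pool) <- "*"
  merged <- GenomicRanges::reduce(pool)
  src <- ifelse(
    GenomicRanges::countOverlaps(merged, human, ignore.strand = TRUE) > 0,
    "human", "mouse_lifted"
  )
  if (length(known_genes)) {
    hits <- GenomicRanges::distanceToNearest(merged, known_genes,
                                             ignore.strand = TRUE)
    too_close <- rep(FALSE, length(merged))
    too_close[S4Vectors::queryHits(hits)] <-
      S4Vectors::mcols(hits)$distance < min_gene_distance
    merged <- merged[!too_close]
    src <- src[!too_close]
  }
  S4Vectors::mcols(merged)$source <- src
  merged
}

#' Filter candidate regions by RNA polymerase II occupancy
#'
#' A ChIP tag is assigned to a region when the tag's 5' position lies inside
#' it (single-point assignment, so no tag is counted twice). Region signal is
#' expressed as RPKM: `tags / (region_kb) / (total_tags / 1e6)`. Regions with
#' RPKM strictly greater than `threshold` are kept; a region at exactly the
#' threshold is removed.
#'
#' @param regions `GRanges` of candidate regions.
#' @param chip_tags `GRanges` of ChIP tag alignments (strand-aware: the 5'
#'   end of a minus-strand tag is its right coordinate).
#' @param total_tags total mapped tag count of the ChIP library (> 0).
#' @param threshold RPKM cutoff (default 0.1, strict).
#' @return the surviving regions with an added `rpolii_rpkm` metadata column.
#' @export
rpolii_filter <- function(regions, chip_tags, total_tags, threshold = 0.1) {
  if (total_tags <= 0) stop("total_tags must be positive")
  pts <- GenomicRanges::resize(chip_tags, width = 1L, fix = "start")
  counts <- GenomicRanges::countOverlaps(regions, pts, ignore.strand = TRUE)
  rpkm_val <- rpkm(counts, GenomicRanges::width(regions), total_tags)
  S4Vectors::mcols(regions)$rpolii_rpkm <- rpkm_val
  regions[rpkm_val > threshold]
}

#' Build a synthetic CSF log-odds matrix
#'
#' A 64 x 65 log-odds table over (reference codon, aligned codon-or-gap)
#' pairs: identical codon pairs score `match`, substituted pairs `mismatch`,
#' and alignment gaps `gap`. A trained mammalian CSF model has richer
#' structure, but only the lookup semantics matter to [csf_score()].
#'
#' @param match log-odds for an identical codon pair (default 1).
#' @param mismatch log-odds for a substituted codon pair (default -1).
#' @param gap log-odds for a gapped codon (default -1).
#' @return a numeric matrix with codon rownames and codon-plus-`"---"`
#'   colnames.
#' @export
make_csf_matrix <- function(match = 1, mismatch = -1, gap = -1) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  m <- matrix(mismatch, nrow = 64, ncol = 65,
              dimnames = list(codons, c(codons, "---")))
  diag(m[, codons]) <- match
  m[, "---"] <- gap
  m
}

# Score one reading-frame orientation of an alignment: ref/alt are equal
# length, ref gap columns already removed. Returns the max window sum over
# the three codon offsets, or -Inf if no full window fits.
csf_frame_max <- function(ref, alt, csf_matrix, window_codons) {
  L <- nchar(ref)
  best <- -Inf
  for (off in 0:2) {
    n_cod <- (L - off) %/% 3L
    if (n_cod < 1L) next
    starts <- off + 3L * (seq_len(n_cod) - 1L) + 1L
    rc <- substring(ref, starts, starts + 2L)
    ac <- substring(alt, starts, starts + 2L)
    ac[grepl("-", ac, fixed = TRUE)] <- "---"
    sc <- rep(0, n_cod)
    ok <- rc %in% rownames(csf_matrix) & ac %in% colnames(csf_matrix)
    sc[ok] <- csf_matrix[cbind(rc[ok], ac[ok])]
    w <- min(window_codons, n_cod) # frames shorter than the window use the
    cs <- c(0, cumsum(sc))         # single maximal in-frame stretch
    wins <- cs[(w + 1L):(n_cod + 1L)] - cs[1:(n_cod - w + 1L)]
    best <- max(best, wins)
  }
  best
}

#' CSF coding-potential score of an aligned region
#'
#' Slides a `window`-base (30-codon) window in 3-base steps across all six
#' reading frames (three codon offsets on each strand) of a codon-resolved
#' alignment; each window scores the sum of `csf_matrix[ref_codon,
#' aligned_codon]` over its codon columns. The region score is the maximum
#' over all windows and frames. Regions shorter than `window` are scored over
#' the single maximal in-frame stretch and flagged with attribute `short`.
#'
#' @param alignment character vector of two or more aligned sequences (equal
#'   length, `-` for gaps); element `ref_row` is the reference.
#' @param csf_matrix log-odds lookup, see [make_csf_matrix()]. Codons absent
#'   from the table (e.g. containing `N`) contribute 0.
#' @param window window width in bases (default 90 = 30 codons).
#' @param ref_row index of the reference row (default 1).
#' @return the maximum window score (numeric scalar); attribute `short` is
#'   `TRUE` when the region could not fit a full window.
#' @export
csf_score <- function(alignment, csf_matrix, window = 90L, ref_row = 1L) {
  stopifnot(length(alignment) >= 2L, window %% 3L == 0L)
  if (length(unique(nchar(alignment))) != 1L) {
    stop("alignment rows must have equal length")
  }
  ref <- toupper(alignment[[ref_row]])
  alts <- toupper(alignment[-ref_row])
  # project onto reference coordinates: drop ref-gap columns
  keep <- which(strsplit(ref, "")[[1]] != "-")
  proj <- function(s) paste(strsplit(s, "")[[1]][keep], collapse = "")
  ref <- proj(ref)
  alts <- vapply(alts, proj, "")
  wc <- window %/% 3L
  best <- -Inf
  for (alt in alts) {
    best <- max(best,
                csf_frame_max(ref, alt, csf_matrix, wc),
                csf_frame_max(revcomp_gapped(ref), revcomp_gapped(alt),
                              csf_matrix, wc))
  }
  if (!is.finite(best)) best <- 0
  attr(best, "short") <- nchar(ref) < window
  best
}

# reverse complement preserving gap characters
revcomp_gapped <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

#' Filter candidate regions by CSF score
#'
#' Regions with `csf_score` strictly greater than `cutoff` are excluded (they
#' likely encode unannotated protein-coding genes); a region at exactly the
#' cutoff is kept.
#'
#' @param regions `GRanges` with a numeric `csf_score` metadata column.
#' @param cutoff exclusion threshold (default 20, strict `>`).
#' @return the surviving regions.
#' @export
csf_filter <- function(regions, cutoff = 20) {
  sc <- S4Vectors::mcols(regions)$csf_score
  if (is.null(sc)) stop("regions must carry a csf_score metadata column")
  regions[sc <= cutoff]
}
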