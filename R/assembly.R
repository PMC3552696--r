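# Transcript assembly inside candidate regions.
#
# Putative exons are maximal read-covered intervals (merged across gaps
# shorter than 10 bp, supported by at least 8 distinct reads). Splice donor
# and acceptor motifs (GT-AG on the Watson strand, CT-AC on the Crick
# strand, both read off the reference) are searched within 25 bp of the exon
# ends; all compatible donor/acceptor pairs within the allowed intron-length
# range form a junction sequence library against which genome-unmapped reads
# are matched. Supported junctions connect exons into transcripts: each
# connected component of the exon/junction graph yields one transcript, a
# declared simplification of full statistical segmentation whose recovery is
# measured against simulated truth.

#' Convert a blocks table to a GRanges of aligned blocks
#'
#' @param aln blocks table (`read_id`, `sample_id`, `chrom`, `start`, `end`,
#'   `strand`), as from [read_bed12()].
#' @return `GRanges` with `read_id` and `sample_id` metadata columns.
#' @export
alignment_blocks <- function(aln) {
  GenomicRanges::GRanges(
    aln$chrom, IRanges::IRanges(aln$start, aln$end), strand = aln$strand,
    read_id = aln$read_id, sample_id = aln$sample_id
  )
}

#' Call putative exons from read coverage
#'
#' Maximal intervals of nonzero coverage inside `region` are formed from the
#' aligned blocks of reads overlapping the region; intervals separated by a
#' gap of fewer than `merge_gap` bases are merged (to a fixpoint); merged
#' intervals supported by at least `min_reads` distinct reads (a read counts
#' if any of its blocks overlaps the interval) are returned.
#'
#' @param blocks `GRanges` of aligned blocks with a `read_id` metadata
#'   column (see [alignment_blocks()]); read ids must be unique per read.
#' @param region `GRanges` of length 1: the candidate region.
#' @param min_reads minimum distinct supporting reads per exon (default 8).
#' @param merge_gap gaps strictly smaller than this many bases are merged
#'   (default 10).
#' @return `GRanges` of putative exons with a `support` metadata column,
#'   empty when no interval reaches `min_reads`.
#' @export
call_putative_exons <- function(blocks, region, min_reads = 8L,
                                merge_gap = 10L) {
  stopifnot(length(region) == 1L)
  in_region <- blocks[
    S4Vectors::subjectHits(GenomicRanges::findOverlaps(region, blocks,
                                                       ignore.strand = TRUE))
  ]
  empty <- GenomicRanges::GRanges(support = integer(0))
  if (length(in_region) == 0L) return(empty)
  islands <- GenomicRanges::reduce(in_region, min.gapwidth = merge_gap,
                                   ignore.strand = TRUE)
  GenomicRanges::strand(islands) <- "*"
  hits <- GenomicRanges::findOverlaps(islands, in_region, ignore.strand = TRUE)
  pair <- unique(data.frame(
    exon = S4Vectors::queryHits(hits),
    read = in_region$read_id[S4Vectors::subjectHits(hits)]
  ))
  support <- tabulate(pair$exon, nbins = length(islands))
  islands$support <- support
  islands[support >= min_reads]
}

#' Find candidate splice donor/acceptor sites near putative exon ends
#'
#' Donor candidates are positions `d` with reference dinucleotide
#' `genome[d, d+1]` equal to `GT` (Watson-strand intron) or `CT`
#' (Crick-strand intron) within `search` bases of an exon's 3' (right)
#' boundary; acceptor candidates are positions `a` whose preceding
#' dinucleotide `genome[a-1, a]` is `AG` or `AC` within `search` bases of an
#' exon's 5' (left) boundary. `d` is the first intronic base and `a` the
#' last; strand is implied by the motif.
#'
#' @param genome `DNAStringSet` of reference sequences.
#' @param exons `GRanges` of putative exons.
#' @param search search radius around the natural intron boundary (default
#'   25 bp).
#' @return a list of two data.frames, `donors` (`exon`, `chrom`, `pos`,
#'   `motif`, `strand`) and `acceptors` (same columns); `exon` indexes into
#'   `exons`.
#' @export
find_splice_sites <- function(genome, exons, search = 25L) {
  donors <- list()
  acceptors <- list()
  for (i in seq_along(exons)) {
    chrom <- as.character(GenomicRanges::seqnames(exons)[i])
    chrom_seq <- genome[[chrom]]
    clen <- length(chrom_seq)
    # donors: first intronic base d in [end+1-search, end+1+search]
    dc <- scan_dinuc(chrom_seq, GenomicRanges::end(exons)[i] + 1L, search,
                     c(GT = "+", CT = "-"), offset = 0L, clen = clen)
    if (nrow(dc)) donors[[length(donors) + 1L]] <-
        cbind(exon = i, chrom = chrom, dc)
    # acceptors: last intronic base a in [start-1-search, start-1+search],
    # dinucleotide at [a-1, a]
    ac <- scan_dinuc(chrom_seq, GenomicRanges::start(exons)[i] - 1L, search,
                     c(AG = "+", AC = "-"), offset = -1L, clen = clen)
    if (nrow(ac)) acceptors[[length(acceptors) + 1L]] <-
        cbind(exon = i, chrom = chrom, ac)
  }
  bind <- function(l) {
    if (length(l)) do.call(rbind, l) else
      data.frame(exon = integer(0), chrom = character(0), pos = integer(0),
                 motif = character(0), strand = character(0))
  }
  list(donors = bind(donors), acceptors = bind(acceptors))
}

# scan for dinucleotide motifs around a center position; `offset` is where
# the motif starts relative to the reported position (0 for donors, -1 for
# acceptors). `motifs` is a named vector motif -> strand.
scan_dinuc <- function(chrom_seq, center, search, motifs, offset, clen) {
  pos <- (center - search):(center + search)
  pos <- pos[pos + offset >= 1L & pos + offset + 1L <= clen]
  if (!length(pos)) {
    return(data.frame(pos = integer(0), motif = character(0),
                      strand = character(0)))
  }
  dinuc <- vapply(pos, function(p) {
    as.character(Biostrings::subseq(chrom_seq, p + offset, p + offset + 1L))
  }, "")
  hit <- dinuc %in% names(motifs)
  data.frame(pos = pos[hit], motif = dinuc[hit],
             strand = unname(motifs[dinuc[hit]]),
             stringsAsFactors = FALSE)
}

#' Build a splice-junction sequence library
#'
#' Every motif-compatible (donor, acceptor) pair on the same chromosome with
#' an intron length (`acceptor - donor + 1`) between `min_intron` and
#' `max_span` bases yields one library entry: `flank` exonic bases upstream
#' of the donor concatenated with `flank` bases downstream of the acceptor.
#' GT donors pair with AG acceptors (plus strand), CT with AC (minus
#' strand). Entries whose flanks hit a contig end are clipped and flagged.
#'
#' @param donors,acceptors data.frames from [find_splice_sites()].
#' @param genome `DNAStringSet`.
#' @param flank exonic flank length per side; the conventional choice is
#'   `read_length - 1` so any junction-spanning read fits in an entry.
#' @param max_span maximum intron length in bases (default 100000).
#' @param min_intron minimum intron length in bases (default 70).
#' @return data.frame with one row per junction: `junction_id`, `chrom`,
#'   `donor`, `acceptor`, `strand`, `motif`, `donor_exon`, `acceptor_exon`,
#'   `seq`, `flank_left`, `flank_right`, `clipped`.
#' @export
build_junction_library <- function(donors, acceptors, genome, flank,
                                   max_span = 100000L, min_intron = 70L) {
  out <- list()
  if (nrow(donors) && nrow(acceptors)) {
    idx <- expand.grid(d = seq_len(nrow(donors)), a = seq_len(nrow(acceptors)))
    d <- donors[idx$d, ]
    a <- acceptors[idx$a, ]
    intron <- a$pos - d$pos + 1L
    ok <- d$chrom == a$chrom & d$strand == a$strand &
      intron >= min_intron & intron <= max_span
    d <- d[ok, ]
    a <- a[ok, ]
    for (k in seq_len(nrow(d))) {
      chrom_seq <- genome[[d$chrom[k]]]
      clen <- length(chrom_seq)
      l_from <- max(1L, d$pos[k] - flank)
      l_to <- d$pos[k] - 1L
      r_from <- a$pos[k] + 1L
      r_to <- min(clen, a$pos[k] + flank)
      if (l_to < l_from || r_from > r_to) next # no exonic sequence at all
      left <- as.character(Biostrings::subseq(chrom_seq, l_from, l_to))
      right <- as.character(Biostrings::subseq(chrom_seq, r_from, r_to))
      # entries are stored in transcript orientation so strand-specific
      # reads match directly: on the minus strand the spliced transcript
      # reads revcomp(right) then revcomp(left)
      if (d$strand[k] == "-") {
        entry_seq <- revcomp_chr(paste0(left, right))
        fl <- nchar(right); fr <- nchar(left)
      } else {
        entry_seq <- paste0(left, right)
        fl <- nchar(left); fr <- nchar(right)
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = d$chrom[k], donor = d$pos[k], acceptor = a$pos[k],
        strand = d$strand[k],
        motif = paste0(d$motif[k], "-", a$motif[k]),
        donor_exon = d$exon[k], acceptor_exon = a$exon[k],
        seq = entry_seq,
        flank_left = fl, flank_right = fr,
        clipped = nchar(left) < flank || nchar(right) < flank,
        stringsAsFactors = FALSE
      )
    }
  }
  lib <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), donor = integer(0), acceptor = integer(0),
               strand = character(0), motif = character(0),
               donor_exon = integer(0), acceptor_exon = integer(0),
               seq = character(0), flank_left = integer(0),
               flank_right = integer(0), clipped = logical(0))
  lib <- unique(lib)
  if (nrow(lib)) lib <- cbind(junction_id = sprintf("jx%05d", seq_len(nrow(lib))), lib)
  else lib <- cbind(junction_id = character(0), lib)
  rownames(lib) <- NULL
  lib
}

#' Match unmapped reads against a junction library
#'
#' A read supports a junction when it matches a library entry ungapped with
#' at most `max_mismatch` mismatches while overhanging the junction point by
#' at least `anchor` bases on both sides. Each read is assigned to at most
#' one junction: the one with the fewest mismatches; reads tied between
#' different junctions are dropped.
#'
#' Exact (0-mismatch) matches are resolved through a hash of all
#' anchor-compatible library windows; only reads without an exact match fall
#' back to the exhaustive mismatch scan.
#'
#' @param reads character vector of read sequences (DNA, sense strand of the
#'   library entries).
#' @param library junction library from [build_junction_library()].
#' @param anchor minimum overhang on each side of the junction point
#'   (default 8).
#' @param max_mismatch maximum tolerated mismatches (default 2).
#' @return a list with `support` (data.frame `junction_id`, `support`) and
#'   `assignment` (per-read junction id or `NA`).
#' @export
match_junction_reads <- function(reads, library, anchor = 8L,
                                 max_mismatch = 2L) {
  n_jx <- nrow(library)
  assignment <- rep(NA_character_, length(reads))
  if (n_jx && length(reads)) {
    rl <- nchar(reads)
    # enumerate anchor-compatible windows per entry for each read length
    for (len in unique(rl)) {
      ridx <- which(rl == len)
      keys_l <- vector("list", n_jx)
      jx_l <- vector("list", n_jx)
      for (j in seq_len(n_jx)) {
        off <- valid_offsets(library$flank_left[j], library$flank_right[j],
                             len, anchor)
        if (!length(off)) next
        keys_l[[j]] <- substring(library$seq[j], off, off + len - 1L)
        jx_l[[j]] <- rep(library$junction_id[j], length(off))
      }
      keys <- unlist(keys_l, use.names = FALSE)
      key_jx <- unlist(jx_l, use.names = FALSE)
      if (!length(keys)) next
      # exact pass: a window shared by several junctions is a tie -> drop
      jx_of <- tapply(key_jx, keys, function(x) {
        ux <- unique(x)
        if (length(ux) == 1L) ux else NA_character_
      })
      hit <- match(reads[ridx], names(jx_of))
      exact <- !is.na(hit)
      assignment[ridx[exact]] <- unname(jx_of[hit[exact]])
      todo <- ridx[!exact]
      if (!length(todo) || max_mismatch < 1L) next
      # inexact pass, pigeonhole prefilter: with <= max_mismatch mismatches
      # over (max_mismatch + 1) disjoint chunks, at least one chunk matches
      # exactly at its aligned position
      n_chunk <- max_mismatch + 1L
      cw <- len %/% n_chunk
      cand_idx <- lapply(seq_len(n_chunk), function(c) {
        split(seq_along(keys), substr(keys, (c - 1L) * cw + 1L, c * cw))
      })
      for (i in todo) {
        cand <- integer(0)
        for (c in seq_len(n_chunk)) {
          hit_k <- cand_idx[[c]][[substr(reads[i], (c - 1L) * cw + 1L,
                                         c * cw)]]
          if (!is.null(hit_k)) cand <- c(cand, hit_k)
        }
        cand <- unique(cand)
        if (!length(cand)) next
        rv <- utf8ToInt(reads[i])
        mm <- vapply(keys[cand], function(k) sum(utf8ToInt(k) != rv),
                     numeric(1), USE.NAMES = FALSE)
        mm_best <- min(mm)
        if (mm_best > max_mismatch) next
        best_jx <- unique(key_jx[cand[mm == mm_best]])
        if (length(best_jx) == 1L) assignment[i] <- best_jx
      }
    }
  }
  support <- data.frame(
    junction_id = library$junction_id,
    support = as.integer(table(factor(assignment,
                                      levels = library$junction_id))),
    stringsAsFactors = FALSE
  )
  list(support = support, assignment = assignment)
}

# offsets (1-based start in entry) at which a read of length len overhangs
# the junction point by >= anchor on both sides
valid_offsets <- function(flank_left, flank_right, len, anchor) {
  lo <- max(1L, flank_left + anchor - len + 1L)
  hi <- min(flank_left - anchor + 1L, flank_left + flank_right - len + 1L)
  if (hi < lo) integer(0) else lo:hi
}

#' Assemble transcript models from exons and supported junctions
#'
#' Exons are nodes and supported junctions are edges; each connected
#' component becomes one transcript whose exons are the component's exons in
#' coordinate order. Exon boundaries are refined to the junction boundaries
#' (the donor's exon ends at `donor - 1`, the acceptor's exon starts at
#' `acceptor + 1`; when several supported junctions refine the same exon
#' side the best-supported one wins). Transcript strand comes from the
#' junction motifs; single-exon components are emitted with strand `*`.
#'
#' @param exons `GRanges` of putative exons (from [call_putative_exons()],
#'   possibly concatenated over regions).
#' @param junctions junction library rows with a `support` column merged in;
#'   only rows with `support > 0` are used.
#' @return a `GRangesList`, one element per transcript (exons sorted,
#'   non-overlapping); metadata columns `spliced_length` and `n_exons`.
#' @export
assemble_transcripts <- function(exons, junctions) {
  n <- length(exons)
  if (n == 0L) {
    grl <- GenomicRanges::GRangesList()
    S4Vectors::mcols(grl)$spliced_length <- integer(0)
    S4Vectors::mcols(grl)$n_exons <- integer(0)
    return(grl)
  }
  jx <- junctions[!is.na(junctions$support) & junctions$support > 0L, ,
                  drop = FALSE]
  jx <- jx[jx$donor_exon != jx$acceptor_exon, , drop = FALSE]
  # union-find over exon indices
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(jx))) {
    a <- find(jx$donor_exon[k])
    b <- find(jx$acceptor_exon[k])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(n), find, integer(1))
  # boundary refinement, best-supported junction wins per exon side
  starts <- GenomicRanges::start(exons)
  ends <- GenomicRanges::end(exons)
  if (nrow(jx)) {
    jx <- jx[order(-jx$support), , drop = FALSE]
    done_end <- logical(n)
    done_start <- logical(n)
    for (k in seq_len(nrow(jx))) {
      de <- jx$donor_exon[k]
      ae <- jx$acceptor_exon[k]
      if (!done_end[de]) {
        ends[de] <- jx$donor[k] - 1L
        done_end[de] <- TRUE
      }
      if (!done_start[ae]) {
        starts[ae] <- jx$acceptor[k] + 1L
        done_start[ae] <- TRUE
      }
    }
  }
  out <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    idx <- idx[order(starts[idx])]
    ok <- starts[idx] <= ends[idx]
    idx <- idx[ok]
    if (!length(idx)) next
    st <- "*"
    if (nrow(jx)) {
      js <- jx$strand[comp[jx$donor_exon] == cid]
      if (length(js)) st <- names(sort(table(js), decreasing = TRUE))[1]
    }
    gr <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(exons)[idx[1]]),
      IRanges::IRanges(starts[idx], ends[idx]), strand = st
    )
    gr <- GenomicRanges::reduce(gr) # guard: refinement must not overlap
    out[[length(out) + 1L]] <- gr
  }
  grl <- GenomicRanges::GRangesList(out)
  names(grl) <- sprintf("tx%04d", seq_along(grl))
  S4Vectors::mcols(grl)$spliced_length <-
    vapply(out, function(g) sum(GenomicRanges::width(g)), numeric(1))
  S4Vectors::mcols(grl)$n_exons <- lengths(out)
  grl
}
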