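# Exon calling, splice-site search, junction library, junction-read
# matching and transcript assembly.

region1k <- GRanges("chr1", IRanges(1, 5000))

mk_blocks <- function(starts, ends, ids = NULL, strand = "+") {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(starts))
  alignment_blocks(data.frame(
    read_id = ids, sample_id = "s01", chrom = "chr1",
    start = starts, end = ends, strand = strand
  ))
}

test_that("putative exons need 8 distinct reads and merge sub-10bp gaps", {
  # 8 identical reads -> one exon
  b <- mk_blocks(rep(100, 8), rep(135, 8))
  ex <- call_putative_exons(b, region1k)
  expect_equal(length(ex), 1L)
  expect_equal(c(start(ex), end(ex)), c(100, 135))
  expect_equal(ex$support, 8L)
  # 7 reads -> nothing
  expect_equal(length(call_putative_exons(b[1:7], region1k)), 0L)
  # two pileups separated by a 4-base gap merge into one exon
  b2 <- mk_blocks(c(rep(100, 8), rep(140, 8)), c(rep(135, 8), rep(175, 8)),
                  ids = sprintf("r%03d", 1:16))
  ex2 <- call_putative_exons(b2, region1k)
  expect_equal(length(ex2), 1L)
  expect_equal(c(start(ex2), end(ex2)), c(100, 175))
  expect_equal(ex2$support, 16L)
  # gap of exactly merge_gap stays split
  b3 <- mk_blocks(c(rep(100, 8), rep(146, 8)), c(rep(135, 8), rep(175, 8)),
                  ids = sprintf("r%03d", 1:16))
  expect_equal(length(call_putative_exons(b3, region1k)), 2L)
  # empty input
  expect_equal(length(call_putative_exons(b[0], region1k)), 0L)
})

test_that("exon calling matches the brute-force coverage oracle", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(10:60, 1)
    st <- sample(1:900, n, replace = TRUE)
    en <- st + sample(20:50, n, replace = TRUE)
    ids <- sprintf("r%03d", sample(n)) # unique ids, shuffled order
    got <- call_putative_exons(mk_blocks(st, en, ids),
                               GRanges("chr1", IRanges(1, 1000)),
                               min_reads = 4L)
    want <- oracle_exons(st, en, ids, 1L, 1000L, min_reads = 4L)
    if (is.null(want)) {
      expect_equal(length(got), 0L)
    } else {
      expect_equal(start(got), want[, 1])
      expect_equal(end(got), want[, 2])
      expect_equal(got$support, want[, 3])
    }
  }
})

test_that("gap merging is order-independent (unique fixpoint)", {
  set.seed(22)
  st <- sample(1:500, 30, TRUE)
  en <- st + sample(20:40, 30, TRUE)
  ids <- sprintf("r%02d", 1:30)
  reg <- GRanges("chr1", IRanges(1, 600))
  a <- call_putative_exons(mk_blocks(st, en, ids), reg, min_reads = 1L)
  o <- sample(30)
  b <- call_putative_exons(mk_blocks(st[o], en[o], ids[o]), reg,
                           min_reads = 1L)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("splice-site search finds motifs near exon boundaries", {
  set.seed(23)
  gs <- paste(sample(c("A", "C"), 400, TRUE), collapse = "") # no G/T noise
  substr(gs, 101, 102) <- "GT"
  substr(gs, 203, 204) <- "AG"
  g <- DNAStringSet(c(chr1 = gs))
  exl <- GRanges("chr1", IRanges(50, 100)) # donor expected at end+1 = 101
  ss <- find_splice_sites(g, exl)
  expect_true(any(ss$donors$pos == 101 & ss$donors$motif == "GT"))
  exr <- GRanges("chr1", IRanges(205, 250)) # acceptor at start-1 = 204
  ss2 <- find_splice_sites(g, exr)
  expect_true(any(ss2$acceptors$pos == 204 & ss2$acceptors$motif == "AG"))
  # no motif in range -> empty
  g0 <- DNAStringSet(c(chr1 = strrep("A", 400)))
  ss0 <- find_splice_sites(g0, exl)
  expect_equal(nrow(ss0$donors), 0L)
  expect_equal(nrow(ss0$acceptors), 0L)
})

test_that("splice-site search equals a brute-force dinucleotide scan", {
  set.seed(24)
  for (i in 1:25) {
    gs <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
    g <- DNAStringSet(c(chr1 = gs))
    ex <- GRanges("chr1", IRanges(sample(100:300, 1), width = 120))
    ss <- find_splice_sites(g, ex, search = 25L)
    # oracle: scan every position of the +-25 windows
    dend <- integer(0)
    for (p in (end(ex) + 1 - 25):(end(ex) + 1 + 25)) {
      if (substr(gs, p, p + 1) %in% c("GT", "CT")) dend <- c(dend, p)
    }
    aend <- integer(0)
    for (p in (start(ex) - 1 - 25):(start(ex) - 1 + 25)) {
      if (substr(gs, p - 1, p) %in% c("AG", "AC")) aend <- c(aend, p)
    }
    expect_equal(sort(ss$donors$pos), sort(dend))
    expect_equal(sort(ss$acceptors$pos), sort(aend))
  }
})

test_that("junction library enumerates compatible pairs with exact bounds", {
  set.seed(25)
  gs <- paste(sample(c("A", "C", "G", "T"), 300000, TRUE), collapse = "")
  g <- DNAStringSet(c(chr1 = gs))
  d <- data.frame(exon = 1L, chrom = "chr1", pos = c(1000L, 1500L),
                  motif = "GT", strand = "+")
  a <- data.frame(exon = 2L, chrom = "chr1",
                  pos = c(2000L, 2500L, 3000L), motif = "AG", strand = "+")
  lib <- build_junction_library(d, a, g, flank = 49L)
  expect_equal(nrow(lib), 6L) # 2 donors x 3 acceptors, all compatible
  # intron length bounds: 69 rejected, 70 accepted
  a69 <- data.frame(exon = 2L, chrom = "chr1", pos = 1000L + 68L,
                    motif = "AG", strand = "+")
  expect_equal(nrow(build_junction_library(d[1, ], a69, g, 49L)), 0L)
  a70 <- data.frame(exon = 2L, chrom = "chr1", pos = 1000L + 69L,
                    motif = "AG", strand = "+")
  expect_equal(nrow(build_junction_library(d[1, ], a70, g, 49L)), 1L)
  # span bounds: 100,000 accepted, 100,001 rejected
  aspan <- data.frame(exon = 2L, chrom = "chr1", pos = 1000L + 100000L - 1L,
                      motif = "AG", strand = "+")
  expect_equal(nrow(build_junction_library(d[1, ], aspan, g, 49L)), 1L)
  aover <- data.frame(exon = 2L, chrom = "chr1", pos = 1000L + 100001L - 1L,
                      motif = "AG", strand = "+")
  expect_equal(nrow(build_junction_library(d[1, ], aover, g, 49L)), 0L)
  # mixed motifs rejected
  amix <- data.frame(exon = 2L, chrom = "chr1", pos = 2000L, motif = "AC",
                     strand = "-")
  expect_equal(nrow(build_junction_library(d[1, ], amix, g, 49L)), 0L)
  # flank clipping at the contig edge is flagged
  d0 <- data.frame(exon = 1L, chrom = "chr1", pos = 30L, motif = "GT",
                   strand = "+")
  a0 <- data.frame(exon = 2L, chrom = "chr1", pos = 130L, motif = "AG",
                   strand = "+")
  lib0 <- build_junction_library(d0, a0, g, flank = 49L)
  expect_true(lib0$clipped)
  expect_equal(lib0$flank_left, 29L)
})

test_that("junction pair counts equal exhaustive enumeration", {
  set.seed(26)
  gs <- paste(sample(c("A", "C", "G", "T"), 250000, TRUE), collapse = "")
  g <- DNAStringSet(c(chr1 = gs))
  for (i in 1:25) {
    nd <- sample(2:6, 1); na <- sample(2:6, 1)
    d <- data.frame(exon = 1L, chrom = "chr1",
                    pos = sample(500:200000, nd),
                    motif = sample(c("GT", "CT"), nd, TRUE),
                    strand = NA)
    d$strand <- ifelse(d$motif == "GT", "+", "-")
    a <- data.frame(exon = 2L, chrom = "chr1",
                    pos = sample(500:200000, na),
                    motif = sample(c("AG", "AC"), na, TRUE),
                    strand = NA)
    a$strand <- ifelse(a$motif == "AG", "+", "-")
    lib <- build_junction_library(d, a, g, flank = 20L)
    expect_equal(nrow(lib), oracle_junction_count(d, a))
  }
})

test_that("junction-read matching honors anchors, mismatches and ties", {
  set.seed(27)
  gs <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  g <- DNAStringSet(c(chr1 = gs))
  d <- data.frame(exon = c(1L, 2L), chrom = "chr1", pos = c(500L, 2500L),
                  motif = "GT", strand = "+")
  a <- data.frame(exon = c(3L, 4L), chrom = "chr1", pos = c(800L, 2800L),
                  motif = "AG", strand = "+")
  lib <- build_junction_library(d, a, g, flank = 49L)
  entry <- lib$seq[1]
  # exact central read
  read <- substr(entry, 49 - 19, 49 + 20) # 40nt, 20 on each side
  mm <- match_junction_reads(read, lib)
  expect_equal(sum(mm$support$support), 1L)
  expect_equal(mm$assignment, lib$junction_id[1])
  # anchor boundary: overhang of anchor-1 on one side is rejected
  read_short <- substr(entry, 49 - 32, 49 + 7) # right overhang 7 < 8
  expect_true(is.na(match_junction_reads(read_short, lib)$assignment))
  # up to two mismatches accepted, three rejected
  mutate_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in k) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  expect_false(is.na(match_junction_reads(mutate_at(read, c(3, 30)),
                                          lib)$assignment))
  expect_true(is.na(match_junction_reads(mutate_at(read, c(3, 18, 30)),
                                         lib)$assignment))
})

test_that("junction matching equals the exhaustive offset scan", {
  set.seed(28)
  gs <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  g <- DNAStringSet(c(chr1 = gs))
  d <- data.frame(exon = 1:3, chrom = "chr1",
                  pos = c(1000L, 5000L, 9000L), motif = "GT", strand = "+")
  a <- data.frame(exon = 4:6, chrom = "chr1",
                  pos = c(1400L, 5400L, 9400L), motif = "AG", strand = "+")
  lib <- build_junction_library(d, a, g, flank = 49L)
  reads <- character(0)
  for (i in 1:60) {
    j <- sample(nrow(lib), 1)
    o <- sample(20:60, 1)
    r <- substr(lib$seq[j], o, o + 39L)
    ch <- strsplit(r, "")[[1]]
    nmut <- sample(0:3, 1)
    if (nmut) {
      at <- sample(40, nmut)
      ch[at] <- sample(c("A", "C", "G", "T"), nmut, TRUE)
    }
    reads <- c(reads, paste(ch, collapse = ""))
  }
  reads <- c(reads, replicate(20, paste(sample(c("A", "C", "G", "T"), 40,
                                               TRUE), collapse = "")))
  got <- match_junction_reads(reads, lib)$assignment
  want <- vapply(reads, oracle_match, "", lib = lib, USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("connected exons assemble into strand-aware transcripts", {
  ex <- GRanges("chr1", IRanges(c(100, 300, 600), c(200, 400, 700)),
                support = 10L)
  jx <- data.frame(
    junction_id = c("j1", "j2"), chrom = "chr1",
    donor = c(206L, 405L), acceptor = c(294L, 594L), strand = "+",
    motif = "GT-AG", donor_exon = c(1L, 2L), acceptor_exon = c(2L, 3L),
    support = c(5L, 7L)
  )
  tx <- assemble_transcripts(ex, jx)
  expect_equal(length(tx), 1L)
  expect_equal(S4Vectors::mcols(tx)$n_exons, 3L)
  # boundaries refined to donor-1 / acceptor+1
  expect_equal(start(tx[[1]]), c(100, 295, 595))
  expect_equal(end(tx[[1]]), c(205, 404, 700))
  expect_equal(as.character(strand(tx[[1]]))[1], "+")
  expect_equal(S4Vectors::mcols(tx)$spliced_length,
               sum(width(tx[[1]])))
  # no junctions -> one single-exon transcript per exon
  tx0 <- assemble_transcripts(ex, jx[0, ])
  expect_equal(length(tx0), 3L)
  expect_true(all(S4Vectors::mcols(tx0)$n_exons == 1L))
  # unsupported junctions do not connect
  jx$support <- 0L
  expect_equal(length(assemble_transcripts(ex, jx)), 3L)
})

test_that("minus-strand junction entries are transcript-oriented", {
  set.seed(29)
  gs <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  substr(gs, 501, 502) <- "CT"
  substr(gs, 799, 800) <- "AC"
  g <- DNAStringSet(c(chr1 = gs))
  d <- data.frame(exon = 1L, chrom = "chr1", pos = 501L, motif = "CT",
                  strand = "-")
  a <- data.frame(exon = 2L, chrom = "chr1", pos = 800L, motif = "AC",
                  strand = "-")
  lib <- build_junction_library(d, a, g, flank = 30L)
  expect_equal(nrow(lib), 1L)
  # the entry must equal the spliced minus-strand transcript context
  rc <- function(s) as.character(reverseComplement(DNAString(s)))
  left_exonic <- substr(gs, 501 - 30, 500)   # genomic left exon suffix
  right_exonic <- substr(gs, 801, 800 + 30)  # genomic right exon prefix
  expect_equal(lib$seq, paste0(rc(right_exonic), rc(left_exonic)))
  # a transcript-sense junction read therefore matches directly
  read <- substr(lib$seq, 16, 45)
  expect_equal(match_junction_reads(read, lib, anchor = 8L)$support$support,
               1L)
})
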