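# Seed-match prediction, site classes, back-projection, upstream controls.

mir1 <- data.frame(id = "m1", mature_seq = "UACGACGUACGACGUACGACGU",
                   stringsAsFactors = FALSE)
# positions 2-8 = ACGACGU -> m8 heptamer ACGTCGT; positions 2-7 = ACGACG ->
# A1 heptamer CGTCGTA

test_that("site classes follow the most-specific-type rule", {
  tx <- paste0(strrep("G", 20), "ACGTCGT", "C", strrep("G", 20))
  m <- predict_seed_matches(tx, mir1)
  expect_equal(nrow(m), 1L)
  expect_equal(m$site_type, "7mer-m8")
  expect_equal(m$transcript_pos, 21L)
  expect_equal(m$site_length, 7L)
  # both conditions -> one 8mer, not also counted as 7mers
  tx8 <- paste0(strrep("G", 20), "ACGTCGTA", strrep("G", 20))
  m8 <- predict_seed_matches(tx8, mir1)
  expect_equal(m8$site_type, "8mer")
  expect_equal(m8$site_length, 8L)
  # A1 heptamer alone
  txa <- paste0(strrep("G", 20), "CGTCGTA", strrep("G", 20))
  ma <- predict_seed_matches(txa, mir1)
  expect_equal(ma$site_type, "7mer-A1")
  # no seed complement -> empty; short transcript -> empty
  expect_equal(nrow(predict_seed_matches(strrep("G", 60), mir1)), 0L)
  expect_equal(nrow(predict_seed_matches("ACGTCGT", mir1)), 0L)
  # U/T interchangeable on the transcript side
  mu <- predict_seed_matches(chartr("T", "U", tx8), mir1)
  expect_equal(mu$site_type, "8mer")
})

test_that("prediction agrees with the naive substring oracle", {
  set.seed(31)
  for (i in 1:60) {
    mat <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
    mir <- data.frame(id = "m", mature_seq = mat)
    # seed the transcript with occasional planted heptamers to get hits
    tx <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    if (i %% 2 == 0) {
      pat <- lincmir:::seed_site_patterns(mat)
      at <- sample(50:250, 2)
      substr(tx, at[1], at[1] + 6) <- pat$m8
      substr(tx, at[2], at[2] + 6) <- pat$a1
    }
    got <- predict_seed_matches(tx, mir)
    want <- oracle_seed_matches(tx, mat)
    got <- got[order(got$transcript_pos, got$site_type), ]
    expect_equal(got$transcript_pos, want$transcript_pos)
    expect_equal(got$site_type, want$site_type)
  }
})

test_that("minus-strand sites back-project to reverse-complement blocks", {
  set.seed(32)
  gs <- paste(sample(c("A", "C"), 600, TRUE), collapse = "")
  exons <- GRanges("chr1", IRanges(c(101, 301), c(200, 400)))
  rc <- function(s) as.character(reverseComplement(DNAString(s)))
  # plant an m8 site crossing the junction of the minus-strand transcript:
  # transcript positions 97-103 map to genomic 198-200 (exon 1 suffix) and
  # 301-304 (exon 2 prefix), in reversed order
  pat <- lincmir:::seed_site_patterns(mir1$mature_seq)
  site <- paste0(pat$m8, "G") # m8 heptamer, no A at position 8
  genomic_site <- rc(site)    # reference-strand spelling, left to right
  substr(gs, 197, 200) <- substr(genomic_site, 1, 4)
  substr(gs, 301, 304) <- substr(genomic_site, 5, 8)
  g <- DNAStringSet(c(chr1 = gs))
  tx <- spliced_sequence(g, exons, "-")
  expect_equal(substr(tx, 97, 104), site)
  m <- predict_seed_matches(tx, mir1, exons = exons, strand = "-")
  m <- m[m$site_type == "7mer-m8" & m$transcript_pos == 97L, ]
  expect_equal(nrow(m), 1L)
  blocks <- strsplit(m$genomic_blocks, ",")[[1]]
  expect_equal(blocks, c("198-200", "301-304")) # crosses the junction
  # reference sequence of the blocks is the reverse complement of the site
  genomic <- paste0(substr(gs, 198, 200), substr(gs, 301, 304))
  expect_equal(rc(genomic), substr(tx, 97, 103))
})

test_that("round trip transcript -> genome -> sequence is consistent", {
  set.seed(33)
  gs <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  g <- DNAStringSet(c(chr1 = gs))
  exons <- GRanges("chr1", IRanges(c(101, 301, 601), c(200, 400, 650)))
  for (strand in c("+", "-")) {
    tx <- spliced_sequence(g, exons, strand)
    expect_equal(nchar(tx), 250L)
    for (k in 1:10) {
      from <- sample(1:240, 1)
      to <- min(250L, from + sample(5:30, 1))
      bl <- transcript_to_genomic(from, to, exons, strand)
      parts <- strsplit(bl, ",")[[1]]
      seqs <- vapply(parts, function(b) {
        se <- as.integer(strsplit(b, "-")[[1]])
        substr(gs, se[1], se[2])
      }, "")
      genomic <- paste(seqs, collapse = "")
      if (strand == "-") {
        genomic <- as.character(reverseComplement(DNAString(genomic)))
      }
      expect_equal(genomic, substr(tx, from, to))
    }
  }
})

test_that("upstream controls are length-matched, 100bp 5', or dropped", {
  m <- data.frame(mirna_id = "m1", lincrna_id = "t1",
                  site_type = c("7mer-m8", "8mer"),
                  transcript_pos = c(150L, 50L),
                  site_length = c(7L, 8L), stringsAsFactors = FALSE)
  ctrl <- upstream_control_sites(m)
  expect_equal(nrow(ctrl), 1L)
  expect_equal(ctrl$transcript_pos, 50L)
  expect_equal(ctrl$site_length, 7L)
  expect_equal(attr(ctrl, "n_dropped"), 1L)
  expect_true(nrow(ctrl) <= nrow(m))
  # boundary: position 101 maps to 1 and survives; 100 is dropped
  m2 <- m[1, ]; m2$transcript_pos <- 101L
  expect_equal(upstream_control_sites(m2)$transcript_pos, 1L)
  m3 <- m[1, ]; m3$transcript_pos <- 100L
  expect_equal(nrow(upstream_control_sites(m3)), 0L)
})

test_that("planted sites on simulated transcripts are all recovered", {
  cfg <- small_sim_config(seed = 5)
  truth <- simulate_genome(cfg)
  # scan each true transcript's spliced sequence directly
  hits <- 0L
  for (i in seq_len(nrow(truth$sites))) {
    s <- truth$sites[i, ]
    exdf <- truth$tx_tab[truth$tx_tab$lincrna_id == s$lincrna_id, ]
    exons <- GRanges(truth$chrom, IRanges(exdf$start, exdf$end))
    tx <- spliced_sequence(truth$genome, exons, exdf$strand[1])
    m <- predict_seed_matches(tx, truth$mirnas[
      truth$mirnas$id == s$mirna_id, , drop = FALSE])
    if (any(m$site_type == "8mer" & m$transcript_pos == s$transcript_pos)) {
      hits <- hits + 1L
    }
  }
  expect_equal(hits, nrow(truth$sites))
})
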