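# The synthetic-data generator: configuration validation, determinism,
# truth-table structure, count law, read emission, alignment simulation.

test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_normal = 1L, n_tumor = 1L), "4 samples")
  expect_error(sim_config(dispersion = 0.5), "dispersion")
  expect_error(sim_config(omega_conserved = 1.5), "omega_conserved")
  expect_error(sim_config(n_true_lincrnas = 60L), "exceeds")
  expect_error(sim_config(n_planted_pairs = 40L, n_true_lincrnas = 15L),
               "n_planted_pairs")
  # genome too small for the layout
  cfg_small <- sim_config(genome_length = 60000L)
  expect_error(simulate_genome(cfg_small), "sizing error")
})

test_that("truth tables mark region classes exactly as configured", {
  cfg <- sim_config(seed = 8, genome_length = 300000L,
                    n_candidate_regions = 10L, n_true_lincrnas = 3L,
                    n_near_gene_regions = 3L, n_coding_regions = 2L,
                    n_known_genes = 4L, n_mirnas = 4L, n_planted_pairs = 2L,
                    mean_depth = 5000L)
  truth <- simulate_genome(cfg)
  expect_equal(sum(truth$regions$class == "near_gene"), 3L)
  expect_equal(sum(truth$regions$class == "lincrna"), 3L)
  expect_equal(sum(truth$regions$class == "coding_like"), 2L)
  expect_equal(nrow(truth$regions), 10L)
  # planted pairs and sites reference existing lincRNAs and miRNAs
  expect_true(all(truth$pairs$mirna_id %in% truth$mirnas$id))
  expect_true(all(truth$pairs$lincrna_id %in% truth$tx_tab$lincrna_id))
  expect_equal(sum(truth$pairs$planted), 2L)
  # planted splice motifs are present in the genome
  for (lid in unique(truth$tx_tab$lincrna_id)) {
    exdf <- truth$tx_tab[truth$tx_tab$lincrna_id == lid, ]
    if (nrow(exdf) < 2) next
    gseq <- as.character(truth$genome[[truth$chrom]])
    for (k in seq_len(nrow(exdf) - 1L)) {
      intron <- substr(gseq, exdf$end[k] + 1L, exdf$start[k + 1L] - 1L)
      if (exdf$strand[1] == "+") {
        expect_equal(substr(intron, 1, 2), "GT")
        expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
      } else {
        expect_equal(substr(intron, 1, 2), "CT")
        expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AC")
      }
    }
  }
})

test_that("identical configurations give byte-identical files", {
  cfg <- small_sim_config(seed = 4)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  files <- list.files(d1)
  expect_true(length(files) > 10)
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "det3")
  simulate_dataset(small_sim_config(seed = 5), dir = d3)
  expect_false(identical(readBin(file.path(d1, "genome.fa"), "raw", 1e7),
                         readBin(file.path(d3, "genome.fa"), "raw", 1e7)))
})

test_that("counts follow the planted mean/variance structure", {
  cfg <- sim_config(seed = 21, dispersion = 2)
  truth <- simulate_genome(cfg)
  cm <- simulate_counts(cfg, truth)
  # overdispersion: pooled Pearson-type ratio near phi for flat features
  fi <- cm$feature_info
  flat <- fi$feature_id[fi$kind == "lincrna" &
                          !fi$feature_id %in%
                          truth$pairs$lincrna_id[truth$pairs$planted]]
  M <- cm$sample_sheet$total_target
  ratios <- vapply(flat, function(f) {
    mu <- exp(fi$b0[fi$feature_id == f]) * M
    mean((cm$counts[f, ] - mu)^2 / mu)
  }, numeric(1))
  expect_gt(mean(ratios), 1.2) # clearly overdispersed
  expect_lt(mean(ratios), 3.5) # but consistent with phi = 2
  # a planted pair shows negative dependence on its miRNA
  pl <- truth$pairs[truth$pairs$planted, ][1, ]
  rho <- cor(cm$x1[pl$mirna_id, ], log(cm$counts[pl$lincrna_id, ] + 1),
             method = "spearman")
  expect_lt(rho, 0)
})

test_that("a null coefficient vector breaks the count-miRNA dependence", {
  cfg <- sim_config(seed = 22, beta = c(-4.8, 0, 0, 0))
  truth <- simulate_genome(cfg)
  cm <- simulate_counts(cfg, truth)
  totals <- colSums(cm$counts)
  x1 <- ln_rpm(cm$counts[truth$mirnas$id, , drop = FALSE], totals)
  pl <- truth$pairs[truth$pairs$planted, ]
  b1 <- vapply(seq_len(nrow(pl)), function(i) {
    f <- fit_pair(cm$counts[pl$lincrna_id[i], ], x1[pl$mirna_id[i], ],
                  cm$sample_sheet$condition, totals)
    coef(f)[["b1"]]
  }, numeric(1))
  expect_lt(abs(mean(b1)), 0.1)
})

test_that("negative planted b1 yields negative expression correlation", {
  cfg <- sim_config(seed = 23) # default b1 = -0.8
  truth <- simulate_genome(cfg)
  cm <- simulate_counts(cfg, truth)
  totals <- colSums(cm$counts)
  pl <- truth$pairs[truth$pairs$planted, ]
  rhos <- vapply(seq_len(nrow(pl)), function(i) {
    rpkm_t <- rpkm(cm$counts[pl$lincrna_id[i], ],
                   cm$feature_info$spliced_length[
                     cm$feature_info$feature_id == pl$lincrna_id[i]],
                   totals)
    cor(rpkm_t, cm$x1[pl$mirna_id[i], ], method = "spearman")
  }, numeric(1))
  expect_true(all(rhos < 0))
})

test_that("every true junction is spanned by a well-anchored raw read", {
  cfg <- small_sim_config(seed = 6)
  truth <- simulate_genome(cfg)
  rd <- simulate_reads(cfg, truth)
  for (lid in unique(truth$tx_tab$lincrna_id)) {
    exdf <- truth$tx_tab[truth$tx_tab$lincrna_id == lid, ]
    if (nrow(exdf) < 2L) next
    strand <- exdf$strand[1]
    ord <- if (strand == "+") seq_len(nrow(exdf)) else rev(seq_len(nrow(exdf)))
    w <- exdf$end[ord] - exdf$start[ord] + 1L
    cumw <- cumsum(w)
    ex <- lincmir:::feature_exons(truth, lid, "lincrna")
    tx <- lincmir:::feature_tx_seq(truth$genome[[truth$chrom]], ex)
    own <- rd$unmapped[startsWith(rd$unmapped$id, paste0(lid, "_")), ]
    st <- lincmir:::match_starts(own$seq, tx)
    en <- st + nchar(own$seq) - 1L
    for (jt in cumw[-length(cumw)]) {
      expect_true(any(st <= jt - 7L & en >= jt + 8L))
    }
  }
})

test_that("unmapped junction reads carry the spliced, not genomic, sequence", {
  cfg <- small_sim_config(seed = 7)
  truth <- simulate_genome(cfg)
  rd <- simulate_reads(cfg, truth)
  gseq <- as.character(truth$genome[[truth$chrom]])
  u <- rd$unmapped[!startsWith(rd$unmapped$id, "defect"), ]
  some <- u[sample(nrow(u), 25), ]
  for (i in seq_len(nrow(some))) {
    # junction reads must not be contiguous genomic substrings
    expect_false(grepl(some$seq[i], gseq, fixed = TRUE))
  }
})

test_that("simulated MAF honors the planted conservation structure", {
  cfg <- small_sim_config(seed = 9)
  truth <- simulate_genome(cfg)
  maf <- simulate_maf(cfg, truth)
  # reference row equals the genome
  b <- maf$maf[[1]]
  expect_equal(b$seqs[["hg"]],
               substr(as.character(truth$genome[[truth$chrom]]),
                      b$start, b$start + b$width - 1L))
  # omega_conserved = 0 would freeze planted sites; here just check the
  # estimator ranks planted sites below background on pooled columns
  tree <- maf$tree
  site_cols <- NULL
  for (i in seq_len(nrow(truth$sites))) {
    s <- truth$sites[i, ]
    m <- maf_columns(maf$maf, truth$chrom, s$gstart, s$gend)
    if (s$planted_pair) site_cols <- cbind(site_cols, m)
  }
  om_site <- estimate_omega(site_cols, tree)$omega
  bg <- truth$regions[truth$regions$class == "background", ][1, ]
  om_bg <- estimate_omega(
    maf_columns(maf$maf, truth$chrom, bg$start, bg$end), tree)$omega
  expect_lt(om_site, om_bg)
})

test_that("a zero conserved-site rate freezes planted sites entirely", {
  cfg <- small_sim_config(seed = 10, omega_conserved = 0)
  truth <- simulate_genome(cfg)
  maf <- simulate_maf(cfg, truth)
  for (i in which(truth$sites$planted_pair)) {
    s <- truth$sites[i, ]
    cols <- maf_columns(maf$maf, truth$chrom, s$gstart, s$gend)
    expect_true(all(cols == cols[rep(1, nrow(cols)), ]))
  }
})
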