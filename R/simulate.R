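# Synthetic-data generator.
#
# Produces every input the pipeline consumes -- genome, known-gene and
# candidate-region annotations, strand-specific spliced alignments for a
# 10-normal / 10-tumor design, pre-miRNA counts and mature miRNA sequences,
# ChIP tags, a multi-species alignment with its tree -- with the statistical
# structure the analysis assumes and full truth tables, so every downstream
# stage can be validated against planted ground truth. All randomness flows
# from the single seed in the configuration; identical configurations give
# byte-identical outputs.

#' Simulation configuration
#'
#' Collects and validates every knob of the generator. Defaults describe the
#' reference study conditions: 10 normal + 10 tumor libraries, ~50 candidate
#' regions of which 15 contain a planted multi-exon lincRNA, 10 planted
#' repressed (miRNA, lincRNA) pairs with miRNA coefficient -0.8, and
#' quasi-Poisson dispersion 1.5.
#'
#' @param seed integer RNG seed; every derived stream offsets from it.
#' @param n_normal,n_tumor library counts per condition (default 10 + 10).
#' @param genome_length toy genome size in bp (default 1e6).
#' @param n_known_genes known protein-coding gene loci (default 8).
#' @param n_candidate_regions candidate K4-K36 regions (default 50).
#' @param n_true_lincrnas regions containing a planted multi-exon lincRNA
#'   (default 15).
#' @param n_near_gene_regions regions planted overlapping/near a known gene,
#'   to be removed by the distance filter (default 8; at most
#'   `n_known_genes`).
#' @param n_coding_regions regions given a codon-preserving alignment so the
#'   CSF filter removes them (default 5).
#' @param n_mirnas mature miRNAs (default 10).
#' @param n_planted_pairs repressed (miRNA, lincRNA) pairs wired into the
#'   count model (default 10; at most `n_true_lincrnas`).
#' @param beta GLM coefficients (b0, b1, b2, b3) of the planted pairs;
#'   b0 is a baseline shifted per lincRNA by its abundance (default
#'   `c(-4.8, -0.8, 0.3, 0)`).
#' @param dispersion quasi-Poisson phi >= 1; overdispersion is realized as a
#'   negative binomial with variance `phi * mu` (default 1.5).
#' @param read_length read length in bp (default 50).
#' @param mean_depth mean mapped reads per sample (default 5e4).
#' @param n_species taxa in the multiple alignment, including the reference
#'   (default 5).
#' @param omega_conserved rate multiplier at planted repressed-pair seed
#'   sites (default 0.2).
#' @param omega_null_site rate multiplier at seed sites of non-repressed
#'   pairs (default 0.6).
#' @param omega_exon rate multiplier over remaining lincRNA exonic bases
#'   (default 0.8).
#' @param omega_background rate multiplier elsewhere (default 1).
#' @param qc_defect_rate fraction of decoy raw reads carrying planted QC
#'   defects (default 0.05).
#' @param x1_mean,x1_sd normal law of the per-sample miRNA ln RPM covariate
#'   (default 9, 1 -- about 8,000 reads per million, so precursor loci are
#'   well covered at the default depth), shared by all pairs of one miRNA.
#' @param n_null_sites_per_lincrna planted seed sites per lincRNA for
#'   non-repressing miRNAs (default 2).
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_normal = 10L, n_tumor = 10L,
                       genome_length = 1000000L, n_known_genes = 8L,
                       n_candidate_regions = 50L, n_true_lincrnas = 15L,
                       n_near_gene_regions = 8L, n_coding_regions = 5L,
                       n_mirnas = 10L, n_planted_pairs = 10L,
                       beta = c(-4.8, -0.8, 0.3, 0), dispersion = 1.5,
                       read_length = 50L, mean_depth = 50000L,
                       n_species = 5L, omega_conserved = 0.2,
                       omega_null_site = 0.6, omega_exon = 0.8,
                       omega_background = 1, qc_defect_rate = 0.05,
                       x1_mean = 9, x1_sd = 1,
                       n_null_sites_per_lincrna = 2L) {
  cfg <- as.list(environment())
  if (n_normal + n_tumor < 4L) stop("need at least 4 samples in total")
  if (length(beta) != 4L) stop("beta must be a 4-vector (b0..b3)")
  if (dispersion < 1) stop("dispersion must be >= 1 (quasi-Poisson)")
  if (omega_conserved >= omega_background) {
    stop("omega_conserved must be smaller than omega_background")
  }
  if (n_true_lincrnas > n_candidate_regions) {
    stop("n_true_lincrnas exceeds n_candidate_regions")
  }
  if (n_true_lincrnas + n_near_gene_regions + n_coding_regions >
      n_candidate_regions) {
    stop("region classes exceed n_candidate_regions")
  }
  if (n_near_gene_regions > n_known_genes) {
    stop("n_near_gene_regions exceeds n_known_genes")
  }
  if (n_planted_pairs > n_true_lincrnas) {
    stop("n_planted_pairs exceeds n_true_lincrnas")
  }
  if (n_species < 2L) stop("need at least 2 taxa")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d + %d samples, %d bp genome, %d candidate regions\n",
              x$n_normal, x$n_tumor, x$genome_length, x$n_candidate_regions))
  cat(sprintf("  %d lincRNAs, %d miRNAs, %d planted repressed pairs\n",
              x$n_true_lincrnas, x$n_mirnas, x$n_planted_pairs))
  cat(sprintf("  beta = (%s), phi = %.2f, seed = %d\n",
              paste(format(x$beta), collapse = ", "), x$dispersion, x$seed))
  invisible(x)
}

random_dna <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate the toy genome, annotations and truth tables
#'
#' Lays out known genes and candidate regions of four classes on a single
#' chromosome: (a) truly intergenic regions containing a planted multi-exon
#' lincRNA (splice motifs written into the sequence, seed-match sites
#' planted in exons), (b) regions overlapping or near known genes, (c)
#' regions with a codon-preserving alignment (high CSF, to be excluded),
#' and (d) inert background regions. Also generates mature miRNAs,
#' pre-miRNA loci, ChIP tags, the two K4-K36 source tracks, and the
#' per-region alignments plus log-odds matrix the CSF filter consumes.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, all files are written
#'   (FASTA, BED, TSV) and their paths returned in `$paths`.
#' @return a list (`truth`) with the genome, annotations, planted
#'   transcripts/pairs/sites and all per-region artifacts; see the fields
#'   used by [simulate_reads()], [simulate_maf()] and [run_pipeline()].
#' @export
simulate_genome <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom <- "chr1"
  margin <- 250L

  # -- transcript structures for the lincRNA regions
  tx <- lapply(seq_len(cfg$n_true_lincrnas), function(i) {
    n_ex <- sample(3:5, 1L)
    ew <- sample(120:300, n_ex, replace = TRUE)
    iw <- sample(120:800, n_ex - 1L, replace = TRUE)
    list(n_ex = n_ex, exon_w = ew, intron_w = iw,
         span = sum(ew) + sum(iw),
         strand = sample(c("+", "-"), 1L))
  })
  if (cfg$genome_length < 10L * max(vapply(tx, `[[`, 0, "span"))) {
    stop("genome too short for the requested transcripts (sizing error)")
  }

  # -- layout items
  n_bg <- cfg$n_candidate_regions - cfg$n_true_lincrnas -
    cfg$n_near_gene_regions - cfg$n_coding_regions
  items <- list()
  for (i in seq_len(cfg$n_true_lincrnas)) {
    items[[length(items) + 1L]] <- list(kind = "lincrna_region", idx = i,
                                        width = tx[[i]]$span + 2L * margin)
  }
  for (i in seq_len(cfg$n_coding_regions)) {
    items[[length(items) + 1L]] <- list(kind = "coding_region", idx = i,
                                        width = sample(900:1500, 1L))
  }
  for (i in seq_len(n_bg)) {
    items[[length(items) + 1L]] <- list(kind = "background_region", idx = i,
                                        width = sample(1500:3000, 1L))
  }
  gene_w <- sample(2000:4000, cfg$n_known_genes, replace = TRUE)
  near_gene <- seq_len(cfg$n_near_gene_regions) # genes carrying a region
  for (g in seq_len(cfg$n_known_genes)) {
    it <- list(kind = "gene", idx = g, width = gene_w[g])
    if (g %in% near_gene) {
      it$near_width <- sample(1500:3000, 1L)
      it$near_gap <- sample(-500:2000, 1L) # negative: overlapping
      it$width <- it$width + max(0L, it$near_gap) + it$near_width
    }
    items[[length(items) + 1L]] <- it
  }
  for (m in seq_len(cfg$n_mirnas)) {
    items[[length(items) + 1L]] <- list(kind = "pre_mirna", idx = m,
                                        width = 90L)
  }
  items <- items[sample(length(items))]
  need <- sum(vapply(items, `[[`, 0, "width")) + 9000 * (length(items) + 1)
  if (need > cfg$genome_length) {
    stop("genome too short to place the requested features (sizing error)")
  }

  # -- place sequentially
  genes <- NULL; regions <- NULL; pre_mirna <- NULL
  cursor <- 1000L
  place <- function(df, row) rbind(df, row)
  for (it in items) {
    gap <- sample(6000:9000, 1L)
    start <- cursor
    if (it$kind == "gene") {
      g_end <- start + gene_w[it$idx] - 1L
      genes <- place(genes, data.frame(gene_id = sprintf("gene%02d", it$idx),
                                       start = start, end = g_end,
                                       strand = sample(c("+", "-"), 1L)))
      if (!is.null(it$near_width)) {
        r_start <- g_end + it$near_gap + 1L
        regions <- place(regions, data.frame(
          class = "near_gene", start = r_start,
          end = r_start + it$near_width - 1L, lincrna = NA_integer_
        ))
      }
    } else if (it$kind == "pre_mirna") {
      pre_mirna <- place(pre_mirna, data.frame(
        mirna = it$idx, start = start, end = start + 89L
      ))
    } else {
      cls <- sub("_region$", "", it$kind)
      cls <- if (cls == "lincrna") "lincrna" else
        if (cls == "coding") "coding_like" else "background"
      regions <- place(regions, data.frame(
        class = cls, start = start, end = start + it$width - 1L,
        lincrna = if (cls == "lincrna") it$idx else NA_integer_
      ))
    }
    cursor <- start + it$width + gap
  }
  regions <- regions[order(regions$start), ]
  regions$region_id <- sprintf("region%03d", seq_len(nrow(regions)))
  rownames(regions) <- NULL

  # -- genome sequence
  genome_chars <- random_dna(cfg$genome_length)

  # -- write lincRNA exon/intron structure and splice motifs
  tx_tab <- list()
  for (i in seq_len(cfg$n_true_lincrnas)) {
    reg <- regions[!is.na(regions$lincrna) & regions$lincrna == i, ]
    t <- tx[[i]]
    pos <- reg$start + margin
    ex_start <- integer(t$n_ex); ex_end <- integer(t$n_ex)
    for (k in seq_len(t$n_ex)) {
      ex_start[k] <- pos
      ex_end[k] <- pos + t$exon_w[k] - 1L
      pos <- ex_end[k] + 1L
      if (k < t$n_ex) {
        is_ <- pos                      # first intronic base
        ie_ <- pos + t$intron_w[k] - 1L # last intronic base
        if (t$strand == "+") {
          genome_chars[is_:(is_ + 1L)] <- c("G", "T")
          genome_chars[(ie_ - 1L):ie_] <- c("A", "G")
        } else {
          genome_chars[is_:(is_ + 1L)] <- c("C", "T")
          genome_chars[(ie_ - 1L):ie_] <- c("A", "C")
        }
        pos <- ie_ + 1L
      }
    }
    tx_tab[[i]] <- data.frame(
      lincrna_id = sprintf("linc%02d", i), exon = seq_len(t$n_ex),
      start = ex_start, end = ex_end, strand = t$strand,
      region_id = reg$region_id
    )
  }
  tx_tab <- do.call(rbind, tx_tab)

  # -- miRNAs
  mirna_ids <- sprintf("miR-%02d", seq_len(cfg$n_mirnas))
  repeat {
    mat <- vapply(seq_len(cfg$n_mirnas), function(i) {
      paste(random_dna(22L), collapse = "")
    }, "")
    seeds <- substr(mat, 2L, 8L)
    if (!anyDuplicated(seeds)) break
  }
  mirnas <- data.frame(id = mirna_ids,
                       mature_seq = chartr("T", "U", mat),
                       stringsAsFactors = FALSE)
  pre_mirna$mirna_id <- mirna_ids[pre_mirna$mirna]

  # -- planted pairs and seed sites
  planted_linc <- sample(cfg$n_true_lincrnas, cfg$n_planted_pairs)
  planted_mirna <- sample(cfg$n_mirnas, cfg$n_planted_pairs, replace = TRUE)
  pairs <- data.frame(
    mirna_id = mirna_ids[planted_mirna],
    lincrna_id = sprintf("linc%02d", planted_linc),
    planted = TRUE, stringsAsFactors = FALSE
  )
  sites <- list()
  used <- lapply(seq_len(cfg$n_true_lincrnas), function(i) integer(0))
  plant_site <- function(linc_idx, mirna_idx, cross_junction, genome_chars,
                         used_pos) {
    t <- tx[[linc_idx]]
    exdf <- tx_tab[tx_tab$lincrna_id == sprintf("linc%02d", linc_idx), ]
    # exons in transcript order
    ord <- if (t$strand == "+") seq_len(t$n_ex) else rev(seq_len(t$n_ex))
    w <- exdf$end[ord] - exdf$start[ord] + 1L
    cumw <- cumsum(w)
    L <- sum(w)
    site8 <- paste0(
      revcomp_chr(chartr("U", "T",
                         substr(mirnas$mature_seq[mirna_idx], 2L, 8L))), "A")
    # choose transcript start position
    tpos <- NA_integer_
    if (cross_junction && t$n_ex >= 2L) {
      tpos <- cumw[1L] - 3L # 4 nt on each side of the first junction
    } else {
      ex_k <- which.max(w)
      for (try in 1:50) {
        # clear of the exon edge; when the exon allows, keep the site >=
        # 110 nt into the transcript so its upstream control stays on it
        lo <- c(0L, cumw)[ex_k] + 15L
        hi <- cumw[ex_k] - 15L - 8L
        if (hi > max(lo, 111L)) lo <- max(lo, 111L)
        if (hi <= lo) next
        cand <- sample(lo:hi, 1L)
        if (!any(abs(cand - used_pos) < 12L)) {
          tpos <- cand
          break
        }
      }
    }
    if (is.na(tpos)) return(NULL)
    # write the 8-nt site into the genome through the exon map; on the minus
    # strand the transcript position counts from the genomic right end
    wg <- exdf$end - exdf$start + 1L
    cg <- cumsum(c(0L, wg))
    gpos <- vapply(0:7, function(off) {
      p <- tpos + off
      p_idx <- if (t$strand == "-") L - p + 1L else p
      k <- findInterval(p_idx, cg, left.open = TRUE)
      exdf$start[k] + (p_idx - cg[k] - 1L)
    }, numeric(1))
    chars <- if (t$strand == "-") strsplit(revcomp_chr(site8), "")[[1]]
             else strsplit(site8, "")[[1]]
    genome_chars[sort(gpos)] <- chars
    list(genome_chars = genome_chars, tpos = tpos, gpos = sort(gpos))
  }
  for (k in seq_len(cfg$n_planted_pairs)) {
    res <- plant_site(planted_linc[k], planted_mirna[k],
                      cross_junction = (k == 1L), genome_chars,
                      used[[planted_linc[k]]])
    if (is.null(res)) stop("could not place a planted site")
    genome_chars <- res$genome_chars
    used[[planted_linc[k]]] <- c(used[[planted_linc[k]]],
                                 res$tpos + 0:7)
    sites[[length(sites) + 1L]] <- data.frame(
      mirna_id = mirna_ids[planted_mirna[k]],
      lincrna_id = sprintf("linc%02d", planted_linc[k]),
      site_type = "8mer", transcript_pos = res$tpos,
      gstart = res$gpos[1L], gend = res$gpos[length(res$gpos)],
      planted_pair = TRUE, stringsAsFactors = FALSE
    )
  }
  # null sites: non-repressing miRNAs on each lincRNA
  null_pairs <- list()
  for (i in seq_len(cfg$n_true_lincrnas)) {
    own <- planted_mirna[planted_linc == i]
    pool <- setdiff(seq_len(cfg$n_mirnas), own)
    ms <- sample(pool, min(cfg$n_null_sites_per_lincrna, length(pool)))
    for (m in ms) {
      res <- plant_site(i, m, cross_junction = FALSE, genome_chars, used[[i]])
      if (is.null(res)) next
      genome_chars <- res$genome_chars
      used[[i]] <- c(used[[i]], res$tpos + 0:7)
      sites[[length(sites) + 1L]] <- data.frame(
        mirna_id = mirna_ids[m], lincrna_id = sprintf("linc%02d", i),
        site_type = "8mer", transcript_pos = res$tpos,
        gstart = res$gpos[1L], gend = res$gpos[length(res$gpos)],
        planted_pair = FALSE, stringsAsFactors = FALSE
      )
      null_pairs[[length(null_pairs) + 1L]] <- data.frame(
        mirna_id = mirna_ids[m], lincrna_id = sprintf("linc%02d", i),
        planted = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  sites <- do.call(rbind, sites)
  pairs <- rbind(pairs, unique(do.call(rbind, null_pairs)))

  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(genome_chars, collapse = ""), chrom))

  # -- K4-K36 source tracks (some regions in both species)
  src <- sample(c("human", "mouse", "both"), nrow(regions), replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
  human_rows <- src %in% c("human", "both")
  mouse_rows <- src %in% c("mouse", "both")
  hstart <- regions$start
  hend <- ifelse(src == "both", regions$end - 150L, regions$end)
  mstart <- ifelse(src == "both", regions$start + 150L, regions$start)
  mend <- regions$end
  k436_human <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(hstart[human_rows], hend[human_rows]))
  k436_mouse <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(mstart[mouse_rows], mend[mouse_rows]))

  # -- ChIP tags (RPolII)
  chip_total <- 1000000L
  tag_pos <- integer(0)
  emit_tags <- function(start, end, rpkm_target) {
    kb <- (end - start + 1L) / 1000
    n <- stats::rpois(1L, rpkm_target * kb * chip_total / 1e6)
    if (n > 0L) sample(start:end, n, replace = TRUE) else integer(0)
  }
  rpolii_active <- logical(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    target <- switch(regions$class[r],
      lincrna = stats::runif(1, 2, 5),
      coding_like = stats::runif(1, 2, 5),
      near_gene = stats::runif(1, 1, 4),
      background = if (stats::runif(1) < 0.2) stats::runif(1, 0.15, 0.4)
                   else stats::runif(1, 0, 0.03)
    )
    rpolii_active[r] <- target > 0.1
    tag_pos <- c(tag_pos, emit_tags(regions$start[r], regions$end[r], target))
  }
  for (g in seq_len(nrow(genes))) {
    tag_pos <- c(tag_pos, emit_tags(genes$start[g], genes$end[g],
                                    stats::runif(1, 3, 8)))
  }
  regions$rpolii_active <- rpolii_active
  chip_tags <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(sort(tag_pos), width = 1L), strand = "+")

  # -- CSF alignment artifact + matrix
  csf_matrix <- make_csf_matrix(match = 1, mismatch = -1, gap = -1)
  mutate_seq <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, "")
    }
    paste(ch, collapse = "")
  }
  csf_aln <- data.frame(
    region_id = regions$region_id,
    start = regions$start, end = regions$end,
    ref = substring(as.character(genome[[chrom]]),
                    regions$start, regions$end),
    stringsAsFactors = FALSE
  )
  csf_aln$alt <- vapply(seq_len(nrow(regions)), function(r) {
    if (regions$class[r] == "coding_like") csf_aln$ref[r]
    else mutate_seq(csf_aln$ref[r], 0.35)
  }, "")

  truth <- list(
    cfg = cfg, chrom = chrom, genome = genome,
    genes = genes, regions = regions, tx = tx, tx_tab = tx_tab,
    mirnas = mirnas, pre_mirna = pre_mirna,
    pairs = pairs, sites = sites,
    k436_human = k436_human, k436_mouse = k436_mouse,
    chip_tags = chip_tags, chip_total = length(chip_tags),
    csf_matrix = csf_matrix, csf_aln = csf_aln
  )
  if (!is.null(dir)) truth$paths <- write_simulated_genome(truth, dir)
  truth
}

# write the genome-level artifacts of simulate_genome to dir
write_simulated_genome <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  p$genome <- file.path(dir, "genome.fa")
  write_fasta(truth$genome, p$genome)
  gene_gr <- GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(truth$genes$start, truth$genes$end),
    strand = truth$genes$strand, name = truth$genes$gene_id)
  p$known_genes <- file.path(dir, "known_genes.bed")
  write_bed(gene_gr, p$known_genes)
  p$k436_human <- file.path(dir, "k436_human.bed")
  write_bed(truth$k436_human, p$k436_human)
  p$k436_mouse <- file.path(dir, "k436_mouse_lifted.bed")
  write_bed(truth$k436_mouse, p$k436_mouse)
  p$chip_tags <- file.path(dir, "rpolii_tags.bed")
  write_bed(truth$chip_tags, p$chip_tags)
  p$mirnas <- file.path(dir, "mirnas_mature.fa")
  write_fasta(Biostrings::BStringSet(
    stats::setNames(truth$mirnas$mature_seq, truth$mirnas$id)), p$mirnas)
  pm <- truth$pre_mirna
  p$pre_mirnas <- file.path(dir, "pre_mirnas.bed")
  write_bed(GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(pm$start, pm$end), strand = "+",
    name = pm$mirna_id), p$pre_mirnas)
  p$truth_regions <- file.path(dir, "truth_regions.tsv")
  write_tsv(truth$regions, p$truth_regions)
  p$truth_transcripts <- file.path(dir, "truth_transcripts.bed12")
  bl <- data.frame(read_id = truth$tx_tab$lincrna_id, chrom = truth$chrom,
                   start = truth$tx_tab$start, end = truth$tx_tab$end,
                   strand = truth$tx_tab$strand)
  write_bed12(bl, p$truth_transcripts)
  p$truth_pairs <- file.path(dir, "truth_pairs.tsv")
  write_tsv(truth$pairs, p$truth_pairs)
  p$truth_sites <- file.path(dir, "truth_sites.tsv")
  write_tsv(truth$sites, p$truth_sites)
  p$csf_aln <- file.path(dir, "csf_alignments.tsv")
  write_tsv(truth$csf_aln, p$csf_aln)
  p$csf_matrix <- file.path(dir, "csf_matrix.tsv")
  utils::write.table(truth$csf_matrix, p$csf_matrix, sep = "\t",
                     quote = FALSE, col.names = NA)
  p
}

#' Simulate per-feature, per-sample read counts
#'
#' Counts follow the repression model: for a planted (miRNA, lincRNA) pair
#' the expected count in sample s is
#' `M_s * exp(b0_i + b1*x1 + b2*x2 + b3*x1*x2)` with `x1` the miRNA's ln RPM
#' in that sample (drawn from a normal law, shared across the miRNA's
#' pairs), `x2` the condition, and `b0_i` set by the lincRNA's relative
#' abundance; unplanted features depend only on their abundance (plus a
#' per-gene condition effect). Overdispersion is negative binomial with
#' variance `phi * mu`.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [simulate_genome()].
#' @return list with `counts` (features x samples), `sample_sheet`
#'   (`sample_id`, `condition`, `total_target`), `x1` (miRNAs x samples ln
#'   RPM truth) and `feature_info` (id, kind, spliced length, b0).
#' @export
simulate_counts <- function(cfg, truth) {
  set.seed(cfg$seed + 1L)
  n_s <- cfg$n_normal + cfg$n_tumor
  sample_id <- sprintf("s%02d", seq_len(n_s))
  condition <- rep(c(0L, 1L), c(cfg$n_normal, cfg$n_tumor))
  M <- round(cfg$mean_depth * stats::runif(n_s, 0.9, 1.1))
  x1 <- matrix(stats::rnorm(cfg$n_mirnas * n_s, cfg$x1_mean, cfg$x1_sd),
               nrow = cfg$n_mirnas,
               dimnames = list(truth$mirnas$id, sample_id))

  linc_ids <- sprintf("linc%02d", seq_len(cfg$n_true_lincrnas))
  gene_ids <- truth$genes$gene_id
  mir_ids <- truth$mirnas$id
  feat <- c(gene_ids, linc_ids, mir_ids)
  kind <- rep(c("gene", "lincrna", "pre_mirna"),
              c(length(gene_ids), length(linc_ids), length(mir_ids)))

  # relative abundances: lincRNAs sized for deep coverage of every position,
  # genes filling most of the library
  w_linc <- stats::runif(cfg$n_true_lincrnas, 0.010, 0.016)
  w_gene <- stats::runif(length(gene_ids), 0.3, 1.5)
  w_gene <- w_gene / sum(w_gene) * 0.6
  gene_b2 <- stats::rnorm(length(gene_ids), 0, 0.3)

  beta <- cfg$beta
  planted <- truth$pairs[truth$pairs$planted, ]
  counts <- matrix(0L, nrow = length(feat), ncol = n_s,
                   dimnames = list(feat, sample_id))
  b0 <- stats::setNames(rep(NA_real_, length(feat)), feat)
  for (i in seq_along(feat)) {
    f <- feat[i]
    if (kind[i] == "pre_mirna") {
      mu <- exp(x1[f, ]) * M / 1e6
    } else if (kind[i] == "lincrna" && f %in% planted$lincrna_id) {
      m <- planted$mirna_id[match(f, planted$lincrna_id)]
      wi <- w_linc[match(f, linc_ids)]
      b0[i] <- log(wi) - beta[2] * cfg$x1_mean
      eta <- b0[i] + beta[2] * x1[m, ] + beta[3] * condition +
        beta[4] * x1[m, ] * condition
      mu <- M * exp(eta)
    } else if (kind[i] == "lincrna") {
      wi <- w_linc[match(f, linc_ids)]
      b0[i] <- log(wi)
      mu <- M * wi
    } else {
      wi <- w_gene[match(f, gene_ids)]
      b0[i] <- log(wi)
      mu <- M * wi * exp(gene_b2[match(f, gene_ids)] * condition)
    }
    counts[i, ] <- rnbinom_qp(n_s, mu, cfg$dispersion)
  }
  ex_len <- function(id) {
    sum(truth$tx_tab$end[truth$tx_tab$lincrna_id == id] -
          truth$tx_tab$start[truth$tx_tab$lincrna_id == id] + 1L)
  }
  spliced <- ifelse(
    kind == "gene", truth$genes$end[match(feat, gene_ids)] -
      truth$genes$start[match(feat, gene_ids)] + 1L,
    ifelse(kind == "pre_mirna", 90L,
           vapply(feat, function(f) {
             if (grepl("^linc", f)) ex_len(f) else NA_integer_
           }, numeric(1)))
  )
  list(
    counts = counts,
    sample_sheet = data.frame(sample_id = sample_id, condition = condition,
                              total_target = M),
    x1 = x1,
    feature_info = data.frame(feature_id = feat, kind = kind,
                              spliced_length = as.integer(spliced), b0 = b0)
  )
}

# exon table of a feature in transcript order with cumulative widths
feature_exons <- function(truth, feature_id, kind) {
  if (kind == "lincrna") {
    exdf <- truth$tx_tab[truth$tx_tab$lincrna_id == feature_id, ]
    strand <- exdf$strand[1L]
    ord <- if (strand == "+") seq_len(nrow(exdf)) else rev(seq_len(nrow(exdf)))
    data.frame(gstart = exdf$start[ord], gend = exdf$end[ord],
               strand = strand)
  } else if (kind == "gene") {
    g <- truth$genes[truth$genes$gene_id == feature_id, ]
    data.frame(gstart = g$start, gend = g$end, strand = g$strand)
  } else {
    pm <- truth$pre_mirna[truth$pre_mirna$mirna_id == feature_id, ]
    data.frame(gstart = pm$start, gend = pm$end, strand = "+")
  }
}

#' Materialize reads from simulated counts
#'
#' Uniformly places each feature's reads along its spliced sequence.
#' Reads contained in one exon become strand-specific single-block
#' alignments (the genome-mappable fraction); reads crossing a splice
#' junction are emitted as raw sequence+quality records (the pool a genomic
#' aligner would leave unmapped), guaranteed to cover every true junction.
#' A configurable fraction of additional decoy records carries planted QC
#' defects (N runs or low-quality tails) to exercise the QC rules.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [simulate_genome()].
#' @param cm optional output of [simulate_counts()] (generated if missing).
#' @param dir optional output directory: per-sample BED12 alignments,
#'   per-sample FASTQ of unmapped reads, and a sample sheet TSV.
#' @return list with `aln` (blocks table), `unmapped` (data.frame
#'   `sample_id`, `id`, `seq`, `qual`), `sample_sheet` (with realized
#'   `total_mapped`), `counts`, `x1`, `feature_info`, and `paths` when `dir`
#'   is given.
#' @export
simulate_reads <- function(cfg, truth, cm = NULL, dir = NULL) {
  if (is.null(cm)) cm <- simulate_counts(cfg, truth)
  set.seed(cfg$seed + 2L)
  rl <- cfg$read_length
  counts <- cm$counts
  n_s <- ncol(counts)
  sample_id <- colnames(counts)
  aln_list <- list()
  unmapped <- list()
  genome_seq <- truth$genome[[truth$chrom]]

  for (f in rownames(counts)) {
    kind <- cm$feature_info$kind[match(f, cm$feature_info$feature_id)]
    ex <- feature_exons(truth, f, kind)
    w <- ex$gend - ex$gstart + 1L
    cumw <- cumsum(w)
    L <- sum(w)
    strand <- ex$strand[1L]
    eff <- max(1L, L - rl + 1L)
    tx_seq <- NULL
    jx_t <- if (nrow(ex) > 1L) cumw[-length(cumw)] else integer(0)
    for (s in seq_len(n_s)) {
      n <- counts[f, s]
      if (n == 0L) next
      st <- sample.int(eff, n, replace = TRUE)
      en <- pmin(st + rl - 1L, L)
      ex_i <- findInterval(st - 1L, cumw) + 1L
      ex_j <- findInterval(en - 1L, cumw) + 1L
      single <- ex_i == ex_j
      ids <- sprintf("%s_%s_r%05d", f, sample_id[s], seq_len(n))
      if (any(single)) {
        k <- ex_i[single]
        o1 <- st[single] - c(0L, cumw)[k] - 1L # 0-based offset in exon
        o2 <- en[single] - c(0L, cumw)[k] - 1L
        if (strand == "+") {
          gs <- ex$gstart[k] + o1
          ge <- ex$gstart[k] + o2
        } else {
          gs <- ex$gend[k] - o2
          ge <- ex$gend[k] - o1
        }
        aln_list[[length(aln_list) + 1L]] <- data.frame(
          read_id = ids[single], sample_id = sample_id[s],
          chrom = truth$chrom, start = gs, end = ge, strand = strand,
          stringsAsFactors = FALSE
        )
      }
      if (any(!single)) {
        if (is.null(tx_seq)) {
          tx_seq <- feature_tx_seq(genome_seq, ex)
        }
        idx <- which(!single)
        unmapped[[length(unmapped) + 1L]] <- data.frame(
          sample_id = sample_id[s], id = ids[idx],
          seq = substring(tx_seq, st[idx], en[idx]),
          qual = vapply(en[idx] - st[idx] + 1L, function(len) {
            int_to_phred(sample(34:40, len, replace = TRUE))
          }, ""),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  aln <- do.call(rbind, aln_list)
  unmapped <- if (length(unmapped)) do.call(rbind, unmapped) else
    data.frame(sample_id = character(0), id = character(0),
               seq = character(0), qual = character(0))

  # explicit junction coverage check and top-up
  extra <- junction_topup(cfg, truth, unmapped, genome_seq)
  if (!is.null(extra)) unmapped <- rbind(unmapped, extra)

  # decoy reads with planted QC defects
  n_defect <- round(cfg$qc_defect_rate * nrow(unmapped))
  if (n_defect > 0L) {
    pos <- sample.int(length(genome_seq) - rl, n_defect)
    dseq <- substring(as.character(genome_seq), pos, pos + rl - 1L)
    dqual <- character(n_defect)
    for (i in seq_len(n_defect)) {
      q <- sample(34:40, rl, replace = TRUE)
      if (i %% 2L == 0L) { # N run -> discarded by the N rule
        ch <- strsplit(dseq[i], "")[[1]]
        ch[sample(rl, 3L)] <- "N"
        dseq[i] <- paste(ch, collapse = "")
      } else {             # low-quality tail -> truncated (or discarded)
        tail_len <- sample(c(10L, 20L), 1L)
        q[(rl - tail_len + 1L):rl] <- 5L
      }
      dqual[i] <- int_to_phred(q)
    }
    unmapped <- rbind(unmapped, data.frame(
      sample_id = sample(colnames(counts), n_defect, replace = TRUE),
      id = sprintf("defect_r%04d", seq_len(n_defect)),
      seq = dseq, qual = dqual, stringsAsFactors = FALSE
    ))
  }

  total_mapped <- as.integer(table(factor(
    aln$sample_id[!duplicated(paste(aln$sample_id, aln$read_id))],
    levels = sample_id)))
  sample_sheet <- cm$sample_sheet
  sample_sheet$total_mapped <- total_mapped

  out <- list(aln = aln, unmapped = unmapped, sample_sheet = sample_sheet,
              counts = counts, x1 = cm$x1, feature_info = cm$feature_info)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- list()
    p$aln <- file.path(dir, sprintf("aln_%s.bed12", sample_id))
    for (s in seq_len(n_s)) {
      write_bed12(aln[aln$sample_id == sample_id[s], ], p$aln[s])
    }
    p$unmapped <- file.path(dir, sprintf("unmapped_%s.fastq", sample_id))
    for (s in seq_len(n_s)) {
      u <- unmapped[unmapped$sample_id == sample_id[s], ]
      write_fastq(u, p$unmapped[s])
    }
    p$sample_sheet <- file.path(dir, "sample_sheet.tsv")
    write_tsv(sample_sheet, p$sample_sheet)
    out$paths <- p
  }
  out
}

feature_tx_seq <- function(genome_seq, ex) {
  parts <- vapply(seq_len(nrow(ex)), function(k) {
    s <- as.character(Biostrings::subseq(genome_seq, ex$gstart[k], ex$gend[k]))
    if (ex$strand[1L] == "-") revcomp_chr(s) else s
  }, "")
  paste(parts, collapse = "")
}

# ensure each true junction is spanned by >= 1 unmapped read with >= 8 nt
# anchors; emit the missing reads (sample s01)
junction_topup <- function(cfg, truth, unmapped, genome_seq) {
  rl <- cfg$read_length
  extra <- list()
  for (i in seq_len(cfg$n_true_lincrnas)) {
    f <- sprintf("linc%02d", i)
    ex <- feature_exons(truth, f, "lincrna")
    if (nrow(ex) < 2L) next
    w <- ex$gend - ex$gstart + 1L
    cumw <- cumsum(w)
    L <- sum(w)
    tx_seq <- feature_tx_seq(genome_seq, ex)
    own <- unmapped[startsWith(unmapped$id, paste0(f, "_")), , drop = FALSE]
    own_st <- if (nrow(own)) {
      match_starts(own$seq, tx_seq)
    } else integer(0)
    for (jt in cumw[-length(cumw)]) {
      covered <- any(own_st <= jt - 8L + 1L &
                       own_st + nchar(own$seq) - 1L >= jt + 8L)
      if (!covered) {
        st0 <- max(1L, min(jt - rl %/% 2L + 1L, L - rl + 1L))
        extra[[length(extra) + 1L]] <- data.frame(
          sample_id = "s01", id = sprintf("%s_s01_jx%06d", f, jt),
          seq = substring(tx_seq, st0, st0 + rl - 1L),
          qual = int_to_phred(rep(38L, min(rl, L - st0 + 1L))),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(extra)) do.call(rbind, extra) else NULL
}

# starting transcript position of each read sequence (exact substring match)
match_starts <- function(seqs, tx_seq) {
  vapply(seqs, function(s) {
    p <- regexpr(s, tx_seq, fixed = TRUE)
    as.integer(p)
  }, integer(1), USE.NAMES = FALSE)
}

#' Simulate the multiple alignment and phylogenetic tree
#'
#' Evolves each candidate region down a fixed tree under Jukes-Cantor
#' substitution with a per-column rate multiplier: `omega_conserved` inside
#' planted repressed-pair seed sites, `omega_null_site` at other planted
#' sites, `omega_exon` over remaining lincRNA exonic bases and
#' `omega_background` elsewhere. The reference taxon (`hg`) hangs off the
#' root with a zero-length branch, so its row equals the reference genome.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [simulate_genome()].
#' @param dir optional output directory (writes `alignment.maf` and
#'   `tree.nwk`).
#' @return list with `maf` (blocks, see [read_maf()]), `tree` (`phylo`) and
#'   `paths` when `dir` is given.
#' @export
simulate_maf <- function(cfg, truth, dir = NULL) {
  set.seed(cfg$seed + 3L)
  tree <- ape::read.tree(text = species_tree_newick(cfg$n_species))
  genome_chars <- strsplit(as.character(truth$genome[[truth$chrom]]),
                           "")[[1]]
  omega_track <- rep(cfg$omega_background, length(genome_chars))
  for (r in seq_len(nrow(truth$tx_tab))) {
    omega_track[truth$tx_tab$start[r]:truth$tx_tab$end[r]] <- cfg$omega_exon
  }
  for (r in seq_len(nrow(truth$sites))) {
    om <- if (truth$sites$planted_pair[r]) cfg$omega_conserved
          else cfg$omega_null_site
    omega_track[truth$sites$gstart[r]:truth$sites$gend[r]] <- om
  }
  blocks <- list()
  for (r in seq_len(nrow(truth$regions))) {
    s <- truth$regions$start[r]
    e <- truth$regions$end[r]
    cols <- simulate_jc_columns(tree, e - s + 1L,
                                omega = omega_track[s:e],
                                root_seq = genome_chars[s:e])
    blocks[[r]] <- list(
      chrom = truth$chrom, start = s, width = e - s + 1L,
      seqs = apply(cols, 1L, paste, collapse = "")
    )
  }
  out <- list(maf = blocks, tree = tree)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(maf = file.path(dir, "alignment.maf"),
              tree = file.path(dir, "tree.nwk"))
    write_maf(blocks, p$maf)
    ape::write.tree(tree, p$tree)
    out$paths <- p
  }
  out
}

# fixed ladder topology: reference hg on a zero-length branch at the root
species_tree_newick <- function(n_species) {
  stopifnot(n_species >= 2L)
  others <- sprintf("sp%d", seq_len(n_species - 1L) + 1L)
  bl <- 0.15 + 0.04 * seq_along(others)
  sub <- sprintf("%s:%.2f", others[length(others)], bl[length(others)])
  if (length(others) > 1L) {
    for (k in rev(seq_len(length(others) - 1L))) {
      sub <- sprintf("(%s:%.2f,%s):0.08", others[k], bl[k], sub)
    }
  }
  sprintf("(hg:0.0,%s);", sub)
}

#' Generate a complete simulated dataset
#'
#' Convenience wrapper running [simulate_genome()], [simulate_counts()],
#' [simulate_reads()] and [simulate_maf()] with one configuration.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory for all files.
#' @return list with `truth`, `reads` (incl. counts and sample sheet) and
#'   `maf`.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  truth <- simulate_genome(cfg, dir = dir)
  reads <- simulate_reads(cfg, truth, dir = dir)
  maf <- simulate_maf(cfg, truth, dir = dir)
  list(truth = truth, reads = reads, maf = maf)
}
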