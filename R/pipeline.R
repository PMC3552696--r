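# End-to-end orchestration.
#
# Mirrors the published seven-step strategy: (1) alignments arrive as
# input, (2) candidate regions are merged and filtered by gene distance,
# RPolII occupancy and CSF coding potential, (3) exon structures are
# assembled from pileups and junction evidence, (4) seed sites are
# predicted on the spliced transcripts, (5) expression is quantified as
# RPKM, (6) reverse correlation is tested pair by pair with the
# quasi-Poisson model, and (7) conservation of sites of reverse-correlated
# pairs is compared against other sites and upstream controls. Every
# filter's count lands in the funnel report, and all stage outputs are
# persisted so the report is recomputable from files.

#' Pipeline configuration
#'
#' @param out_dir output directory for stage outputs (`NULL`: nothing
#'   written).
#' @param sim a [sim_config()] to generate the inputs, or `NULL` when
#'   `inputs` is supplied.
#' @param inputs a pre-built input bundle (see [run_pipeline()] details).
#' @param min_gene_distance bp, candidate regions closer to a known gene
#'   are dropped (default 5000).
#' @param rpolii_threshold RPKM, strict lower bound on RPolII signal
#'   (default 0.1).
#' @param csf_cutoff CSF score above which a region is excluded (default
#'   20).
#' @param min_reads minimum reads per putative exon (default 8).
#' @param merge_gap exon-merge gap in bp (default 10).
#' @param splice_search splice-site search radius in bp (default 25).
#' @param max_span maximum intron length in bp (default 100000).
#' @param min_intron minimum intron length in bp (default 70).
#' @param anchor junction-read anchor in bp (default 8).
#' @param max_mismatch junction-read mismatch allowance (default 2).
#' @param min_rpkm detectability RPKM threshold (default 0.5).
#' @param min_samples detectability sample-count threshold (default 15,
#'   strict).
#' @param alpha_interaction interaction significance level (default 0.05).
#' @param fdr_cutoff reverse-correlation FDR threshold (default 0.2).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = NULL, sim = NULL, inputs = NULL,
                            min_gene_distance = 5000L,
                            rpolii_threshold = 0.1, csf_cutoff = 20,
                            min_reads = 8L, merge_gap = 10L,
                            splice_search = 25L, max_span = 100000L,
                            min_intron = 70L, anchor = 8L, max_mismatch = 2L,
                            min_rpkm = 0.5, min_samples = 15L,
                            alpha_interaction = 0.05, fdr_cutoff = 0.2) {
  cfg <- as.list(environment())
  stopifnot(rpolii_threshold >= 0, min_reads >= 1, merge_gap >= 1,
            min_intron >= 1, max_span >= min_intron, min_rpkm >= 0,
            fdr_cutoff >= 0)
  if (is.null(sim) && is.null(inputs)) {
    stop("provide either `sim` (a sim_config) or `inputs`")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the discovery and reverse-correlation pipeline
#'
#' Executes all stages on a simulated or supplied dataset and returns a run
#' object holding the funnel report and every stage result. The input
#' bundle (built internally from `sim`, or passed as `inputs`) is a list
#' with: `genome` (`DNAStringSet`), `known_genes`, `k436_human`,
#' `k436_mouse`, `chip_tags` (`GRanges`), `chip_total`, `mirnas`
#' (data.frame id/mature_seq), `pre_mirna` (data.frame mirna_id/start/end),
#' `chrom`, `aln` (blocks table), `unmapped` (reads table with
#' `sample_id`), `sample_sheet`, `csf_aln`, `csf_matrix`, `maf`, `tree`,
#' `read_length`.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `"lincmir_run"`; see `print()` for the funnel
#'   and `$` for stage outputs (`regions`, `transcripts`, `sites`,
#'   `counts`, `rpkm`, `pair_calls`, `conservation`, `funnel`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- config$inputs
  truth <- NULL
  if (!is.null(config$sim)) {
    ds <- simulate_dataset(config$sim, dir = NULL)
    truth <- ds$truth
    inputs <- dataset_inputs(ds)
  }
  funnel <- list()

  # (1) QC on the raw (unmapped) read pool
  qc <- qc_filter_reads(inputs$unmapped)
  qc$reads$sample_id <- inputs$unmapped$sample_id[
    match(qc$reads$id, inputs$unmapped$id)]
  funnel$raw_unmapped_reads <- nrow(inputs$unmapped)
  funnel$qc_passed_reads <- nrow(qc$reads)

  # (2) candidate regions
  regions <- merge_and_exclude(inputs$k436_human, inputs$k436_mouse,
                               inputs$known_genes,
                               config$min_gene_distance)
  funnel$candidate_regions <- length(regions)
  regions <- rpolii_filter(regions, inputs$chip_tags, inputs$chip_total,
                           config$rpolii_threshold)
  funnel$rpolii_passed <- length(regions)
  S4Vectors::mcols(regions)$csf_score <- region_csf_scores(
    regions, inputs$csf_aln, inputs$csf_matrix)
  regions <- csf_filter(regions, config$csf_cutoff)
  funnel$csf_passed <- length(regions)

  # (3) assembly
  blocks <- alignment_blocks(inputs$aln)
  asm <- assemble_regions(blocks, regions, inputs$genome, qc$reads, config,
                          inputs$read_length)
  transcripts <- asm$transcripts
  funnel$assembled_transcripts <- length(transcripts)
  funnel$multi_exon_transcripts <-
    sum(S4Vectors::mcols(transcripts)$n_exons > 1L)

  # (4) seed-site prediction on spliced transcripts
  sites <- list()
  tx_seq <- character(length(transcripts))
  tx_strand <- character(length(transcripts))
  for (i in seq_along(transcripts)) {
    ex <- transcripts[[i]]
    st <- as.character(GenomicRanges::strand(ex))[1]
    if (st == "*") st <- "+"
    tx_strand[i] <- st
    tx_seq[i] <- spliced_sequence(inputs$genome, ex, st)
    m <- predict_seed_matches(tx_seq[i], inputs$mirnas,
                              lincrna_id = names(transcripts)[i],
                              exons = ex, strand = st)
    if (nrow(m)) sites[[length(sites) + 1L]] <- m
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    predict_seed_matches("", inputs$mirnas[0, , drop = FALSE])
  funnel$predicted_sites <- nrow(sites)
  funnel$predicted_pairs <- nrow(unique(sites[c("mirna_id", "lincrna_id")]))

  # (5) quantification
  features <- c(
    as.list(transcripts),
    stats::setNames(lapply(seq_len(length(inputs$known_genes)), function(i) {
      inputs$known_genes[i]
    }), inputs$known_genes$name),
    stats::setNames(lapply(seq_len(nrow(inputs$pre_mirna)), function(i) {
      GenomicRanges::GRanges(inputs$chrom,
                             IRanges::IRanges(inputs$pre_mirna$start[i],
                                              inputs$pre_mirna$end[i]),
                             strand = "+")
    }), inputs$pre_mirna$mirna_id)
  )
  features <- GenomicRanges::GRangesList(features)
  samples <- inputs$sample_sheet$sample_id
  counts <- count_reads(blocks, features, samples = samples)
  totals <- inputs$sample_sheet$total_mapped
  lens <- vapply(features, function(g) sum(GenomicRanges::width(g)),
                 numeric(1))
  rpkm_mat <- rpkm(counts, lens, totals)
  detectable <- detectability_filter(rpkm_mat, config$min_rpkm,
                                     config$min_samples)
  funnel$detectable_lincrnas <-
    sum(detectable[names(transcripts)], na.rm = TRUE)
  funnel$detectable_mirnas <-
    sum(detectable[inputs$pre_mirna$mirna_id], na.rm = TRUE)

  # (6) reverse-correlation GLM
  x1_mat <- ln_rpm(counts[inputs$pre_mirna$mirna_id, , drop = FALSE], totals)
  pair_tab <- unique(sites[c("mirna_id", "lincrna_id")])
  eligible <- detectable[pair_tab$lincrna_id] & detectable[pair_tab$mirna_id]
  pair_tab <- pair_tab[eligible, , drop = FALSE]
  funnel$eligible_pairs <- nrow(pair_tab)
  pair_calls <- NULL
  if (nrow(pair_tab)) {
    pairs_df <- data.frame(
      pair_id = paste(pair_tab$mirna_id, pair_tab$lincrna_id, sep = ":"),
      target_id = pair_tab$lincrna_id, mirna_id = pair_tab$mirna_id,
      family = "lincrna", stringsAsFactors = FALSE
    )
    pair_calls <- call_pairs(pairs_df, counts, x1_mat,
                             inputs$sample_sheet$condition, totals,
                             alpha_interaction = config$alpha_interaction,
                             fdr_cutoff = config$fdr_cutoff)
  }
  funnel$reverse_correlated_pairs <-
    if (is.null(pair_calls)) 0L else sum(pair_calls$reverse_correlated)
  funnel$condition_specific_pairs <-
    if (is.null(pair_calls)) 0L else
      sum(pair_calls$condition_specific & pair_calls$fitted)

  # (7) conservation of predicted sites
  conservation <- NULL
  if (!is.null(inputs$maf) && !is.null(pair_calls) && nrow(sites)) {
    conservation <- site_conservation_stage(sites, pair_calls, inputs,
                                            transcripts, tx_strand)
    funnel$conservation_p_ranksum <- conservation$tests$p_ranksum
    funnel$conservation_p_signedrank <- conservation$tests$p_signedrank
  }

  # RPolII signal vs expression check over genes
  gene_ids <- inputs$known_genes$name
  pol_pts <- GenomicRanges::resize(inputs$chip_tags, 1L, fix = "start")
  pol_counts <- GenomicRanges::countOverlaps(inputs$known_genes, pol_pts,
                                             ignore.strand = TRUE)
  pol_rpkm <- rpkm(pol_counts, GenomicRanges::width(inputs$known_genes),
                   inputs$chip_total)
  expr <- rowMeans(rpkm_mat[gene_ids, , drop = FALSE])
  rc <- if (length(gene_ids) >= 4) rank_correlation(pol_rpkm, expr) else
    list(rho = NA_real_, p = NA_real_)
  funnel$rpolii_expression_rho <- rc$rho

  run <- structure(list(
    config = config, funnel = funnel, regions = regions,
    transcripts = transcripts, tx_seq = tx_seq, tx_strand = tx_strand,
    sites = sites, counts = counts, rpkm = rpkm_mat,
    detectable = detectable, x1 = x1_mat, pair_calls = pair_calls,
    conservation = conservation, qc_tally = qc$tally,
    sample_sheet = inputs$sample_sheet, truth = truth
  ), class = "lincmir_run")
  if (!is.null(config$out_dir)) persist_run(run, config$out_dir)
  run
}

#' Load pipeline inputs from a directory of standard-format files
#'
#' Reads the file layout written by [simulate_dataset()] (`genome.fa`,
#' `known_genes.bed`, `k436_human.bed`, `k436_mouse_lifted.bed`,
#' `rpolii_tags.bed`, `mirnas_mature.fa`, `pre_mirnas.bed`,
#' `aln_<sample>.bed12`, `unmapped_<sample>.fastq`, `sample_sheet.tsv`,
#' `csf_alignments.tsv`, `csf_matrix.tsv`, `alignment.maf`, `tree.nwk`)
#' into the input bundle [run_pipeline()] consumes.
#'
#' @param dir directory containing the input files.
#' @param read_length read length of the libraries (default 50).
#' @return the input bundle list (see [run_pipeline()]).
#' @export
load_pipeline_inputs <- function(dir, read_length = 50L) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", p)
    p
  }
  genome <- read_genome(need("genome.fa"))
  sample_sheet <- read_tsv(need("sample_sheet.tsv"))
  aln <- do.call(rbind, lapply(sample_sheet$sample_id, function(s) {
    read_bed12(need(sprintf("aln_%s.bed12", s)), sample_id = s)
  }))
  unmapped <- do.call(rbind, lapply(sample_sheet$sample_id, function(s) {
    u <- read_fastq(need(sprintf("unmapped_%s.fastq", s)))
    if (nrow(u)) cbind(sample_id = s, u) else NULL
  }))
  chip_tags <- read_bed(need("rpolii_tags.bed"))
  pre <- read_bed(need("pre_mirnas.bed"))
  csf_matrix <- as.matrix(utils::read.delim(need("csf_matrix.tsv"),
                                            row.names = 1,
                                            check.names = FALSE))
  list(
    genome = genome, chrom = names(genome)[1],
    known_genes = read_bed(need("known_genes.bed")),
    k436_human = read_bed(need("k436_human.bed")),
    k436_mouse = read_bed(need("k436_mouse_lifted.bed")),
    chip_tags = chip_tags, chip_total = length(chip_tags),
    mirnas = read_mirnas(need("mirnas_mature.fa")),
    pre_mirna = data.frame(mirna_id = pre$name,
                           start = GenomicRanges::start(pre),
                           end = GenomicRanges::end(pre)),
    aln = aln, unmapped = unmapped, sample_sheet = sample_sheet,
    csf_aln = read_tsv(need("csf_alignments.tsv")),
    csf_matrix = csf_matrix,
    maf = read_maf(need("alignment.maf")),
    tree = ape::read.tree(need("tree.nwk")),
    read_length = read_length
  )
}

# bundle an in-memory simulate_dataset() result into pipeline inputs
dataset_inputs <- function(ds) {
  truth <- ds$truth
  list(
    genome = truth$genome, chrom = truth$chrom,
    known_genes = GenomicRanges::GRanges(
      truth$chrom, IRanges::IRanges(truth$genes$start, truth$genes$end),
      strand = truth$genes$strand, name = truth$genes$gene_id),
    k436_human = truth$k436_human, k436_mouse = truth$k436_mouse,
    chip_tags = truth$chip_tags, chip_total = truth$chip_total,
    mirnas = truth$mirnas, pre_mirna = truth$pre_mirna,
    aln = ds$reads$aln, unmapped = ds$reads$unmapped,
    sample_sheet = ds$reads$sample_sheet,
    csf_aln = truth$csf_aln, csf_matrix = truth$csf_matrix,
    maf = ds$maf$maf, tree = ds$maf$tree,
    read_length = truth$cfg$read_length
  )
}

region_csf_scores <- function(regions, csf_aln, csf_matrix) {
  vapply(seq_along(regions), function(i) {
    hit <- which(csf_aln$start == GenomicRanges::start(regions)[i] &
                   csf_aln$end == GenomicRanges::end(regions)[i])
    if (!length(hit)) {
      hit <- which(csf_aln$start <= GenomicRanges::end(regions)[i] &
                     csf_aln$end >= GenomicRanges::start(regions)[i])
    }
    if (!length(hit)) return(0)
    as.numeric(csf_score(c(csf_aln$ref[hit[1]], csf_aln$alt[hit[1]]),
                         csf_matrix))
  }, numeric(1))
}

assemble_regions <- function(blocks, regions, genome, qc_reads, config,
                             read_length) {
  all_exons <- GenomicRanges::GRanges()
  lib_list <- list()
  for (i in seq_along(regions)) {
    ex <- call_putative_exons(blocks, regions[i],
                              min_reads = config$min_reads,
                              merge_gap = config$merge_gap)
    if (length(ex) == 0L) next
    ss <- find_splice_sites(genome, ex, search = config$splice_search)
    offset <- length(all_exons)
    ss$donors$exon <- ss$donors$exon + offset
    ss$acceptors$exon <- ss$acceptors$exon + offset
    lib <- build_junction_library(ss$donors, ss$acceptors, genome,
                                  flank = read_length - 1L,
                                  max_span = config$max_span,
                                  min_intron = config$min_intron)
    if (nrow(lib)) lib_list[[length(lib_list) + 1L]] <- lib
    all_exons <- c(all_exons, ex)
  }
  library <- if (length(lib_list)) do.call(rbind, lib_list) else
    build_junction_library(
      data.frame(exon = integer(0), chrom = character(0), pos = integer(0),
                 motif = character(0), strand = character(0)),
      data.frame(exon = integer(0), chrom = character(0), pos = integer(0),
                 motif = character(0), strand = character(0)),
      genome, flank = read_length - 1L)
  if (nrow(library)) {
    library$junction_id <- sprintf("jx%05d", seq_len(nrow(library)))
  }
  mm <- match_junction_reads(qc_reads$seq, library,
                             anchor = config$anchor,
                             max_mismatch = config$max_mismatch)
  library$support <- mm$support$support
  list(
    transcripts = assemble_transcripts(all_exons, library),
    exons = all_exons, library = library, junction_support = mm$support
  )
}

site_conservation_stage <- function(sites, pair_calls, inputs, transcripts,
                                    tx_strand) {
  pair_key <- paste(sites$mirna_id, sites$lincrna_id, sep = ":")
  rc_pairs <- pair_calls$pair_id[pair_calls$reverse_correlated]
  fitted_pairs <- pair_calls$pair_id[pair_calls$fitted]
  is_rc <- pair_key %in% rc_pairs
  is_other <- pair_key %in% setdiff(fitted_pairs, rc_pairs)
  omega_site <- score_site_blocks_omega(inputs$maf, inputs$tree,
                                        inputs$chrom, sites$genomic_blocks)
  # paired upstream controls for the reverse-correlated sites
  up_omega <- rep(NA_real_, nrow(sites))
  idx_rc <- which(is_rc)
  if (length(idx_rc)) {
    for (i in idx_rc) {
      txi <- match(sites$lincrna_id[i], names(transcripts))
      ctrl <- upstream_control_sites(sites[i, , drop = FALSE],
                                     exons = transcripts[[txi]],
                                     strand = tx_strand[txi])
      if (nrow(ctrl)) {
        up_omega[i] <- score_site_blocks_omega(inputs$maf, inputs$tree,
                                               inputs$chrom,
                                               ctrl$genomic_blocks)
      }
    }
  }
  ok_rc <- is_rc & is.finite(omega_site)
  ok_other <- is_other & is.finite(omega_site)
  paired_ok <- ok_rc & is.finite(up_omega)
  tests <- list(p_ranksum = NA_real_, p_signedrank = NA_real_)
  if (sum(ok_rc) >= 3 && sum(ok_other) >= 3) {
    tests <- compare_site_conservation(
      omega_site[ok_rc], omega_site[ok_other],
      omega_upstream = NULL
    )
    tests$p_signedrank <- NA_real_
  }
  if (sum(paired_ok) >= 3) {
    sr <- stats::wilcox.test(omega_site[paired_ok], up_omega[paired_ok],
                             paired = TRUE, exact = FALSE)
    tests$p_signedrank <- sr$p.value
    tests$median_upstream <- stats::median(up_omega[paired_ok])
  }
  list(
    tests = tests,
    table = data.frame(sites, omega = omega_site, upstream_omega = up_omega,
                       reverse_correlated = is_rc,
                       stringsAsFactors = FALSE)
  )
}

persist_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(run$regions, file.path(out_dir, "candidate_regions.bed"))
  tx <- run$transcripts
  if (length(tx)) {
    bl <- do.call(rbind, lapply(seq_along(tx), function(i) {
      data.frame(read_id = names(tx)[i],
                 chrom = as.character(GenomicRanges::seqnames(tx[[i]])),
                 start = GenomicRanges::start(tx[[i]]),
                 end = GenomicRanges::end(tx[[i]]),
                 strand = run$tx_strand[i])
    }))
    write_bed12(bl, file.path(out_dir, "lincrnas.bed12"))
  }
  write_tsv(run$sites, file.path(out_dir, "seed_sites.tsv"))
  utils::write.table(run$counts, file.path(out_dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(run$rpkm, file.path(out_dir, "rpkm.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(run$pair_calls)) {
    write_tsv(run$pair_calls, file.path(out_dir, "pair_calls.tsv"))
  }
  if (!is.null(run$conservation)) {
    write_tsv(run$conservation$table,
              file.path(out_dir, "site_conservation.tsv"))
  }
  write_tsv(run$qc_tally, file.path(out_dir, "qc_tally.tsv"))
  jsonlite::write_json(run$funnel, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.lincmir_run <- function(x, ...) {
  cat("lincRNA discovery / miRNA reverse-correlation run\n")
  f <- x$funnel
  fmt <- function(k) if (is.null(f[[k]])) "-" else format(f[[k]])
  cat(sprintf("  candidate regions:        %s\n", fmt("candidate_regions")))
  cat(sprintf("  RPolII > threshold:       %s\n", fmt("rpolii_passed")))
  cat(sprintf("  CSF <= cutoff:            %s\n", fmt("csf_passed")))
  cat(sprintf("  assembled transcripts:    %s (%s multi-exon)\n",
              fmt("assembled_transcripts"), fmt("multi_exon_transcripts")))
  cat(sprintf("  predicted sites / pairs:  %s / %s\n",
              fmt("predicted_sites"), fmt("predicted_pairs")))
  cat(sprintf("  eligible pairs:           %s\n", fmt("eligible_pairs")))
  cat(sprintf("  reverse-correlated:       %s\n",
              fmt("reverse_correlated_pairs")))
  cat(sprintf("  condition-specific:       %s\n",
              fmt("condition_specific_pairs")))
  if (!is.null(f$conservation_p_ranksum)) {
    cat(sprintf("  conservation rank-sum p:  %.3g, signed-rank p: %.3g\n",
                f$conservation_p_ranksum,
                if (is.null(f$conservation_p_signedrank) ||
                    is.na(f$conservation_p_signedrank)) NA
                else f$conservation_p_signedrank))
  }
  invisible(x)
}
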