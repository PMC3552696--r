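# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles are written from the rule statements directly, with
# plain loops, and never call the implementation they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

random_read <- function(len = 50L, n_prob = 0.03) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  bases[runif(len) < n_prob] <- "N"
  list(bases = paste(bases, collapse = ""),
       quals = sample(0:41, len, replace = TRUE))
}

# qc rules, literal loops
oracle_qc <- function(bases, quals, n_max = 2L, window = 5L,
                      min_avg_q = 20, min_len = 35L) {
  n <- nchar(bases)
  if (sum(strsplit(bases, "")[[1]] == "N") > n_max) return("discarded_n")
  keep <- n
  if (n >= window) {
    for (i in 1:(n - window + 1L)) {
      if (mean(quals[i:(i + window - 1L)]) < min_avg_q) {
        keep <- i - 1L
        break
      }
    }
  }
  if (keep < min_len) return("discarded_short")
  keep
}

# coverage islands + gap merge to fixpoint + distinct-read support
oracle_exons <- function(starts, ends, read_ids, region_start, region_end,
                         min_reads = 8L, merge_gap = 10L) {
  inr <- ends >= region_start & starts <= region_end
  starts <- starts[inr]; ends <- ends[inr]; read_ids <- read_ids[inr]
  if (!length(starts)) return(NULL)
  lo <- min(starts); hi <- max(ends)
  cov <- rep(FALSE, hi - lo + 1L)
  for (i in seq_along(starts)) {
    cov[(starts[i] - lo + 1L):(ends[i] - lo + 1L)] <- TRUE
  }
  r <- rle(cov)
  pos <- cumsum(c(0L, r$lengths))
  iv <- cbind(pos[-length(pos)][r$values] + lo,
              pos[-1L][r$values] + lo - 1L)
  repeat {
    merged <- FALSE
    k <- 1L
    while (k < nrow(iv)) {
      if (iv[k + 1L, 1] - iv[k, 2] - 1L < merge_gap) {
        iv[k, 2] <- iv[k + 1L, 2]
        iv <- iv[-(k + 1L), , drop = FALSE]
        merged <- TRUE
      } else k <- k + 1L
    }
    if (!merged) break
  }
  out <- NULL
  for (k in seq_len(nrow(iv))) {
    sup <- length(unique(read_ids[ends >= iv[k, 1] & starts <= iv[k, 2]]))
    if (sup >= min_reads) out <- rbind(out, c(iv[k, ], sup))
  }
  out
}

# count of valid (donor, acceptor) pairs under the junction rules
oracle_junction_count <- function(donors, acceptors, max_span = 100000L,
                                  min_intron = 70L) {
  motif_pairs <- c(GT = "AG", CT = "AC")
  n <- 0L
  for (i in seq_len(nrow(donors))) {
    for (j in seq_len(nrow(acceptors))) {
      if (donors$chrom[i] != acceptors$chrom[j]) next
      if (motif_pairs[donors$motif[i]] != acceptors$motif[j]) next
      intron <- acceptors$pos[j] - donors$pos[i] + 1L
      if (intron >= min_intron && intron <= max_span) n <- n + 1L
    }
  }
  n
}

# naive substring scan over the transcript for all three site classes
oracle_seed_matches <- function(tx, mature_rna) {
  dna <- chartr("U", "T", toupper(mature_rna))
  rc <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  m8 <- rc(substr(dna, 2, 8))
  a1 <- paste0(rc(substr(dna, 2, 7)), "A")
  L <- nchar(tx)
  out <- NULL
  for (p in seq_len(max(0L, L - 6L))) {
    if (substr(tx, p, p + 6L) == m8) {
      type <- if (p + 7L <= L && substr(tx, p + 7L, p + 7L) == "A") "8mer"
              else "7mer-m8"
      out <- rbind(out, data.frame(site_type = type, transcript_pos = p))
    }
    if (substr(tx, p, p + 6L) == a1) {
      covered <- p >= 2L && substr(tx, p - 1L, p + 6L) == paste0(m8, "A")
      if (!covered) {
        out <- rbind(out, data.frame(site_type = "7mer-A1",
                                     transcript_pos = p))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(site_type = character(0), transcript_pos = integer(0))
  }
  out[order(out$transcript_pos, out$site_type), , drop = FALSE]
}

# textbook BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# all windows x six frames, loops only
oracle_csf <- function(ref, alt, mat, window = 90L) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  score_one <- function(r, a) {
    best <- -Inf
    for (off in 0:2) {
      L <- nchar(r)
      n_cod <- (L - off) %/% 3L
      if (n_cod < 1L) next
      sc <- numeric(n_cod)
      for (k in seq_len(n_cod)) {
        i <- off + 3L * (k - 1L) + 1L
        rcod <- substr(r, i, i + 2L)
        acod <- substr(a, i, i + 2L)
        if (grepl("-", acod)) acod <- "---"
        sc[k] <- if (rcod %in% rownames(mat) && acod %in% colnames(mat)) {
          mat[rcod, acod]
        } else 0
      }
      w <- min(window %/% 3L, n_cod)
      for (s in 1:(n_cod - w + 1L)) {
        best <- max(best, sum(sc[s:(s + w - 1L)]))
      }
    }
    best
  }
  max(score_one(ref, alt), score_one(rc(ref), rc(alt)))
}

# exhaustive read-vs-library scan honoring anchors and ties
oracle_match <- function(read, lib, anchor = 8L, max_mismatch = 2L) {
  len <- nchar(read)
  best_mm <- max_mismatch + 1L
  best_jx <- character(0)
  for (j in seq_len(nrow(lib))) {
    entry <- lib$seq[j]
    fl <- lib$flank_left[j]
    for (o in seq_len(max(0L, nchar(entry) - len + 1L))) {
      if (o > fl - anchor + 1L) next
      if (o + len - 1L < fl + anchor) next
      w <- substr(entry, o, o + len - 1L)
      mm <- sum(strsplit(w, "")[[1]] != strsplit(read, "")[[1]])
      if (mm < best_mm) {
        best_mm <- mm
        best_jx <- lib$junction_id[j]
      } else if (mm == best_mm) {
        best_jx <- union(best_jx, lib$junction_id[j])
      }
    }
  }
  if (best_mm <= max_mismatch && length(best_jx) == 1L) best_jx
  else NA_character_
}

test_tree <- function() {
  ape::read.tree(
    text = "(hg:0.0,(sp2:0.19,(sp3:0.23,(sp4:0.27,sp5:0.31):0.08):0.08):0.08);"
  )
}

small_sim_config <- function(seed = 3L, ...) {
  sim_config(seed = seed, genome_length = 300000L, n_candidate_regions = 12L,
             n_true_lincrnas = 4L, n_near_gene_regions = 2L,
             n_coding_regions = 2L, n_known_genes = 4L, n_mirnas = 4L,
             n_planted_pairs = 3L, mean_depth = 15000L, ...)
}

# simulate one dataset at the repression-model level only (counts, no reads)
count_level_run <- function(seed, fdr_cutoff = 0.2) {
  cfg <- sim_config(seed = seed)
  truth <- simulate_genome(cfg)
  cm <- simulate_counts(cfg, truth)
  totals <- colSums(cm$counts)
  x1_mat <- ln_rpm(cm$counts[truth$mirnas$id, , drop = FALSE], totals)
  pairs <- truth$pairs
  pairs_df <- data.frame(
    pair_id = paste(pairs$mirna_id, pairs$lincrna_id, sep = ":"),
    target_id = pairs$lincrna_id, mirna_id = pairs$mirna_id,
    family = "lincrna", stringsAsFactors = FALSE
  )
  calls <- call_pairs(pairs_df, cm$counts, x1_mat,
                      cm$sample_sheet$condition, totals,
                      fdr_cutoff = fdr_cutoff)
  calls$planted <- pairs$planted
  calls
}
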