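# Conservation scoring via a rate-multiplier (omega) estimator.
#
# For a block of aligned columns over taxa related by a fixed tree, omega
# scales every branch length; the Jukes-Cantor likelihood of the columns is
# maximized over omega on [0, omega_max] (one shared omega per block).
# Smaller omega means fewer substitutions than the neutral tree predicts,
# i.e. stronger conservation. Gaps and Ns are treated as missing data;
# columns with gaps in more than half the taxa, or fewer than two informative
# taxa, are skipped. This shared-omega JC estimator is a deliberate
# simplification adequate for the rank-based comparisons downstream, which
# are ordinal in omega.

DNA_STATES <- c("A", "C", "G", "T")

# JC69 transition probability matrix for branch length t (expected
# substitutions per site)
jc_pmat <- function(t) {
  e <- exp(-4 * t / 3)
  p_same <- 0.25 + 0.75 * e
  p_diff <- 0.25 - 0.25 * e
  m <- matrix(p_diff, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  diag(m) <- p_same
  m
}

# Felsenstein pruning log-likelihood of pattern columns on a tree with all
# branch lengths scaled by omega. `patterns` is a 4 x npat x ntip... here:
# leaf_part is a list (by tip index) of 4 x npat partial likelihood matrices.
pruning_loglik <- function(omega, tree, leaf_part, pat_count) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  part <- vector("list", nnode)
  part[seq_len(ntip)] <- leaf_part
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge
  blen <- ord$edge.length * omega
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]
    child <- edges[k, 2]
    P <- jc_pmat(blen[k])
    contrib <- P %*% part[[child]]
    if (is.null(part[[parent]])) {
      part[[parent]] <- contrib
    } else {
      part[[parent]] <- part[[parent]] * contrib
    }
  }
  root <- edges[nrow(edges), 1]
  lik <- colSums(part[[root]] * 0.25)
  sum(pat_count * log(pmax(lik, 1e-300)))
}

#' Estimate the conservation rate multiplier of an alignment block
#'
#' Maximum-likelihood estimate of the shared rate multiplier omega of a
#' block of aligned columns under Jukes-Cantor substitution on `tree`
#' (branch lengths in expected substitutions per site at omega = 1).
#'
#' @param block character matrix, taxa x columns, of aligned bases
#'   (`A,C,G,T`; `-`, `N` and other characters are treated as missing);
#'   rownames must match the tree's tip labels (taxa missing from the block
#'   are treated as all-missing).
#' @param tree an `ape` `phylo` tree with branch lengths.
#' @param omega_max upper bound of the search interval (default 10).
#' @param tol optimization tolerance (default 1e-6).
#' @return list with `omega` (the estimate; exactly 0 for blocks with no
#'   observable substitution), `n_sites` (columns used), `n_skipped`
#'   (columns dropped by the missingness rules), `loglik`, and `defined`
#'   (`FALSE` when every column was skipped).
#' @export
estimate_omega <- function(block, tree, omega_max = 10, tol = 1e-6) {
  stopifnot(is.matrix(block), !is.null(rownames(block)))
  taxa <- tree$tip.label
  ntip <- length(taxa)
  ncol_in <- ncol(block)
  full <- matrix("N", nrow = ntip, ncol = ncol_in, dimnames = list(taxa, NULL))
  shared <- intersect(taxa, rownames(block))
  full[shared, ] <- toupper(block[shared, , drop = FALSE])
  informative <- full %in% DNA_STATES
  dim(informative) <- dim(full)
  n_info <- colSums(informative)
  gappy <- colSums(full == "-") > ntip / 2
  use <- n_info >= 2L & !gappy
  n_skipped <- sum(!use)
  if (!any(use)) {
    return(list(omega = NA_real_, n_sites = 0L, n_skipped = n_skipped,
                loglik = NA_real_, defined = FALSE))
  }
  cols <- full[, use, drop = FALSE]
  # no observable substitution anywhere -> boundary optimum omega = 0
  identical_cols <- vapply(seq_len(ncol(cols)), function(j) {
    v <- cols[informative[, use, drop = FALSE][, j], j]
    length(unique(v)) == 1L
  }, logical(1))
  if (all(identical_cols)) {
    ll <- pruning_loglik(0, tree, leaf_partials(cols), pattern_counts(cols))
    return(list(omega = 0, n_sites = sum(use), n_skipped = n_skipped,
                loglik = ll, defined = TRUE))
  }
  # pattern compression
  pat <- apply(cols, 2, paste, collapse = "")
  tab <- table(pat)
  upat <- names(tab)
  cnt <- as.numeric(tab)
  mat <- matrix(unlist(strsplit(upat, "")), nrow = nrow(cols),
                dimnames = list(rownames(cols), NULL))
  lp <- leaf_partials(mat)
  nll <- function(om) -pruning_loglik(om, tree, lp, cnt)
  opt <- stats::optimize(nll, c(0, omega_max), tol = tol)
  omega <- opt$minimum
  # boundary checks
  if (nll(omega_max) <= opt$objective) omega <- omega_max
  list(omega = omega, n_sites = sum(use), n_skipped = n_skipped,
       loglik = -nll(omega), defined = TRUE)
}

leaf_partials <- function(cols) {
  lapply(seq_len(nrow(cols)), function(i) {
    m <- matrix(1, 4, ncol(cols), dimnames = list(DNA_STATES, NULL))
    obs <- cols[i, ] %in% DNA_STATES
    if (any(obs)) {
      m[, obs] <- 0
      m[cbind(match(cols[i, obs], DNA_STATES), which(obs))] <- 1
    }
    m
  })
}

pattern_counts <- function(cols) {
  rep(1, ncol(cols))
}

#' Score genomic intervals for conservation from MAF blocks
#'
#' Collects the alignment columns overlapping each query interval (in
#' reference coordinates) from the MAF blocks and estimates one omega per
#' interval.
#'
#' @param maf list of MAF blocks ([read_maf()]); reference row first, with
#'   no gaps in the reference (as emitted by [simulate_maf()]).
#' @param tree `phylo` tree whose tip labels match the MAF taxa.
#' @param intervals `GRanges` of query intervals.
#' @param ... passed to [estimate_omega()].
#' @return data.frame with one row per interval: `omega`, `n_sites`,
#'   `defined`.
#' @export
score_intervals_omega <- function(maf, tree, intervals, ...) {
  out <- data.frame(omega = rep(NA_real_, length(intervals)),
                    n_sites = 0L, defined = FALSE)
  for (i in seq_along(intervals)) {
    cols <- maf_columns(maf,
                        as.character(GenomicRanges::seqnames(intervals)[i]),
                        GenomicRanges::start(intervals)[i],
                        GenomicRanges::end(intervals)[i])
    if (is.null(cols) || ncol(cols) == 0L) next
    est <- estimate_omega(cols, tree, ...)
    out$omega[i] <- est$omega
    out$n_sites[i] <- est$n_sites
    out$defined[i] <- est$defined
  }
  out
}

#' Extract alignment columns covering a reference interval
#'
#' @param maf list of MAF blocks ([read_maf()]), reference rows gap-free.
#' @param chrom,start,end reference interval (1-based closed).
#' @return character matrix taxa x columns, or `NULL` when uncovered.
#' @export
maf_columns <- function(maf, chrom, start, end) {
  cols <- NULL
  for (b in maf) {
    if (b$chrom != chrom || b$start > end || b$start + b$width - 1L < start) {
      next
    }
    lo <- max(start, b$start) - b$start + 1L
    hi <- min(end, b$start + b$width - 1L) - b$start + 1L
    sub <- vapply(b$seqs, function(x) substr(x, lo, hi), "")
    m <- do.call(rbind, strsplit(sub, ""))
    rownames(m) <- names(b$seqs)
    cols <- if (is.null(cols)) m else cbind(cols, m)
  }
  cols
}

#' Estimate omega for sites given as genomic block strings
#'
#' Sites predicted on spliced transcripts may back-project to several
#' genomic blocks; the blocks' alignment columns are pooled into one
#' estimate per site.
#'
#' @param maf MAF blocks.
#' @param tree `phylo` tree.
#' @param chrom chromosome of the sites.
#' @param blocks character vector of comma-separated `start-end` block
#'   strings (as produced by [transcript_to_genomic()]).
#' @param ... passed to [estimate_omega()].
#' @return numeric vector of omega estimates (NA where undefined).
#' @export
score_site_blocks_omega <- function(maf, tree, chrom, blocks, ...) {
  vapply(blocks, function(bs) {
    cols <- NULL
    for (part in strsplit(bs, ",")[[1]]) {
      se <- as.integer(strsplit(part, "-")[[1]])
      m <- maf_columns(maf, chrom, se[1], se[2])
      if (!is.null(m)) cols <- if (is.null(cols)) m else cbind(cols, m)
    }
    if (is.null(cols) || ncol(cols) == 0L) return(NA_real_)
    estimate_omega(cols, tree, ...)$omega
  }, numeric(1), USE.NAMES = FALSE)
}

#' Compare conservation between site classes
#'
#' Two tests mirroring the standard analysis of predicted binding sites:
#' a two-sided rank-sum (Mann-Whitney) test of reverse-correlated sites
#' against other predicted sites, and a paired signed-rank (Wilcoxon) test
#' of each reverse-correlated site against its own upstream control.
#'
#' @param omega_correlated omega values at sites of reverse-correlated pairs.
#' @param omega_uncorrelated omega values at other predicted sites.
#' @param omega_upstream omega values at the 100-bp-upstream controls,
#'   paired with `omega_correlated` (same length, may be `NULL`).
#' @return list with `p_ranksum`, `p_signedrank`, and the median omega of
#'   each class; direction is readable off the medians (smaller omega =
#'   more conserved).
#' @export
compare_site_conservation <- function(omega_correlated, omega_uncorrelated,
                                      omega_upstream = NULL) {
  # exact distributions at small n without ties, normal approximation
  # otherwise (wilcox.test's default); tie fallback warnings are expected
  rs <- suppressWarnings(
    stats::wilcox.test(omega_correlated, omega_uncorrelated,
                       alternative = "two.sided")
  )
  p_sr <- NA_real_
  if (!is.null(omega_upstream)) {
    stopifnot(length(omega_upstream) == length(omega_correlated))
    sr <- suppressWarnings(
      stats::wilcox.test(omega_correlated, omega_upstream, paired = TRUE,
                         alternative = "two.sided")
    )
    p_sr <- sr$p.value
  }
  list(
    p_ranksum = rs$p.value,
    p_signedrank = p_sr,
    median_correlated = stats::median(omega_correlated, na.rm = TRUE),
    median_uncorrelated = stats::median(omega_uncorrelated, na.rm = TRUE),
    median_upstream = if (is.null(omega_upstream)) NA_real_
                      else stats::median(omega_upstream, na.rm = TRUE)
  )
}

#' Spearman rank correlation with tie-corrected p-value
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho` and `p`.
#' @export
rank_correlation <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Simulate aligned columns under Jukes-Cantor on a tree
#'
#' Evolves independent columns from a uniform root down `tree`, with every
#' branch length multiplied by the per-column rate `omega`.
#'
#' @param tree `phylo` with branch lengths.
#' @param n_col number of columns.
#' @param omega scalar or per-column rate multiplier.
#' @param root_seq optional root states (character vector length `n_col`);
#'   drawn uniformly when `NULL`.
#' @return character matrix taxa x columns of leaf states.
#' @export
simulate_jc_columns <- function(tree, n_col, omega = 1, root_seq = NULL) {
  omega <- rep_len(omega, n_col)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  if (is.null(root_seq)) {
    root_seq <- sample(DNA_STATES, n_col, replace = TRUE)
  }
  seqs[[root]] <- root_seq
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE] # preorder
  blen <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]
    child <- edges[k, 2]
    p_change <- 0.75 * (1 - exp(-4 * blen[k] * omega / 3))
    s <- seqs[[parent]]
    mut <- stats::runif(n_col) < p_change
    if (any(mut)) {
      cur <- s[mut]
      new <- vapply(cur, function(b) sample(setdiff(DNA_STATES, b), 1L), "")
      s[mut] <- new
    }
    seqs[[child]] <- s
  }
  out <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(out) <- tree$tip.label
  out
}
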