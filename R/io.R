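# File readers/writers for the formats the pipeline exchanges on disk.
# BED goes through rtracklayer, FASTA/FASTQ through Biostrings, trees through
# ape. MAF has no reader among the installed Bioconductor stack, so a minimal
# coordinate-aware parser/writer lives here.
#
# Internal coordinates are 1-based closed (the GRanges convention); BED files
# are written/read 0-based half-open as usual. rtracklayer handles the shift.

#' Read a genome FASTA into a DNAStringSet
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return a [Biostrings::DNAStringSet] named by sequence id.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write sequences to FASTA
#'
#' @param seqs a named `DNAStringSet` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a BED6 file as a GRanges
#'
#' @param path path to a BED file (3-6 columns).
#' @return a `GRanges` with `name` and `score` metadata columns when present.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write a GRanges to BED6
#'
#' @param gr a `GRanges`; `name` and `score` metadata columns are used if set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read spliced alignments or transcript models from BED12
#'
#' Each BED12 line becomes one or more rows of a blocks table: one row per
#' aligned block, sharing the line's `name` as `read_id`.
#'
#' @param path path to a BED12 file.
#' @param sample_id sample label attached to every row (default: file stem).
#' @return a data.frame with columns `read_id`, `sample_id`, `chrom`, `start`,
#'   `end` (1-based closed), `strand`.
#' @export
read_bed12 <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.bed(12)?$", "", basename(path))
  }
  gr <- rtracklayer::import(path, format = "BED")
  blocks <- gr$blocks
  if (is.null(blocks)) { # plain BED6: single-block records
    return(data.frame(
      read_id = as.character(gr$name), sample_id = sample_id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    ))
  }
  nb <- lengths(blocks)
  ub <- unlist(blocks, use.names = FALSE)
  anchor <- rep(GenomicRanges::start(gr), nb)
  data.frame(
    read_id = rep(as.character(gr$name), nb),
    sample_id = sample_id,
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), nb),
    start = anchor + IRanges::start(ub) - 1L,
    end = anchor + IRanges::end(ub) - 1L,
    strand = rep(as.character(GenomicRanges::strand(gr)), nb),
    stringsAsFactors = FALSE
  )
}

#' Write a blocks table to BED12
#'
#' The inverse of [read_bed12()]: rows sharing a `read_id` become one BED12
#' line whose blocks are the rows in coordinate order.
#'
#' @param blocks data.frame with columns `read_id`, `chrom`, `start`, `end`
#'   (1-based closed), `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(blocks, path) {
  if (nrow(blocks) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  o <- order(blocks$read_id, blocks$start)
  b <- blocks[o, , drop = FALSE]
  first <- !duplicated(b$read_id)
  grp <- cumsum(first)
  chrom_start <- b$start[first] - 1L # 0-based
  chrom_end <- vapply(split(b$end, grp), max, integer(1))
  n_blk <- tabulate(grp)
  sizes <- vapply(split(b$end - b$start + 1L, grp),
                  function(x) paste0(paste(x, collapse = ","), ","), "")
  starts0 <- b$start - 1L - rep(chrom_start, n_blk)
  starts <- vapply(split(starts0, grp),
                   function(x) paste0(paste(x, collapse = ","), ","), "")
  lines <- paste(b$chrom[first], chrom_start, chrom_end, b$read_id[first],
                 0L, b$strand[first], chrom_start, chrom_end, "0",
                 n_blk, sizes, starts, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a reads table
#'
#' @param path path to an uncompressed FASTQ file with Sanger (phred+33)
#'   qualities.
#' @return data.frame with columns `id`, `seq`, `qual` (phred+33 string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a reads table to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Convert a phred+33 quality string to integer scores
#' @param qual character vector of quality strings.
#' @return list of integer vectors.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Convert integer quality scores to a phred+33 string
#' @param q integer vector of scores.
#' @return a quality string.
#' @export
int_to_phred <- function(q) {
  intToUtf8(q + 33L)
}

# ---- MAF ---------------------------------------------------------------

#' Read a multiple alignment file (MAF)
#'
#' Minimal MAF support: `a` lines start a block, `s` lines carry
#' `src start size strand srcSize text` with 0-based starts relative to the
#' forward strand of the source.
#'
#' @param path path to an uncompressed MAF file.
#' @return list of blocks; each block is a list with `chrom`, `start` (1-based
#'   position of the first reference column), `width` (reference bases
#'   covered), and `seqs`, a named character vector of aligned rows (the first
#'   row is the reference).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur) && length(cur$seqs)) blocks[[length(blocks) + 1L]] <- cur
    blocks
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      blocks <- flush(cur, blocks)
      cur <- list(seqs = character(0))
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      src <- f[2]; start0 <- as.integer(f[3]); size <- as.integer(f[4])
      text <- f[7]
      taxon <- sub("\\..*$", "", src)
      if (length(cur$seqs) == 0L) {
        cur$chrom <- sub("^[^.]*\\.", "", src)
        cur$start <- start0 + 1L
        cur$width <- size
      }
      cur$seqs[taxon] <- text
    }
  }
  blocks <- flush(cur, blocks)
  blocks
}

#' Write alignment blocks to MAF
#'
#' @param blocks list of blocks as returned by [read_maf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a score=0.0", con)
    taxa <- names(b$seqs)
    for (i in seq_along(b$seqs)) {
      s <- b$seqs[[i]]
      ungapped <- nchar(gsub("-", "", s))
      start0 <- if (i == 1L) b$start - 1L else 0L
      src <- paste0(taxa[i], ".", b$chrom)
      writeLines(sprintf("s %s %d %d + %d %s", src, start0, ungapped,
                         max(ungapped, b$width), s), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read/write a plain TSV
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
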