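#' Read PWMs from MEME-minimal-style text
#'
#' Parses a minimal MEME motif file (ACGT alphabet, one probability row per
#' position under each `MOTIF` header with a `letter-probability matrix`
#' line). Background frequencies are taken from a
#' `Background letter frequencies` block when present, else uniform.
#'
#' @param path file path.
#' @param pseudocount probability floor applied on load.
#' @return named list of [pwm] objects.
#' @export
read_meme <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) == 1 && bgl < length(lines)) {
    tok <- strsplit(trimws(lines[bgl + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    num <- vals[!is.na(vals)]
    if (length(num) == 4) bg <- num
  }
  starts <- grep("^MOTIF", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- s + which(grepl("letter-probability matrix", lines[(s + 1):length(lines)]))[1]
    rows <- list()
    i <- hdr + 1
    while (i <= length(lines)) {
      tok <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(tok) != 4 || any(is.na(tok))) break
      rows[[length(rows) + 1]] <- tok
      i <- i + 1
    }
    probs <- t(do.call(rbind, rows))  # 4 x L
    out[[name]] <- pwm(probs, name = name, background = bg,
                       pseudocount = pseudocount)
  }
  out
}

#' Write PWMs as MEME-minimal-style text
#'
#' @param pwms a [pwm] or list of [pwm] objects.
#' @param path output file path.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", c("A", "C", "G", "T"),
                             pwms[[1]]$background), collapse = " "),
               ""), con)
  for (m in pwms) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       pwm_length(m)), con)
    for (j in seq_len(pwm_length(m))) {
      writeLines(paste(sprintf("%.6f", m$probs[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a PWM from a plain 4 x L TSV
#'
#' Rows A, C, G, T (optionally labelled in a first column); columns are
#' positions.
#'
#' @param path file path.
#' @param name motif identifier.
#' @param ... passed to [pwm()].
#' @export
read_pwm_tsv <- function(path, name = basename(path), ...) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  if (is.character(x[[1]])) x <- x[, -1, drop = FALSE]
  pwm(as.matrix(x), name = name, ...)
}

#' Read a genome FASTA as a named character vector
#' @param path FASTA file path.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write named sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read exon intervals from BED
#'
#' @param path BED file (0-based half-open).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a signal track as position/score pairs
#'
#' Accepts a bedGraph file (each covered position of an interval receives the
#' interval's score) or a 2/3-column TSV of `[chrom,] pos, score` with
#' 0-based positions.
#'
#' @param path file path.
#' @param chrom chromosome name used when the TSV has no chrom column.
#' @return data.frame with `chrom`, `pos` (0-based), `score`.
#' @export
read_track <- function(path, chrom = "chr") {
  if (grepl("\\.(bedgraph|bg)$", tolower(path))) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    st <- GenomicRanges::start(gr) - 1L
    en <- GenomicRanges::end(gr)
    n <- sum(en - st)
    if (n > 5e6) stop("track too large to expand per-position")
    data.frame(
      chrom = rep(as.character(GenomicRanges::seqnames(gr)), en - st),
      pos = unlist(mapply(function(a, b) seq.int(a, b - 1L), st, en,
                          SIMPLIFY = FALSE)),
      score = rep(gr$score, en - st),
      stringsAsFactors = FALSE
    )
  } else {
    x <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
    if (ncol(x) == 2) x <- cbind(chrom, x)
    setNames(x, c("chrom", "pos", "score"))
  }
}

#' Read a TF expression table
#'
#' @param path TSV with columns `gene`, `stage`, `level` (header optional).
#' @return data.frame with those columns.
#' @export
read_expression <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE,
                  stringsAsFactors = FALSE)
  if (!all(c("gene", "stage", "level") %in% names(x))) {
    x <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
    names(x) <- c("gene", "stage", "level")[seq_len(ncol(x))]
  }
  x
}

#' Write a ChIP dataset to TSV (+ FASTA of window sequences)
#'
#' @param dataset a `chip_dataset` (see [build_dataset()]).
#' @param path output TSV path; the FASTA is written next to it.
#' @export
write_dataset <- function(dataset, path) {
  w <- dataset$windows
  write.table(w, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ids <- sprintf("%s:%d-%d", w$chrom, w$start, w$end)
  write_fasta(setNames(dataset$seqs, ids), sub("\\.tsv$", ".fa", path))
  invisible(path)
}
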