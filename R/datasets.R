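#' Smooth a signal track into 500 bp windows on a 50 bp grid
#'
#' Each raw position/score pair is mapped to the nearest genomic position
#' that is a multiple of `step`; the score of a window is the mean of all
#' mapped scores inside it. Windows start at every multiple of `step` and
#' have length `window`; windows with no mapped scores score 0.
#'
#' @param track data.frame with `chrom`, `pos` (0-based), `score` (see
#'   [read_track()]).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param window window length in bp.
#' @param step grid step in bp.
#' @return data.frame with `chrom`, `start`, `end`, `score`, one row per
#'   gridded window.
#' @export
smooth_track <- function(track, chrom_lengths, window = 500, step = 50) {
  if (nrow(track) > 0 && any(track$pos < 0)) stop("negative positions in track")
  k <- window / step
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n_grid <- floor(len / step) + 1L           # grid points 0, step, ...
    n_win <- max(0L, n_grid - k)               # windows fully inside
    if (n_win == 0) return(NULL)
    sums <- numeric(n_grid)
    cnts <- numeric(n_grid)
    t <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(t) > 0) {
      g <- pmin(round(t$pos / step), n_grid - 1L) + 1L
      sums <- as.numeric(tapply(t$score, factor(g, levels = 1:n_grid), sum))
      sums[is.na(sums)] <- 0
      cnts <- as.numeric(table(factor(g, levels = 1:n_grid)))
    }
    cs <- cumsum(c(0, sums))
    cc <- cumsum(c(0, cnts))
    i <- seq_len(n_win)
    wsum <- cs[i + k] - cs[i]
    wcnt <- cc[i + k] - cc[i]
    score <- ifelse(wcnt > 0, wsum / wcnt, 0)
    data.frame(chrom = ch, start = (i - 1L) * step, end = (i - 1L) * step + window,
               score = score, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.overlaps_any <- function(start, end, sel_start, sel_end) {
  if (length(sel_start) == 0) return(FALSE)
  any(start < sel_end & end > sel_start)
}

#' Build a peak / non-peak ChIP dataset
#'
#' Selects the `n_peaks` highest-scoring mutually non-overlapping windows as
#' peaks (greedy by descending score, ties broken by genomic coordinate),
#' then draws `n_nonpeaks` non-overlapping, non-exonic windows uniformly
#' without replacement from the remainder of the genome (or from a supplied
#' pool of other TFs' peak windows). Window sequences are attached from the
#' genome.
#'
#' @param window_scores output of [smooth_track()].
#' @param genome named character vector of chromosome sequences (see
#'   [read_genome()]).
#' @param exons optional exon intervals (data.frame `chrom`, `start`, `end`);
#'   windows overlapping any exon by >= 1 bp are excluded from the non-peak
#'   pool.
#' @param n_peaks,n_nonpeaks dataset sizes (paper scale: 1000 + 1000).
#' @param negative_mode `"random_noncoding"` (default) or `"other_tf_peaks"`.
#' @param other_peaks window data.frame (`chrom`, `start`, `end`, `score`)
#'   used as the non-peak pool when `negative_mode = "other_tf_peaks"`.
#' @param seed RNG seed for the non-peak draw.
#' @param name dataset name (`TF_SRC_STAGE` convention).
#' @return A `chip_dataset`: list with `name`, `windows` (data.frame `chrom`,
#'   `start`, `end`, `label`, `chip`, `accessibility`, `accessible`) and
#'   `seqs` (character vector aligned with `windows`).
#' @export
build_dataset <- function(window_scores, genome, exons = NULL,
                          n_peaks = 1000, n_nonpeaks = 1000,
                          negative_mode = c("random_noncoding",
                                            "other_tf_peaks"),
                          other_peaks = NULL, seed = 1, name = "dataset") {
  negative_mode <- match.arg(negative_mode)
  ws <- window_scores[order(-window_scores$score, window_scores$chrom,
                            window_scores$start), , drop = FALSE]
  # greedy non-overlapping peak selection
  sel <- integer(0)
  occ <- lapply(unique(ws$chrom), function(ch) list(start = numeric(0),
                                                    end = numeric(0)))
  names(occ) <- unique(ws$chrom)
  for (i in seq_len(nrow(ws))) {
    ch <- ws$chrom[i]
    if (!.overlaps_any(ws$start[i], ws$end[i], occ[[ch]]$start,
                       occ[[ch]]$end)) {
      sel <- c(sel, i)
      occ[[ch]]$start <- c(occ[[ch]]$start, ws$start[i])
      occ[[ch]]$end <- c(occ[[ch]]$end, ws$end[i])
      if (length(sel) == n_peaks) break
    }
  }
  if (length(sel) < n_peaks) {
    stop(sprintf("only %d non-overlapping peaks available (need %d)",
                 length(sel), n_peaks))
  }
  peaks <- ws[sel, , drop = FALSE]

  # non-peak pool
  if (negative_mode == "other_tf_peaks") {
    if (is.null(other_peaks)) stop("`other_peaks` required for this mode")
    pool <- other_peaks
  } else {
    pool <- window_scores
  }
  # exclude windows overlapping selected peaks or exons
  keep <- vapply(seq_len(nrow(pool)), function(i) {
    ch <- pool$chrom[i]
    if (ch %in% names(occ) &&
        .overlaps_any(pool$start[i], pool$end[i], occ[[ch]]$start,
                      occ[[ch]]$end)) return(FALSE)
    if (!is.null(exons)) {
      ex <- exons[exons$chrom == ch, , drop = FALSE]
      if (nrow(ex) > 0 &&
          .overlaps_any(pool$start[i], pool$end[i], ex$start, ex$end)) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  pool <- pool[keep, , drop = FALSE]

  set.seed(seed)
  ord <- sample.int(nrow(pool))
  np_occ <- lapply(names(occ), function(ch) list(start = numeric(0),
                                                 end = numeric(0)))
  names(np_occ) <- names(occ)
  np_sel <- integer(0)
  for (i in ord) {
    ch <- pool$chrom[i]
    if (is.null(np_occ[[ch]])) np_occ[[ch]] <- list(start = numeric(0),
                                                    end = numeric(0))
    if (!.overlaps_any(pool$start[i], pool$end[i], np_occ[[ch]]$start,
                       np_occ[[ch]]$end)) {
      np_sel <- c(np_sel, i)
      np_occ[[ch]]$start <- c(np_occ[[ch]]$start, pool$start[i])
      np_occ[[ch]]$end <- c(np_occ[[ch]]$end, pool$end[i])
      if (length(np_sel) == n_nonpeaks) break
    }
  }
  if (length(np_sel) < n_nonpeaks) {
    stop(sprintf("only %d non-peak windows available (need %d)",
                 length(np_sel), n_nonpeaks))
  }
  nonpeaks <- pool[np_sel, , drop = FALSE]

  windows <- rbind(
    data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
               label = "peak", chip = peaks$score, stringsAsFactors = FALSE),
    data.frame(chrom = nonpeaks$chrom, start = nonpeaks$start,
               end = nonpeaks$end, label = "nonpeak", chip = nonpeaks$score,
               stringsAsFactors = FALSE)
  )
  windows$accessibility <- NA_real_
  windows$accessible <- NA
  seqs <- vapply(seq_len(nrow(windows)), function(i) {
    substr(genome[[windows$chrom[i]]], windows$start[i] + 1, windows$end[i])
  }, character(1))
  structure(list(name = name, windows = windows, seqs = seqs),
            class = "chip_dataset")
}

#' @export
print.chip_dataset <- function(x, ...) {
  cat(sprintf("chip_dataset '%s': %d peaks + %d non-peaks\n", x$name,
              sum(x$windows$label == "peak"),
              sum(x$windows$label == "nonpeak")))
  invisible(x)
}

#' Select the primary motif for a dataset
#'
#' Fits a single-motif model for each candidate PWM by cross-validation and
#' returns the candidate with the highest cross-validated Pearson
#' correlation with the ChIP scores (ties: first by input order).
#'
#' @param candidates list of [pwm] objects.
#' @param dataset a `chip_dataset`.
#' @param config a [stap_config()].
#' @param folds fold assignment from [make_cv_folds()]; generated with
#'   `config$seed` when `NULL`.
#' @return the winning [pwm], with the per-candidate CCs in attribute `"cc"`.
#' @export
select_primary_motif <- function(candidates, dataset,
                                 config = stap_config("single"),
                                 folds = NULL) {
  if (length(candidates) < 1) stop("no candidate motifs")
  if (is.null(folds)) {
    folds <- make_cv_folds(dataset$windows$label, k = config$k,
                           seed = config$seed)
  }
  ccs <- vapply(candidates, function(m) {
    fit <- try(cross_validate_stap(dataset, list(m), config, folds),
               silent = TRUE)
    if (inherits(fit, "try-error")) NA_real_ else fit$cc
  }, numeric(1))
  if (all(is.na(ccs))) stop("all candidate motifs failed to fit")
  best <- which.max(ccs)
  structure(candidates[[best]], cc = ccs)
}

#' Rank secondary-motif candidates by TF expression
#'
#' Ranks the TFs in a motif catalog by their expression in the requested
#' developmental stage(s): expression is log1p-transformed, z-normalized
#' within each stage, averaged across stages, and sorted in decreasing
#' order. Motifs of heterodimeric complexes are excluded. The motifs of the
#' top `top_fraction` of ranked TFs are returned.
#'
#' @param expression data.frame with `gene`, `stage`, `level`.
#' @param stages stage identifiers to use.
#' @param motif_catalog named list of [pwm] objects (names or `$tf` fields
#'   give the TF gene).
#' @param top_fraction fraction of the ranked list to keep (paper settings:
#'   0.10-0.15, 0.25, 0.50).
#' @return ordered list of [pwm] objects (highest-expressed TF first).
#' @export
rank_secondary_candidates <- function(expression, stages, motif_catalog,
                                      top_fraction = 0.10) {
  if (!all(stages %in% expression$stage)) {
    stop("expression table does not cover all requested stages")
  }
  motif_catalog <- Filter(function(m) !isTRUE(m$heterodimer), motif_catalog)
  tfs <- vapply(motif_catalog, function(m) m$tf, character(1))
  e <- expression[expression$stage %in% stages, , drop = FALSE]
  e$z <- stats::ave(log1p(e$level), e$stage,
                    FUN = function(v) (v - mean(v)) / sd(v))
  score <- tapply(e$z, e$gene, mean)
  score <- score[match(tfs, names(score))]
  score[is.na(score)] <- -Inf
  ord <- order(-score)
  n_keep <- ceiling(top_fraction * length(motif_catalog))
  motif_catalog[ord][seq_len(n_keep)]
}

#' Attach accessibility scores and flags to a dataset
#'
#' Smooths an accessibility track with the same 500 bp / 50 bp convention as
#' the ChIP track, assigns each dataset window its accessibility score
#' (0 when the track does not cover it), and flags a window accessible when
#' its score is at or above the given percentile of all dataset windows
#' (ties at the threshold are accessible).
#'
#' @param dataset a `chip_dataset`.
#' @param accessibility_track data.frame `chrom`, `pos`, `score`, or an
#'   already-smoothed window table (`chrom`, `start`, `end`, `score`).
#' @param chrom_lengths named chromosome lengths (needed when smoothing).
#' @param percentile accessibility threshold percentile (default 0.90).
#' @return the dataset with `accessibility` and `accessible` filled in.
#' @export
attach_accessibility <- function(dataset, accessibility_track,
                                 chrom_lengths = NULL, percentile = 0.90) {
  if (all(c("start", "end", "score") %in% names(accessibility_track))) {
    sm <- accessibility_track
  } else {
    if (is.null(chrom_lengths)) stop("`chrom_lengths` needed to smooth track")
    sm <- smooth_track(accessibility_track, chrom_lengths)
  }
  key <- paste(sm$chrom, sm$start)
  idx <- match(paste(dataset$windows$chrom, dataset$windows$start), key)
  acc <- sm$score[idx]
  missing <- is.na(acc)
  acc[missing] <- 0
  thr <- quantile(acc, percentile, names = FALSE)
  dataset$windows$accessibility <- acc
  dataset$windows$accessible <- acc >= thr
  attr(dataset, "accessibility_uncovered") <- sum(missing)
  dataset
}
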