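#' Adjacent heterotypic site pairs and their spacings
#'
#' Scans each segment for sites of both motifs at a fixed per-site score
#' p-value threshold (the FIMO-style e^-7 default, converted to an exact LLR
#' threshold under the background model), orders all sites by start
#' coordinate, and returns every pair of consecutive sites belonging to
#' different motifs together with the gap (end of the left site to start of
#' the right site, in bp; negative for overlapping sites).
#'
#' @param segments character vector of segment sequences.
#' @param m1,m2 [pwm] objects for the primary and secondary motif.
#' @param alpha per-site score p-value threshold (default `exp(-7)`).
#' @param sites optional precomputed site list (as returned in the `sites`
#'   attribute) to skip rescanning.
#' @return data.frame with `segment`, `spacing`, `left_motif`, `right_motif`;
#'   the per-segment site tables are attached as attribute `"sites"`.
#' @export
heterotypic_pairs <- function(segments, m1, m2, alpha = exp(-7),
                              sites = NULL) {
  if (m1$name == m2$name) stop("motifs must be distinct")
  if (is.null(sites)) {
    t1 <- llr_threshold_pvalue(m1, alpha)
    t2 <- llr_threshold_pvalue(m2, alpha)
    sites <- lapply(segments, function(s) {
      a <- scan_sites(m1, s, llr_min = t1)
      b <- scan_sites(m2, s, llr_min = t2)
      d <- rbind(a, b)
      d[order(d$start, d$end), , drop = FALSE]
    })
  }
  out <- lapply(seq_along(sites), function(i) {
    d <- sites[[i]]
    if (nrow(d) < 2) return(NULL)
    j <- seq_len(nrow(d) - 1)
    het <- d$motif[j] != d$motif[j + 1]
    if (!any(het)) return(NULL)
    data.frame(segment = i,
               spacing = d$start[j + 1][het] - d$end[j][het],
               left_motif = d$motif[j][het],
               right_motif = d$motif[j + 1][het],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(segment = integer(0), spacing = numeric(0),
                      left_motif = character(0), right_motif = character(0))
  }
  attr(out, "sites") <- sites
  out
}

#' Shuffled-site background for spacing tests
#'
#' For each segment, redraws the positions of its predicted sites uniformly
#' at random without overlap, preserving the number of sites, their motif
#' identities and their lengths; adjacent heterotypic pair spacings are then
#' recomputed. `n_randomizations` such data sets are pooled.
#'
#' @param sites per-segment site tables (the `"sites"` attribute of
#'   [heterotypic_pairs()]).
#' @param segment_lengths segment lengths in bp.
#' @param n_randomizations number of pooled randomized data sets.
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling attempts per segment before error.
#' @return data.frame of background pair spacings (columns as in
#'   [heterotypic_pairs()], plus `randomization`).
#' @export
shuffle_site_background <- function(sites, segment_lengths,
                                    n_randomizations = 10, seed = 1,
                                    max_attempts = 1000) {
  .with_seed(seed, {
    pooled <- lapply(seq_len(n_randomizations), function(r) {
      shuf <- lapply(seq_along(sites), function(i) {
        d <- sites[[i]]
        if (nrow(d) < 2) return(d)
        lens <- d$end - d$start
        L <- segment_lengths[i]
        for (att in seq_len(max_attempts)) {
          st <- vapply(lens, function(l) sample.int(L - l + 1, 1) - 1,
                       numeric(1))
          en <- st + lens
          o <- order(st, en)
          if (all(en[o][-length(o)] <= st[o][-1])) {
            d2 <- d
            d2$start <- st
            d2$end <- en
            return(d2[o, , drop = FALSE])
          }
        }
        stop(sprintf("could not place %d sites in segment %d without overlap",
                     nrow(d), i))
      })
      p <- heterotypic_pairs(NULL, list(name = "a"), list(name = "b"),
                             sites = shuf)
      if (nrow(p) > 0) p$randomization <- r
      p
    })
    out <- do.call(rbind, pooled)
    if (is.null(out)) {
      out <- data.frame(segment = integer(0), spacing = numeric(0),
                        left_motif = character(0),
                        right_motif = character(0),
                        randomization = integer(0))
    }
    out
  })
}

#' One-tailed Fisher test for spacing enrichment in one bin
#'
#' Builds the 2x2 table (observed vs background) x (spacing in bin vs out of
#' bin) and returns the one-tailed (enrichment) Fisher exact p-value.
#'
#' @param observed_spacings spacings (bp) of observed adjacent heterotypic
#'   pairs.
#' @param background_spacings spacings from [shuffle_site_background()].
#' @param bin length-2 inclusive spacing range `[lo, hi]` in bp (the bins
#'   tested are `[1,2], [2,3], ..., [29,30]`).
#' @return list with `pvalue`, `table` (2x2 counts) and `empty_observed`
#'   flag (`pvalue = 1` when there are no observed pairs).
#' @export
spacing_bias_test <- function(observed_spacings, background_spacings, bin) {
  stopifnot(length(bin) == 2)
  oi <- sum(observed_spacings >= bin[1] & observed_spacings <= bin[2])
  oo <- length(observed_spacings) - oi
  bi <- sum(background_spacings >= bin[1] & background_spacings <= bin[2])
  bo <- length(background_spacings) - bi
  tab <- matrix(c(oi, oo, bi, bo), nrow = 2,
                dimnames = list(c("in_bin", "out_bin"),
                                c("observed", "background")))
  if (length(observed_spacings) == 0) {
    return(list(pvalue = 1, table = tab, empty_observed = TRUE))
  }
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(pvalue = p, table = tab, empty_observed = FALSE)
}

#' Scan all spacing bins for bias between two motifs
#'
#' Runs [heterotypic_pairs()], builds the shuffled-site background, and
#' applies the one-tailed Fisher test to every spacing bin. The reported
#' per-analysis p-value is the minimum over bins (no multiplicity
#' correction, matching the reporting convention of the source tables).
#'
#' @param segments character vector of segment sequences (e.g. the top-250
#'   peaks, or the bottom-250 non-peaks, analyzed separately).
#' @param m1,m2 [pwm] objects.
#' @param bins integer vector of bin left edges (bin `d` covers `[d, d+1]`).
#' @param alpha per-site score p-value threshold.
#' @param n_randomizations,seed background construction parameters.
#' @param segment_set identifier recorded in the output (e.g. `"peaks"`).
#' @return list with `per_bin` (data.frame of counts and p-values),
#'   `min_pvalue`, `best_bin`, `n_pairs`, `segment_set`.
#' @export
spacing_bias_scan <- function(segments, m1, m2, bins = 1:29,
                              alpha = exp(-7), n_randomizations = 10,
                              seed = 1, segment_set = "peaks") {
  obs <- heterotypic_pairs(segments, m1, m2, alpha)
  bg <- shuffle_site_background(attr(obs, "sites"), nchar(segments),
                                n_randomizations, seed)
  per_bin <- do.call(rbind, lapply(bins, function(d) {
    t <- spacing_bias_test(obs$spacing, bg$spacing, c(d, d + 1))
    data.frame(bin_lo = d, bin_hi = d + 1,
               obs_in = t$table[1, 1], obs_out = t$table[2, 1],
               bg_in = t$table[1, 2], bg_out = t$table[2, 2],
               pvalue = t$pvalue)
  }))
  best <- which.min(per_bin$pvalue)
  list(per_bin = per_bin, min_pvalue = per_bin$pvalue[best],
       best_bin = c(per_bin$bin_lo[best], per_bin$bin_hi[best]),
       n_pairs = nrow(obs), segment_set = segment_set)
}
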