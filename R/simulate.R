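#' Generate a random PWM with a target information content
#'
#' Draws flat-Dirichlet base columns and tempers them (raises to a power,
#' renormalizing) until the total information content matches the target;
#' the exponent is found by bisection, so the result is deterministic per
#' seed. Targets within 5% of the attainable maximum (set by the
#' pseudocount) return the sharpest attainable PWM; higher targets error.
#'
#' @param length motif length (4-20 positions).
#' @param information_bits target total information content (bits, uniform
#'   background).
#' @param seed RNG seed.
#' @param name motif identifier.
#' @param ... passed to [pwm()].
#' @return a [pwm] object whose IC is within 5% of the target.
#' @export
gen_pwm <- function(length, information_bits, seed = 1,
                    name = sprintf("sim%dx%.1f", length, information_bits),
                    ...) {
  if (length < 4 || length > 20) stop("length must be in 4..20")
  if (information_bits <= 0 || information_bits > 2 * length) {
    stop("information_bits must be in (0, 2*length]")
  }
  .with_seed(seed, {
    base <- matrix(rexp(4 * length), nrow = 4)
    base <- sweep(base, 2, colSums(base), "/")
    temper <- function(t) {
      p <- base^t
      pwm(sweep(p, 2, colSums(p), "/"), name = name, ...)
    }
    t_hi <- 60
    ic_max <- information_content(temper(t_hi))
    if (ic_max < information_bits) {
      if (ic_max >= 0.95 * information_bits) return(temper(t_hi))
      stop(sprintf("target IC %.2f bits unattainable (max %.2f)",
                   information_bits, ic_max))
    }
    lo <- 0; hi <- t_hi
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (information_content(temper(mid)) < information_bits) lo <- mid
      else hi <- mid
    }
    temper(hi)
  })
}

#' Ground-truth model for synthetic ChIP data
#'
#' Describes the stated world the generator emulates: 500 bp windows whose
#' ChIP-like scores are occupancies under a known binding model plus
#' Gaussian noise, with primary sites planted in peak-destined windows and
#' secondary sites planted according to the interaction mode (paired within
#' `d_T` for cooperative/antagonistic, overlapping the primary site for
#' competition, or acting as an accessibility "pioneer" in the mediated
#' setting).
#'
#' @param primary,secondary [pwm] objects (secondary may be `NULL` for
#'   single mode).
#' @param log10_gamma true log10 gamma per motif. The default `c(0, 2)`
#'   puts the primary TF in the sensitive, unsaturated regime (a consensus
#'   site has fractional occupancy 0.5 at gamma = 1), where interaction
#'   effects are expressed in the occupancy rather than flattened by
#'   saturation, and makes the secondary TF abundant (gamma = 100) so its
#'   planted influence on the primary is pronounced.
#' @param omega true interaction term.
#' @param d_T true distance threshold (bp).
#' @param mode interaction mode.
#' @param primary_rate mean number of extra primary sites per peak window
#'   (each peak window gets `1 + rpois(primary_rate)` planted primary
#'   sites).
#' @param pair_fraction fraction of peak windows whose first primary site is
#'   accompanied by a planted secondary site.
#' @param secondary_bg_rate Poisson rate of background secondary sites per
#'   window (all windows).
#' @param spacing_range inclusive gap range (bp) for planted pairs; default
#'   `[2, d_T - 5]`.
#' @param overlap_bp bases of overlap for competition-mode planting.
#' @param noise_sd additive Gaussian noise on the ChIP-like score.
#' @param accessibility `"independent"` (track unrelated to binding),
#'   `"coupled"` (track correlated with primary-motif occupancy), or
#'   `"mediated"` (secondary motif acts as a pioneer: windows with a planted
#'   secondary site are accessible, and the ChIP score is the primary-only
#'   occupancy gated by accessibility).
#' @param gc background GC content.
#' @return list of class `"truth_model"`.
#' @export
truth_model <- function(primary, secondary = NULL, log10_gamma = c(0, 2),
                        omega = 1, d_T = 150,
                        mode = c("single", "cooperative", "antagonistic",
                                 "competition"),
                        primary_rate = 0.5, pair_fraction = 0.6,
                        secondary_bg_rate = 0.15, spacing_range = NULL,
                        overlap_bp = 1, noise_sd = 0.15,
                        accessibility = c("independent", "coupled",
                                          "mediated"),
                        gc = 0.41) {
  mode <- match.arg(mode)
  accessibility <- match.arg(accessibility)
  if (is.null(spacing_range)) spacing_range <- c(2, max(2, d_T - 5))
  if (mode != "single" && is.null(secondary)) {
    stop("secondary motif required for mode ", mode)
  }
  structure(list(primary = primary, secondary = secondary,
                 log10_gamma = rep(log10_gamma, length.out = 2),
                 omega = omega, d_T = d_T, mode = mode,
                 primary_rate = primary_rate, pair_fraction = pair_fraction,
                 secondary_bg_rate = secondary_bg_rate,
                 spacing_range = spacing_range, overlap_bp = overlap_bp,
                 noise_sd = noise_sd, accessibility = accessibility,
                 gc = gc),
            class = "truth_model")
}

# sample a site sequence from sharpened PWM column probabilities; planted
# sites emulate the strong matches found in real ChIP peaks (exponent 2
# halves the expected LLR deficit from consensus) while retaining affinity
# diversity
.sample_site_seq <- function(pwm, sharpen = 2) {
  paste(apply(pwm$probs^sharpen, 2,
              function(p) sample(c("A", "C", "G", "T"), 1, prob = p / sum(p))),
        collapse = "")
}

.revcomp <- function(s) {
  paste(rev(.COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# place an interval of length len avoiding (with pad) existing intervals
.place <- function(len, L, taken_start, taken_end, pad = 2,
                   attempts = 50) {
  for (i in seq_len(attempts)) {
    st <- sample.int(L - len + 1, 1) - 1
    if (length(taken_start) == 0 ||
        !any(st < taken_end + pad & st + len > taken_start - pad)) {
      return(st)
    }
  }
  NA_integer_
}

#' Generate background windows with planted motif sites
#'
#' Draws i.i.d. background sequence at the truth model's GC content and
#' plants primary/secondary sites according to the truth model. The first
#' `n_peak_windows` windows are peak-destined (they receive primary sites);
#' all windows may receive background secondary sites. Planted site
#' sequences are sampled from the PWM columns, so planted affinities vary
#' realistically.
#'
#' @param n_windows total number of windows.
#' @param n_peak_windows number of peak-destined windows (default half).
#' @param length window length in bp.
#' @param truth a [truth_model()].
#' @param seed RNG seed.
#' @return list with `seqs` (character vector) and `manifest` (data.frame of
#'   planted sites: `window`, `motif`, `start`, `end`, `strand`, `kind`,
#'   `spacing`).
#' @export
gen_windows <- function(n_windows, n_peak_windows = n_windows %/% 2,
                        length = 500, truth, seed = 1) {
  L <- length
  .with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    pr <- c((1 - truth$gc) / 2, truth$gc / 2, truth$gc / 2,
            (1 - truth$gc) / 2)
    seqs <- vapply(seq_len(n_windows), function(i) {
      paste(sample(bases, L, replace = TRUE, prob = pr), collapse = "")
    }, character(1))
    man <- list()
    plant <- function(w, m, st, strand, kind, spacing = NA_real_) {
      sseq <- .sample_site_seq(m)
      if (strand == "-") sseq <- .revcomp(sseq)
      substr(seqs[w], st + 1, st + nchar(sseq)) <<- sseq
      man[[length(man) + 1]] <<- data.frame(
        window = w, motif = m$name, start = st, end = st + nchar(sseq),
        strand = strand, kind = kind, spacing = spacing,
        stringsAsFactors = FALSE)
      invisible(NULL)
    }
    L1 <- pwm_length(truth$primary)
    L2 <- if (!is.null(truth$secondary)) pwm_length(truth$secondary) else 0L
    paired <- truth$mode %in% c("cooperative", "antagonistic") ||
      truth$accessibility == "mediated"
    # keep room to the right of a primary site for its planted partner
    room <- if (!is.null(truth$secondary)) {
      if (paired) truth$spacing_range[2] + L2 + 2 else L2
    } else 0
    for (w in seq_len(n_windows)) {
      taken_s <- numeric(0); taken_e <- numeric(0)
      if (w <= n_peak_windows) {
        n_p <- 1 + rpois(1, truth$primary_rate)
        first_site <- NA
        for (k in seq_len(n_p)) {
          st <- .place(L1, L - room, taken_s, taken_e)
          if (is.na(st)) next
          plant(w, truth$primary, st, sample(c("+", "-"), 1), "primary")
          taken_s <- c(taken_s, st); taken_e <- c(taken_e, st + L1)
          if (is.na(first_site)) first_site <- st
        }
        if (!is.null(truth$secondary) && !is.na(first_site) &&
            runif(1) < truth$pair_fraction) {
          if (paired) {
            gaps <- seq(truth$spacing_range[1], truth$spacing_range[2])
            gap <- gaps[sample.int(length(gaps), 1)]
            st2 <- first_site + L1 + gap
            if (st2 + L2 <= L &&
                !any(st2 < taken_e & st2 + L2 > taken_s)) {
              plant(w, truth$secondary, st2, "+", "pair", spacing = gap)
              taken_s <- c(taken_s, st2); taken_e <- c(taken_e, st2 + L2)
            }
          } else if (truth$mode == "competition") {
            # overlap the tail of the primary site; overlapping bases are
            # drawn from the product of the two PWMs' column probabilities
            # so both sites keep appreciable affinity
            o <- truth$overlap_bp
            st2 <- first_site + L1 - o
            if (st2 + L2 <= L) {
              p2 <- truth$secondary$probs
              p1 <- truth$primary$probs
              mix <- p2
              for (j in seq_len(o)) {
                v <- p1[, L1 - o + j] * p2[, j]
                mix[, j] <- v / sum(v)
              }
              sseq <- paste(apply(mix, 2, function(p)
                sample(c("A", "C", "G", "T"), 1, prob = p)), collapse = "")
              substr(seqs[w], st2 + 1, st2 + L2) <- sseq
              man[[length(man) + 1]] <- data.frame(
                window = w, motif = truth$secondary$name, start = st2,
                end = st2 + L2, strand = "+", kind = "overlap",
                spacing = -o, stringsAsFactors = FALSE)
              taken_s <- c(taken_s, st2); taken_e <- c(taken_e, st2 + L2)
            }
          }
        }
      }
      if (!is.null(truth$secondary)) {
        n_bg <- rpois(1, truth$secondary_bg_rate)
        for (k in seq_len(n_bg)) {
          st <- .place(L2, L, taken_s, taken_e)
          if (is.na(st)) next
          plant(w, truth$secondary, st, sample(c("+", "-"), 1), "bg")
          taken_s <- c(taken_s, st); taken_e <- c(taken_e, st + L2)
        }
      }
    }
    manifest <- if (length(man) > 0) do.call(rbind, man) else
      data.frame(window = integer(0), motif = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 kind = character(0), spacing = numeric(0))
    list(seqs = seqs, manifest = manifest)
  })
}

# the binding model the truth scores windows with (mediated accessibility
# uses the primary-only model; the secondary acts through the gate)
.truth_binding_model <- function(truth) {
  if (truth$mode == "single" || truth$accessibility == "mediated") {
    binding_model(truth$primary, gamma = 10^truth$log10_gamma[1],
                  mode = "single")
  } else {
    binding_model(list(truth$primary, truth$secondary),
                  gamma = 10^truth$log10_gamma, omega = truth$omega,
                  d_T = truth$d_T, mode = truth$mode)
  }
}

#' ChIP-like scores for generated windows
#'
#' The score of a window is its expected bound primary-site count under the
#' truth binding model, plus additive Gaussian noise; in the
#' accessibility-mediated setting the occupancy is first gated by the
#' window's accessibility indicator.
#'
#' @param seqs window sequences.
#' @param truth a [truth_model()].
#' @param seed RNG seed (noise).
#' @param gate optional logical accessibility gate per window.
#' @return numeric scores.
#' @export
gen_chip_scores <- function(seqs, truth, seed = 1, gate = NULL) {
  model <- .truth_binding_model(truth)
  occ <- predict_windows(seqs, model)
  if (!is.null(gate)) occ <- occ * as.numeric(gate)
  .with_seed(seed, occ + rnorm(length(occ), 0, truth$noise_sd))
}

#' Simulate a complete peak / non-peak ChIP dataset with known truth
#'
#' Generates window sequences with planted sites ([gen_windows()]), scores
#' them under the truth model ([gen_chip_scores()]), attaches an
#' accessibility track per the truth model's accessibility setting, and
#' labels the top-scoring half as peaks. All randomness derives from `seed`.
#'
#' @param truth a [truth_model()].
#' @param n_peaks,n_nonpeaks dataset sizes.
#' @param window_length window length (bp).
#' @param seed master RNG seed.
#' @param name dataset name.
#' @return a `chip_dataset` with extra fields `truth` and `manifest`.
#' @export
simulate_chip_dataset <- function(truth, n_peaks = 200, n_nonpeaks = 200,
                                  window_length = 500, seed = 1,
                                  name = sprintf("SIM_%s_d%d", truth$mode,
                                                 truth$d_T)) {
  n <- n_peaks + n_nonpeaks
  gw <- gen_windows(n, n_peak_windows = n_peaks, length = window_length,
                    truth = truth, seed = seed)
  sec_count <- integer(n)
  if (nrow(gw$manifest) > 0 && !is.null(truth$secondary)) {
    m2 <- gw$manifest[gw$manifest$motif == truth$secondary$name, ]
    tab <- table(factor(m2$window, levels = seq_len(n)))
    sec_count <- as.integer(tab)
  }
  acc <- .with_seed(seed + 1000L, switch(
    truth$accessibility,
    independent = abs(rnorm(n, 1, 0.3)),
    coupled = {
      occ1 <- predict_windows(gw$seqs,
                              binding_model(truth$primary,
                                            gamma = 10^truth$log10_gamma[1],
                                            mode = "single"))
      occ1 + rnorm(n, 0, 1)
    },
    mediated = sec_count + rnorm(n, 0, 0.2)
  ))
  chip <- gen_chip_scores(gw$seqs, truth, seed = seed + 2000L)
  # mediated: the pioneer influences the ChIP signal only through the
  # accessibility it creates (open chromatin reads into the ChIP signal,
  # weighted like a half-occupied site), so partialing accessibility out of
  # the ChIP scores removes the secondary's influence by construction
  if (truth$accessibility == "mediated") chip <- chip + 0.5 * acc
  lab <- rep("nonpeak", n)
  lab[order(-chip)[seq_len(n_peaks)]] <- "peak"
  windows <- data.frame(
    chrom = "chrSim",
    start = (seq_len(n) - 1L) * (window_length + 100L),
    end = (seq_len(n) - 1L) * (window_length + 100L) + window_length,
    label = lab, chip = chip, accessibility = acc,
    accessible = acc >= quantile(acc, 0.9),
    stringsAsFactors = FALSE
  )
  structure(list(name = name, windows = windows, seqs = gw$seqs,
                 truth = truth, manifest = gw$manifest),
            class = "chip_dataset")
}

#' Generate a stage x gene TF expression table
#'
#' Log-normal expression levels per gene and stage; genes named in
#' `top_tfs` are forced above every other gene in every stage, so they rank
#' at the top after stage normalization.
#'
#' @param tfs character vector of TF gene names.
#' @param stages stage identifiers.
#' @param seed RNG seed.
#' @param top_tfs genes forced into the top of the ranking.
#' @return data.frame with `gene`, `stage`, `level`.
#' @export
gen_expression_table <- function(tfs, stages, seed = 1, top_tfs = NULL) {
  .with_seed(seed, {
    out <- expand.grid(gene = tfs, stage = stages, stringsAsFactors = FALSE)
    out$level <- exp(rnorm(nrow(out), 3, 1))
    if (!is.null(top_tfs)) {
      for (s in stages) {
        i <- out$stage == s
        mx <- max(out$level[i])
        out$level[i & out$gene %in% top_tfs] <- mx * 2
      }
    }
    out[order(out$stage, out$gene), ]
  })
}
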