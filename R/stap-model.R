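#' Thermodynamic binding model
#'
#' Bundles the quantities that define the occupancy model for one window:
#' one or two motifs (primary first), the concentration parameter gamma per
#' motif (the product of the consensus-site equilibrium constant and TF
#' concentration), the interaction term omega applied to adjacent bound
#' heterotypic site pairs separated by at most `d_T` bp, and the interaction
#' mode. `omega > 1` is cooperative, `omega < 1` antagonistic, `omega = 1`
#' no interaction; competitive influence at overlapping sites needs no extra
#' term because overlapping sites are never bound simultaneously.
#'
#' @param motifs a [pwm] or list of 1-2 [pwm] objects (primary first); may be
#'   `NULL` for site-level calculations that bypass scanning.
#' @param gamma positive numeric, one per motif.
#' @param omega interaction term (> 0); must be >= 1 for `"cooperative"`,
#'   <= 1 for `"antagonistic"`, and 1 for `"single"`/`"competition"`.
#' @param d_T distance threshold in bp for the interaction term (gap between
#'   site intervals; 30 = short range, 150 = long range).
#' @param mode one of `"single"`, `"cooperative"`, `"antagonistic"`,
#'   `"competition"`.
#' @param gamma_bounds allowed gamma range (default `[1, 1e4]`).
#' @return An object of class `"binding_model"`.
#' @examples
#' m <- binding_model(NULL, gamma = 1)
#' sites <- site_df(start = c(0, 20), end = c(10, 30),
#'                  rel_affinity = c(0.9, 0.5))
#' occupancy(sites, m)  # 0.807
#' @export
binding_model <- function(motifs = NULL, gamma = 1, omega = 1, d_T = 150,
                          mode = c("single", "cooperative", "antagonistic",
                                   "competition"),
                          gamma_bounds = c(1, 1e4)) {
  mode <- match.arg(mode)
  if (inherits(motifs, "pwm")) motifs <- list(motifs)
  n_motifs <- if (is.null(motifs)) length(gamma) else length(motifs)
  if (n_motifs < 1 || n_motifs > 2) stop("model takes 1 or 2 motifs")
  if (length(gamma) != n_motifs) gamma <- rep(gamma, length.out = n_motifs)
  if (any(gamma < 0)) stop("gamma must be non-negative")
  if (omega <= 0) stop("omega must be positive")
  if (mode %in% c("single", "competition") && omega != 1) {
    stop(sprintf("mode '%s' requires omega = 1", mode))
  }
  if (mode == "cooperative" && omega < 1) stop("cooperative requires omega >= 1")
  if (mode == "antagonistic" && omega > 1) stop("antagonistic requires omega <= 1")
  structure(
    list(motifs = motifs, gamma = gamma, omega = omega, d_T = d_T,
         mode = mode, gamma_bounds = gamma_bounds),
    class = "binding_model"
  )
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("binding_model: mode=%s, gamma=(%s), omega=%.3g, d_T=%d\n",
              x$mode, paste(signif(x$gamma, 3), collapse = ", "),
              x$omega, as.integer(x$d_T)))
  invisible(x)
}

#' Construct a site table directly
#'
#' Convenience constructor for site-level occupancy calculations that do not
#' go through sequence scanning (e.g. worked examples with given statistical
#' weights). Coordinates are 0-based half-open.
#'
#' @param start,end site interval bounds (bp).
#' @param rel_affinity relative affinity in (0, 1] (site weight q equals
#'   `gamma * rel_affinity`).
#' @param motif 1 for the primary motif, 2 for the secondary.
#' @export
site_df <- function(start, end, rel_affinity = 1, motif = 1) {
  data.frame(start = start, end = end,
             rel_affinity = rep(rel_affinity, length.out = length(start)),
             motif = rep(as.integer(motif), length.out = length(start)))
}

.as_sitemat <- function(sites) {
  if (is.matrix(sites)) return(sites)
  m <- cbind(sites$start, sites$end,
             if (is.null(sites$motif)) rep(1, nrow(sites)) else sites$motif,
             sites$rel_affinity)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Statistical weight of a bound site
#'
#' q(S) = gamma * exp(LLR(S) - LLR(S_max)) = gamma * rel_affinity: the
#' Boltzmann factor a bound site contributes to a configuration's weight.
#' Equals gamma for a consensus site; an isolated site's fractional
#' occupancy is q / (1 + q).
#'
#' @param site a site table row (or any object with `rel_affinity`), or a
#'   bare numeric rel_affinity vector.
#' @param gamma concentration parameter (> 0).
#' @export
site_weight <- function(site, gamma) {
  ra <- if (is.numeric(site)) site else site$rel_affinity
  gamma * ra
}

# omega factor between two sites under a model (adjacent-bound pairing is
# enforced by the caller)
.pair_omega <- function(s1, e1, m1, s2, e2, m2, model) {
  gap <- s2 - e1
  if (m1 != m2 && gap >= 0 && gap <= model$d_T) model$omega else 1
}

#' Enumerate all bound-site configurations (brute-force oracle)
#'
#' Enumerates every subset of candidate sites, discards those with
#' overlapping sites, and computes each configuration's Boltzmann weight
#' W(sigma) = product of site weights q(S) times omega for each adjacent
#' bound heterotypic pair within `d_T`. The empty configuration has weight 1.
#' Exponential in the number of sites; intended as the oracle against which
#' the dynamic program is validated.
#'
#' @param sites site table (see [site_df()] / [scan_sites()]).
#' @param model a [binding_model].
#' @return data.frame with one row per valid configuration: `weight`,
#'   `n_primary`, and a list-column `bound` of site row indices.
#' @export
enumerate_configurations <- function(sites, model) {
  m <- .as_sitemat(sites)
  n <- nrow(m)
  if (n > 25) stop("too many sites for enumeration; use occupancy() (DP)")
  ids <- list()
  weights <- numeric(0)
  nprim <- integer(0)
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(max(n - 1, 0)))) != 0L)
    if (n == 0) sel <- integer(0)
    if (length(sel) > 1) {
      o <- sel[order(m[sel, 1])]
      if (any(m[o[-length(o)], 2] > m[o[-1], 1])) next  # overlap
      sel <- o
    }
    w <- 1
    np <- 0L
    if (length(sel) > 0) {
      g <- ifelse(m[sel, 3] == 1, model$gamma[1],
                  model$gamma[min(2, length(model$gamma))])
      w <- prod(g * m[sel, 4])
      np <- sum(m[sel, 3] == 1)
      if (length(sel) > 1) {
        for (i in seq_len(length(sel) - 1)) {
          a <- sel[i]; b <- sel[i + 1]
          w <- w * .pair_omega(m[a, 1], m[a, 2], m[a, 3],
                               m[b, 1], m[b, 2], m[b, 3], model)
        }
      }
    }
    ids[[length(ids) + 1]] <- sel
    weights <- c(weights, w)
    nprim <- c(nprim, np)
  }
  out <- data.frame(weight = weights, n_primary = nprim)
  out$bound <- ids
  out
}

#' Expected bound primary-site count by configuration enumeration
#'
#' OCC = sum_sigma N(sigma) W(sigma) / sum_sigma W(sigma), where N counts
#' bound primary-motif sites. Brute-force oracle; see [occupancy()] for the
#' equivalent dynamic program.
#'
#' @inheritParams enumerate_configurations
#' @return expected number of bound primary sites (>= 0).
#' @export
occupancy_brute_force <- function(sites, model) {
  cfg <- enumerate_configurations(sites, model)
  sum(cfg$n_primary * cfg$weight) / sum(cfg$weight)
}

#' Expected bound primary-site count (dynamic program)
#'
#' Computes the same configuration average as [occupancy_brute_force()] by a
#' last-bound-site dynamic program: exact because the interaction term
#' applies only to adjacent bound pairs, and linear-time in the number of
#' candidate sites for sparse site sets.
#'
#' @inheritParams enumerate_configurations
#' @return expected number of bound primary sites (>= 0).
#' @export
occupancy <- function(sites, model) {
  m <- .as_sitemat(sites)
  g2 <- if (length(model$gamma) > 1) model$gamma[2] else model$gamma[1]
  .occ_dp_cpp(m[, 1], m[, 2], as.integer(m[, 3]), m[, 4],
              model$gamma[1], g2, model$omega, model$d_T)
}

#' Predict the occupancy (STAP score) of a sequence window
#'
#' Scans the window for sites of the model's motif(s) and returns the
#' expected number of bound primary-motif sites under the model.
#'
#' @param seq window sequence (single string).
#' @param model a [binding_model] with motifs attached.
#' @param min_rel_affinity scan threshold (see [scan_sites()]).
#' @return STAP score (>= 0).
#' @export
predict_window <- function(seq, model, min_rel_affinity = 0.01) {
  predict_windows(seq, model, min_rel_affinity)[1]
}

#' Predict occupancies for many windows
#'
#' @param seqs character vector of window sequences.
#' @param model a [binding_model] with motifs attached.
#' @param min_rel_affinity scan threshold.
#' @param sitemats optional precomputed output of an internal scan (as used
#'   by the training code) to skip rescanning.
#' @return numeric vector of STAP scores.
#' @export
predict_windows <- function(seqs, model, min_rel_affinity = 0.01,
                            sitemats = NULL) {
  if (is.null(sitemats)) {
    if (is.null(model$motifs)) stop("model has no motifs; supply `sitemats`")
    sitemats <- scan_windows(seqs, model$motifs, min_rel_affinity)
  }
  g2 <- if (length(model$gamma) > 1) model$gamma[2] else model$gamma[1]
  .predict_batch_cpp(sitemats, model$gamma[1], g2, model$omega, model$d_T)
}
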