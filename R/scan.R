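#' Scan a sequence for motif sites
#'
#' Scores every position on both strands with the PWM's log-likelihood-ratio
#' matrix and returns the sites passing the threshold. The threshold is
#' either a minimum relative affinity (`rel_affinity = exp(llr - llr_max)`,
#' so `min_rel_affinity = 0.01` keeps sites within ln(0.01) nats of the
#' consensus) or an absolute LLR floor `llr_min`, whichever is supplied
#' (`llr_min` wins). Sites overlapping a non-ACGT base are excluded.
#' Coordinates are 0-based half-open.
#'
#' @param pwm a [pwm] object.
#' @param seq sequence as a single character string.
#' @param min_rel_affinity minimum relative affinity in (0, 1]; 0 keeps all
#'   positions.
#' @param llr_min absolute LLR threshold (natural log); overrides
#'   `min_rel_affinity`. Use [llr_threshold_pvalue()] to derive one from a
#'   per-site score p-value.
#' @return data.frame with columns `motif`, `start`, `end`, `strand`, `llr`,
#'   `rel_affinity`, sorted by `start`.
#' @export
scan_sites <- function(pwm, seq, min_rel_affinity = 0.01, llr_min = NULL) {
  stopifnot(inherits(pwm, "pwm"), is.character(seq), length(seq) == 1)
  lmax <- llr_max(pwm)
  thr <- if (!is.null(llr_min)) llr_min else {
    if (min_rel_affinity <= 0) -Inf else lmax + log(min_rel_affinity)
  }
  hits <- .scan_cpp(seq, llr_matrix(pwm), thr)
  L <- pwm_length(pwm)
  out <- data.frame(
    motif = rep(pwm$name, nrow(hits)),
    start = hits$start,
    end = hits$start + L,
    strand = c("+", "-")[hits$strand + 1L],
    llr = hits$llr,
    rel_affinity = exp(hits$llr - lmax),
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

# Merge primary (and optional secondary) scan results into the internal
# site matrix used by the occupancy DP: columns start, end, motif (1/2),
# rel_affinity, sorted by start.
site_matrix <- function(primary_sites, secondary_sites = NULL) {
  m <- cbind(primary_sites$start, primary_sites$end,
             rep(1, nrow(primary_sites)), primary_sites$rel_affinity)
  if (!is.null(secondary_sites) && nrow(secondary_sites) > 0) {
    m <- rbind(m, cbind(secondary_sites$start, secondary_sites$end,
                        rep(2, nrow(secondary_sites)),
                        secondary_sites$rel_affinity))
  }
  if (is.null(m) || nrow(m) == 0) {
    return(matrix(numeric(0), ncol = 4))
  }
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Scan every window for every motif of a model; returns a list (one per
# window) of site matrices. `motifs` is a list of 1 or 2 pwm objects.
scan_windows <- function(seqs, motifs, min_rel_affinity = 0.01) {
  lapply(seqs, function(s) {
    p <- scan_sites(motifs[[1]], s, min_rel_affinity)
    q <- if (length(motifs) > 1) scan_sites(motifs[[2]], s, min_rel_affinity)
    site_matrix(p, q)
  })
}
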