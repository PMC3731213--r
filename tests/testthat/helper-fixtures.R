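# Shared fixtures and independent oracles for the test suite.

# -- small PWMs ---------------------------------------------------------------

uniform_pwm <- function(L = 4) {
  pwm(matrix(0.25, nrow = 4, ncol = L), name = "unif", pseudocount = 0)
}

# deterministic high-IC test motifs (distinct consensus sequences)
fix_primary <- function() gen_pwm(8, 11, seed = 11, name = "prim")
fix_secondary <- function() gen_pwm(8, 10, seed = 22, name = "sec")

# -- independent oracles ------------------------------------------------------

# information content by direct formula, independent of the pwm class
oracle_ic <- function(probs, bg = rep(0.25, 4)) {
  sum(probs * log2(probs / bg))
}

# Pearson correlation via the covariance formula
oracle_cc <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sd(x) * sd(y))
}

# AUC by brute-force pairwise comparison
oracle_auc <- function(scores, pos) {
  s1 <- scores[pos]
  s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# semi-partial correlation by regressing z out of y
oracle_spcc <- function(x, y, z) {
  res <- residuals(lm(y ~ z))
  cor(x, res)
}

# one-tailed (enrichment) Fisher p by explicit hypergeometric enumeration:
# margins fixed, sum the point probabilities of all tables with the
# top-left cell >= observed
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b        # row 1 total (in-bin)
  n_ <- c + d       # row 2 total
  k <- a + c        # column 1 total (observed set)
  lo <- max(0, k - n_)
  hi <- min(k, m)
  p <- 0
  for (x in a:hi) {
    p <- p + exp(lchoose(m, x) + lchoose(n_, k - x) - lchoose(m + n_, k))
  }
  p
}

# occupancy by direct configuration enumeration written independently of
# the package's enumerate_configurations (recursive inclusion/exclusion)
oracle_occ <- function(start, end, motif, q, omega, dT) {
  n <- length(start)
  totW <- 0
  totN <- 0
  recurse <- function(i, chosen) {
    if (i > n) {
      w <- 1
      np <- 0
      if (length(chosen) > 0) {
        o <- chosen[order(start[chosen])]
        w <- prod(q[o])
        np <- sum(motif[o] == 1)
        if (length(o) > 1) {
          for (j in seq_len(length(o) - 1)) {
            gap <- start[o[j + 1]] - end[o[j]]
            if (motif[o[j]] != motif[o[j + 1]] && gap >= 0 && gap <= dT) {
              w <- w * omega
            }
          }
        }
      }
      totW <<- totW + w
      totN <<- totN + w * np
      return(invisible(NULL))
    }
    ok <- TRUE
    if (length(chosen) > 0) {
      ok <- all(end[chosen] <= start[i] | start[chosen] >= end[i])
    }
    if (ok) recurse(i + 1, c(chosen, i))
    recurse(i + 1, chosen)
    invisible(NULL)
  }
  recurse(1, integer(0))
  totN / totW
}

# random non-degenerate site instance for DP-vs-enumeration checks
random_site_instance <- function(n_sites, span = 300, two_motifs = TRUE) {
  start <- sort(sample.int(span, n_sites))
  len <- sample(6:10, n_sites, replace = TRUE)
  data.frame(start = start, end = start + len,
             rel_affinity = runif(n_sites, 0.01, 1),
             motif = if (two_motifs) sample(1:2, n_sites, replace = TRUE)
                     else rep(1L, n_sites))
}

# small simulated dataset cached across tests (cooperative truth)
fix_coop_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tm <- truth_model(fix_primary(), fix_secondary(), omega = 10,
                        d_T = 150, mode = "cooperative")
      cache <<- simulate_chip_dataset(tm, 100, 100, seed = 7)
    }
    cache
  }
})
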