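#' Position weight matrix (PWM)
#'
#' Constructs a PWM object: per-position base probabilities plus a background
#' distribution. A pseudocount is added to every entry and columns are
#' renormalized on construction, so all probabilities are strictly positive
#' and log-likelihood ratios are finite.
#'
#' @param probs numeric matrix of base probabilities, 4 rows (A, C, G, T) by
#'   L columns (positions). An L x 4 matrix is transposed automatically.
#' @param name motif identifier.
#' @param background length-4 background base probabilities (A, C, G, T);
#'   defaults to uniform.
#' @param pseudocount probability floor added to every entry before
#'   renormalization.
#' @param tf associated TF gene symbol (used for expression-based candidate
#'   ranking); defaults to `name`.
#' @param heterodimer logical; motifs of heterodimeric complexes are excluded
#'   from secondary-candidate ranking.
#' @return An object of class `"pwm"`.
#' @examples
#' m <- pwm(matrix(c(0.7, 0.1, 0.1, 0.1), nrow = 4), name = "toy")
#' llr_score(m, "A")
#' @export
pwm <- function(probs, name = "motif", background = rep(0.25, 4),
                pseudocount = 1e-3, tf = name, heterodimer = FALSE) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4 && ncol(probs) == 4) probs <- t(probs)
  if (nrow(probs) != 4) stop("`probs` must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 1) stop("PWM must have at least one column")
  if (any(probs < 0) || any(!is.finite(probs))) {
    stop("PWM probabilities must be finite and non-negative")
  }
  if (length(background) != 4 || any(background <= 0)) {
    stop("`background` must be 4 positive probabilities")
  }
  background <- background / sum(background)
  probs <- probs + pseudocount
  probs <- sweep(probs, 2, colSums(probs), "/")
  dimnames(probs) <- list(c("A", "C", "G", "T"), NULL)
  structure(
    list(name = name, probs = probs, background = background,
         pseudocount = pseudocount, tf = tf, heterodimer = heterodimer),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d positions, IC = %.2f bits\n",
              x$name, pwm_length(x), information_content(x)))
  print(round(x$probs, 3))
  invisible(x)
}

#' Number of positions in a PWM
#' @param x a [pwm] object.
#' @export
pwm_length <- function(x) ncol(x$probs)

#' Per-position log-likelihood-ratio matrix (natural log)
#' @param x a [pwm] object.
#' @return 4 x L matrix of ln(p / background).
#' @export
llr_matrix <- function(x) log(x$probs / x$background)

#' Maximum attainable LLR (consensus site score)
#' @param x a [pwm] object.
#' @export
llr_max <- function(x) sum(apply(llr_matrix(x), 2, max))

#' Consensus sequence of a PWM
#' @param x a [pwm] object.
#' @export
consensus_seq <- function(x) {
  paste(c("A", "C", "G", "T")[apply(llr_matrix(x), 2, which.max)],
        collapse = "")
}

.BASES <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Log-likelihood-ratio score of a k-mer
#'
#' Scores a k-mer against a PWM as the sum over positions of
#' ln(p_i(b_i) / bg(b_i)) in natural log units. On the minus strand the
#' reverse complement of the k-mer is scored.
#'
#' @param pwm a [pwm] object.
#' @param kmer string over A/C/G/T with `nchar(kmer) == pwm_length(pwm)`.
#' @param strand `"+"` or `"-"`.
#' @return LLR in natural-log units.
#' @export
llr_score <- function(pwm, kmer, strand = "+") {
  bases <- strsplit(toupper(kmer), "")[[1]]
  if (length(bases) != pwm_length(pwm)) {
    stop(sprintf("k-mer length %d does not match PWM length %d",
                 length(bases), pwm_length(pwm)))
  }
  if (strand == "-") bases <- rev(.COMP[bases])
  idx <- .BASES[bases]
  if (any(is.na(idx))) stop("k-mer contains non-ACGT symbols")
  lm <- llr_matrix(pwm)
  sum(lm[cbind(idx, seq_along(idx))])
}

#' Information content of a PWM
#'
#' Total information content in bits relative to the background:
#' sum over positions of sum_b p log2(p / bg). Non-negative; zero for a PWM
#' equal to its background.
#'
#' @param x a [pwm] object.
#' @return bits.
#' @export
information_content <- function(x) {
  sum(x$probs * log2(x$probs / x$background))
}

#' Shuffle a PWM, preserving information content
#'
#' Applies one random permutation to the 4 base rows and one to the columns.
#' With a uniform background this preserves the information content exactly
#' and the multiset of column probability vectors up to base relabeling;
#' used to build the empirical null for secondary-motif influence.
#' Uses the current R random number stream.
#'
#' @param pwm a [pwm] object.
#' @return A shuffled [pwm].
#' @export
shuffle_pwm <- function(pwm) {
  p <- pwm$probs[sample.int(4), sample.int(ncol(pwm$probs)), drop = FALSE]
  rownames(p) <- c("A", "C", "G", "T")
  out <- pwm
  out$probs <- p
  out$name <- paste0(pwm$name, "_shuf")
  out
}

#' Exact LLR threshold for a score p-value under the background model
#'
#' Computes, by exact dynamic programming over the discretized PWM score
#' distribution, the smallest LLR threshold t such that a random background
#' k-mer scores >= t with probability <= `alpha`. Used to emulate scanning
#' at a fixed site p-value (e.g. the e^-7 used for spacing-bias site calls).
#'
#' @param pwm a [pwm] object.
#' @param alpha per-site score p-value; default `exp(-7)`.
#' @param bin LLR discretization step (natural-log units).
#' @return LLR threshold (natural log).
#' @export
llr_threshold_pvalue <- function(pwm, alpha = exp(-7), bin = 0.01) {
  lm <- llr_matrix(pwm)
  L <- ncol(lm)
  ilm <- round(lm / bin)  # integer scores per (base, position)
  off <- apply(ilm, 2, min)
  span <- sum(apply(ilm, 2, max) - off)
  # pmf over shifted integer scores 0..span
  pmf <- numeric(span + 1); pmf[1] <- 1
  bg <- pwm$background
  for (j in seq_len(L)) {
    s <- ilm[, j] - off[j]
    new <- numeric(span + 1)
    for (b in 1:4) {
      sh <- s[b]
      idx <- seq_len(span + 1 - sh)
      new[idx + sh] <- new[idx + sh] + pmf[idx] * bg[b]
    }
    pmf <- new
  }
  tail <- rev(cumsum(rev(pmf)))
  k <- which(tail <= alpha)
  if (length(k) == 0) return(Inf)
  (min(k) - 1 + sum(off)) * bin
}
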