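#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: CC undefined")
  cor(x, y)
}

#' P-value of a Pearson correlation via the t-transform
#'
#' t = r sqrt((n-2) / (1-r^2)) referred to a t distribution with n-2 degrees
#' of freedom.
#'
#' @param r correlation.
#' @param n sample size (>= 3).
#' @param tail `"one"` (positive association) or `"two"`.
#' @return p-value.
#' @export
cc_pvalue <- function(r, n, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (n < 3) stop("need n >= 3")
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  if (tail == "one") pt(t, df = n - 2, lower.tail = FALSE)
  else 2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Modified Z-score (robust outlier statistic)
#'
#' z = 0.6745 (x - median(pool)) / MAD(pool), with MAD the raw median
#' absolute deviation. When the MAD is zero the mean absolute deviation is
#' used with the 1.253 consistency constant. Used to flag a candidate
#' secondary motif's correlation improvement as exceptional among all
#' candidates tested.
#'
#' @param x value to score.
#' @param pool reference values (>= 3).
#' @return modified Z-score.
#' @export
modified_zscore <- function(x, pool) {
  if (length(pool) < 3) stop("pool must have at least 3 values")
  med <- median(pool)
  m <- median(abs(pool - med))
  if (m > 0) return(0.6745 * (x - med) / m)
  md <- mean(abs(pool - med))
  if (md > 0) return((x - med) / (1.253 * md))
  stop("zero dispersion in pool")
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve for a score-threshold classifier, computed as
#' the Mann-Whitney statistic (ties count 1/2).
#'
#' @param scores numeric prediction scores.
#' @param labels logical or two-level vector; `TRUE` (or the second sorted
#'   level) marks positives.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == sort(unique(labels))[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Zero out predictions in inaccessible windows
#'
#' Implements "predict zero occupancy in inaccessible regions": scores are
#' kept in accessible windows and set to 0 elsewhere.
#'
#' @param stap_scores predicted occupancies.
#' @param accessible_flags logical vector of the same length.
#' @export
accessibility_filtered_scores <- function(stap_scores, accessible_flags) {
  if (length(stap_scores) != length(accessible_flags)) stop("length mismatch")
  stap_scores * as.numeric(accessible_flags)
}

#' Semi-partial correlation
#'
#' Correlation between `x` and `y` after partialing the third variable `z`
#' out of `y` only: `(r_xy - r_xz r_yz) / sqrt(1 - r_yz^2)`. Equals the
#' Pearson correlation between `x` and the residuals of `y` regressed on
#' `z`. Here `x` is the model prediction, `y` the ChIP score and `z`
#' accessibility.
#'
#' @param x,y,z numeric vectors of equal length.
#' @return semi-partial correlation coefficient.
#' @export
semi_partial_cc <- function(x, y, z) {
  rxy <- pearson_cc(x, y)
  rxz <- pearson_cc(x, z)
  ryz <- pearson_cc(y, z)
  if (abs(ryz) >= 1 - 1e-12) stop("y and z are collinear: SPCC undefined")
  (rxy - rxz * ryz) / sqrt(1 - ryz^2)
}

#' Correlation within peak and non-peak subsets
#'
#' @param predictions,chip aligned score vectors.
#' @param labels `"peak"` / `"nonpeak"` labels.
#' @return named numeric: `overall`, `peak`, `nonpeak`.
#' @export
subset_cc <- function(predictions, chip, labels) {
  c(overall = pearson_cc(predictions, chip),
    peak = pearson_cc(predictions[labels == "peak"],
                      chip[labels == "peak"]),
    nonpeak = pearson_cc(predictions[labels == "nonpeak"],
                         chip[labels == "nonpeak"]))
}

#' Consistency of trained gamma ratios with expression ratios
#'
#' For one TF profiled at two stages, compares the ratio of trained gamma
#' values (which the model interprets as a concentration ratio) with the
#' ratio of the TF's expression levels. Consistency means the two log-ratios
#' share a sign (first or third quadrant).
#'
#' @param fit_a,fit_b `stap_fit` objects for the two stages.
#' @param expr_a,expr_b expression levels (> 0) at the two stages.
#' @return list with `log_gamma_ratio`, `log_expr_ratio`, `consistent`.
#' @export
gamma_expression_consistency <- function(fit_a, fit_b, expr_a, expr_b) {
  if (expr_a <= 0 || expr_b <= 0) stop("expression levels must be positive")
  lga <- mean(fit_a$fold_params$log10_gamma1)
  lgb <- mean(fit_b$fold_params$log10_gamma1)
  lgr <- lga - lgb
  ler <- log10(expr_a / expr_b)
  list(log_gamma_ratio = lgr, log_expr_ratio = ler,
       consistent = sign(lgr) == sign(ler))
}

# internal: scan one motif over windows, returning per-window matrices with
# the given motif index
.scan_motif <- function(seqs, pwm, min_rel_affinity, motif_index = 1) {
  lmax <- llr_max(pwm)
  thr <- if (min_rel_affinity <= 0) -Inf else lmax + log(min_rel_affinity)
  .scan_windows_cpp(seqs, llr_matrix(pwm), thr, lmax, motif_index)
}

.merge_sitemats <- function(a, b) .merge_sitemats_cpp(a, b)

# internal: cross-validated CC given precomputed site matrices; a model
# whose predictions are constant (e.g. a motif with no sites) gets CC 0
.cv_cc <- function(sitemats, chip, config, folds, n_motifs) {
  cv_pred <- rep(NA_real_, length(chip))
  lg1 <- numeric(0)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- tryCatch(
      fit_stap(sitemats[tr], chip[tr], config, n_motifs),
      error = function(e) list(log10_gamma = rep(0, n_motifs), omega = 1,
                               cc_train = NA_real_))
    g <- 10^fit$log10_gamma
    g2 <- if (n_motifs > 1) g[2] else g[1]
    cv_pred[!tr] <- .predict_batch_cpp(sitemats[!tr], g[1], g2, fit$omega,
                                       config$d_T)
    lg1 <- c(lg1, fit$log10_gamma[1])
  }
  list(cc = if (sd(cv_pred) > 0) pearson_cc(cv_pred, chip) else 0,
       cv_predictions = cv_pred, log10_gamma1 = lg1)
}

#' Assess the influence of one secondary motif
#'
#' Computes the cross-validated correlation of the primary-only model
#' (CC(M1)), the secondary-only model (CC(M2)) and the two-motif model in
#' the requested interaction mode (CC(M1+M2)), then the improvements
#' `delta_cc = CC(M1+M2) - CC(M1)` and `delta_cc_prime = CC(M1+M2) -
#' |CC(M2)|`. If `delta_cc` passes the 0.04 screen, an empirical p-value is
#' estimated by refitting the two-motif model with `n_shuffles`
#' information-content-preserving shuffles of the secondary PWM (ties count
#' as successes). The modified Z-score is computed against
#' `delta_cc_pool` (the delta_cc values of all candidate secondaries) when
#' supplied. A secondary is significant when delta_cc >= 0.04,
#' delta_cc_prime >= 0.04, p <= 0.05 and Z >= 3.
#'
#' @param dataset a `chip_dataset`.
#' @param primary,secondary [pwm] objects.
#' @param mode `"cooperative"`, `"antagonistic"` or `"competition"`.
#' @param d_T interaction distance threshold (bp).
#' @param config optional [stap_config()] for the two-motif model; derived
#'   from `mode` and `d_T` when `NULL`.
#' @param folds fold assignment; derived from `config` when `NULL`.
#' @param n_shuffles number of PWM shuffles for the empirical p-value.
#' @param delta_cc_pool delta_cc values over all candidates (for the Z-score).
#' @param seed RNG seed for the shuffles.
#' @param cc_m1 optionally, a precomputed CC(M1) to avoid refitting.
#' @return object of class `"influence_result"`.
#' @export
assess_secondary_influence <- function(dataset, primary, secondary,
                                       mode = c("cooperative", "antagonistic",
                                                "competition"),
                                       d_T = 150, config = NULL, folds = NULL,
                                       n_shuffles = 100,
                                       delta_cc_pool = NULL, seed = 1,
                                       cc_m1 = NULL) {
  mode <- match.arg(mode)
  if (is.null(config)) config <- stap_config(mode, d_T = d_T)
  cfg1 <- config
  cfg1$mode <- "single"
  cfg1$omega_bounds <- c(1, 1)
  if (is.null(folds)) {
    folds <- make_cv_folds(dataset$windows$label, k = config$k,
                           seed = config$seed)
  }
  chip <- dataset$windows$chip
  sm1 <- .scan_motif(dataset$seqs, primary, config$min_rel_affinity, 1)
  sm2 <- .scan_motif(dataset$seqs, secondary, config$min_rel_affinity, 2)
  if (is.null(cc_m1)) cc_m1 <- .cv_cc(sm1, chip, cfg1, folds, 1)$cc
  sm2_as1 <- lapply(sm2, function(m) {
    if (nrow(m) > 0) m[, 3] <- 1
    m
  })
  cc_m2 <- .cv_cc(sm2_as1, chip, cfg1, folds, 1)$cc
  cc_m1m2 <- .cv_cc(.merge_sitemats(sm1, sm2), chip, config, folds, 2)$cc
  delta_cc <- cc_m1m2 - cc_m1
  delta_cc_prime <- cc_m1m2 - abs(cc_m2)

  pvalue <- NA_real_
  if (delta_cc >= 0.04 && n_shuffles > 0) {
    sh_delta <- .with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
      shm <- shuffle_pwm(secondary)
      sms <- .scan_motif(dataset$seqs, shm, config$min_rel_affinity, 2)
      .cv_cc(.merge_sitemats(sm1, sms), chip, config, folds, 2)$cc - cc_m1
    }, numeric(1)))
    pvalue <- mean(sh_delta >= delta_cc)
  }
  zscore <- if (!is.null(delta_cc_pool)) {
    modified_zscore(delta_cc, delta_cc_pool)
  } else NA_real_
  significant <- isTRUE(delta_cc >= 0.04) && isTRUE(delta_cc_prime >= 0.04) &&
    isTRUE(pvalue <= 0.05) && isTRUE(zscore >= 3)
  structure(
    list(dataset = dataset$name, secondary = secondary$name, mode = mode,
         d_T = d_T, cc_m1 = cc_m1, cc_m2 = cc_m2, cc_m1m2 = cc_m1m2,
         delta_cc = delta_cc, delta_cc_prime = delta_cc_prime,
         pvalue = pvalue, zscore = zscore, significant = significant,
         n_shuffles = n_shuffles),
    class = "influence_result"
  )
}

#' @export
print.influence_result <- function(x, ...) {
  cat(sprintf(
    "influence: %s on %s (%s, d_T=%d)\n  CC(M1)=%.3f CC(M2)=%.3f CC(M1+M2)=%.3f dCC=%.3f dCC'=%.3f p=%s Z=%s %s\n",
    x$secondary, x$dataset, x$mode, as.integer(x$d_T), x$cc_m1, x$cc_m2,
    x$cc_m1m2, x$delta_cc, x$delta_cc_prime,
    ifelse(is.na(x$pvalue), "NA",
           ifelse(x$pvalue == 0, sprintf("<%.3g", 1 / x$n_shuffles),
                  sprintf("%.2f", x$pvalue))),
    ifelse(is.na(x$zscore), "NA", sprintf("%.1f", x$zscore)),
    if (x$significant) "*significant*" else ""))
  invisible(x)
}

#' Screen and assess a pool of candidate secondary motifs
#'
#' Computes delta_cc for every candidate (the Z-score pool), then runs the
#' full significance assessment ([assess_secondary_influence()]) for each
#' candidate, reusing the shared CC(M1) fit. The shuffled-motif p-value is
#' only computed for candidates passing the delta_cc >= 0.04 screen.
#'
#' @inheritParams assess_secondary_influence
#' @param candidates named list of [pwm] objects.
#' @return data.frame with one row per candidate (columns mirroring the
#'   influence tables: CC(M1), CC(M2), CC(M1+M2), ImprOverM1, ImprOverM2,
#'   P-value, Z-score, significant).
#' @export
assess_secondary_candidates <- function(dataset, primary, candidates,
                                        mode = c("cooperative",
                                                 "antagonistic",
                                                 "competition"),
                                        d_T = 150, config = NULL,
                                        folds = NULL, n_shuffles = 100,
                                        seed = 1) {
  mode <- match.arg(mode)
  if (is.null(config)) config <- stap_config(mode, d_T = d_T)
  if (is.null(folds)) {
    folds <- make_cv_folds(dataset$windows$label, k = config$k,
                           seed = config$seed)
  }
  cfg1 <- config
  cfg1$mode <- "single"
  cfg1$omega_bounds <- c(1, 1)
  chip <- dataset$windows$chip
  sm1 <- .scan_motif(dataset$seqs, primary, config$min_rel_affinity, 1)
  cc_m1 <- .cv_cc(sm1, chip, cfg1, folds, 1)$cc
  # first pass: delta_cc pool (no shuffling)
  res <- lapply(seq_along(candidates), function(i) {
    assess_secondary_influence(dataset, primary, candidates[[i]], mode, d_T,
                               config, folds, n_shuffles = 0,
                               seed = seed + i, cc_m1 = cc_m1)
  })
  pool <- vapply(res, function(r) r$delta_cc, numeric(1))
  out <- lapply(seq_along(res), function(i) {
    r <- res[[i]]
    r$zscore <- modified_zscore(r$delta_cc, pool)
    if (r$delta_cc >= 0.04 && n_shuffles > 0) {
      r2 <- assess_secondary_influence(dataset, primary, candidates[[i]],
                                       mode, d_T, config, folds,
                                       n_shuffles = n_shuffles,
                                       delta_cc_pool = pool, seed = seed + i,
                                       cc_m1 = cc_m1)
      r$pvalue <- r2$pvalue
    }
    r$significant <- isTRUE(r$delta_cc >= 0.04) &&
      isTRUE(r$delta_cc_prime >= 0.04) && isTRUE(r$pvalue <= 0.05) &&
      isTRUE(r$zscore >= 3)
    data.frame(dataset = r$dataset, motif2 = r$secondary, mode = r$mode,
               d_T = r$d_T, cc_m1 = r$cc_m1, cc_m2 = r$cc_m2,
               cc_m1m2 = r$cc_m1m2, delta_cc = r$delta_cc,
               delta_cc_prime = r$delta_cc_prime, pvalue = r$pvalue,
               zscore = r$zscore, significant = r$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(names(candidates))) out$motif2 <- names(candidates)
  out
}

#' Accessibility-aware influence: delta-SPCC alongside delta-CC
#'
#' Recomputes the primary-only and two-motif cross-validated predictions and
#' compares their semi-partial correlations with the ChIP scores after
#' partialing accessibility out of the ChIP scores. A secondary whose
#' delta_cc is significant but whose `delta_spcc < 0.04` is classified
#' "accessibility-mediated"; `delta_spcc >= 0.04` is
#' "accessibility-independent".
#'
#' @inheritParams assess_secondary_influence
#' @return list with `spcc_m1`, `spcc_m1m2`, `delta_spcc`, `classification`.
#' @export
assess_influence_spcc <- function(dataset, primary, secondary,
                                  mode = c("cooperative", "antagonistic",
                                           "competition"),
                                  d_T = 150, config = NULL, folds = NULL) {
  mode <- match.arg(mode)
  if (is.null(config)) config <- stap_config(mode, d_T = d_T)
  if (is.null(folds)) {
    folds <- make_cv_folds(dataset$windows$label, k = config$k,
                           seed = config$seed)
  }
  acc <- dataset$windows$accessibility
  if (all(is.na(acc))) stop("dataset has no accessibility scores")
  cfg1 <- config
  cfg1$mode <- "single"
  cfg1$omega_bounds <- c(1, 1)
  chip <- dataset$windows$chip
  sm1 <- .scan_motif(dataset$seqs, primary, config$min_rel_affinity, 1)
  sm2 <- .scan_motif(dataset$seqs, secondary, config$min_rel_affinity, 2)
  f1 <- .cv_cc(sm1, chip, cfg1, folds, 1)
  f12 <- .cv_cc(.merge_sitemats(sm1, sm2), chip, config, folds, 2)
  spcc_m1 <- semi_partial_cc(f1$cv_predictions, chip, acc)
  spcc_m1m2 <- semi_partial_cc(f12$cv_predictions, chip, acc)
  delta_spcc <- spcc_m1m2 - spcc_m1
  list(spcc_m1 = spcc_m1, spcc_m1m2 = spcc_m1m2, delta_spcc = delta_spcc,
       delta_cc = f12$cc - f1$cc,
       classification = if (delta_spcc >= 0.04) "accessibility-independent"
       else "accessibility-mediated")
}
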