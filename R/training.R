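# evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Training configuration for the occupancy model
#'
#' @param mode interaction mode (see [binding_model()]).
#' @param d_T distance threshold in bp.
#' @param gamma_bounds allowed gamma range; default `[1, 1e4]`.
#' @param gamma_step grid step in log10 gamma.
#' @param omega_bounds allowed omega range; defaults to `[1, 100]` for
#'   cooperative, `[0.01, 1]` for antagonistic, `1` otherwise.
#' @param omega_step grid step in log10 omega.
#' @param min_rel_affinity site-inclusion threshold for scanning.
#' @param k number of cross-validation folds.
#' @param seed seed for fold assignment and any other randomness.
#' @param refine run a derivative-free local refinement from the best grid
#'   point.
#' @return list of class `"stap_config"`.
#' @export
stap_config <- function(mode = c("single", "cooperative", "antagonistic",
                                 "competition"),
                        d_T = 150, gamma_bounds = c(1, 1e4),
                        gamma_step = 0.5, omega_bounds = NULL,
                        omega_step = 0.5, min_rel_affinity = 0.01,
                        k = 4, seed = 1, refine = TRUE) {
  mode <- match.arg(mode)
  if (is.null(omega_bounds)) {
    omega_bounds <- switch(mode, cooperative = c(1, 100),
                           antagonistic = c(0.01, 1), c(1, 1))
  }
  structure(list(mode = mode, d_T = d_T, gamma_bounds = gamma_bounds,
                 gamma_step = gamma_step, omega_bounds = omega_bounds,
                 omega_step = omega_step,
                 min_rel_affinity = min_rel_affinity, k = k, seed = seed,
                 refine = refine),
            class = "stap_config")
}

# parameter grid (log10 gamma / log10 omega), one row per grid point
.param_grid <- function(config, n_motifs) {
  lg <- seq(log10(config$gamma_bounds[1]), log10(config$gamma_bounds[2]),
            by = config$gamma_step)
  lo <- if (diff(log10(config$omega_bounds)) == 0) 0 else {
    seq(log10(config$omega_bounds[1]), log10(config$omega_bounds[2]),
        by = config$omega_step)
  }
  if (n_motifs == 1) {
    expand.grid(lg1 = lg, lg2 = 0, lomega = 0)
  } else {
    expand.grid(lg1 = lg, lg2 = lg, lomega = lo)
  }
}

#' Fit model parameters on a training set
#'
#' Maximizes the training-set Pearson correlation between predicted
#' occupancies and ChIP scores over gamma (per motif) and omega, by a coarse
#' grid in log10 space followed by Nelder-Mead refinement within the bounds.
#'
#' @param sitemats per-window site matrices (internal scan output; supplied
#'   by [cross_validate_stap()]).
#' @param chip training ChIP scores, one per window.
#' @param config a [stap_config()].
#' @param n_motifs 1 or 2.
#' @return list with `log10_gamma`, `omega`, `cc_train`.
#' @export
fit_stap <- function(sitemats, chip, config, n_motifs = 1) {
  if (length(unique(chip)) < 2) stop("constant ChIP scores: CC undefined")
  grid <- .param_grid(config, n_motifs)
  pm <- cbind(10^grid$lg1, 10^grid$lg2, 10^grid$lomega)
  cc <- .grid_cc_cpp(sitemats, chip, pm, config$d_T)
  if (all(is.na(cc))) stop("model predictions constant at every grid point")
  best <- which.max(cc)
  theta <- as.numeric(grid[best, ])
  free <- if (n_motifs == 1) 1L else if (diff(log10(config$omega_bounds)) == 0)
    1:2 else 1:3
  cc_best <- cc[best]
  if (config$refine && length(free) >= 1) {
    lb <- c(log10(config$gamma_bounds[1]), log10(config$gamma_bounds[1]),
            log10(config$omega_bounds[1]))
    ub <- c(log10(config$gamma_bounds[2]), log10(config$gamma_bounds[2]),
            log10(config$omega_bounds[2]))
    obj <- function(x) {
      th <- theta
      th[free] <- x
      if (any(th[free] < lb[free] - 1e-12) || any(th[free] > ub[free] + 1e-12)) {
        return(2)  # outside bounds; cc in [-1,1] so 2 never wins
      }
      p <- matrix(10^th, nrow = 1)
      v <- .grid_cc_cpp(sitemats, chip, p, config$d_T)
      if (is.na(v)) 2 else -v
    }
    opt <- suppressWarnings(
      optim(theta[free], obj, method = "Nelder-Mead",
            control = list(reltol = 1e-4, maxit = 120))
    )
    if (-opt$value >= cc_best) {
      theta[free] <- pmin(pmax(opt$par, lb[free]), ub[free])
      cc_best <- -obj(theta[free])
    }
  }
  list(log10_gamma = theta[seq_len(n_motifs)], omega = 10^theta[3],
       cc_train = cc_best)
}

#' Consistency of per-fold trained parameters
#'
#' The dataset-exclusion surrogate: a cross-validated fit is flagged
#' inconsistent when the per-fold primary-motif log10 gamma values span more
#' than `max_range` (widely different optima across folds).
#'
#' @param log10_gammas per-fold log10 gamma values.
#' @param max_range allowed range (default 2 decades).
#' @export
fold_consistency <- function(log10_gammas, max_range = 2) {
  diff(range(log10_gammas)) <= max_range
}

#' Stratified cross-validation folds
#'
#' Randomly assigns windows to `k` folds, stratified by label so each fold
#' holds an equal number of peaks and of non-peaks.
#'
#' @param labels character vector of `"peak"` / `"nonpeak"` labels.
#' @param k fold count (default 4).
#' @param seed RNG seed.
#' @return integer fold assignment per window.
#' @export
make_cv_folds <- function(labels, k = 4, seed = 1) {
  .with_seed(seed, {
    folds <- integer(length(labels))
    for (lab in unique(labels)) {
      i <- which(labels == lab)
      folds[i] <- sample(rep(seq_len(k), length.out = length(i)))
    }
    folds
  })
}

#' Cross-validated occupancy model fit
#'
#' For each fold, fits the model parameters on the other k-1 folds and
#' predicts the held-out windows; every window is predicted exactly once.
#' The fit is flagged inconsistent when the primary-motif log10 gamma varies
#' by more than 2 across folds (the dataset-exclusion surrogate for widely
#' different per-fold optima).
#'
#' @param dataset a `chip_dataset`.
#' @param motifs list of 1-2 [pwm] objects (primary first).
#' @param config a [stap_config()].
#' @param folds fold assignment (from [make_cv_folds()]); generated from
#'   `config$seed` when `NULL`.
#' @param sitemats optional precomputed scan (internal reuse).
#' @return object of class `"stap_fit"`: `cc` (cross-validated Pearson CC),
#'   `cv_predictions`, `fold_params` (per-fold log10 gamma, omega, training
#'   CC), `consistent`, plus the inputs.
#' @export
cross_validate_stap <- function(dataset, motifs, config, folds = NULL,
                                sitemats = NULL) {
  if (inherits(motifs, "pwm")) motifs <- list(motifs)
  chip <- dataset$windows$chip
  if (is.null(folds)) {
    folds <- make_cv_folds(dataset$windows$label, k = config$k,
                           seed = config$seed)
  }
  if (is.null(sitemats)) {
    sitemats <- scan_windows(dataset$seqs, motifs, config$min_rel_affinity)
  }
  n_motifs <- length(motifs)
  cv_pred <- rep(NA_real_, length(chip))
  fp <- vector("list", config$k)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- try(fit_stap(sitemats[tr], chip[tr], config, n_motifs),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      stop(sprintf("fit failed in fold %d: %s", f,
                   attr(fit, "condition")$message))
    }
    g <- 10^fit$log10_gamma
    g2 <- if (n_motifs > 1) g[2] else g[1]
    cv_pred[!tr] <- .predict_batch_cpp(sitemats[!tr], g[1], g2, fit$omega,
                                       config$d_T)
    fp[[f]] <- data.frame(fold = f, log10_gamma1 = fit$log10_gamma[1],
                          log10_gamma2 = if (n_motifs > 1)
                            fit$log10_gamma[2] else NA_real_,
                          omega = fit$omega, cc_train = fit$cc_train)
  }
  fold_params <- do.call(rbind, fp)
  cc <- if (sd(cv_pred) > 0) pearson_cc(cv_pred, chip) else NA_real_
  structure(
    list(cc = cc, cv_predictions = cv_pred, fold_params = fold_params,
         consistent = fold_consistency(fold_params$log10_gamma1),
         motifs = motifs, config = config, folds = folds),
    class = "stap_fit"
  )
}

#' @export
print.stap_fit <- function(x, ...) {
  cat(sprintf("stap_fit: %d motif(s), mode=%s, CV CC = %.3f%s\n",
              length(x$motifs), x$config$mode, x$cc,
              if (x$consistent) "" else " [inconsistent folds]"))
  invisible(x)
}
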