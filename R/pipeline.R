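#' Configuration for an end-to-end analysis run
#'
#' @param dataset a prebuilt `chip_dataset`, or `NULL` to simulate one from
#'   `truth`.
#' @param truth a [truth_model()] used when `dataset` is `NULL`.
#' @param n_peaks,n_nonpeaks simulated dataset sizes.
#' @param primary primary [pwm]; defaults to the truth model's.
#' @param candidates named list of candidate secondary [pwm]s; defaults to
#'   the truth secondary plus shuffled decoys when simulating.
#' @param modes interaction modes to run (subset of `"single"`,
#'   `"cooperative"`, `"antagonistic"`, `"competition"`).
#' @param d_T distance thresholds to run (default `c(30, 150)`).
#' @param n_shuffles shuffles for empirical p-values.
#' @param n_decoys shuffled decoy candidates added when simulating.
#' @param spacing_bins spacing-bias bin left edges.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory for the report TSVs and run log.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(dataset = NULL, truth = NULL, n_peaks = 200,
                       n_nonpeaks = 200, primary = NULL, candidates = NULL,
                       modes = c("single", "cooperative"), d_T = c(30, 150),
                       n_shuffles = 100, n_decoys = 9, spacing_bins = 1:29,
                       seed = 1, out_dir = tempfile("thermoccupancy_run_")) {
  if (is.null(dataset) && is.null(truth)) stop("need `dataset` or `truth`")
  if (length(modes) == 0 || length(d_T) == 0) stop("modes/d_T must be non-empty")
  structure(list(dataset = dataset, truth = truth, n_peaks = n_peaks,
                 n_nonpeaks = n_nonpeaks, primary = primary,
                 candidates = candidates, modes = modes, d_T = d_T,
                 n_shuffles = n_shuffles, n_decoys = n_decoys,
                 spacing_bins = spacing_bins, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis sequence: build or simulate the dataset, fit
#' the single-motif baseline (cross-validated CC, SPCC, ROC AUC, peak /
#' non-peak subset CCs), screen and assess every candidate secondary motif
#' in each requested interaction mode and distance threshold, re-analyze
#' significant influences against accessibility (delta-CC vs delta-SPCC),
#' and test inter-site spacing bias for significant cooperative or
#' antagonistic pairs on the top-250 peaks and bottom-250 non-peaks. All
#' outputs are written as TSVs under `config$out_dir` together with a JSON
#' run log of seeds and fitted parameters.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the computed tables and output paths.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log <- list(seed = seed, started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  dataset <- config$dataset
  if (is.null(dataset)) {
    dataset <- simulate_chip_dataset(config$truth, config$n_peaks,
                                     config$n_nonpeaks, seed = seed)
    log$simulated <- dataset$name
  }
  primary <- config$primary
  if (is.null(primary)) {
    if (!is.null(config$truth)) primary <- config$truth$primary
    else stop("`primary` motif required for a prebuilt dataset")
  }
  candidates <- config$candidates
  if (is.null(candidates)) {
    if (is.null(config$truth) || is.null(config$truth$secondary)) {
      candidates <- list()
    } else {
      sec <- config$truth$secondary
      decoys <- .with_seed(seed + 1L, lapply(seq_len(config$n_decoys),
                                             function(i) shuffle_pwm(sec)))
      candidates <- c(setNames(list(sec), sec$name),
                      setNames(decoys, paste0(sec$name, "_decoy",
                                              seq_len(config$n_decoys))))
    }
  }

  cfg1 <- stap_config("single", seed = seed)
  folds <- make_cv_folds(dataset$windows$label, k = cfg1$k, seed = seed)
  fit1 <- cross_validate_stap(dataset, list(primary), cfg1, folds)
  chip <- dataset$windows$chip
  acc <- dataset$windows$accessibility
  has_acc <- !all(is.na(acc))
  sub <- subset_cc(fit1$cv_predictions, chip, dataset$windows$label)
  baseline <- data.frame(
    dataset = dataset$name, motif1 = primary$name, cc_m1 = fit1$cc,
    spcc_m1 = if (has_acc) semi_partial_cc(fit1$cv_predictions, chip, acc)
              else NA_real_,
    cc_peaks = sub[["peak"]], cc_nonpeaks = sub[["nonpeak"]],
    auc = roc_auc(fit1$cv_predictions, chip >= median(chip)),
    consistent = fit1$consistent
  )
  paths <- list(baseline = .write_tsv(baseline,
                                      file.path(config$out_dir,
                                                "baseline.tsv")))
  log$baseline_fold_params <- fit1$fold_params
  results <- list(dataset = dataset, baseline = baseline)

  influence <- list()
  int_modes <- setdiff(config$modes, "single")
  for (mode in int_modes) {
    dts <- if (mode == "competition") config$d_T[1] else config$d_T
    for (dt in dts) {
      if (length(candidates) == 0) next
      tab <- assess_secondary_candidates(
        dataset, primary, candidates, mode = mode, d_T = dt,
        config = stap_config(mode, d_T = dt, seed = seed), folds = folds,
        n_shuffles = config$n_shuffles, seed = seed + 100L)
      influence[[sprintf("%s_d%d", mode, dt)]] <- tab
      paths[[sprintf("influence_%s_d%d", mode, dt)]] <-
        .write_tsv(tab, file.path(config$out_dir,
                                  sprintf("influence_%s_d%d.tsv", mode, dt)))
    }
  }
  results$influence <- influence

  sig <- do.call(rbind, influence)
  if (!is.null(sig)) sig <- sig[sig$significant, , drop = FALSE]
  if (!is.null(sig) && nrow(sig) > 0 && has_acc) {
    spcc_tab <- do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
      sp <- assess_influence_spcc(
        dataset, primary, candidates[[sig$motif2[i]]], mode = sig$mode[i],
        d_T = sig$d_T[i],
        config = stap_config(sig$mode[i], d_T = sig$d_T[i], seed = seed),
        folds = folds)
      data.frame(motif2 = sig$motif2[i], mode = sig$mode[i], d_T = sig$d_T[i],
                 delta_cc = sig$delta_cc[i], spcc_m1 = sp$spcc_m1,
                 spcc_m1m2 = sp$spcc_m1m2, delta_spcc = sp$delta_spcc,
                 classification = sp$classification)
    }))
    results$spcc <- spcc_tab
    paths$spcc <- .write_tsv(spcc_tab, file.path(config$out_dir, "spcc.tsv"))
  }

  if (!is.null(sig) && nrow(sig) > 0) {
    sp_pairs <- sig[sig$mode %in% c("cooperative", "antagonistic"), ,
                    drop = FALSE]
    if (nrow(sp_pairs) > 0) {
      w <- dataset$windows
      top_idx <- order(-w$chip)[seq_len(min(250, sum(w$label == "peak")))]
      np_idx <- which(w$label == "nonpeak")
      bot_idx <- np_idx[order(w$chip[np_idx])][
        seq_len(min(250, length(np_idx)))]
      spacing_tab <- do.call(rbind, lapply(seq_len(nrow(sp_pairs)),
                                           function(i) {
        m2 <- candidates[[sp_pairs$motif2[i]]]
        res <- lapply(list(peaks = top_idx, nonpeaks = bot_idx),
                      function(idx) {
          spacing_bias_scan(dataset$seqs[idx], primary, m2,
                            bins = config$spacing_bins, seed = seed + 7L)
        })
        data.frame(motif2 = sp_pairs$motif2[i], mode = sp_pairs$mode[i],
                   d_T = sp_pairs$d_T[i],
                   segment_set = c("top250_peaks", "bottom250_nonpeaks"),
                   min_pvalue = c(res$peaks$min_pvalue,
                                  res$nonpeaks$min_pvalue),
                   best_bin_lo = c(res$peaks$best_bin[1],
                                   res$nonpeaks$best_bin[1]),
                   n_pairs = c(res$peaks$n_pairs, res$nonpeaks$n_pairs))
      }))
      results$spacing <- spacing_tab
      paths$spacing <- .write_tsv(spacing_tab,
                                  file.path(config$out_dir, "spacing.tsv"))
    }
  }

  log$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  log_path <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths$log <- log_path
  results$paths <- paths
  invisible(results)
}
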