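#' Experiment run configuration
#'
#' Bundles everything [run_experiment()] needs: how many synthetic
#' participants to simulate, their trial counts, the analysis windows, the
#' decoder variants, the cross-validation plan and the model recipe. One
#' global seed cascades to every stage (simulation, folds, training,
#' permutations), so a rerun with the same configuration is bit-identical.
#'
#' @param n_participants synthetic participants to simulate.
#' @param trials_per_class voluntary-trial count per participant (recycled);
#'   spontaneous trials are generated in excess and balanced down.
#' @param windows list of analysis windows (seconds pairs).
#' @param variants decoder variants to evaluate.
#' @param plan a [cv_plan()].
#' @param model a [model_config()].
#' @param sim a [sim_config()] template; per-participant seeds and trial
#'   counts are filled in.
#' @param n_perm permutations for test p-values.
#' @param outer_subset optional subset of outer folds (see [nested_cv()]).
#' @param seed global integer seed.
#' @param plots also render topography PNGs in the report.
#' @return A `run_config` object.
#' @export
run_config <- function(n_participants = 3, trials_per_class = 200,
                       windows = list(c(-0.2, 0.5), c(-0.2, 1.0)),
                       variants = c("lf", "var"), plan = cv_plan(),
                       model = model_config(), sim = sim_config(),
                       n_perm = 200, outer_subset = NULL, seed = 1,
                       plots = FALSE) {
  stopifnot(n_participants >= 1)
  for (w in windows)
    if (w[1] < sim$epoch_window[1] || w[2] > sim$epoch_window[2])
      stop("config error: analysis window outside simulated epoch")
  structure(list(n_participants = as.integer(n_participants),
                 trials_per_class = rep_len(trials_per_class, n_participants),
                 windows = windows, variants = variants, plan = plan,
                 model = model, sim = sim, n_perm = n_perm,
                 outer_subset = outer_subset, seed = as.integer(seed),
                 plots = isTRUE(plots)), class = "run_config")
}

.window_tag <- function(w) sprintf("%g..%g", w[1], w[2])

#' Run the full synthetic experiment
#'
#' simulate -> label -> preprocess -> nested CV (every variant x window) ->
#' interpret -> report. Every synthetic participant gets a gaze log (labeled
#' and counted), a simulated MEG dataset, per-window preprocessed epochs,
#' nested-CV results per variant, and - for the first window's LF decoder -
#' activation patterns, latent-source class weights, an FVE map and the
#' frontal-artifact diagnostic computed from each outer fold's naive model
#' on its own training split. Results are written to `outdir` by
#' [write_report()].
#'
#' @param config a [run_config()].
#' @param outdir report directory (created if needed).
#' @return Invisibly, the in-memory result list (`participants`, `group`,
#'   `manifest`).
#' @export
run_experiment <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  participants <- list()
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("S%02d", p)
    pseed <- config$seed + 1000L * p
    message(sprintf("[%s] simulating (seed %d)", pid, pseed))

    gaze <- simulate_gaze_log(60, 0.6, seed = pseed, p_boundary = 0.1)
    labeled <- label_fixations(gaze)
    sim <- config$sim
    sim$seed <- pseed
    sim$n_voluntary <- config$trials_per_class[p]
    sim$n_spontaneous <- round(config$trials_per_class[p] * 1.5)
    ds <- simulate_epochs(sim)
    bal <- balance_classes(ds$labels, seed = pseed)
    keep <- sort(c(bal$voluntary, bal$spontaneous))
    epochs_bal <- .subset_epochs(ds$epochs, keep)

    res <- list()
    interp <- NULL
    for (w in config$windows) {
      message(sprintf("[%s] window %s", pid, .window_tag(w)))
      prep <- preprocess_epochs(epochs_bal, window = w)
      for (v in config$variants) {
        cfg <- config$model
        cfg$seed <- config$model$seed + 17L * p
        plan <- config$plan
        plan$seed <- config$plan$seed + 31L * p
        keep_m <- identical(w, config$windows[[1]]) && v == "lf"
        cv <- nested_cv(prep, v, plan, cfg, n_perm = config$n_perm,
                        outer_subset = config$outer_subset,
                        keep_models = keep_m)
        res[[paste(v, .window_tag(w))]] <- cv
        if (keep_m) {
          interp <- lapply(cv$models, function(fm) {
            tr <- .subset_epochs(prep, fm$train_idx)
            pat <- compute_patterns(fm$naive$W, tr)
            ow <- output_weight_tensor(fm$naive)
            list(patterns = pat,
                 weights_vol = ls_class_weights(ow, 1),
                 weights_spo = ls_class_weights(ow, 0),
                 fve = fve_map(tr, pat$A, pat$S_hat),
                 diag = frontal_diagnostic(pat, ow, ds$layout$frontal_mask, 1))
          })
          cv$models <- NULL
          res[[paste(v, .window_tag(w))]] <- cv
        }
      }
    }
    participants[[pid]] <- list(
      id = pid, seed = pseed,
      n_trials_per_class = length(bal$voluntary),
      gaze_counts = table(labeled$label),
      cv = res, interpretation = interp, layout = ds$layout)
  }

  group <- NULL
  if (config$n_participants >= 3) {
    counts <- vapply(participants, function(pp) pp$n_trials_per_class,
                     numeric(1))
    group <- lapply(config$windows, function(w) {
      by_variant <- lapply(config$variants, function(v)
        lapply(participants, function(pp) pp$cv[[paste(v, .window_tag(w))]]))
      names(by_variant) <- config$variants
      group_summary(by_variant, counts)
    })
    names(group) <- vapply(config$windows, .window_tag, character(1))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("fixdecode")),
    seed = config$seed,
    participant_seeds = vapply(participants, function(pp) pp$seed, numeric(1)),
    windows = lapply(config$windows, as.numeric),
    variants = config$variants,
    outer_folds = config$plan$outer_folds,
    inner_folds = config$plan$inner_folds,
    n_perm = config$n_perm,
    group_stats = if (is.null(group)) "insufficient n" else "computed",
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  result <- list(participants = participants, group = group,
                 manifest = manifest, config = config)
  write_report(result, outdir)
  invisible(result)
}

#' Write the experiment report
#'
#' Emits, under `outdir`: `table1_<variant>_<window>.csv` (per-participant
#' fold-averaged AUCs with the permutation flag: `+` all folds significant
#' at 0.05, `-` none), `table2.csv` (group mean and SD per variant, window
#' and testing method), `fve_<participant>.csv` and
#' `patterns_<participant>.csv` (per-channel values), `diagnostics.csv`
#' (frontal-artifact correlations), and `manifest.json`. With
#' `config$plots = TRUE` topography PNGs are rendered as well.
#'
#' @param result the list produced by [run_experiment()].
#' @param outdir output directory.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(result, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create report directory: ", outdir)
  config <- result$config
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }

  for (w in config$windows) {
    for (v in config$variants) {
      key <- paste(v, .window_tag(w))
      rows <- lapply(result$participants, function(pp) {
        cv <- pp$cv[[key]]
        data.frame(
          participant = pp$id,
          n_trials_per_class = pp$n_trials_per_class,
          auc_val_mean = mean(cv$folds$auc_val),
          auc_val_sd = stats::sd(cv$folds$auc_val),
          auc_naive_mean = mean(cv$folds$auc_naive),
          auc_naive_sd = stats::sd(cv$folds$auc_naive),
          auc_ensemble_mean = mean(cv$folds$auc_ensemble),
          auc_ensemble_sd = stats::sd(cv$folds$auc_ensemble),
          perm_flag = .perm_flag(cv$folds$p_ensemble))
      })
      emit(do.call(rbind, rows),
           sprintf("table1_%s_%s.csv", v, .window_tag(w)))
    }
  }

  t2 <- list()
  for (w in config$windows) for (v in config$variants) {
    key <- paste(v, .window_tag(w))
    for (m in c("auc_naive", "auc_ensemble")) {
      vals <- vapply(result$participants,
                     function(pp) mean(pp$cv[[key]]$folds[[m]]), numeric(1))
      t2[[paste(key, m)]] <- data.frame(
        window = .window_tag(w), variant = v, testing = sub("auc_", "", m),
        mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else NA)
    }
  }
  emit(do.call(rbind, t2), "table2.csv")

  diag_rows <- list()
  for (pp in result$participants) {
    if (is.null(pp$interpretation)) next
    fve_mean <- rowMeans(vapply(pp$interpretation,
                                function(ii) ii$fve$fve,
                                numeric(length(pp$layout$channel_ids))))
    pat_mean <- rowMeans(vapply(pp$interpretation,
                                function(ii) average_pattern(ii$patterns),
                                numeric(length(pp$layout$channel_ids))))
    emit(data.frame(channel_id = pp$layout$channel_ids, fve = fve_mean),
         sprintf("fve_%s.csv", pp$id))
    emit(data.frame(channel_id = pp$layout$channel_ids,
                    mean_pattern = pat_mean),
         sprintf("patterns_%s.csv", pp$id))
    diag_rows[[pp$id]] <- data.frame(
      participant = pp$id,
      pearson_r = mean(vapply(pp$interpretation,
                              function(ii) ii$diag$pearson_r, numeric(1))),
      full_fve = mean(vapply(pp$interpretation,
                             function(ii) ii$fve$full_fve, numeric(1))))
    if (config$plots) {
      png_path <- file.path(outdir, sprintf("fve_topo_%s.png", pp$id))
      grDevices::png(png_path, width = 480, height = 480)
      plot_topography(pp$layout, fve_mean,
                      main = sprintf("FVE %s", pp$id))
      grDevices::dev.off()
      written <- c(written, png_path)
    }
  }
  if (length(diag_rows) > 0)
    emit(do.call(rbind, diag_rows), "diagnostics.csv")

  if (!is.null(result$group)) {
    grows <- list()
    for (wt in names(result$group)) {
      g <- result$group[[wt]]
      gm <- g$metrics
      gm$window <- wt
      grows[[wt]] <- gm
    }
    emit(do.call(rbind, grows), "group_metrics.csv")
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(result$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  written <- c(written, manifest_path)
  invisible(written)
}
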