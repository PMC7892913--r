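#' ROC AUC as the Mann-Whitney concordance probability
#'
#' Probability that a randomly chosen positive trial scores higher than a
#' randomly chosen negative one, with ties credited 0.5 (midrank
#' computation).
#'
#' @param scores numeric score per trial (higher = more voluntary).
#' @param labels per-trial class labels, 0/1.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("undefined-AUC: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Cross-validation plan
#'
#' @param outer_folds outer (testing) folds.
#' @param inner_folds inner (validation) folds; the inner split is
#'   train/validation in ratio `(inner_folds - 1) : 1`.
#' @param seed integer seed controlling fold assignment and derived
#'   training seeds.
#' @return A `cv_plan` object.
#' @export
cv_plan <- function(outer_folds = 5, inner_folds = 4, seed = 1) {
  stopifnot(outer_folds >= 2, inner_folds >= 2)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)), class = "cv_plan")
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so class proportions are as equal as fold sizes allow.
# Consumes the current RNG stream.
.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Optimal training-iteration count from validation traces
#'
#' For each inner fold, the iteration index at which the validation AUC
#' trace attains its maximum (earliest index on ties); the returned count is
#' the arithmetic mean of these indices across folds, rounded to the nearest
#' integer, with a floor of 1.
#'
#' @param traces list of numeric per-iteration validation AUC vectors.
#' @return integer iteration count.
#' @export
select_iterations <- function(traces) {
  if (length(traces) == 0) stop("empty traces")
  argmax <- vapply(traces, function(tr) {
    if (length(tr) == 0 || all(is.na(tr))) stop("empty trace")
    which.max(tr)
  }, integer(1))
  max(1L, as.integer(round(mean(argmax))))
}

#' Label-permutation significance test
#'
#' Estimates the null distribution of the AUC by permuting the test labels
#' uniformly at random; the p-value uses the add-one estimator
#' `p = (1 + #{permuted AUC >= observed}) / (n_perm + 1)`.
#'
#' @param scores per-trial scores.
#' @param labels per-trial 0/1 labels.
#' @param n_perm number of permutations (>= 1).
#' @param seed optional integer seed.
#' @return A `perm_test` object: list with `p_value`, `observed`, `null`
#'   (the permuted AUCs).
#' @export
permutation_test <- function(scores, labels, n_perm = 1000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  labels <- as.integer(labels)
  observed <- roc_auc(scores, labels)
  if (!is.null(seed)) set.seed(as.integer(seed))
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  null <- vapply(seq_len(n_perm), function(b) {
    pos <- sample.int(length(labels), n1)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  }, numeric(1))
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  structure(list(p_value = p, observed = observed, null = null,
                 n_perm = as.integer(n_perm)), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: AUC = %.3f, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

.subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$fs, epochs$window,
            epochs$labels[idx], epochs$channel_ids)
}

#' Nested cross-validation of a decoder
#'
#' Outer stratified `outer_folds`-fold CV estimates test performance; within
#' each outer training set an inner stratified `inner_folds`-fold CV trains
#' one model per inner fold, tracking validation AUC at every training
#' iteration. The per-fold optimal iteration count
#' ([select_iterations()]) then drives two test estimates:
#'
#' * naive: one fresh model retrained on the entire outer training set for
#'   the optimal number of iterations;
#' * ensemble: the inner models' voluntary-class probabilities on the test
#'   fold, averaged.
#'
#' Both test AUCs receive a label-permutation p-value.
#'
#' @param epochs labeled, preprocessed [epoch_set()].
#' @param variant `"lf"` or `"var"`.
#' @param plan a [cv_plan()].
#' @param config a [model_config()]; its seed is combined with the plan seed
#'   and fold indices so every model trains on its own stream.
#' @param n_perm permutations for the test p-values.
#' @param outer_subset optional integer vector restricting which outer folds
#'   are evaluated (the partition itself is unchanged).
#' @param keep_models keep the trained naive and inner models in the result.
#' @return A `cv_result`: list with `folds` (data.frame: `fold`, `auc_val`,
#'   `auc_naive`, `auc_ensemble`, `p_naive`, `p_ensemble`,
#'   `optimal_iterations`), `summary` (per-metric mean and SD), `plan`,
#'   `variant`, and optionally `models`.
#' @export
nested_cv <- function(epochs, variant = c("lf", "var"), plan = cv_plan(),
                      config = model_config(), n_perm = 1000,
                      outer_subset = NULL, keep_models = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(plan, "cv_plan"))
  labels <- epochs$labels
  if (is.null(labels)) stop("insufficient-data: epochs must carry labels")
  counts <- table(factor(labels, levels = c(0, 1)))
  if (length(counts) < 2 || min(counts) < plan$outer_folds)
    stop("insufficient-data: need at least outer_folds trials per class")
  d <- dim(epochs$data)
  set.seed(plan$seed)
  outer_fold <- .stratified_folds(labels, plan$outer_folds)
  folds_to_run <- if (is.null(outer_subset)) seq_len(plan$outer_folds) else
    intersect(seq_len(plan$outer_folds), outer_subset)

  rows <- list()
  models <- list()
  for (f in folds_to_run) {
    test_idx <- which(outer_fold == f)
    train_idx <- which(outer_fold != f)
    tr_labels <- labels[train_idx]
    set.seed(plan$seed * 1000L + f)
    inner_fold <- .stratified_folds(tr_labels, plan$inner_folds)

    inner_models <- list()
    traces <- list()
    for (j in seq_len(plan$inner_folds)) {
      it_idx <- train_idx[inner_fold != j]
      iv_idx <- train_idx[inner_fold == j]
      cfg <- config
      cfg$seed <- config$seed + 7919L * f + 104729L * j
      m <- build_model(variant, d[2], d[3], cfg)
      m <- train_model(m, .subset_epochs(epochs, it_idx),
                       .subset_epochs(epochs, iv_idx))
      inner_models[[j]] <- m
      traces[[j]] <- m$trace
    }
    optimal <- select_iterations(traces)
    auc_val <- mean(vapply(traces, max, numeric(1)))

    cfg <- config
    cfg$seed <- config$seed + 7919L * f
    cfg$max_iterations <- optimal
    naive <- build_model(variant, d[2], d[3], cfg)
    naive <- train_model(naive, .subset_epochs(epochs, train_idx))

    test_set <- .subset_epochs(epochs, test_idx)
    y_test <- labels[test_idx]
    p_naive_scores <- predict_proba(naive, test_set)[, 2]
    ens_scores <- rowMeans(vapply(inner_models, function(m)
      predict_proba(m, test_set)[, 2], numeric(length(test_idx))))

    pt_n <- permutation_test(p_naive_scores, y_test, n_perm,
                             seed = plan$seed * 100L + f)
    pt_e <- permutation_test(ens_scores, y_test, n_perm,
                             seed = plan$seed * 100L + f + 50L)
    rows[[length(rows) + 1]] <- data.frame(
      fold = f, auc_val = auc_val,
      auc_naive = roc_auc(p_naive_scores, y_test),
      auc_ensemble = roc_auc(ens_scores, y_test),
      p_naive = pt_n$p_value, p_ensemble = pt_e$p_value,
      optimal_iterations = optimal)
    if (keep_models)
      models[[as.character(f)]] <- list(naive = naive, inner = inner_models,
                                        test_idx = test_idx,
                                        train_idx = train_idx,
                                        perm_naive = pt_n, perm_ensemble = pt_e)
  }
  folds <- do.call(rbind, rows)
  metrics <- c("auc_val", "auc_naive", "auc_ensemble")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(folds[[m]]), numeric(1)))
  structure(list(folds = folds, summary = summary, plan = plan,
                 variant = variant, n_trials_per_class = min(table(labels)),
                 models = if (keep_models) models else NULL),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("nested CV (%s, %d outer x %d inner folds over %d trials/class)\n",
              toupper(x$variant), x$plan$outer_folds, x$plan$inner_folds,
              x$n_trials_per_class))
  for (m in x$summary$metric)
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m,
                x$summary$mean[x$summary$metric == m],
                x$summary$sd[x$summary$metric == m]))
  invisible(x)
}

# "+" when every evaluated fold is significant at alpha, "-" when none is,
# blank otherwise.
.perm_flag <- function(p, alpha = 0.05) {
  if (all(p < alpha)) "+" else if (all(p >= alpha)) "-" else ""
}

#' Group-level summary across participants
#'
#' Aggregates per-participant nested-CV results into group mean and SD per
#' metric, the Pearson correlation between test AUC and trials per class,
#' and (when two variants are supplied) the paired two-sided Wilcoxon
#' signed-rank test comparing the variants per testing procedure. When all
#' paired differences are zero the Wilcoxon p-value is defined as 1.
#'
#' @param results named list of `cv_result` lists: either one variant
#'   (`list(lf = list(...))`) or two (`list(lf = ..., var = ...)`), each
#'   inner list holding one `cv_result` per participant.
#' @param trial_counts numeric vector of trials per class, one per
#'   participant.
#' @return A `group_result`: list with `metrics` (data.frame of mean/SD per
#'   variant and metric), `correlation` (data.frame of Pearson r and p per
#'   variant and test metric) and `wilcoxon` (data.frame or NULL).
#' @export
group_summary <- function(results, trial_counts) {
  stopifnot(is.list(results), length(results) >= 1)
  n_participants <- length(results[[1]])
  if (!all(vapply(results, length, integer(1)) == n_participants))
    stop("mismatched participant sets across variants")
  if (n_participants < 3)
    stop("correlation requires at least 3 participants")
  if (length(trial_counts) != n_participants)
    stop("trial_counts length must match participant count")

  metric_of <- function(res, metric)
    vapply(res, function(r) mean(r$folds[[metric]]), numeric(1))
  metrics <- c("auc_val", "auc_naive", "auc_ensemble")

  mrows <- list(); crows <- list()
  for (v in names(results)) {
    for (m in metrics) {
      vals <- metric_of(results[[v]], m)
      mrows[[paste(v, m)]] <- data.frame(variant = v, metric = m,
                                         mean = mean(vals),
                                         sd = stats::sd(vals))
    }
    for (m in c("auc_naive", "auc_ensemble")) {
      vals <- metric_of(results[[v]], m)
      if (stats::sd(vals) == 0 || stats::sd(trial_counts) == 0) {
        # constant AUCs or trial counts: correlation undefined
        crows[[paste(v, m)]] <- data.frame(variant = v, metric = m,
                                           r = NA_real_, p = NA_real_)
      } else {
        ct <- stats::cor.test(vals, trial_counts)
        crows[[paste(v, m)]] <- data.frame(variant = v, metric = m,
                                           r = unname(ct$estimate),
                                           p = ct$p.value)
      }
    }
  }

  wil <- NULL
  if (length(results) == 2) {
    v1 <- names(results)[1]; v2 <- names(results)[2]
    wrows <- list()
    for (m in c("auc_naive", "auc_ensemble")) {
      a <- metric_of(results[[v1]], m)
      b <- metric_of(results[[v2]], m)
      if (all(a == b)) {
        wrows[[m]] <- data.frame(metric = m, statistic = NA_real_, p = 1)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                  exact = FALSE))
        wrows[[m]] <- data.frame(metric = m,
                                 statistic = unname(wt$statistic),
                                 p = wt$p.value)
      }
    }
    wil <- do.call(rbind, wrows)
  }
  structure(list(metrics = do.call(rbind, mrows),
                 correlation = do.call(rbind, crows),
                 wilcoxon = wil,
                 n_participants = n_participants),
            class = "group_result")
}
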