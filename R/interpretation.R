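#' Latent source time courses
#'
#' Projects every trial through the spatial filters: `S_hat = W' X`.
#'
#' @param W spatial filter matrix, channels x k.
#' @param epochs an [epoch_set()] (or trials x channels x time array).
#' @return numeric array, k x time x trials.
#' @export
latent_timecourses <- function(W, epochs) {
  data <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  d <- dim(data)
  if (nrow(W) != d[2]) stop("shape mismatch: W rows must equal channel count")
  k <- ncol(W)
  S <- array(NA_real_, c(k, d[3], d[1]))
  for (i in seq_len(d[1]))
    S[, , i] <- crossprod(W, data[i, , ])
  S
}

# Moore-Penrose pseudo-inverse with a relative singular-value cutoff.
.pinv <- function(M, rcond = 1e-10) {
  sv <- svd(M)
  keep <- sv$d > rcond * max(sv$d)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Activation patterns from spatial filters
#'
#' Recovers the activation patterns of the latent sources from the
#' discriminative spatial filters via the data covariance:
#' `A = Sigma_X W Sigma_S^-1`, where `Sigma_X` is the channel covariance of
#' the data concatenated over trials and time and `Sigma_S` the covariance
#' of the latent time courses. Unlike the filters `W`, the columns of `A`
#' are interpretable as the sensor projections of the latent sources.
#' `Sigma_S` is inverted by pseudo-inverse with a relative singular-value
#' cutoff; a near-singular latent covariance triggers a
#' `degenerate-latents` warning (the pseudo-inverse result is still
#' returned).
#'
#' @param W spatial filter matrix, channels x k.
#' @param epochs an [epoch_set()] (or trials x channels x time array).
#' @param cond_threshold condition-number threshold for the warning.
#' @return A `pattern_set`: list with `A` (channels x k), `sigma_X`,
#'   `sigma_S`, `S_hat` (k x time x trials) and `degenerate` flag.
#' @export
compute_patterns <- function(W, epochs, cond_threshold = 1e10) {
  data <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  d <- dim(data)
  if (prod(d[c(1, 3)]) < 2) stop("need at least 2 timepoints in total")
  Xc <- matrix(aperm(data, c(2, 3, 1)), nrow = d[2])  # channels x samples
  Xc <- Xc - rowMeans(Xc)
  N <- ncol(Xc)
  sigma_X <- tcrossprod(Xc) / N
  S_hat <- latent_timecourses(W, data)
  Sc <- matrix(S_hat, nrow = ncol(W))
  Sc <- Sc - rowMeans(Sc)
  sigma_S <- tcrossprod(Sc) / N
  sv <- svd(sigma_S)$d
  degenerate <- min(sv) <= 1e-10 * max(sv) ||
    max(sv) / max(min(sv), .Machine$double.xmin) > cond_threshold
  if (degenerate)
    warning("degenerate-latents: latent covariance is near-singular; ",
            "patterns computed by pseudo-inverse")
  A <- sigma_X %*% W %*% .pinv(sigma_S)
  structure(list(A = A, sigma_X = sigma_X, sigma_S = sigma_S, S_hat = S_hat,
                 degenerate = degenerate), class = "pattern_set")
}

#' Per-class latent-source contribution weights
#'
#' The contribution of latent source `s` to the assignment of class `c` is
#' the normalised L1 norm of that source's output-layer weights:
#' `w_s^c = sum_j |w[j, s, c]| / sum_i sum_j |w[j, i, c]|`. The weights are
#' nonnegative and sum to 1 over sources; with `k` sources an uninformative
#' model fluctuates around the mean weight `1 / k`.
#'
#' @param output_weights pooled-time x k x 2 tensor (see
#'   [output_weight_tensor()]).
#' @param class_index 0 (spontaneous) or 1 (voluntary).
#' @return numeric vector of length k summing to 1.
#' @export
ls_class_weights <- function(output_weights, class_index) {
  stopifnot(length(dim(output_weights)) == 3, class_index %in% c(0, 1))
  if (any(!is.finite(output_weights))) stop("output weights must be finite")
  wc <- abs(output_weights[, , class_index + 1, drop = FALSE])
  num <- apply(wc, 2, sum)
  denom <- sum(num)
  if (denom == 0)
    stop("undefined-weights: all output weights are zero for this class")
  num / denom
}

#' Weighted average of activation patterns
#'
#' Collapses the k pattern columns into one per-channel vector:
#' `sum_s weight_s * A[, s]`. With uniform weights (`weights = NULL`) this
#' is the mean pattern in which every latent source counts `1 / k`.
#'
#' @param patterns a [compute_patterns()] result (or a channels x k matrix).
#' @param weights optional length-k weight vector (e.g.
#'   [ls_class_weights()]).
#' @return numeric per-channel vector.
#' @export
average_pattern <- function(patterns, weights = NULL) {
  A <- if (inherits(patterns, "pattern_set")) patterns$A else patterns
  k <- ncol(A)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k) stop("weights length must equal pattern count")
  as.numeric(A %*% weights)
}

#' Fraction of explained variance per channel
#'
#' Reconstructs the sensor signal from the latent subspace
#' (`X_rec = A S_hat`) and reports, per channel, the squared Pearson
#' correlation between the original and reconstructed time courses
#' concatenated over trials. `full_fve` is the unweighted mean over
#' channels. A channel that is constant in the original data has undefined
#' FVE; it is flagged and excluded from `full_fve`. A constant
#' reconstruction explains nothing and scores 0.
#'
#' @param epochs an [epoch_set()] (or trials x channels x time array).
#' @param A activation patterns, channels x k.
#' @param S_hat latent time courses, k x time x trials.
#' @return An `fve_map`: list with `fve` (per-channel values in `[0, 1]`),
#'   `full_fve`, and `flagged` (indices of constant channels).
#' @export
fve_map <- function(epochs, A, S_hat) {
  data <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  d <- dim(data)
  if (nrow(A) != d[2] || dim(S_hat)[1] != ncol(A) ||
      dim(S_hat)[2] != d[3] || dim(S_hat)[3] != d[1])
    stop("shape mismatch between data, A and S_hat")
  X <- matrix(aperm(data, c(2, 3, 1)), nrow = d[2])
  Sc <- matrix(S_hat, nrow = ncol(A))
  Xrec <- A %*% Sc
  fve <- numeric(d[2])
  flagged <- integer(0)
  for (i in seq_len(d[2])) {
    if (stats::sd(X[i, ]) == 0) {
      fve[i] <- NA_real_
      flagged <- c(flagged, i)
    } else if (stats::sd(Xrec[i, ]) == 0) {
      fve[i] <- 0
    } else {
      fve[i] <- stats::cor(X[i, ], Xrec[i, ])^2
    }
  }
  structure(list(fve = fve, full_fve = mean(fve, na.rm = TRUE),
                 flagged = flagged), class = "fve_map")
}

#' Frontal ocular-artifact diagnostic
#'
#' Relates each latent source's loading on the frontal sensors (the ones
#' most exposed to eye-movement artifacts) to its contribution to the
#' classification: `f_s` is the L1 norm of the frontal entries of pattern
#' column `s` (or filter column, see `source_matrix`), `o_s` the L1 norm of
#' the source's output weights for the given class, and `pearson_r` their
#' correlation across sources. A strongly positive correlation indicates
#' the classifier leans on frontal (artifact-prone) sources. When either
#' vector is constant the correlation is undefined and flagged.
#'
#' @param patterns a [compute_patterns()] result (its activation patterns
#'   `A` are used) or any channels x k matrix — pass the spatial filters `W`
#'   directly to base the diagnostic on filters instead of patterns.
#' @param output_weights pooled-time x k x 2 tensor.
#' @param frontal_mask logical per-channel mask (non-empty).
#' @param class_index 0 or 1 (default 1, voluntary).
#' @return An `artifact_diagnostic`: list with `frontal_l1`, `output_l1`,
#'   `pearson_r`, `undefined`.
#' @export
frontal_diagnostic <- function(patterns, output_weights, frontal_mask,
                               class_index = 1) {
  M <- if (inherits(patterns, "pattern_set")) patterns$A else patterns
  if (!any(frontal_mask)) stop("frontal mask must select at least 1 channel")
  if (length(frontal_mask) != nrow(M))
    stop("frontal mask length must equal channel count")
  k <- ncol(M)
  if (k < 3) stop("need at least 3 latent sources for a correlation")
  f <- colSums(abs(M[frontal_mask, , drop = FALSE]))
  wc <- abs(output_weights[, , class_index + 1, drop = FALSE])
  o <- apply(wc, 2, sum)
  undefined <- stats::sd(f) == 0 || stats::sd(o) == 0
  r <- if (undefined) NA_real_ else stats::cor(f, o)
  structure(list(frontal_l1 = f, output_l1 = o, pearson_r = r,
                 undefined = undefined), class = "artifact_diagnostic")
}
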