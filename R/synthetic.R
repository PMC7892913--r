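#' Simulation configuration for synthetic MEG epochs
#'
#' Defines the study conditions the generator emulates: 204 planar
#' gradiometers sampled at 1000 Hz, epochs spanning -0.2 to 1.0 s around
#' fixation onset, and a small set of planted latent sources mixed into the
#' sensors as `X = A S + noise`. The voluntary class carries a slow
#' quarter-sine deflection rising from fixation onset to the 0.5 s feedback
#' time; an evoked post-feedback transient is present in both classes with a
#' larger voluntary gain; an optional frontal step-like source mimics
#' oculomotor artifacts.
#'
#' @param n_voluntary,n_spontaneous trials per class.
#' @param n_channels number of gradiometer channels (must be even; channels
#'   come in pairs sharing a sensor position).
#' @param fs sampling rate in Hz.
#' @param epoch_window numeric pair, epoch limits in seconds relative to
#'   fixation onset (start < 0 < end).
#' @param k_true number of planted latent sources.
#' @param slow_amplitude amplitude of the voluntary-only slow deflection.
#' @param evoked_amplitude amplitude of the post-feedback evoked transient.
#' @param artifact_amplitude amplitude of the frontal step-like artifact
#'   source (0 disables it; its class gain makes it discriminative when on).
#' @param background_amplitude amplitude of the class-neutral 10 Hz
#'   oscillatory background sources.
#' @param noise_sd standard deviation of the additive Gaussian sensor noise.
#' @param seed integer RNG seed; generation is bit-reproducible given the
#'   configuration.
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(n_voluntary = 200, n_spontaneous = 200,
                       n_channels = 204, fs = 1000,
                       epoch_window = c(-0.2, 1.0), k_true = 6,
                       slow_amplitude = 0.4, evoked_amplitude = 2.5,
                       artifact_amplitude = 0, background_amplitude = 1,
                       noise_sd = 1, seed = 1) {
  if (n_channels < 2 || n_channels %% 2 != 0)
    stop("invalid-config: n_channels must be even (gradiometer pairs)")
  if (!(epoch_window[1] < 0 && epoch_window[2] > 0))
    stop("invalid-config: epoch_window must satisfy start < 0 < end")
  if (fs <= 0) stop("invalid-config: fs must be positive")
  amps <- c(slow_amplitude, evoked_amplitude, artifact_amplitude,
            background_amplitude, noise_sd)
  if (any(amps < 0)) stop("invalid-config: amplitudes must be >= 0")
  if (k_true < 1) stop("invalid-config: k_true must be >= 1")
  structure(list(
    n_voluntary = n_voluntary, n_spontaneous = n_spontaneous,
    n_channels = n_channels, fs = fs, epoch_window = epoch_window,
    k_true = k_true, slow_amplitude = slow_amplitude,
    evoked_amplitude = evoked_amplitude,
    artifact_amplitude = artifact_amplitude,
    background_amplitude = background_amplitude, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' Construct a sensor layout on the unit disc
#'
#' Places `n_channels / 2` sensor positions on concentric rings of a unit
#' disc (a schematic head seen from above, positive y towards the face) and
#' assigns two gradiometer channels per position, the second member of each
#' pair offset slightly so that every channel has a unique coordinate. The
#' frontal mask selects the channels whose vertical coordinate lies above the
#' `1 - frontal_fraction` quantile; these are the sensors most exposed to
#' ocular artifacts.
#'
#' @param n_channels even channel count (>= 2).
#' @param frontal_fraction fraction of channels flagged frontal (0 < f < 1).
#' @param seed integer seed controlling ring angle offsets.
#' @return A `sensor_layout`: list with `channel_ids`, `positions`
#'   (n x 2 matrix) and logical `frontal_mask`.
#' @export
make_layout <- function(n_channels = 204, frontal_fraction = 0.1, seed = 1) {
  if (n_channels < 2 || n_channels %% 2 != 0)
    stop("invalid-layout: n_channels must be even and >= 2")
  if (frontal_fraction <= 0 || frontal_fraction >= 1)
    stop("invalid-layout: frontal_fraction must be in (0, 1)")
  set.seed(as.integer(seed))
  n_pos <- n_channels / 2
  if (n_pos == 1) {
    centers <- matrix(0, 1, 2)
  } else {
    n_rings <- max(1, round(sqrt(n_pos / 3)))
    radii <- 0.92 * seq_len(n_rings) / n_rings
    raw <- radii / sum(radii) * n_pos
    counts <- floor(raw)
    rem <- n_pos - sum(counts)
    if (rem > 0) {
      extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    centers <- do.call(rbind, lapply(seq_len(n_rings), function(r) {
      m <- counts[r]
      if (m == 0) return(NULL)
      th <- 2 * pi * (seq_len(m) - 1) / m + runif(1, 0, 2 * pi / max(m, 1))
      cbind(radii[r] * cos(th), radii[r] * sin(th))
    }))
  }
  # pair members share a position up to a small fixed offset
  pos <- matrix(NA_real_, n_channels, 2)
  pos[seq(1, n_channels, by = 2), ] <- centers
  pos[seq(2, n_channels, by = 2), ] <- cbind(centers[, 1], centers[, 2] + 0.012)
  ids <- sprintf("GRAD%03d%s", rep(seq_len(n_pos), each = 2), c("a", "b"))
  thr <- stats::quantile(pos[, 2], 1 - frontal_fraction, names = FALSE)
  mask <- pos[, 2] > thr
  if (!any(mask)) mask[which.max(pos[, 2])] <- TRUE
  if (all(mask)) mask[which.min(pos[, 2])] <- FALSE
  structure(list(channel_ids = ids, positions = pos, frontal_mask = mask),
            class = "sensor_layout")
}

# Gaussian spatial profile over channels, unit Euclidean norm.
.gauss_column <- function(positions, center, width) {
  d2 <- (positions[, 1] - center[1])^2 + (positions[, 2] - center[2])^2
  a <- exp(-d2 / (2 * width^2))
  a / sqrt(sum(a^2))
}

#' Planted ground truth: mixing matrix, source kinds and class gains
#'
#' Builds the generative mixing matrix `A_true` (channels x k) whose columns
#' are smooth spatial Gaussians on the sensor layout, unit-normalised. Source
#' kinds are assigned in the order slow-deflection (left central/parietal
#' sensors), evoked (medial parietal), artifact (frontal), then oscillatory
#' background. Class gains (columns: spontaneous, voluntary) make the slow
#' source voluntary-only, the evoked and artifact sources stronger in the
#' voluntary class, and the background class-neutral.
#'
#' @param config a [sim_config()].
#' @param layout a [make_layout()] result with matching channel count.
#' @return A `ground_truth`: list with `A_true`, `source_kinds`, `class_gain`.
#' @export
make_ground_truth <- function(config, layout) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "sensor_layout"))
  if (nrow(layout$positions) != config$n_channels)
    stop("layout/config channel mismatch")
  k <- config$k_true
  kinds <- c("slow-deflection", "evoked", "artifact",
             rep("oscillatory", max(0, k - 3)))[seq_len(k)]
  pos <- layout$positions
  frontal_center <- c(mean(pos[layout$frontal_mask, 1]),
                      max(pos[, 2]) * 0.95)
  A <- matrix(NA_real_, config$n_channels, k)
  gain <- matrix(1, k, 2, dimnames = list(NULL, c("spontaneous", "voluntary")))
  osc_centers <- cbind(runif(k, -0.6, 0.6), runif(k, -0.6, 0.2))
  for (s in seq_len(k)) {
    A[, s] <- switch(kinds[s],
      "slow-deflection" = .gauss_column(pos, c(-0.38, -0.12), 0.30),
      "evoked"          = .gauss_column(pos, c(0.02, -0.42), 0.30),
      "artifact"        = .gauss_column(pos, frontal_center, 0.16),
      "oscillatory"     = .gauss_column(pos, osc_centers[s, ], 0.35))
    gain[s, ] <- switch(kinds[s],
      "slow-deflection" = c(0, 1),
      "evoked"          = c(0.5, 1),
      "artifact"        = c(0.25, 1),
      "oscillatory"     = c(1, 1))
  }
  structure(list(A_true = A, source_kinds = kinds, class_gain = gain),
            class = "ground_truth")
}

#' Simulate latent source time courses for one trial
#'
#' Emits the `k_true x n_times` source matrix for a single trial of the given
#' class. The slow-deflection source ramps as a quarter sine from fixation
#' onset to the 0.5 s feedback time and then holds; the evoked source is a
#' damped 5 Hz transient over 0.5-0.9 s; oscillatory sources are 10 Hz
#' sinusoids with a fresh uniform random phase per trial; the artifact source
#' is a smooth step at a random time before feedback. Each source is scaled
#' by its amplitude and by the class gain. Consumes the current RNG stream.
#'
#' @param config a [sim_config()].
#' @param truth a [make_ground_truth()] result.
#' @param label 0 (spontaneous) or 1 (voluntary).
#' @return `k_true x n_times` matrix.
#' @export
simulate_sources <- function(config, truth, label) {
  stopifnot(label %in% c(0, 1))
  w <- config$epoch_window
  nt <- round((w[2] - w[1]) * config$fs)
  tt <- w[1] + (seq_len(nt) - 1) / config$fs
  gcol <- label + 1L
  S <- matrix(0, config$k_true, nt)
  for (s in seq_len(config$k_true)) {
    g <- truth$class_gain[s, gcol]
    S[s, ] <- switch(truth$source_kinds[s],
      "slow-deflection" = {
        u <- pmin(pmax(tt / 0.5, 0), 1)
        config$slow_amplitude * g * sin(pi * u / 2)
      },
      "evoked" = {
        v <- numeric(nt)
        inw <- tt >= 0.5 & tt <= 0.9
        v[inw] <- sin(2 * pi * 5 * (tt[inw] - 0.5)) *
          exp(-(tt[inw] - 0.5) / 0.15)
        config$evoked_amplitude * g * v
      },
      "oscillatory" = {
        phi <- runif(1, 0, 2 * pi)
        config$background_amplitude * g * sin(2 * pi * 10 * tt + phi)
      },
      "artifact" = {
        t0 <- runif(1, 0, 0.5)
        config$artifact_amplitude * g * plogis((tt - t0) / 0.02)
      },
      numeric(nt))
  }
  S
}

#' Generate a synthetic MEG dataset
#'
#' Draws every trial as `A_true %*% S(label) + noise`, with white Gaussian
#' sensor noise of standard deviation `noise_sd`, labels shuffled in trial
#' order, and all randomness controlled by `config$seed` (two calls with the
#' same configuration produce identical arrays).
#'
#' @param config a [sim_config()].
#' @param layout optional [make_layout()]; built from the config when absent.
#' @return A `synthetic_dataset`: list with `epochs` (an [epoch_set()] of
#'   dimension trials x channels x time), `labels`, `layout`, `truth`,
#'   `config`.
#' @export
simulate_epochs <- function(config, layout = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_voluntary < 1 || config$n_spontaneous < 1)
    stop("invalid-config: trial counts must be positive")
  if (is.null(layout))
    layout <- make_layout(config$n_channels, 0.1, seed = config$seed)
  set.seed(config$seed)
  truth <- make_ground_truth(config, layout)
  n_tr <- config$n_voluntary + config$n_spontaneous
  labels <- sample(rep(c(1L, 0L), c(config$n_voluntary, config$n_spontaneous)))
  w <- config$epoch_window
  nt <- round((w[2] - w[1]) * config$fs)
  S_all <- array(NA_real_, c(config$k_true, nt, n_tr))
  for (i in seq_len(n_tr))
    S_all[, , i] <- simulate_sources(config, truth, labels[i])
  sig <- truth$A_true %*% matrix(S_all, config$k_true)
  dim(sig) <- c(config$n_channels, nt, n_tr)
  if (config$noise_sd > 0)
    sig <- sig + array(rnorm(length(sig), sd = config$noise_sd), dim(sig))
  data <- aperm(sig, c(3, 1, 2))
  epochs <- epoch_set(data, fs = config$fs, window = w, labels = labels,
                      channel_ids = layout$channel_ids)
  structure(list(epochs = epochs, labels = labels, layout = layout,
                 truth = truth, config = config),
            class = "synthetic_dataset")
}

#' Simulate a gaze event log with known intent
#'
#' Emits a time-ordered gaze log in the on-disk CSV schema: ball dwells with
#' ground-truth intent, confirmation fixations following voluntary dwells
#' within the interface timing windows (feedback at dwell onset + 500 ms),
#' and exploration fixations after spontaneous dwells. When `p_boundary > 0`
#' a fixed rotation of boundary cases is interleaved: below-threshold dwells,
#' dwells with a late initial fixation onset, and dwells with a delayed
#' confirmation, all carrying ground truth `"excluded"`.
#'
#' @param n_moves number of ball dwells to emit.
#' @param p_spontaneous probability a non-boundary dwell is spontaneous.
#' @param seed integer seed.
#' @param p_boundary probability a dwell is a boundary case (default 0).
#' @return `data.frame` with columns `event_id`, `kind`, `target_id`,
#'   `onset_ms`, `offset_ms`, `initial_onset_latency_ms`, `truth_intent`.
#' @export
simulate_gaze_log <- function(n_moves, p_spontaneous, seed, p_boundary = 0) {
  if (p_spontaneous < 0 || p_spontaneous > 1)
    stop("p_spontaneous must be in [0, 1]")
  set.seed(as.integer(seed))
  rows <- list()
  t_cur <- 0
  eid <- 0L
  boundary_kinds <- c("below-threshold", "late-onset", "delayed-confirmation")
  n_boundary <- 0L
  emit <- function(kind, target, onset, offset, lat, truth) {
    eid <<- eid + 1L
    rows[[eid]] <<- data.frame(
      event_id = eid, kind = kind, target_id = target,
      onset_ms = round(onset), offset_ms = round(offset),
      initial_onset_latency_ms = round(lat), truth_intent = truth,
      stringsAsFactors = FALSE)
  }
  for (m in seq_len(n_moves)) {
    t_cur <- t_cur + runif(1, 80, 300)
    ball <- sprintf("ball_%02d", 1 + (m %% 20))
    if (runif(1) < p_boundary) {
      n_boundary <- n_boundary + 1L
      bk <- boundary_kinds[1 + (n_boundary %% 3L)]
      if (bk == "below-threshold") {
        dur <- runif(1, 200, 480)
        emit("ball_dwell", ball, t_cur, t_cur + dur, runif(1, 0, 40),
             "excluded")
        t_cur <- t_cur + dur
      } else if (bk == "late-onset") {
        dur <- runif(1, 550, 800)
        emit("ball_dwell", ball, t_cur, t_cur + dur, runif(1, 60, 140),
             "excluded")
        t_cur <- t_cur + dur
        emit("other_fix", "other", t_cur + 40, t_cur + 340, 0, NA)
        t_cur <- t_cur + 340
      } else {
        dur <- runif(1, 600, 900)
        off <- t_cur + dur
        conf_on <- off + runif(1, 260, 420)
        emit("ball_dwell", ball, t_cur, off, runif(1, 0, 40), "excluded")
        emit("confirm_fix", "confirm", conf_on, conf_on + runif(1, 400, 650),
             0, NA)
        t_cur <- conf_on + 650
      }
    } else if (runif(1) < p_spontaneous) {
      dur <- runif(1, 500, 900)
      emit("ball_dwell", ball, t_cur, t_cur + dur, runif(1, 0, 40),
           "spontaneous")
      t_cur <- t_cur + dur
      emit("other_fix", "other", t_cur + 30, t_cur + 30 + runif(1, 150, 400),
           0, NA)
      t_cur <- t_cur + 430
    } else {
      dur <- 500 + runif(1, 40, 440)
      off <- t_cur + dur
      conf_on <- off + runif(1, 20, 180)
      emit("ball_dwell", ball, t_cur, off, runif(1, 0, 40), "voluntary")
      emit("confirm_fix", "confirm", conf_on, conf_on + runif(1, 400, 650),
           0, NA)
      t_cur <- conf_on + 650
    }
  }
  do.call(rbind, rows)
}
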