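# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept tiny so the full suite stays fast.

# A small labeled epoch set with a planted mean offset on three channels
# separating the classes (strongly separable).
separable_epochs <- function(n_per_class = 50, n_channels = 8, n_times = 30,
                             offset = 2, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  data <- array(rnorm(n * n_channels * n_times, sd = 0.5),
                c(n, n_channels, n_times))
  labels <- rep(0:1, each = n_per_class)
  for (ch in c(2, 3, 5))
    data[labels == 1, ch, ] <- data[labels == 1, ch, ] + offset
  epoch_set(data, fs = 125, window = c(-0.2, n_times / 125 - 0.2),
            labels = labels)
}

# Pure-noise epochs with arbitrary balanced labels (null association).
null_epochs <- function(n_per_class = 30, n_channels = 8, n_times = 30,
                        seed = 7) {
  set.seed(seed)
  n <- 2 * n_per_class
  data <- array(rnorm(n * n_channels * n_times), c(n, n_channels, n_times))
  epoch_set(data, fs = 125, window = c(-0.2, n_times / 125 - 0.2),
            labels = rep(0:1, each = n_per_class))
}

# Fast model recipe for structural tests.
tiny_config <- function(...) {
  defaults <- list(k = 4, l_filt = 7, pool = 4, batch_size = 32,
                   max_iterations = 40, dropout_rate = 0.5,
                   l1_penalty = 3e-4, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

# Gaze event rows for labeling tests.
gaze_row <- function(kind, onset, offset, lat = 0, target = "ball_01") {
  data.frame(kind = kind, target_id = target, onset_ms = onset,
             offset_ms = offset, initial_onset_latency_ms = lat,
             stringsAsFactors = FALSE)
}
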