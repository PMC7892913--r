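test_that("layout places channels on the unit disc with a sensible frontal mask", {
  lay <- make_layout(204, 0.1, seed = 7)
  expect_length(lay$channel_ids, 204)
  expect_equal(dim(lay$positions), c(204, 2))
  expect_true(all(sqrt(rowSums(lay$positions^2)) <= 1.01))
  # ~10% of channels frontal, in whole gradiometer pairs give or take the
  # pair offset
  expect_gte(sum(lay$frontal_mask), 12)
  expect_lte(sum(lay$frontal_mask), 30)
  # frontal channels are the topmost ones
  expect_gt(min(lay$positions[lay$frontal_mask, 2]),
            max(lay$positions[!lay$frontal_mask, 2]) - 1e-12)
})

test_that("layout honors the proper-subset invariant at minimum size", {
  lay <- make_layout(2, 0.5, seed = 0)
  expect_equal(sum(lay$frontal_mask), 1)
})

test_that("layout rejects odd channel counts", {
  expect_error(make_layout(3, 0.1, seed = 0), "invalid-layout")
})

test_that("layout is deterministic under a fixed seed", {
  expect_identical(make_layout(60, 0.1, seed = 3), make_layout(60, 0.1, seed = 3))
})

test_that("ground-truth mixing columns are unit-norm and spatially targeted", {
  cfg <- sim_config(n_channels = 204, artifact_amplitude = 1, seed = 2)
  lay <- make_layout(204, 0.1, seed = 2)
  set.seed(2)
  gt <- make_ground_truth(cfg, lay)
  expect_equal(colSums(gt$A_true^2), rep(1, cfg$k_true), tolerance = 1e-12)
  frontal_share <- colSums(abs(gt$A_true[lay$frontal_mask, , drop = FALSE])) /
    colSums(abs(gt$A_true))
  slow <- which(gt$source_kinds == "slow-deflection")
  art <- which(gt$source_kinds == "artifact")
  expect_lt(frontal_share[slow], 0.2)   # slow source mostly non-frontal
  expect_gt(frontal_share[art], 0.5)    # artifact source mostly frontal
  # class gains: slow is voluntary-only, background class-neutral
  expect_equal(unname(gt$class_gain[slow, "spontaneous"]), 0)
  expect_equal(unname(gt$class_gain[slow, "voluntary"]), 1)
  osc <- gt$source_kinds == "oscillatory"
  expect_true(all(gt$class_gain[osc, ] == 1))
})

test_that("slow source ramps as a quarter sine and peaks at the feedback time", {
  cfg <- sim_config(n_channels = 8, k_true = 2, slow_amplitude = 1.7,
                    background_amplitude = 0, seed = 1)
  lay <- make_layout(8, 0.2, seed = 1)
  set.seed(1)
  gt <- make_ground_truth(cfg, lay)
  S <- simulate_sources(cfg, gt, label = 1)
  tt <- cfg$epoch_window[1] + (seq_len(ncol(S)) - 1) / cfg$fs
  s <- S[which(gt$source_kinds == "slow-deflection"), ]
  expect_equal(s[which.min(abs(tt - 0.5))], 1.7,
               tolerance = 1e-6)                      # sin(pi/2) at ramp end
  expect_equal(s[which.min(abs(tt - 0.25))], 1.7 * sin(pi / 4),
               tolerance = 1e-6)
  expect_true(all(s[tt < 0] == 0))
  expect_true(all(s[tt > 0.5] == 1.7))                # held after feedback
  # voluntary-only
  S0 <- simulate_sources(cfg, gt, label = 0)
  expect_true(all(S0[which(gt$source_kinds == "slow-deflection"), ] == 0))
})

test_that("null class gains make the two classes identically distributed", {
  cfg <- sim_config(n_channels = 8, k_true = 4, slow_amplitude = 0,
                    evoked_amplitude = 0, seed = 1)
  lay <- make_layout(8, 0.2, seed = 1)
  set.seed(1)
  gt <- make_ground_truth(cfg, lay)
  set.seed(5); S1 <- simulate_sources(cfg, gt, label = 1)
  set.seed(5); S0 <- simulate_sources(cfg, gt, label = 0)
  expect_identical(S1, S0)
})

test_that("oscillatory sources have zero mean over random phases", {
  cfg <- sim_config(n_channels = 8, k_true = 4, seed = 1)
  lay <- make_layout(8, 0.2, seed = 1)
  set.seed(1)
  gt <- make_ground_truth(cfg, lay)
  osc <- which(gt$source_kinds == "oscillatory")[1]
  set.seed(99)
  draws <- replicate(1000, simulate_sources(cfg, gt, label = 0)[osc, 300])
  # random-phase expectation is 0; amplitude 1 => sd = 1/sqrt(2)
  se <- 1 / sqrt(2) / sqrt(1000)
  expect_lt(abs(mean(draws)), 4 * se)
})

test_that("silent configuration yields all-zero epochs", {
  cfg <- sim_config(n_voluntary = 4, n_spontaneous = 4, n_channels = 6,
                    fs = 250, epoch_window = c(-0.1, 0.1), k_true = 3,
                    slow_amplitude = 0, evoked_amplitude = 0,
                    background_amplitude = 0, noise_sd = 0, seed = 1)
  ds <- simulate_epochs(cfg)
  expect_true(all(ds$epochs$data == 0))
})

test_that("pure-noise epochs have unit sample variance", {
  cfg <- sim_config(n_voluntary = 100, n_spontaneous = 100, n_channels = 8,
                    fs = 500, epoch_window = c(-0.1, 0.1), k_true = 3,
                    slow_amplitude = 0, evoked_amplitude = 0,
                    background_amplitude = 0, noise_sd = 1, seed = 3)
  ds <- simulate_epochs(cfg)
  v <- var(as.numeric(ds$epochs$data))
  n <- length(ds$epochs$data)
  expect_lt(abs(v - 1), 3 * sqrt(2 / n))
})

test_that("dataset generation is bit-reproducible and label counts match", {
  cfg <- sim_config(n_voluntary = 7, n_spontaneous = 12, n_channels = 10,
                    fs = 250, epoch_window = c(-0.2, 0.2), seed = 11)
  d1 <- simulate_epochs(cfg)
  d2 <- simulate_epochs(cfg)
  expect_identical(d1$epochs$data, d2$epochs$data)
  expect_identical(d1$labels, d2$labels)
  expect_equal(sum(d1$labels == 1), 7)
  expect_equal(sum(d1$labels == 0), 12)
  expect_equal(dim(d1$epochs$data)[3], round(0.4 * 250))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_channels = 7), "invalid-config")
  expect_error(sim_config(epoch_window = c(0.1, 0.5)), "invalid-config")
  expect_error(sim_config(noise_sd = -1), "invalid-config")
  expect_error(simulate_epochs(sim_config(n_voluntary = 0)), "invalid-config")
})

test_that("class difference on slow-loaded channels grows with slow amplitude", {
  diffs <- vapply(c(0.25, 1, 4), function(a) {
    cfg <- sim_config(n_voluntary = 100, n_spontaneous = 100, n_channels = 16,
                      fs = 250, k_true = 4, slow_amplitude = a,
                      evoked_amplitude = 0, noise_sd = 1, seed = 21)
    ds <- simulate_epochs(cfg)
    slow_col <- ds$truth$A_true[, ds$truth$source_kinds == "slow-deflection"]
    ch <- which.max(abs(slow_col))
    tt <- cfg$epoch_window[1] +
      (seq_len(dim(ds$epochs$data)[3]) - 1) / cfg$fs
    late <- tt >= 0.25 & tt <= 0.5
    mean(ds$epochs$data[ds$labels == 1, ch, late]) -
      mean(ds$epochs$data[ds$labels == 0, ch, late])
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})

test_that("gaze log with no spontaneous moves confirms every dwell in time", {
  log <- simulate_gaze_log(40, p_spontaneous = 0, seed = 4)
  dwells <- which(log$kind == "ball_dwell")
  expect_true(all(log$offset_ms[dwells] - log$onset_ms[dwells] >= 500))
  for (i in dwells) {
    expect_lt(i, nrow(log))
    expect_equal(log$kind[i + 1], "confirm_fix")
    expect_lte(log$onset_ms[i + 1] - log$offset_ms[i], 200)
  }
})

test_that("gaze log with only spontaneous moves emits no confirmations", {
  log <- simulate_gaze_log(40, p_spontaneous = 1, seed = 4)
  expect_false(any(log$kind == "confirm_fix"))
})

test_that("labeling recovers ground-truth intent from the simulated log", {
  log <- simulate_gaze_log(100, p_spontaneous = 0.5, seed = 8,
                           p_boundary = 0.2)
  lab <- label_fixations(log)
  # every ball dwell gets exactly one label
  expect_equal(nrow(lab), sum(log$kind == "ball_dwell"))
  expect_true(all(lab$label %in% c("voluntary", "spontaneous", "excluded")))
  # non-boundary rows match their stored intent exactly; boundary rows are
  # excluded
  expect_identical(lab$label, lab$truth_intent)
  expect_true(any(lab$label == "excluded"))
  expect_true(all(nchar(lab$reason[lab$label == "excluded"]) > 0))
})

test_that("gaze log and layout round-trip through their CSV schemas", {
  log <- simulate_gaze_log(10, 0.5, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_gaze_log(log, f)
  back <- read_gaze_log(f)
  expect_equal(back$onset_ms, log$onset_ms)
  expect_equal(back$kind, log$kind)
  lay <- make_layout(12, 0.25, seed = 5)
  f2 <- tempfile(fileext = ".csv")
  write_layout(lay, f2)
  lay2 <- read_layout(f2)
  expect_equal(lay2$channel_ids, lay$channel_ids)
  expect_equal(lay2$frontal_mask, lay$frontal_mask)
  expect_equal(lay2$positions[, 1], lay$positions[, 1], tolerance = 1e-12)
  unlink(c(f, f2))
})
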