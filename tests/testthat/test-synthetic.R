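# Synthetic-data generators: trajectories, tuned spike trains, LFP,
# waveforms, and the multi-session protocol.

test_that("trajectory generator respects bounds, rate and determinism", {
  traj <- generate_trajectory(duration = 120, arena_size = 1, fs = 50,
                              seed = 1)
  expect_length(traj$t, 6000)
  expect_true(all(traj$x >= 0 & traj$x <= 1))
  expect_true(all(traj$y >= 0 & traj$y <= 1))
  expect_equal(diff(traj$t), rep(0.02, 5999), tolerance = 1e-12)
  traj2 <- generate_trajectory(duration = 120, arena_size = 1, fs = 50,
                               seed = 1)
  expect_identical(traj$x, traj2$x)
  expect_identical(traj$hd, traj2$hd)
  expect_error(generate_trajectory(duration = -5), "duration")
  expect_error(generate_trajectory(fs = 0), "fs")
})

test_that("20-minute foraging covers the arena and hits the target speed", {
  traj <- fix_traj()
  expect_equal(mean(traj_speed(traj)), 0.15, tolerance = 0.1)
  occ <- occupancy_maps(traj)$raw
  # near-full coverage: at least 97% of the 2 cm bins are visited
  expect_lt(sum(occ == 0) / length(occ), 0.03)
})

test_that("grid spike generator is an inhomogeneous Poisson sampler", {
  traj <- fix_traj()
  # zero intensity -> empty train
  gt0 <- ground_truth("grid", peak_rate = 0, baseline_rate = 0)
  expect_length(generate_grid_spikes(traj, gt0, seed = 1)$times, 0)
  # peak below baseline is rejected
  gtbad <- ground_truth("grid", peak_rate = 1, baseline_rate = 5)
  expect_error(generate_grid_spikes(traj, gtbad), "peak_rate")
  # spike count within 3 SD of the integrated intensity along the path
  gt <- fix_grid_gt()
  lam <- gridnet:::cell_intensity(gt, traj$x, traj$y)
  expected <- sum(lam) / traj$fs
  n_obs <- length(fix_grid_spikes()$times)
  expect_lt(abs(n_obs - expected), 3 * sqrt(expected))
  # determinism
  s1 <- generate_grid_spikes(traj, gt, seed = 7)
  s2 <- generate_grid_spikes(traj, gt, seed = 7)
  expect_identical(s1$times, s2$times)
})

test_that("empirical in/out-field rate ratio matches the intensity map", {
  traj <- fix_traj()
  gt <- fix_grid_gt()
  spk <- fix_grid_spikes()
  g <- gridnet:::grid_intensity(traj$x, traj$y, gt$spacing, gt$orientation,
                                gt$phase)
  hi <- g > 0.7
  lo <- g < 0.3
  idx <- pmin(pmax(round((spk$times - traj$t[1]) * traj$fs) + 1, 1),
              length(traj$t))
  rate_hi <- sum(hi[idx]) / (sum(hi) / traj$fs)
  rate_lo <- sum(lo[idx]) / (sum(lo) / traj$fs)
  lam_hi <- mean(gridnet:::cell_intensity(gt, traj$x[hi], traj$y[hi]))
  lam_lo <- mean(gridnet:::cell_intensity(gt, traj$x[lo], traj$y[lo]))
  expect_equal(rate_hi / rate_lo, lam_hi / lam_lo, tolerance = 0.15)
})

test_that("burst injection and theta modulation behave as configured", {
  traj <- generate_trajectory(duration = 300, seed = 3)
  gtb <- ground_truth("grid", spacing = 0.4, peak_rate = 10,
                      baseline_rate = 1, burst_prob = 0.5)
  spk <- generate_cell_spikes(traj, gtb, seed = 4)
  br <- bursting_ratio(spk)
  expect_gt(br$n_burst, 0)
  gtn <- ground_truth("grid", spacing = 0.4, peak_rate = 10,
                      baseline_rate = 1)
  spk0 <- generate_cell_spikes(traj, gtn, seed = 4)
  br0 <- bursting_ratio(spk0)
  expect_gt(br$ratio, br0$ratio)
})

test_that("session protocol remaps coherently and reuses the familiar map", {
  pop <- list(fix_grid_gt(),
              ground_truth("grid", spacing = 0.4, phase = c(0.25, 0.05)))
  proto <- session_protocol(durations = 60, remap_rotation = pi / 6,
                            remap_shift = c(0.1, 0.05))
  bundle <- generate_session_protocol(proto, pop, seed = 9)
  expect_named(bundle$sessions, c("Familiar I", "Novel I", "Novel II",
                                  "Novel III", "Familiar II"))
  gt_fam <- bundle$sessions[["Familiar I"]]$ground_truth
  gt_nov <- bundle$sessions[["Novel I"]]$ground_truth
  gt_fam2 <- bundle$sessions[["Familiar II"]]$ground_truth
  # familiar II uses the familiar map; novel maps share rotation + shift
  expect_equal(gt_fam[[1]]$phase, gt_fam2[[1]]$phase)
  expect_equal(gt_nov[[1]]$orientation - gt_fam[[1]]$orientation, pi / 6)
  R <- matrix(c(cos(pi / 6), sin(pi / 6), -sin(pi / 6), cos(pi / 6)), 2, 2)
  expect_equal(gt_nov[[1]]$phase,
               as.numeric(R %*% gt_fam[[1]]$phase) + c(0.1, 0.05))
  # coherent remap preserves pairwise phase offsets in the lattice frame:
  # arena-frame offsets are rotated by exactly the remap rotation
  off_fam <- gt_fam[[2]]$phase - gt_fam[[1]]$phase
  off_nov <- gt_nov[[2]]$phase - gt_nov[[1]]$phase
  expect_equal(off_nov, as.numeric(R %*% off_fam))
  # identity remap: novel ground truth equals familiar
  proto0 <- session_protocol(durations = 60, remap_rotation = 0,
                             remap_shift = c(0, 0))
  b0 <- generate_session_protocol(proto0, pop, seed = 9)
  expect_equal(b0$sessions[["Novel I"]]$ground_truth[[1]],
               b0$sessions[["Familiar I"]]$ground_truth[[1]])
  expect_error(generate_session_protocol(proto, list()), "non-empty")
})

test_that("phase drift destabilizes the within-session map", {
  pop <- list(ground_truth("grid", spacing = 0.4, peak_rate = 20,
                           baseline_rate = 0.2, phase = c(0.1, 0.1)))
  proto_stable <- session_protocol(labels = c("Familiar I", "Novel I"),
                                   durations = 600, drift_sigma = 0)
  proto_drift <- session_protocol(labels = c("Familiar I", "Novel I"),
                                  durations = 600, drift_sigma = 0.02)
  b_s <- generate_session_protocol(proto_stable, pop, seed = 11)
  b_d <- generate_session_protocol(proto_drift, pop, seed = 11)
  r_s <- within_trial_stability(b_s$sessions[["Novel I"]]$spikes[[1]],
                                b_s$sessions[["Novel I"]]$trajectory)
  r_d <- within_trial_stability(b_d$sessions[["Novel I"]]$spikes[[1]],
                                b_d$sessions[["Novel I"]]$trajectory)
  expect_gt(r_s, 0.6)
  expect_lt(r_d, r_s - 0.1)
})

test_that("LFP generator produces the requested oscillator", {
  traj <- generate_trajectory(duration = 120, seed = 5)
  # pure sinusoid: PSD peak at f0, bit-identical under a fixed seed
  lfp <- generate_lfp(traj, f0 = 8, beta_f = 0, beta_a = 0, noise_sd = 0,
                      seed = 1)
  pk <- psd_theta_peak(preprocess_lfp(lfp, lfp$fs))
  expect_equal(pk$peak_freq, 8, tolerance = 0.26)
  lfp2 <- generate_lfp(traj, f0 = 8, beta_f = 0, beta_a = 0, noise_sd = 0,
                       seed = 1)
  expect_identical(lfp$samples, lfp2$samples)
  # Nyquist violation rejected
  expect_error(generate_lfp(traj, f0 = 8, beta_f = 0, fs = 15), "Nyquist")
})

test_that("waveform generator separates narrow and broad templates", {
  wf <- generate_waveforms(5, 5, noise_sd = 0, seed = 1)
  feats <- lapply(wf$waveforms, waveform_features, fs = wf$fs)
  labels <- classify_waveform_types(feats)
  expect_identical(labels, wf$labels)
  t2p <- vapply(feats, `[[`, numeric(1), "trough_to_peak")
  expect_equal(mean(t2p[wf$labels == "narrow"]), 0.2, tolerance = 0.05)
  expect_equal(mean(t2p[wf$labels == "broad"]), 0.6, tolerance = 0.08)
  # amplitude-scaled template has identical features
  f1 <- waveform_features(wf$waveforms[[1]], wf$fs)
  f2 <- waveform_features(2 * wf$waveforms[[1]], wf$fs)
  expect_equal(f1$trough_to_peak, f2$trough_to_peak)
  expect_equal(f1$half_width, f2$half_width)
})

test_that("waveform labels recover under moderate noise", {
  wf <- generate_waveforms(30, 30, noise_sd = 0.05, seed = 2)
  feats <- lapply(wf$waveforms, waveform_features, fs = wf$fs)
  labels <- classify_waveform_types(feats)
  expect_gte(mean(labels == wf$labels), 0.95)
})
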