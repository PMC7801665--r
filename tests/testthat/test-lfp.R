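# LFP preprocessing, Morlet wavelet spectrogram, speed coupling, Welch PSD.

test_that("preprocessing decimates, z-scores and rejects bad input", {
  t_raw <- seq(0, 10, by = 1 / 4800)
  x <- sin(2 * pi * 8 * t_raw)
  lfp <- preprocess_lfp(x, 4800)
  expect_equal(lfp$fs, 250)
  expect_equal(mean(lfp$samples), 0, tolerance = 1e-9)
  expect_equal(sd(lfp$samples), 1, tolerance = 1e-9)
  pk <- psd_theta_peak(lfp)
  expect_equal(pk$peak_freq, 8, tolerance = 0.26)
  expect_error(preprocess_lfp(rep(1, 4800), 4800), "constant")
  expect_error(preprocess_lfp(c(x[1:100], NaN), 4800), "indices")
  expect_error(preprocess_lfp(x, 300), "twice")
})

test_that("the anti-alias filter suppresses power above the new Nyquist", {
  set.seed(6)
  x <- rnorm(4800 * 10)
  cutoff <- 0.72 * 125
  bf <- signal::butter(8, cutoff / 2400, type = "low")
  y <- as.numeric(signal::filtfilt(bf, x))
  pw_in <- welch_psd(x, 4800, 4096)
  pw_out <- welch_psd(y, 4800, 4096)
  hi <- pw_in$freqs > 125 & pw_in$freqs < 1000
  atten <- 10 * log10(mean(pw_in$psd[hi]) / mean(pw_out$psd[hi]))
  expect_gt(atten, 40)
})

test_that("the Morlet spectrogram tracks pure tones and chirps", {
  fs <- 250
  tt <- seq(0, 60, by = 1 / fs)
  lfp <- lfp_signal(sin(2 * pi * 8 * tt), fs, zscored = TRUE)
  spec <- wavelet_spectrogram(lfp)
  bm <- gridnet:::band_measures(spec, c(4, 12))
  mid <- seq(round(length(tt) * 0.3), round(length(tt) * 0.7))
  expect_equal(mean(bm$peak_freq[mid]), 8, tolerance = 0.1)
  expect_true(all(abs(bm$peak_freq[mid] - 8) <= 0.1 + 1e-9))
  # linear chirp 6 -> 10 Hz: tracked frequency increases monotonically
  f_inst <- 6 + 4 * tt / 60
  chirp <- lfp_signal(sin(2 * pi * cumsum(f_inst) / fs), fs, zscored = TRUE)
  bm2 <- gridnet:::band_measures(wavelet_spectrogram(chirp), c(4, 12))
  sm <- stats::lm(bm2$peak_freq[mid] ~ tt[mid])
  expect_equal(unname(coef(sm)[2]), 4 / 60, tolerance = 0.02)
  # two tones: both spectral ridges present
  two <- lfp_signal(sin(2 * pi * 5 * tt) + sin(2 * pi * 15 * tt), fs,
                    zscored = TRUE)
  sp2 <- wavelet_spectrogram(two)
  prof <- rowMeans(sp2$power[, mid])
  p5 <- prof[abs(sp2$freqs - 5) < 0.2]
  p15 <- prof[abs(sp2$freqs - 15) < 0.2]
  p10 <- prof[abs(sp2$freqs - 10) < 0.2]
  expect_gt(min(mean(p5), mean(p15)), 5 * mean(p10))
  expect_error(wavelet_spectrogram(lfp_signal(rnorm(50), 250)), "short")
})

test_that("total wavelet theta power tracks band-limited variance", {
  set.seed(7)
  fs <- 250
  tt <- seq(0, 120, by = 1 / fs)
  amps <- seq(0.2, 2, length.out = 6)
  pw <- vapply(amps, function(a) {
    x <- a * sin(2 * pi * 8 * tt) + 0.3 * rnorm(length(tt))
    spec <- wavelet_spectrogram(lfp_signal(x, fs, zscored = TRUE),
                                freqs = seq(4, 12, by = 0.25))
    mean(spec$power[, !spec$coi[1, ]])
  }, numeric(1))
  # z-scoring caps total variance at 1, so relative theta power saturates
  expect_true(all(diff(pw) > 0) || cor(amps, pw) > 0.95)
})

test_that("speed-conditioned theta profile recovers generator slopes", {
  # slow speed fluctuations (velocity correlation time 10 s), so the
  # multi-second support of the omega0 = 80 wavelet does not blur the
  # frequency estimate across speed bins
  traj <- fixture("slow_traj", function()
    generate_trajectory(duration = 1200, tau = 10, seed = 33))
  lfp <- generate_lfp(traj, f0 = 7, beta_f = 3, a0 = 1, beta_a = 2,
                      noise_sd = 0.3, seed = 12)
  z <- preprocess_lfp(lfp, lfp$fs)
  spec <- wavelet_spectrogram(z)
  prof <- speed_theta_profile(spec, traj)
  sel <- prof$counts > 100
  expect_gt(sum(sel), 10)
  # frequency-speed slope recovered within 10%
  fit <- stats::lm(prof$peak_freq[sel] ~ prof$speed_centers[sel])
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 0.1 * 3)
  # amplitude grows with speed -> monotone power profile
  expect_gt(cor(prof$speed_centers[sel], prof$mean_power[sel]), 0.8)
})

test_that("power and frequency scores respond to speed coupling", {
  traj <- fixture("slow_traj", function()
    generate_trajectory(duration = 1200, tau = 10, seed = 33))
  lfp_flat <- generate_lfp(traj, f0 = 8, beta_f = 0, beta_a = 0,
                           noise_sd = 0.3, seed = 13)
  sc_flat <- power_frequency_scores(preprocess_lfp(lfp_flat, 250), traj)
  expect_lt(abs(sc_flat$power_score), 0.25)
  expect_lt(abs(sc_flat$frequency_score), 0.25)
  lfp_mod <- generate_lfp(traj, f0 = 7, beta_f = 3, beta_a = 2,
                          noise_sd = 0.3, seed = 14)
  sc_mod <- power_frequency_scores(preprocess_lfp(lfp_mod, 250), traj)
  expect_gt(sc_mod$power_score, 0.8)
  expect_gt(sc_mod$frequency_score, 0.5)
  # scores are invariant to amplitude rescaling of the raw trace
  sc_scaled <- power_frequency_scores(
    preprocess_lfp(lfp_signal(5 * lfp_mod$samples, 250), 250), traj)
  expect_equal(sc_scaled$power_score, sc_mod$power_score, tolerance = 1e-9)
  expect_error(power_frequency_scores(
    lfp_signal(rnorm(250 * 30), 250, zscored = TRUE), traj), "60 s")
})

test_that("bootstrap CI over recordings collapses for identical inputs", {
  expect_equal(bootstrap_ci(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)),
                            n_boot = 100, seed = 1), c(2, 2))
  set.seed(2)
  narrow <- replicate(8, rnorm(5, 10, 0.1), simplify = FALSE)
  wide <- replicate(8, rnorm(5, 10, 5), simplify = FALSE)
  ci_n <- bootstrap_ci(narrow, n_boot = 500, seed = 3)
  ci_w <- bootstrap_ci(wide, n_boot = 500, seed = 3)
  expect_lt(diff(ci_n), diff(ci_w))
  expect_error(bootstrap_ci(list(1)), "at least 2")
})
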