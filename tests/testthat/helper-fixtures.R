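# Shared fixtures, built in code and cached for the whole test run.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env))
    assign(name, build(), envir = fixture_env)
  get(name, envir = fixture_env)
}

# 20-minute open-field trajectory + a clean grid cell recorded on it
fix_traj <- function() fixture("traj", function()
  generate_trajectory(duration = 1200, seed = 101))

fix_grid_gt <- function() ground_truth("grid", spacing = 0.4,
                                       orientation = 0.2,
                                       phase = c(0.1, 0.2),
                                       peak_rate = 15, baseline_rate = 0.5)

fix_grid_spikes <- function() fixture("grid_spikes", function()
  generate_grid_spikes(fix_traj(), fix_grid_gt(), seed = 102))

fix_grid_map <- function() fixture("grid_map", function()
  compute_rate_map(fix_grid_spikes(), fix_traj()))

fix_grid_acorr <- function() fixture("grid_acorr", function()
  compute_autocorrelogram(fix_grid_map()))

# ideal hexagonal lattice of Gaussian bumps (known spacing and orientation)
hex_lattice_map <- function(n = 60, spacing_bins = 15, sigma_bins = 2.5,
                            theta = 0, center = c(n + 1, n + 1) / 2) {
  a1 <- spacing_bins * c(cos(theta), sin(theta))
  a2 <- spacing_bins * c(cos(theta + pi / 3), sin(theta + pi / 3))
  m <- matrix(0, n, n)
  for (p in -8:8) for (q in -8:8) {
    ctr <- center + p * a1 + q * a2
    if (any(ctr < -10) || any(ctr > n + 10)) next
    ii <- max(1, floor(ctr[1] - 10)):min(n, ceiling(ctr[1] + 10))
    jj <- max(1, floor(ctr[2] - 10)):min(n, ceiling(ctr[2] + 10))
    m[ii, jj] <- m[ii, jj] +
      exp(-outer((ii - ctr[1])^2, (jj - ctr[2])^2, "+") /
            (2 * sigma_bins^2))
  }
  m
}

# rotationally symmetric concentric-ring pattern packaged as an
# autocorrelogram (its rotation correlations are all ~1 by symmetry)
radial_ring_acorr <- function(n = 81, bin_size = 0.02) {
  ctr <- (n + 1) / 2
  rr <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  vals <- exp(-rr / 30) * cos(2 * pi * rr / 12)
  structure(list(values = vals, center = c(ctr, ctr), bin_size = bin_size,
                 wrap = FALSE),
            class = "autocorrelogram")
}

# tiny deterministic trajectory visiting every bin of a small arena equally
uniform_grid_traj <- function(arena = 0.1, bin = 0.02, dwell_samples = 4,
                              fs = 50) {
  n <- arena / bin
  centers <- (seq_len(n) - 0.5) * bin
  xy <- expand.grid(x = centers, y = centers)
  x <- rep(xy$x, each = dwell_samples)
  y <- rep(xy$y, each = dwell_samples)
  trajectory(t = seq_along(x) / fs, x = x, y = y, fs = fs,
             arena_size = arena)
}

# direct-summation full autocorrelogram oracle (independent of the FFT path)
direct_autocorr <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, 2 * n1 - 1, 2 * n2 - 1)
  for (du in -(n1 - 1):(n1 - 1)) for (dv in -(n2 - 1):(n2 - 1)) {
    i <- max(1, 1 - du):min(n1, n1 - du)
    j <- max(1, 1 - dv):min(n2, n2 - dv)
    out[du + n1, dv + n2] <- sum(m[i, j] * m[i + du, j + dv])
  }
  out
}

# direct periodic cross-correlation oracle
direct_xcorr_wrap <- function(a, b) {
  n1 <- nrow(a); n2 <- ncol(a)
  out <- matrix(0, n1, n2)
  for (du in 0:(n1 - 1)) for (dv in 0:(n2 - 1)) {
    bs <- b[((seq_len(n1) - 1 + du) %% n1) + 1,
            ((seq_len(n2) - 1 + dv) %% n2) + 1]
    out[du + 1, dv + 1] <- sum(a * bs)
  }
  si <- floor(n1 / 2); sj <- floor(n2 / 2)
  out[c((si + 1):n1, seq_len(si)), c((sj + 1):n2, seq_len(sj))]
}
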