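# Synthetic open-field experiment generator. Every analysis stage in the
# package can be exercised against these generators, whose tuning parameters
# are known exactly (ground truth), in place of raw recordings.

#' Simulate a foraging trajectory in a square arena
#'
#' Velocity follows a two-dimensional Ornstein-Uhlenbeck process
#' (correlation time `tau`), integrated with reflective walls. The
#' stationary speed distribution is Rayleigh with the requested mean.
#'
#' @param duration Session length in seconds.
#' @param arena_size Arena side in meters.
#' @param fs Tracking rate in Hz.
#' @param mean_speed Target mean running speed in m/s.
#' @param tau Velocity correlation time in seconds.
#' @param hd_noise_kappa von Mises concentration of head-direction noise
#'   about the heading of motion (larger = less noise).
#' @param seed Optional RNG seed for reproducibility.
#' @return A [trajectory()].
#' @export
generate_trajectory <- function(duration = 1200, arena_size = 1, fs = 50,
                                mean_speed = 0.15, tau = 1,
                                hd_noise_kappa = 10, seed = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (fs <= 0) stop("fs must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  dt <- 1 / fs
  # Rayleigh mean = sigma_v * sqrt(pi/2)
  sigma_v <- mean_speed / sqrt(pi / 2)
  a <- exp(-dt / tau)
  s <- sigma_v * sqrt(1 - a^2)
  vx <- vy <- x <- y <- numeric(n)
  x[1] <- runif(1, 0.25, 0.75) * arena_size
  y[1] <- runif(1, 0.25, 0.75) * arena_size
  vx[1] <- rnorm(1, 0, sigma_v)
  vy[1] <- rnorm(1, 0, sigma_v)
  ex <- rnorm(n)
  ey <- rnorm(n)
  for (i in 2:n) {
    vx[i] <- a * vx[i - 1] + s * ex[i]
    vy[i] <- a * vy[i - 1] + s * ey[i]
    xi <- x[i - 1] + vx[i] * dt
    yi <- y[i - 1] + vy[i] * dt
    if (xi < 0) { xi <- -xi; vx[i] <- -vx[i] }
    if (xi > arena_size) { xi <- 2 * arena_size - xi; vx[i] <- -vx[i] }
    if (yi < 0) { yi <- -yi; vy[i] <- -vy[i] }
    if (yi > arena_size) { yi <- 2 * arena_size - yi; vy[i] <- -vy[i] }
    x[i] <- xi
    y[i] <- yi
  }
  heading <- atan2(vy, vx) %% (2 * pi)
  hd <- (heading + rvonmises(n, 0, hd_noise_kappa)) %% (2 * pi)
  trajectory(t = seq(0, by = dt, length.out = n), x = x, y = y, hd = hd,
             fs = fs, arena_size = arena_size)
}

# Normalized hexagonal grid intensity g(x, y) in [0, 1]: sum of three plane
# waves at 60 degree separation, wave number 4*pi/(sqrt(3)*spacing). g = 1 at
# the field centers (x, y) = phase + lattice vectors.
grid_intensity <- function(x, y, spacing, orientation = 0, phase = c(0, 0)) {
  k <- 4 * pi / (sqrt(3) * spacing)
  ang <- orientation + c(0, pi / 3, 2 * pi / 3)
  dx <- x - phase[1]
  dy <- y - phase[2]
  g <- 0
  for (a in ang) g <- g + cos(k * (cos(a) * dx + sin(a) * dy))
  (g + 1.5) / 4.5
}

# Intensity (Hz) of a ground-truth cell along candidate sample points.
# `drift` is an optional 2-column matrix of phase offsets per point.
cell_intensity <- function(gt, x, y, hd = NULL, speed = NULL, drift = NULL) {
  switch(gt$cell_type,
    grid = {
      px <- gt$phase[1] + if (is.null(drift)) 0 else drift[, 1]
      py <- gt$phase[2] + if (is.null(drift)) 0 else drift[, 2]
      k <- 4 * pi / (sqrt(3) * gt$spacing)
      ang <- gt$orientation + c(0, pi / 3, 2 * pi / 3)
      g <- 0
      for (a in ang) g <- g + cos(k * (cos(a) * (x - px) + sin(a) * (y - py)))
      g <- (g + 1.5) / 4.5
      gt$baseline_rate + (gt$peak_rate - gt$baseline_rate) * g
    },
    hd = {
      tune <- exp(gt$hd_kappa * (cos(hd - gt$hd_mu) - 1))
      gt$baseline_rate + (gt$peak_rate - gt$baseline_rate) * tune
    },
    speed = pmax(0, gt$baseline_rate + gt$speed_slope * speed),
    noise = rep(gt$peak_rate, length(x))
  )
}

#' Simulate a spike train from a tuned intensity function
#'
#' Draws an inhomogeneous Poisson process by exact thinning against the
#' cell's intensity evaluated at the (interpolated) trajectory, with optional
#' multiplicative theta modulation and burst injection.
#'
#' @param traj A [trajectory()].
#' @param gt A [ground_truth()] describing the tuning.
#' @param theta_mod Theta modulation depth in `[0, 1)` (0 = none).
#' @param theta_freq Theta frequency in Hz.
#' @param drift Optional 2-column matrix of grid-phase offsets (m), one row
#'   per trajectory sample (random-walk destabilization).
#' @param unit_id Unit label for the returned train.
#' @param seed Optional RNG seed.
#' @return A [spike_train()].
#' @export
generate_cell_spikes <- function(traj, gt, theta_mod = 0, theta_freq = 8,
                                 drift = NULL, unit_id = gt$cell_type,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (gt$peak_rate < gt$baseline_rate)
    stop("peak_rate must be >= baseline_rate")
  t0 <- traj$t[1]
  t1 <- traj$t[length(traj$t)]
  speed <- NULL
  if (gt$cell_type == "speed") speed <- traj_speed(traj)
  lam_max <- switch(gt$cell_type,
    grid = gt$peak_rate,
    hd = gt$peak_rate,
    # intensity is linear in speed, so its maximum sits at a speed extreme
    speed = max(pmax(0, gt$baseline_rate +
                       gt$speed_slope * range(traj_speed(traj)))),
    noise = gt$peak_rate)
  lam_max <- lam_max * (1 + theta_mod)
  if (lam_max <= 0)
    return(spike_train(numeric(0), t0, t1, unit_id))
  n_cand <- rpois(1, lam_max * (t1 - t0))
  cand <- sort(runif(n_cand, t0, t1))
  idx <- pmin(pmax(round((cand - t0) * traj$fs) + 1, 1), length(traj$t))
  pos <- traj_interp(traj, cand)
  lam <- cell_intensity(gt, pos$x, pos$y,
                        hd = if (is.null(traj$hd)) NULL else traj$hd[idx],
                        speed = if (is.null(speed)) NULL else speed[idx],
                        drift = if (is.null(drift)) NULL else
                          drift[idx, , drop = FALSE])
  if (theta_mod > 0)
    lam <- lam * (1 + theta_mod * cos(2 * pi * theta_freq * cand))
  keep <- runif(n_cand) < lam / lam_max
  times <- cand[keep]
  if (gt$burst_prob > 0 && length(times)) {
    burst <- runif(length(times)) < gt$burst_prob
    extra <- lapply(which(burst), function(i) {
      n_extra <- sample(1:3, 1)          # burst of 2-4 spikes total
      times[i] + 0.005 * seq_len(n_extra)
    })
    times <- sort(c(times, unlist(extra)))
    times <- times[times <= t1]
  }
  spike_train(unique(times), t0, t1, unit_id, group = NA_character_)
}

#' @rdname generate_cell_spikes
#' @export
generate_grid_spikes <- function(traj, gt, theta_mod = 0, theta_freq = 8,
                                 drift = NULL, unit_id = "grid",
                                 seed = NULL) {
  stopifnot(gt$cell_type == "grid")
  generate_cell_spikes(traj, gt, theta_mod, theta_freq, drift, unit_id, seed)
}

#' Simulate a full multi-session experiment
#'
#' Generates one trajectory plus one spike train per ground-truth unit for
#' every session of a protocol. In novel-environment sessions all grid cells
#' share one rotation and phase shift (coherent remapping); `drift_sigma > 0`
#' adds a random-walk phase drift (shared or per-cell according to
#' `drift_mode`) that destabilizes the map within novel sessions. The second
#' familiar session reuses the familiar map.
#'
#' @param protocol A [session_protocol()].
#' @param population List of [ground_truth()] objects.
#' @param traj_args List of extra arguments for [generate_trajectory()].
#' @param theta_mod Theta modulation depth passed to the spike generator.
#' @param seed Optional RNG seed.
#' @return A list with `sessions` (each: `label`, `trajectory`, `spikes`,
#'   `ground_truth` as realized in that session), `population`, `protocol`.
#' @export
generate_session_protocol <- function(protocol, population,
                                      traj_args = list(), theta_mod = 0,
                                      seed = NULL) {
  if (!length(population)) stop("population must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  sessions <- vector("list", length(protocol$labels))
  names(sessions) <- protocol$labels
  for (si in seq_along(protocol$labels)) {
    label <- protocol$labels[si]
    dur <- protocol$durations[si]
    traj <- do.call(generate_trajectory,
                    c(list(duration = dur), traj_args))
    novel <- is_novel_label(label)
    n <- length(traj$t)
    # per-session drift paths (novel sessions only)
    common_drift <- NULL
    if (novel && protocol$drift_sigma > 0 && protocol$drift_mode == "common")
      common_drift <- apply(matrix(rnorm(2 * n, 0,
                                         protocol$drift_sigma / sqrt(traj$fs)),
                                   ncol = 2), 2, cumsum)
    spikes <- vector("list", length(population))
    gts <- vector("list", length(population))
    for (ui in seq_along(population)) {
      gt <- population[[ui]]
      gt_s <- gt
      drift <- NULL
      if (novel && gt$cell_type == "grid") {
        # the whole sheet rotates and shifts coherently: phases move with
        # the lattice, so pairwise offsets are preserved in lattice frame
        th <- protocol$remap_rotation
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        gt_s$orientation <- gt$orientation + th
        gt_s$phase <- as.numeric(R %*% gt$phase) + protocol$remap_shift
        if (protocol$drift_sigma > 0) {
          drift <- if (protocol$drift_mode == "common") common_drift else
            apply(matrix(rnorm(2 * n, 0,
                               protocol$drift_sigma / sqrt(traj$fs)),
                         ncol = 2), 2, cumsum)
        }
      }
      id <- sprintf("unit%02d_%s", ui, gt$cell_type)
      spikes[[ui]] <- generate_cell_spikes(traj, gt_s, theta_mod = theta_mod,
                                           drift = drift, unit_id = id)
      gts[[ui]] <- gt_s
    }
    sessions[[si]] <- list(label = label, trajectory = traj, spikes = spikes,
                           ground_truth = gts)
  }
  list(sessions = sessions, population = population, protocol = protocol)
}

#' Simulate a speed-coupled theta LFP
#'
#' A theta oscillator whose instantaneous frequency is `f0 + beta_f * v(t)`
#' and amplitude `a0 + beta_a * v(t)` (v = running speed resampled to the LFP
#' clock), plus `1/f^noise_exponent` background noise.
#'
#' @param traj A [trajectory()] providing the speed signal.
#' @param f0 Base theta frequency, Hz.
#' @param beta_f Frequency-speed slope, Hz per m/s.
#' @param a0 Base amplitude (arbitrary units).
#' @param beta_a Amplitude-speed slope, units per m/s.
#' @param noise_exponent Spectral exponent of the background (0 = none when
#'   `noise_sd = 0`).
#' @param noise_sd Standard deviation of the background noise.
#' @param fs LFP sampling rate in Hz (the analysis rate).
#' @param seed Optional RNG seed.
#' @return An `lfp_signal` (see [lfp_signal()]).
#' @export
generate_lfp <- function(traj, f0 = 8, beta_f = 2, a0 = 1, beta_a = 1,
                         noise_exponent = 1, noise_sd = 0.5, fs = 250,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- traj_speed(traj)
  if (fs < 2 * (f0 + beta_f * max(sp)))
    stop("fs violates Nyquist for the maximum instantaneous theta frequency")
  t_lfp <- seq(traj$t[1], traj$t[length(traj$t)], by = 1 / fs)
  v <- approx(traj$t, sp, xout = t_lfp, rule = 2)$y
  inst_f <- f0 + beta_f * v
  phase <- 2 * pi * cumsum(inst_f) / fs
  amp <- a0 + beta_a * v
  x <- amp * cos(phase)
  if (noise_sd > 0) {
    n <- length(x)
    white <- rnorm(n)
    f <- c(1, seq_len(n - 1))            # avoid DC blow-up
    shape <- 1 / (abs(pmin(f, n - f + 1))^(noise_exponent / 2))
    noise <- Re(fft(fft(white) * shape, inverse = TRUE)) / n
    noise <- noise / sd(noise) * noise_sd
    x <- x + noise
  }
  lfp_signal(x, fs = fs, t_start = t_lfp[1], zscored = FALSE)
}

#' Simulate mean spike waveforms of narrow- and broad-spiking units
#'
#' Two templates (trough-to-peak about 0.2 ms for narrow and 0.6 ms for
#' broad units) plus Gaussian noise; ground-truth labels are returned.
#'
#' @param n_narrow,n_broad Number of units per class.
#' @param noise_sd Noise standard deviation relative to trough amplitude 1.
#' @param fs Waveform sampling rate in Hz.
#' @param n_samples Samples per waveform.
#' @param seed Optional RNG seed.
#' @return List with `waveforms` (list of one-column matrices), `labels`
#'   (character), `fs`.
#' @export
generate_waveforms <- function(n_narrow, n_broad, noise_sd = 0.02,
                               fs = 48000, n_samples = 50, seed = NULL) {
  stopifnot(n_narrow >= 0, n_broad >= 0)
  if (!is.null(seed)) set.seed(seed)
  tms <- (seq_len(n_samples) - 1) / fs * 1000   # ms
  template <- function(t2p_ms, trough_sd_ms, peak_sd_ms) {
    t_tr <- 0.25
    -1 * exp(-0.5 * ((tms - t_tr) / trough_sd_ms)^2) +
      0.45 * exp(-0.5 * ((tms - t_tr - t2p_ms) / peak_sd_ms)^2)
  }
  tmpl <- list(narrow = template(0.2, 0.05, 0.12),
               broad  = template(0.6, 0.12, 0.25))
  labels <- c(rep("narrow", n_narrow), rep("broad", n_broad))
  waveforms <- lapply(labels, function(lb)
    matrix(tmpl[[lb]] + rnorm(n_samples, 0, noise_sd), ncol = 1))
  list(waveforms = waveforms, labels = labels, fs = fs)
}
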