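# Theta-band LFP analysis: preprocessing/decimation, Morlet continuous
# wavelet transform (nondimensional frequency omega0 = 80), speed-conditioned
# theta power and frequency, power/frequency scores, and Welch PSD peaks.

#' LFP signal container
#'
#' @param samples Numeric samples (z-scored after preprocessing).
#' @param fs Sampling rate in Hz (analysis rate 250).
#' @param t_start Time of the first sample, seconds.
#' @param zscored Whether samples have been z-scored.
#' @return An object of class `lfp_signal`.
#' @export
lfp_signal <- function(samples, fs, t_start = 0, zscored = FALSE) {
  structure(list(samples = as.numeric(samples), fs = fs, t_start = t_start,
                 zscored = zscored),
            class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("lfp_signal: %d samples @ %g Hz (%.1f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (x$zscored) ", z-scored" else ""))
  invisible(x)
}

lfp_times <- function(lfp) lfp$t_start + (seq_along(lfp$samples) - 1) / lfp$fs

#' Preprocess a raw LFP trace to the analysis rate
#'
#' Zero-phase Butterworth low-pass (order 8, cutoff 0.72 times the target
#' Nyquist) followed by linear interpolation onto the target clock, then
#' per-session z-scoring. Signals already at the target rate are only
#' z-scored.
#'
#' @param raw Numeric samples or an `lfp_signal`.
#' @param raw_fs Input sampling rate in Hz (stored rate, e.g. 4800).
#' @param target_fs Analysis rate in Hz.
#' @return A z-scored `lfp_signal` at `target_fs`.
#' @export
preprocess_lfp <- function(raw, raw_fs, target_fs = 250) {
  x <- if (inherits(raw, "lfp_signal")) raw$samples else as.numeric(raw)
  t_start <- if (inherits(raw, "lfp_signal")) raw$t_start else 0
  if (inherits(raw, "lfp_signal")) raw_fs <- raw$fs
  if (raw_fs < 2 * target_fs && raw_fs != target_fs)
    stop("raw_fs must be at least twice the target rate")
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("NaN/Inf samples at indices: ",
         paste(head(bad, 10), collapse = ", "))
  if (sd(x) == 0) stop("constant signal cannot be z-scored")
  if (raw_fs != target_fs) {
    cutoff <- 0.72 * (target_fs / 2)
    bf <- signal::butter(8, cutoff / (raw_fs / 2), type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))
    t_in <- t_start + (seq_along(x) - 1) / raw_fs
    t_out <- seq(t_in[1], t_in[length(t_in)], by = 1 / target_fs)
    x <- approx(t_in, x, xout = t_out)$y
  }
  if (sd(x) == 0) stop("constant signal cannot be z-scored")
  lfp_signal((x - mean(x)) / sd(x), target_fs, t_start, zscored = TRUE)
}

#' Morlet wavelet spectrogram of an LFP signal
#'
#' Continuous wavelet transform with a Morlet mother wavelet of
#' nondimensional frequency omega0 (default 80, a very narrowband analysis
#' suited to tracking theta frequency), evaluated on a regular frequency
#' grid; power is the squared coefficient magnitude. Samples inside the
#' cone of influence at each frequency are flagged.
#'
#' @param lfp An `lfp_signal`.
#' @param freqs Analysis frequencies in Hz (default 2-20 Hz by 0.1).
#' @param omega0 Morlet nondimensional frequency.
#' @return A `spectrogram` list: `freqs`, `times`, `power`
#'   (frequency x time), `coi` (logical matrix, TRUE = inside cone of
#'   influence), `omega0`.
#' @export
wavelet_spectrogram <- function(lfp, freqs = seq(2, 20, by = 0.1),
                                omega0 = 80) {
  x <- lfp$samples
  n <- length(x)
  dt <- 1 / lfp$fs
  # Fourier factor: wavelength / scale for the Morlet wavelet
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- 1 / (freqs * fourier_factor)
  if (n * dt < 2 / min(freqs)) stop("signal too short for the lowest frequency")
  m <- stats::nextn(n)
  xf <- fft(c(x - mean(x), rep(0, m - n)))
  w <- 2 * pi * c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / (m * dt)
  power <- matrix(0, length(freqs), n)
  coi <- matrix(FALSE, length(freqs), n)
  tidx <- seq_len(n)
  for (k in seq_along(scales)) {
    s <- scales[k]
    psi <- numeric(m)
    pos <- w > 0
    psi[pos] <- pi^(-0.25) * exp(-0.5 * (s * w[pos] - omega0)^2)
    psi <- psi * sqrt(2 * pi * s / dt)
    wt <- fft(xf * psi, inverse = TRUE)[tidx] / m
    power[k, ] <- Mod(wt)^2
    # e-folding time sqrt(2) * s from each edge
    ncoi <- ceiling(sqrt(2) * s / dt)
    if (ncoi >= 1) {
      coi[k, seq_len(min(ncoi, n))] <- TRUE
      coi[k, seq(max(1, n - ncoi + 1), n)] <- TRUE
    }
  }
  structure(list(freqs = freqs, times = lfp_times(lfp), power = power,
                 coi = coi, omega0 = omega0),
            class = "spectrogram")
}

# band-average power and within-band peak frequency per sample
band_measures <- function(spec, band = c(4, 12), use_coi = TRUE) {
  sel <- spec$freqs >= band[1] & spec$freqs <= band[2]
  p <- spec$power[sel, , drop = FALSE]
  if (use_coi) p[spec$coi[sel, , drop = FALSE]] <- NA
  bp <- colMeans(p, na.rm = TRUE)
  pf <- spec$freqs[sel][max.col(t(ifelse(is.na(p), -Inf, p)))]
  pf[!is.finite(bp)] <- NA
  list(band_power = bp, peak_freq = pf)
}

#' Speed-conditioned theta power and frequency profile
#'
#' Theta-band (default 4-12 Hz) wavelet power and peak frequency are
#' averaged within running-speed bins of 0.02 m/s over 0.02-1 m/s, with
#' speed linearly resampled onto the LFP clock.
#'
#' @param spec A `spectrogram`.
#' @param traj A [trajectory()].
#' @param band Theta band in Hz.
#' @param speed_edges Speed bin edges in m/s.
#' @return A `theta_speed_profile` list: `speed_edges`, `speed_centers`,
#'   `mean_power`, `peak_freq`, `counts`.
#' @export
speed_theta_profile <- function(spec, traj, band = c(4, 12),
                                speed_edges = seq(0.02, 1, by = 0.02)) {
  v <- approx(traj$t, traj_speed(traj), xout = spec$times, rule = 2)$y
  bm <- band_measures(spec, band)
  nb <- length(speed_edges) - 1
  bin <- findInterval(v, speed_edges, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= nb & is.finite(bm$band_power)
  mp <- pf <- rep(NaN, nb)
  counts <- integer(nb)
  for (b in seq_len(nb)) {
    sel <- ok & bin == b
    counts[b] <- sum(sel)
    if (counts[b]) {
      mp[b] <- mean(bm$band_power[sel])
      pf[b] <- mean(bm$peak_freq[sel], na.rm = TRUE)
    }
  }
  structure(list(speed_edges = speed_edges,
                 speed_centers = speed_edges[-1] - 0.01,
                 mean_power = mp, peak_freq = pf, counts = counts),
            class = "theta_speed_profile")
}

#' Theta power and frequency scores of a session
#'
#' Band power and peak frequency are averaged in 1 s time bins; bins whose
#' mean running speed lies in `[0.02, 1]` m/s are kept, and each measure is
#' correlated (Pearson) against the binned speed.
#'
#' @param lfp An `lfp_signal` (z-scored or not; it is preprocessed if not).
#' @param traj A [trajectory()].
#' @param band Theta band in Hz.
#' @param bin_width Time bin in seconds.
#' @param spec Optional precomputed `spectrogram`.
#' @return List: `power_score`, `frequency_score`, `n_bins`.
#' @export
power_frequency_scores <- function(lfp, traj, band = c(4, 12),
                                   bin_width = 1, spec = NULL) {
  if (!lfp$zscored) lfp <- preprocess_lfp(lfp, lfp$fs, lfp$fs)
  dur <- length(lfp$samples) / lfp$fs
  if (dur < 60) stop("session must be at least 60 s")
  if (is.null(spec)) spec <- wavelet_spectrogram(lfp)
  bm <- band_measures(spec, band)
  v <- approx(traj$t, traj_speed(traj), xout = spec$times, rule = 2)$y
  tb <- floor((spec$times - spec$times[1]) / bin_width)
  agg <- function(x) tapply(x, tb, mean, na.rm = TRUE)
  mv <- agg(v)
  mp <- agg(bm$band_power)
  mf <- agg(bm$peak_freq)
  keep <- is.finite(mv) & is.finite(mp) & is.finite(mf) &
    mv >= 0.02 & mv <= 1
  if (sum(keep) < 10)
    return(list(power_score = NaN, frequency_score = NaN,
                n_bins = sum(keep)))
  list(power_score = cor(mp[keep], mv[keep]),
       frequency_score = cor(mf[keep], mv[keep]),
       n_bins = sum(keep))
}

#' Welch power spectral density
#'
#' Averaged modified periodograms (Hann window, 50% overlap).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param nperseg Segment length in samples.
#' @return List: `freqs` (Hz), `psd` (power/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 1024) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- nperseg %/% 2
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(win^2)
  starts <- seq(1, n - nperseg + 1, by = step)
  acc <- numeric(nperseg %/% 2 + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(fft(seg)[seq_len(nperseg %/% 2 + 1)])^2
    acc <- acc + sp
  }
  psd <- acc / length(starts) / (fs * u)
  psd[2:(length(psd) - 1)] <- 2 * psd[2:(length(psd) - 1)]
  list(freqs = (seq_len(nperseg %/% 2 + 1) - 1) * fs / nperseg, psd = psd)
}

#' Theta peak of the Welch PSD
#'
#' @param lfp An `lfp_signal` (z-scored if not already).
#' @param band Search band in Hz (default 6-12).
#' @param nperseg Welch segment length.
#' @return List: `peak_freq` (Hz), `peak_power` (dB/Hz), `freqs`, `psd`.
#'   Falls back to the band boundary (with a warning) when no interior
#'   local maximum exists.
#' @export
psd_theta_peak <- function(lfp, band = c(6, 12), nperseg = 1024) {
  if (!lfp$zscored) lfp <- preprocess_lfp(lfp, lfp$fs, lfp$fs)
  w <- welch_psd(lfp$samples, lfp$fs, nperseg)
  sel <- which(w$freqs >= band[1] & w$freqs <= band[2])
  if (!length(sel)) stop("band outside resolved frequencies")
  p <- w$psd[sel]
  i <- which.max(p)
  if (i == 1 || i == length(p))
    warning("theta peak at band boundary (no interior local maximum)")
  list(peak_freq = w$freqs[sel][i], peak_power = 10 * log10(p[i]),
       freqs = w$freqs, psd = w$psd)
}
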