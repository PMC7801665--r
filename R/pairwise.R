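# Pairwise spatiotemporal cross-correlations of simultaneously recorded
# units and their stability across sessions. Temporal correlograms use
# z-scored kernel rates at 1 kHz over lags of +/-1 s; spatial correlograms
# are periodic cross-correlations of z-scored rate maps. Stability of a pair
# is the Pearson correlation of its correlograms in two sessions.

# linear cross-correlation c[k] = sum_t a[t] b[t+k] for k in -max_lag..max_lag
xcorr_lags <- function(a, b, max_lag) {
  n <- length(a)
  m <- stats::nextn(n + max_lag)
  fa <- fft(c(a, rep(0, m - n)))
  fb <- fft(c(b, rep(0, m - n)))
  cc <- Re(fft(Conj(fa) * fb, inverse = TRUE)) / m
  c(cc[(m - max_lag + 1):m], cc[1:(max_lag + 1)])
}

#' Temporal cross-correlogram of two spike trains
#'
#' Instantaneous rates (Gaussian kernel, default 10 ms, sampled at 1 kHz)
#' are z-scored and cross-correlated at lags from -1 to +1 s; the raw
#' correlation is divided by the number of samples so values lie in
#' `[-1, 1]`. Positive lags mean unit b fires after unit a.
#'
#' @param spk_a,spk_b [spike_train()] objects from the same session.
#' @param kernel_sigma Rate kernel sigma in seconds.
#' @param fs Rate sampling frequency in Hz.
#' @param max_lag Maximum lag in seconds.
#' @param theta_bandstop Remove 4-10 Hz from the rate series with a
#'   zero-phase order-4 Butterworth band-stop filter before correlating.
#' @return A `cross_correlogram` list: `lags` (s), `values`, `pair`.
#' @export
temporal_cross_correlation <- function(spk_a, spk_b, kernel_sigma = 0.010,
                                       fs = 1000, max_lag = 1,
                                       theta_bandstop = FALSE) {
  t0 <- min(spk_a$t_start, spk_b$t_start)
  t1 <- max(spk_a$t_stop, spk_b$t_stop)
  lag_n <- round(max_lag * fs)
  lags <- (-lag_n:lag_n) / fs
  if (!length(spk_a$times) || !length(spk_b$times))
    return(structure(list(lags = lags, values = rep(NaN, length(lags)),
                          pair = c(spk_a$unit_id, spk_b$unit_id)),
                     class = "cross_correlogram"))
  ra <- instantaneous_rate(spk_a, kernel_sigma, fs, t0, t1)$rate
  rb <- instantaneous_rate(spk_b, kernel_sigma, fs, t0, t1)$rate
  if (theta_bandstop) {
    bf <- signal::butter(4, c(4, 10) / (fs / 2), type = "stop")
    ra <- as.numeric(signal::filtfilt(bf, ra))
    rb <- as.numeric(signal::filtfilt(bf, rb))
  }
  za <- (ra - mean(ra)) / pop_sd(ra)
  zb <- (rb - mean(rb)) / pop_sd(rb)
  vals <- xcorr_lags(za, zb, lag_n) / length(za)
  structure(list(lags = lags, values = vals,
                 pair = c(spk_a$unit_id, spk_b$unit_id)),
            class = "cross_correlogram")
}

#' Spatial cross-correlation map of two rate maps
#'
#' Both maps are z-scored and cross-correlated with periodic (wrap)
#' boundaries; the result is divided by the bin count so values lie in
#' `[-1, 1]`. Zero offset sits at bin `floor(n/2) + 1` in each dimension.
#'
#' @param map_a,map_b [rate_map()] objects (or matrices) of equal shape.
#' @return A `spatial_cross_map` list: `values`, `center`.
#' @export
spatial_cross_correlation <- function(map_a, map_b) {
  a <- if (inherits(map_a, "rate_map")) map_a$values else map_a
  b <- if (inherits(map_b, "rate_map")) map_b$values else map_b
  if (!all(dim(a) == dim(b))) stop("rate maps have different shapes")
  if (sd(a) == 0 || sd(b) == 0)
    return(structure(list(values = matrix(NaN, nrow(a), ncol(a)),
                          center = c(floor(nrow(a) / 2) + 1L,
                                     floor(ncol(a) / 2) + 1L)),
                     class = "spatial_cross_map"))
  za <- (a - mean(a)) / pop_sd(a)
  zb <- (b - mean(b)) / pop_sd(b)
  vals <- xcorr2_wrap(za, zb) / length(a)
  structure(list(values = vals,
                 center = c(floor(nrow(a) / 2) + 1L, floor(ncol(a) / 2) + 1L)),
            class = "spatial_cross_map")
}

# remove spikes landing outside the unit's firing fields
strip_out_of_field <- function(spikes, traj, bin_size = 0.02, sigma = 0.03) {
  map <- compute_rate_map(spikes, traj, bin_size, sigma)
  acorr <- compute_autocorrelogram(map)
  fm <- identify_fields(map, acorr)
  if (!length(fm$fields)) return(spikes)
  pos <- traj_interp(traj, spikes$times)
  n <- nrow(fm$labels)
  sx <- bin_index(pos$x, bin_size, n)
  sy <- bin_index(pos$y, bin_size, n)
  keep <- fm$labels[cbind(sx, sy)] > 0
  spike_train(spikes$times[keep], spikes$t_start, spikes$t_stop,
              spikes$unit_id)
}

#' Stability of pairwise cross-correlations across two sessions
#'
#' For every pair, the cross-correlogram (temporal or spatial) is computed
#' in each session and the pair's stability is the Pearson correlation
#' between the two correlograms (2-D maps flattened; NaN bins excluded
#' pairwise). Symmetric in session order.
#'
#' @param session_a,session_b Session lists with elements `trajectory` and
#'   `spikes` (list of [spike_train()]); both sessions must contain the
#'   paired units at the same indices.
#' @param pairs Two-column integer matrix of unit indices.
#' @param mode `"temporal"` or `"spatial"`.
#' @param control `"none"`, `"theta_bandstop"` (temporal mode: 4-10 Hz
#'   zero-phase band-stop on the rate series) or `"in_field_only"` (drop
#'   out-of-field spikes first).
#' @param bin_size,sigma Rate-map parameters for the spatial mode.
#' @param fs Rate sampling frequency for the temporal mode, Hz.
#' @return Numeric vector of per-pair Pearson r (NA for dropped pairs).
#' @export
pairwise_stability <- function(session_a, session_b, pairs,
                               mode = c("spatial", "temporal"),
                               control = c("none", "theta_bandstop",
                                           "in_field_only"),
                               bin_size = 0.02, sigma = 0.03, fs = 1000) {
  mode <- match.arg(mode)
  control <- match.arg(control)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  prep <- function(sess) {
    spikes <- sess$spikes
    if (control == "in_field_only")
      spikes <- lapply(spikes, strip_out_of_field, traj = sess$trajectory,
                       bin_size = bin_size, sigma = sigma)
    if (mode == "spatial")
      list(maps = lapply(spikes, compute_rate_map, traj = sess$trajectory,
                         bin_size = bin_size, sigma = sigma))
    else list(spikes = spikes)
  }
  pa <- prep(session_a)
  pb <- prep(session_b)
  ccg <- function(p, i, j) {
    if (mode == "spatial")
      as.numeric(spatial_cross_correlation(p$maps[[i]], p$maps[[j]])$values)
    else
      temporal_cross_correlation(p$spikes[[i]], p$spikes[[j]], fs = fs,
                                 theta_bandstop =
                                   control == "theta_bandstop")$values
  }
  out <- rep(NA_real_, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ca <- ccg(pa, pairs[k, 1], pairs[k, 2])
    cb <- ccg(pb, pairs[k, 1], pairs[k, 2])
    ok <- is.finite(ca) & is.finite(cb)
    if (sum(ok) < 3 || sd(ca[ok]) == 0 || sd(cb[ok]) == 0) {
      message(sprintf("pair %d-%d dropped (undefined correlogram)",
                      pairs[k, 1], pairs[k, 2]))
      next
    }
    out[k] <- cor(ca[ok], cb[ok])
  }
  out
}
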