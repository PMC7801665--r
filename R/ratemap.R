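# Occupancy-normalized firing-rate maps and their spatial correlations.

#' Rate map container
#'
#' Values are laid out as `values[ix, iy]` with bin (1,1) at the lower-left
#' corner of the arena and half-open bins `[k*b, (k+1)*b)`.
#'
#' @param values Matrix of firing rates (Hz).
#' @param occupancy Matrix of raw (unsmoothed) dwell times (s), or `NULL`.
#' @param occupancy_smoothed Matrix of smoothed dwell times, or `NULL`.
#' @param bin_size Bin side in meters.
#' @param sigma Smoothing sigma in meters (NA if unsmoothed).
#' @param arena_size Arena side in meters.
#' @return An object of class `rate_map`.
#' @export
rate_map <- function(values, occupancy = NULL, occupancy_smoothed = NULL,
                     bin_size = 0.02, sigma = NA_real_, arena_size = 1) {
  stopifnot(is.matrix(values))
  structure(list(values = values, occupancy = occupancy,
                 occupancy_smoothed = occupancy_smoothed,
                 bin_size = bin_size, sigma = sigma,
                 arena_size = arena_size),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("rate_map: %d x %d bins of %.0f cm, sigma %s cm, peak %.2f Hz\n",
              nrow(x$values), ncol(x$values), 100 * x$bin_size,
              ifelse(is.na(x$sigma), "-", format(100 * x$sigma)),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

# Separable truncated-Gaussian smoothing (zero-padded boundaries), as a pair
# of banded matrix products. The band matrices are memoised: map smoothing is
# called once per spike-shuffle surrogate, thousands of times per session.
.smooth_cache <- new.env(parent = emptyenv())

smooth_band <- function(n, sigma_bins) {
  key <- paste(n, sigma_bins)
  if (!is.null(.smooth_cache[[key]])) return(.smooth_cache[[key]])
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- exp(-0.5 * ((-half:half) / sigma_bins)^2)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (o in -half:half) {
    idx <- seq_len(n)
    src <- idx + o
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[o + half + 1]
  }
  .smooth_cache[[key]] <- K
  K
}

smooth2d <- function(m, sigma_bins) {
  if (sigma_bins <= 0) return(m)
  smooth_band(nrow(m), sigma_bins) %*% m %*%
    t(smooth_band(ncol(m), sigma_bins))
}

bin_index <- function(p, bin_size, n) pmin(pmax(floor(p / bin_size), 0), n - 1) + 1

#' Compute an occupancy-normalized smoothed rate map
#'
#' The arena is divided into square bins (default 2 cm); spike and occupancy
#' maps are accumulated, each smoothed with a truncated 2-D Gaussian, and
#' divided bin-wise. Two customary smoothing presets are sigma = 3 cm and
#' 5 cm.
#'
#' @param spikes A [spike_train()].
#' @param traj A [trajectory()].
#' @param bin_size Bin side in meters.
#' @param sigma Gaussian smoothing sigma in meters (0 disables smoothing).
#' @param occ_cache Optional precomputed occupancy (from
#'   [occupancy_maps()]) to reuse across many trains on one trajectory.
#' @return A [rate_map()]. Bins where the smoothed occupancy is zero get
#'   rate 0 and are flagged in attribute `"zero_occupancy"`.
#' @export
compute_rate_map <- function(spikes, traj, bin_size = 0.02, sigma = 0.03,
                             occ_cache = NULL) {
  if (!length(traj$t)) stop("empty trajectory")
  n <- ceiling(traj$arena_size / bin_size)
  if (is.null(occ_cache)) occ_cache <- occupancy_maps(traj, bin_size, sigma)
  occ <- occ_cache$raw
  occ_s <- occ_cache$smoothed
  spk <- matrix(0, n, n)
  if (length(spikes$times)) {
    pos <- traj_interp(traj, spikes$times)
    sx <- bin_index(pos$x, bin_size, n)
    sy <- bin_index(pos$y, bin_size, n)
    spk[] <- tabulate(sx + n * (sy - 1), nbins = n * n)
  }
  sb <- sigma / bin_size
  spk_s <- smooth2d(spk, sb)
  zero <- occ_s <= .Machine$double.eps
  rate <- matrix(0, n, n)
  rate[!zero] <- spk_s[!zero] / occ_s[!zero]
  out <- rate_map(rate, occupancy = occ, occupancy_smoothed = occ_s,
                  bin_size = bin_size, sigma = sigma,
                  arena_size = traj$arena_size)
  attr(out, "zero_occupancy") <- zero
  out
}

#' Raw and smoothed occupancy maps of a trajectory
#'
#' Precompute once when mapping many units (or spike-shuffle surrogates)
#' recorded on the same trajectory.
#'
#' @inheritParams compute_rate_map
#' @return List: `raw` (seconds per bin), `smoothed`.
#' @export
occupancy_maps <- function(traj, bin_size = 0.02, sigma = 0.03) {
  n <- ceiling(traj$arena_size / bin_size)
  ix <- bin_index(traj$x, bin_size, n)
  iy <- bin_index(traj$y, bin_size, n)
  occ <- matrix(0, n, n)
  occ[] <- tabulate(ix + n * (iy - 1), nbins = n * n) / traj$fs
  list(raw = occ, smoothed = smooth2d(occ, sigma / bin_size))
}

#' Spatial autocorrelogram of a rate map
#'
#' The full un-normalized 2-D auto-cross-correlation (sliding dot product) of
#' the smoothed rate map with itself, size `(2n-1) x (2n-1)`, or the
#' periodic (wrap) autocorrelation of size `n x n` for activity on a torus.
#'
#' @param map A [rate_map()] or a plain matrix.
#' @param wrap Use periodic boundary conditions (for sheet activity).
#' @return An object of class `autocorrelogram` with fields `values`,
#'   `center` (bin coordinates of zero offset) and `bin_size`.
#' @export
compute_autocorrelogram <- function(map, wrap = FALSE) {
  m <- if (inherits(map, "rate_map")) map$values else map
  bin_size <- if (inherits(map, "rate_map")) map$bin_size else 1
  if (any(!is.finite(m))) stop("rate map must be finite")
  if (wrap) {
    vals <- xcorr2_wrap(m, m)
    center <- c(floor(nrow(m) / 2) + 1L, floor(ncol(m) / 2) + 1L)
  } else {
    vals <- conv2_full(m, rot180(m))
    center <- c(nrow(m), ncol(m))
  }
  structure(list(values = vals, center = center, bin_size = bin_size,
                 wrap = wrap),
            class = "autocorrelogram")
}

#' Pearson spatial correlation between two rate maps
#'
#' Bins with zero raw occupancy in either map (unvisited arena locations) are
#' excluded; maps built without occupancy use all bins.
#'
#' @param map_a,map_b [rate_map()] objects (or matrices) of identical shape.
#' @return Pearson r in `[-1, 1]`, or `NaN` if fewer than 2 bins remain.
#' @export
spatial_correlation <- function(map_a, map_b) {
  va <- if (inherits(map_a, "rate_map")) map_a$values else map_a
  vb <- if (inherits(map_b, "rate_map")) map_b$values else map_b
  if (!all(dim(va) == dim(vb))) stop("rate maps have different shapes")
  keep <- rep(TRUE, length(va))
  if (inherits(map_a, "rate_map") && !is.null(map_a$occupancy))
    keep <- keep & (map_a$occupancy > 0)
  if (inherits(map_b, "rate_map") && !is.null(map_b$occupancy))
    keep <- keep & (map_b$occupancy > 0)
  keep <- keep & is.finite(va) & is.finite(vb)
  a <- va[keep]; b <- vb[keep]
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) return(NaN)
  cor(a, b)
}

#' Within-trial spatial stability
#'
#' Correlates the rate map of the first 10 minutes against the rate map of
#' the last 10 minutes (sessions shorter than 20 minutes are split at the
#' midpoint, with a flag).
#'
#' @inheritParams compute_rate_map
#' @param min_spikes Minimum spikes per half; below this `NaN` is returned
#'   with a warning.
#' @return Pearson r; attribute `"split_at_midpoint"` marks short sessions.
#' @export
within_trial_stability <- function(spikes, traj, bin_size = 0.02,
                                   sigma = 0.03, min_spikes = 10) {
  dur <- traj$t[length(traj$t)] - traj$t[1]
  midpoint <- dur < 1200 - 1 / traj$fs
  t_cut1 <- traj$t[1] + if (midpoint) dur / 2 else 600
  t_cut2 <- traj$t[length(traj$t)] - if (midpoint) dur / 2 else 600
  sub_traj <- function(keep) trajectory(traj$t[keep], traj$x[keep],
                                        traj$y[keep],
                                        if (is.null(traj$hd)) NULL else
                                          traj$hd[keep],
                                        traj$fs, traj$arena_size)
  first <- traj$t <= t_cut1
  last <- traj$t >= t_cut2
  spk1 <- spikes$times[spikes$times <= t_cut1]
  spk2 <- spikes$times[spikes$times >= t_cut2]
  if (length(spk1) < min_spikes || length(spk2) < min_spikes) {
    warning("too few spikes in a half-session; stability undefined")
    return(NaN)
  }
  m1 <- compute_rate_map(spike_train(spk1, traj$t[1], t_cut1, spikes$unit_id),
                         sub_traj(first), bin_size, sigma)
  m2 <- compute_rate_map(spike_train(spk2, t_cut2, traj$t[length(traj$t)],
                                     spikes$unit_id),
                         sub_traj(last), bin_size, sigma)
  r <- spatial_correlation(m1, m2)
  attr(r, "split_at_midpoint") <- midpoint
  r
}
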