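# Instantaneous-rate-based tuning scores (speed, head direction), spike
# shuffle null distributions, and functional cell classification.

#' Kernel-density instantaneous firing rate
#'
#' Spike counts on a regular grid convolved with a normalized Gaussian
#' kernel; the integral of the returned rate equals the spike count (up to
#' edge truncation of the kernel).
#'
#' @param spikes A [spike_train()].
#' @param kernel_sigma Kernel standard deviation in seconds.
#' @param fs_out Output sampling rate in Hz.
#' @param t_start,t_stop Time span (defaults to the train's bounds).
#' @return List: `t` (bin centers, s), `rate` (Hz).
#' @export
instantaneous_rate <- function(spikes, kernel_sigma = 0.4, fs_out = 50,
                               t_start = spikes$t_start,
                               t_stop = spikes$t_stop) {
  stopifnot(kernel_sigma > 0)
  dt <- 1 / fs_out
  edges <- seq(t_start, t_stop + dt / 2, by = dt)
  centers <- edges[-length(edges)] + dt / 2
  counts <- numeric(length(centers))
  if (length(spikes$times)) {
    idx <- findInterval(spikes$times, edges, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), length(centers))
    tab <- tabulate(idx, nbins = length(centers))
    counts <- tab
  }
  half <- max(1L, ceiling(4 * kernel_sigma * fs_out))
  k <- exp(-0.5 * ((-half:half) / (kernel_sigma * fs_out))^2)
  k <- k / sum(k)
  n <- length(counts)
  padded <- c(rep(0, half), counts, rep(0, half))
  sm <- stats::filter(padded, k, sides = 2)[(half + 1):(half + n)]
  list(t = centers, rate = as.numeric(sm) * fs_out)
}

#' Speed score of a unit
#'
#' Pearson correlation between the instantaneous firing rate (Gaussian
#' kernel, default sigma 0.4 s, sampled on the tracking clock) and running
#' speed, restricted to speeds between 0.02 and 1.0 m/s.
#'
#' @param spikes A [spike_train()].
#' @param traj A [trajectory()].
#' @param kernel_sigma Rate kernel sigma in seconds.
#' @param speed_range Included speed interval, m/s.
#' @return Pearson r (`NaN` with fewer than 2 valid samples).
#' @export
speed_score <- function(spikes, traj, kernel_sigma = 0.4,
                        speed_range = c(0.02, 1.0)) {
  v <- traj_speed(traj)
  ir <- instantaneous_rate(spikes, kernel_sigma, fs_out = traj$fs,
                           t_start = traj$t[1],
                           t_stop = traj$t[length(traj$t)])
  rate <- approx(ir$t, ir$rate, xout = traj$t, rule = 2)$y
  ok <- v >= speed_range[1] & v <= speed_range[2]
  if (sum(ok) < 2 || sd(rate[ok]) == 0 || sd(v[ok]) == 0) return(NaN)
  cor(rate[ok], v[ok])
}

#' Head-direction tuning of a unit
#'
#' Occupancy-normalized firing rate per angular bin; the tuning strength is
#' the resultant vector length of the rate-weighted unit vectors and the
#' preferred direction its argument.
#'
#' @param spikes A [spike_train()].
#' @param traj A [trajectory()] with head direction.
#' @param n_bins Number of angular bins (default 60 x 6 degrees).
#' @return List: `vector_length` in `[0, 1]`, `preferred_direction`
#'   (radians), `rates` (Hz per bin), `bin_centers`.
#' @export
head_direction_tuning <- function(spikes, traj, n_bins = 60) {
  if (is.null(traj$hd)) stop("trajectory has no head direction")
  edges <- seq(0, 2 * pi, length.out = n_bins + 1)
  centers <- edges[-1] - pi / n_bins
  hb <- findInterval(traj$hd %% (2 * pi), edges, rightmost.closed = TRUE)
  occ <- tabulate(hb, nbins = n_bins) / traj$fs
  idx <- pmin(pmax(round((spikes$times - traj$t[1]) * traj$fs) + 1, 1),
              length(traj$t))
  sb <- findInterval(traj$hd[idx] %% (2 * pi), edges,
                     rightmost.closed = TRUE)
  cnt <- tabulate(sb, nbins = n_bins)
  rates <- ifelse(occ > 0, cnt / occ, NA_real_)
  ok <- !is.na(rates)
  tot <- sum(rates[ok])
  if (tot == 0 || !any(ok))
    return(list(vector_length = NaN, preferred_direction = NaN,
                rates = rates, bin_centers = centers))
  z <- sum(rates[ok] * exp(1i * centers[ok]))
  list(vector_length = Mod(z) / tot,
       preferred_direction = Arg(z) %% (2 * pi),
       rates = rates, bin_centers = centers)
}

#' Spike-shuffle null distribution of a statistic
#'
#' Each surrogate is the whole train shifted by a uniform draw from
#' `[-shift, +shift]` seconds; with `edges = "wrap"` times falling outside
#' the session wrap circularly, with `edges = "drop"` they are discarded.
#' The 95th percentile of the surrogate statistics is the customary
#' classification threshold.
#'
#' @param spikes A [spike_train()].
#' @param statistic_fn Function of a `spike_train` returning a scalar.
#' @param n Number of surrogates.
#' @param shift Maximum shift in seconds.
#' @param edges `"wrap"` or `"drop"`.
#' @param seed Optional RNG seed.
#' @return A `shuffle_null` list: `values`, `percentile_95`, `observed`,
#'   `shift`, `n`.
#' @export
shuffle_distribution <- function(spikes, statistic_fn, n = 1000, shift = 30,
                                 edges = c("wrap", "drop"), seed = NULL) {
  edges <- match.arg(edges)
  if (!is.null(seed)) set.seed(seed)
  dur <- spikes$t_stop - spikes$t_start
  if (dur <= 2 * shift) stop("session too short for the shift window")
  shifts <- runif(n, -shift, shift)
  vals <- vapply(shifts, function(s) {
    tt <- spikes$times - spikes$t_start + s
    if (edges == "wrap") tt <- tt %% dur
    else tt <- tt[tt >= 0 & tt <= dur]
    surr <- spike_train(sort(tt) + spikes$t_start, spikes$t_start,
                        spikes$t_stop, spikes$unit_id)
    statistic_fn(surr)
  }, numeric(1))
  if (mean(!is.finite(vals)) > 0.1)
    warning("statistic undefined on more than 10% of surrogates")
  structure(list(values = vals,
                 percentile_95 = quantile(vals, 0.95, na.rm = TRUE,
                                          names = FALSE),
                 observed = statistic_fn(spikes), shift = shift, n = n),
            class = "shuffle_null")
}

null_threshold <- function(x) {
  if (inherits(x, "shuffle_null")) x$percentile_95 else as.numeric(x)
}

#' Classify a unit into functional cell types
#'
#' A unit is a grid cell when both its gridness and spatial information
#' exceed their shuffle 95th percentiles, a speed cell when its speed score
#' does, and a head-direction cell when its resultant vector length does.
#' A "pure" speed cell is a speed cell that is neither grid nor
#' head-direction tuned.
#'
#' @param observed Named list of observed values: `gridness`,
#'   `spatial_information`, `speed_score`, `hd_vector_length` (missing
#'   entries skip the corresponding class).
#' @param nulls Named list of `shuffle_null` objects (or numeric thresholds)
#'   for the same names.
#' @return List: `classes` (character subset of `c("grid","speed","hd")`),
#'   `pure_speed` (logical).
#' @export
classify_functional_cell_types <- function(observed, nulls) {
  need <- intersect(names(observed),
                    c("gridness", "spatial_information", "speed_score",
                      "hd_vector_length"))
  missing_nulls <- setdiff(need, names(nulls))
  if (length(missing_nulls))
    stop("missing null distributions for: ",
         paste(missing_nulls, collapse = ", "))
  exceeds <- function(nm) {
    !is.null(observed[[nm]]) && is.finite(observed[[nm]]) &&
      observed[[nm]] > null_threshold(nulls[[nm]])
  }
  classes <- character(0)
  is_grid <- all(c("gridness", "spatial_information") %in% need) &&
    exceeds("gridness") && exceeds("spatial_information")
  if (is_grid) classes <- c(classes, "grid")
  is_speed <- "speed_score" %in% need && exceeds("speed_score")
  if (is_speed) classes <- c(classes, "speed")
  is_hd <- "hd_vector_length" %in% need && exceeds("hd_vector_length")
  if (is_hd) classes <- c(classes, "hd")
  list(classes = classes, pure_speed = is_speed && !is_grid && !is_hd)
}
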