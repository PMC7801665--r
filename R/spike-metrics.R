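# Interspike-interval variability, bursting, and waveform-based unit typing.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# runs of TRUE in a logical vector -> matrix of (start, end) indices
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Coefficient of variation of the interspike intervals
#'
#' Three variants: `whole_session` computes CV = sigma_ISI / mu_ISI over all
#' intervals; `in_field_pass` computes one CV per pass through a firing
#' field (>= 3 spikes per pass) and averages; `low_speed` computes one CV
#' per slow-running segment (speed < 8 cm/s, duration > 0.2 s, >= 2 spikes)
#' and averages. The standard deviation is the population form (divide by
#' n); set `sample_sd = TRUE` for the n-1 form.
#'
#' @param spikes A [spike_train()].
#' @param traj A [trajectory()] (needed for the pass/speed variants).
#' @param fieldmap A `field_map` (needed for `in_field_pass`).
#' @param method One of `"whole_session"`, `"in_field_pass"`, `"low_speed"`.
#' @param bin_size Bin size of the field map, meters.
#' @param speed_thresh Speed threshold for `low_speed`, m/s.
#' @param sample_sd Use the sample (n-1) standard deviation.
#' @return List: `cv`, `sigma_isi`, `mu_isi`, `method`, `n_segments`.
#'   `cv` is `NaN` when no qualifying intervals/passes exist.
#' @export
cv_isi <- function(spikes, traj = NULL, fieldmap = NULL,
                   method = c("whole_session", "in_field_pass", "low_speed"),
                   bin_size = 0.02, speed_thresh = 0.08, sample_sd = FALSE) {
  method <- match.arg(method)
  sdev <- if (sample_sd) sd else pop_sd
  cv_of <- function(times) {
    isi <- diff(times)
    if (length(isi) < 1 || mean(isi) == 0) return(NaN)
    sdev(isi) / mean(isi)
  }
  if (method == "whole_session") {
    isi <- diff(spikes$times)
    if (length(isi) < 2) return(list(cv = NaN, sigma_isi = NaN, mu_isi = NaN,
                                     method = method, n_segments = 0))
    return(list(cv = sdev(isi) / mean(isi), sigma_isi = sdev(isi),
                mu_isi = mean(isi), method = method, n_segments = 1))
  }
  if (method == "in_field_pass") {
    stopifnot(!is.null(traj), !is.null(fieldmap))
    n <- nrow(fieldmap$labels)
    ix <- bin_index(traj$x, bin_size, n)
    iy <- bin_index(traj$y, bin_size, n)
    inside <- fieldmap$labels[cbind(ix, iy)] > 0
    seg <- runs_of(inside)
    seg <- seg[seg[, "end"] - seg[, "start"] >= 1, , drop = FALSE]  # >= 2 samples
    min_spikes <- 3
  } else {
    stopifnot(!is.null(traj))
    slow <- traj_speed(traj) < speed_thresh
    seg <- runs_of(slow)
    dur <- (seg[, "end"] - seg[, "start"]) / traj$fs
    seg <- seg[dur > 0.2, , drop = FALSE]
    min_spikes <- 2
  }
  cvs <- numeric(0)
  for (k in seq_len(nrow(seg))) {
    t0 <- traj$t[seg[k, "start"]]
    t1 <- traj$t[seg[k, "end"]]
    st <- spikes$times[spikes$times >= t0 & spikes$times <= t1]
    if (length(st) >= min_spikes) cvs <- c(cvs, cv_of(st))
  }
  cvs <- cvs[is.finite(cvs)]
  if (!length(cvs)) return(list(cv = NaN, sigma_isi = NaN, mu_isi = NaN,
                                method = method, n_segments = 0))
  list(cv = mean(cvs), sigma_isi = NA_real_, mu_isi = NA_real_,
       method = method, n_segments = length(cvs))
}

#' Bursting ratio of a spike train
#'
#' A spike with pre-ISI > 10 ms and post-ISI < 10 ms starts a burst; a spike
#' with both ISIs > 10 ms is a single-spike event; everything else (spikes
#' inside a burst) is uncounted. First and last spikes have infinite pre-
#' and post-ISI respectively.
#'
#' @param spikes A [spike_train()] (or numeric spike times in seconds).
#' @param isi_thresh Threshold in seconds (10 ms).
#' @return List: `n_burst`, `n_single`, `n_uncounted`, `ratio`
#'   (`n_burst / n_single`, `NaN` if no single-spike events).
#' @export
bursting_ratio <- function(spikes, isi_thresh = 0.010) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else
    sort(as.numeric(spikes))
  n <- length(times)
  if (n < 2) return(list(n_burst = 0L, n_single = n, n_uncounted = 0L,
                         ratio = if (n) 0 / n else NaN))
  pre <- c(Inf, diff(times))
  post <- c(diff(times), Inf)
  burst <- pre > isi_thresh & post < isi_thresh
  single <- pre > isi_thresh & post > isi_thresh
  n_b <- sum(burst)
  n_s <- sum(single)
  list(n_burst = n_b, n_single = n_s,
       n_uncounted = n - n_b - n_s,
       ratio = if (n_s > 0) n_b / n_s else NaN)
}

#' Trough-to-peak time and half-width of a mean spike waveform
#'
#' The channel with the largest trough is used. The trough-to-peak time is
#' measured on a 200-fold cubic-spline-upsampled trace (trough minimum to
#' the subsequent maximum); the half-width is the time between the two
#' half-amplitude crossings of the trough, refined by linear interpolation.
#'
#' @param waveform Numeric vector or matrix (samples x channels), uV.
#' @param fs Sampling rate in Hz.
#' @param upsample Upsampling factor for the cubic interpolation.
#' @return List: `trough_to_peak` (ms), `half_width` (ms), `channel`.
#' @export
waveform_features <- function(waveform, fs, upsample = 200) {
  w <- if (is.matrix(waveform)) waveform else matrix(waveform, ncol = 1)
  ch <- unname(which.min(apply(w, 2, min)))
  y <- w[, ch]
  n <- length(y)
  if (all(diff(y) >= 0) || all(diff(y) <= 0)) stop("monotone waveform trace")
  tms <- (seq_len(n) - 1) / fs * 1000
  up <- spline(tms, y, n = upsample * n)
  i_tr <- which.min(up$y)
  after <- seq(i_tr, length(up$y))
  i_pk <- after[which.max(up$y[after])]
  t2p <- up$x[i_pk] - up$x[i_tr]
  if (t2p <= 0) stop("no peak after the trough")
  half <- up$y[i_tr] / 2
  cross_t <- function(i0, i1) {   # linear interpolation between two samples
    x0 <- up$x[i0]; x1 <- up$x[i1]
    y0 <- up$y[i0]; y1 <- up$y[i1]
    x0 + (half - y0) / (y1 - y0) * (x1 - x0)
  }
  left <- which(up$y[seq_len(i_tr)] > half)
  right <- which(up$y[seq(i_tr, length(up$y))] > half)
  if (!length(left) || !length(right)) stop("trough does not cross half amplitude")
  iL <- max(left)
  iR <- i_tr + min(right) - 1L
  hw <- cross_t(iR - 1L, iR) - cross_t(iL, iL + 1L)
  list(trough_to_peak = t2p, half_width = hw, channel = ch)
}

#' Separate narrow- and broad-spiking units by k-means on waveform features
#'
#' Two-cluster k-means of (trough-to-peak, half-width), run separately per
#' experimental group; the cluster with the smaller mean trough-to-peak is
#' labeled narrow. Initialization is deterministic (centers at the units
#' with extreme trough-to-peak), so results do not depend on input order.
#'
#' @param features Data frame (or list of lists) with columns/fields
#'   `trough_to_peak` and `half_width`.
#' @param group Optional group label per unit; clustering is run per group.
#' @return Character vector of `"narrow"` / `"broad"` labels.
#' @export
classify_waveform_types <- function(features, group = NULL) {
  if (!is.data.frame(features))
    features <- data.frame(
      trough_to_peak = vapply(features, `[[`, numeric(1), "trough_to_peak"),
      half_width = vapply(features, `[[`, numeric(1), "half_width"))
  n <- nrow(features)
  if (n < 2) stop("need at least 2 units")
  if (is.null(group)) group <- rep("all", n)
  labels <- character(n)
  for (g in unique(group)) {
    idx <- which(group == g)
    x <- as.matrix(features[idx, c("trough_to_peak", "half_width")])
    if (max(x[, 1]) - min(x[, 1]) < 1e-12 && nrow(unique(x)) == 1) {
      warning("identical features: single cluster")
      labels[idx] <- "narrow"
      next
    }
    init <- x[c(which.min(x[, 1]), which.max(x[, 1])), , drop = FALSE]
    km <- kmeans(x, centers = init)
    narrow_cluster <- which.min(tapply(x[, 1], km$cluster, mean))
    labels[idx] <- ifelse(km$cluster == narrow_cluster, "narrow", "broad")
  }
  labels
}
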