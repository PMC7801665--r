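# S3 containers for recordings. Plain lists with validated fields, in the
# style of ape's "phylo": cheap to build in tests, printable, no magic.

#' Construct a trajectory object
#'
#' A trajectory holds tracked positions in an open-field arena, sampled on a
#' regular clock, together with head direction and the arena geometry.
#'
#' @param t Sample times in seconds, strictly increasing, spacing `1/fs`.
#' @param x,y Positions in meters within `[0, arena_size]`.
#' @param hd Head direction in radians in `[0, 2*pi)`, or `NULL`.
#' @param fs Sampling rate in Hz.
#' @param arena_size Side length of the square arena in meters.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(t, x, y, hd = NULL, fs, arena_size = 1) {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (length(t) > 1 && any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(x < 0 | x > arena_size | y < 0 | y > arena_size))
    stop("positions outside arena")
  if (!is.null(hd)) stopifnot(length(hd) == length(t))
  structure(list(t = t, x = x, y = y, hd = hd, fs = fs,
                 arena_size = arena_size),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples @ %g Hz, %.0f x %.0f cm arena, %.1f s\n",
              length(x$t), x$fs, 100 * x$arena_size, 100 * x$arena_size,
              diff(range(x$t))))
  invisible(x)
}

#' Construct a spike train object
#'
#' @param times Spike times in seconds, sorted, within `[t_start, t_stop]`.
#' @param t_start,t_stop Recording bounds in seconds.
#' @param unit_id Unit label.
#' @param waveform Optional mean waveform matrix (samples x channels, uV).
#' @param group Optional experimental group label (e.g. "control", "chABC").
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, t_start, t_stop, unit_id = "unit",
                        waveform = NULL, group = NA_character_) {
  times <- as.numeric(times)
  if (is.unsorted(times)) times <- sort(times)
  if (length(times) && (times[1] < t_start || times[length(times)] > t_stop))
    stop("spike times outside [t_start, t_stop]")
  structure(list(times = times, t_start = t_start, t_stop = t_stop,
                 unit_id = unit_id, waveform = waveform, group = group),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train '%s': %d spikes in [%.1f, %.1f] s (%.2f Hz)\n",
              x$unit_id, length(x$times), x$t_start, x$t_stop,
              length(x$times) / (x$t_stop - x$t_start)))
  invisible(x)
}

#' Ground-truth tuning parameters for a synthetic unit
#'
#' Describes the intensity function a synthetic spike train is drawn from,
#' so analyses can be checked against known parameters.
#'
#' @param cell_type One of `"grid"`, `"hd"`, `"speed"`, `"noise"`.
#' @param spacing Grid spacing in meters (grid cells).
#' @param orientation Grid orientation in radians.
#' @param phase Numeric length-2 spatial phase offset in meters.
#' @param peak_rate,baseline_rate Peak / baseline intensity in Hz.
#' @param hd_kappa von Mises concentration of head-direction tuning.
#' @param hd_mu Preferred head direction in radians.
#' @param speed_slope Rate gain in Hz per m/s (speed cells).
#' @param burst_prob Probability that a spike is replaced by a burst.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(cell_type = c("grid", "hd", "speed", "noise"),
                         spacing = 0.4, orientation = 0, phase = c(0, 0),
                         peak_rate = 15, baseline_rate = 0.5,
                         hd_kappa = 2, hd_mu = 0, speed_slope = 10,
                         burst_prob = 0) {
  cell_type <- match.arg(cell_type)
  stopifnot(spacing > 0, peak_rate >= 0, baseline_rate >= 0,
            burst_prob >= 0, burst_prob <= 1, length(phase) == 2)
  structure(list(cell_type = cell_type, spacing = spacing,
                 orientation = orientation, phase = phase,
                 peak_rate = peak_rate, baseline_rate = baseline_rate,
                 hd_kappa = hd_kappa, hd_mu = hd_mu,
                 speed_slope = speed_slope, burst_prob = burst_prob),
            class = "ground_truth")
}

#' Multi-session recording protocol
#'
#' The default emulates the novel-environment paradigm: a familiar session,
#' three sessions in a novel room (where grid maps remap coherently), and a
#' return to the familiar room.
#'
#' @param labels Ordered session labels.
#' @param durations Session durations in seconds (recycled to length of
#'   `labels`).
#' @param remap_rotation Rotation (radians) applied to all grid maps in novel
#'   sessions.
#' @param remap_shift Numeric length-2 phase shift in meters applied to all
#'   grid maps in novel sessions.
#' @param drift_sigma Random-walk step of the grid phase in m/sqrt(s);
#'   positive values destabilize the map within a session.
#' @param drift_mode `"common"` (one walk shared by all grid cells, preserving
#'   their pairwise offsets) or `"independent"` (one walk per cell).
#' @return An object of class `session_protocol`.
#' @export
session_protocol <- function(labels = c("Familiar I", "Novel I", "Novel II",
                                        "Novel III", "Familiar II"),
                             durations = 1200,
                             remap_rotation = pi / 6,
                             remap_shift = c(0.13, 0.07),
                             drift_sigma = 0,
                             drift_mode = c("common", "independent")) {
  durations <- rep_len(durations, length(labels))
  stopifnot(all(durations > 0), length(remap_shift) == 2, drift_sigma >= 0)
  structure(list(labels = labels, durations = durations,
                 remap_rotation = remap_rotation, remap_shift = remap_shift,
                 drift_sigma = drift_sigma,
                 drift_mode = match.arg(drift_mode)),
            class = "session_protocol")
}

# is a session label a novel-environment one?
is_novel_label <- function(label) grepl("^Novel", label)
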