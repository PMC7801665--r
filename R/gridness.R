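# Gridness score and grid geometry from the spatial autocorrelogram.
#
# The score is the classic rotational-symmetry statistic: the masked annulus
# of the autocorrelogram is rotated in 30 degree steps up to 150 degrees and
# score = min(r60, r120) - max(r30, r90, r150), where r_theta is the Pearson
# correlation between the rotated and unrotated annulus.

# Strict 3x3 local maxima of a matrix, value above `rel_thresh` times the
# largest peripheral peak. Returns a matrix of (i, j) rows.
local_maxima <- function(m, rel_thresh = 0) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  ismax <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
    ismax <- ismax & (m > nb)
  }
  which(ismax, arr.ind = TRUE)
}

#' Locate the central and peripheral peaks of an autocorrelogram
#'
#' Local maxima (3x3 neighborhood) are found; the peak closest to the array
#' center is the central peak and the rest are ordered by distance to it
#' (ties broken by angle from the positive x-axis). Peripheral peaks below
#' 10% of the strongest peripheral peak are discarded.
#'
#' @param acorr An `autocorrelogram` (see [compute_autocorrelogram()]).
#' @param rel_thresh Relative height threshold for peripheral peaks.
#' @return List with `center` (bin coords) and `peaks` (matrix of bin
#'   coords, ordered by radius).
#' @export
find_autocorr_peaks <- function(acorr, rel_thresh = 0.1) {
  m <- acorr$values
  cands <- local_maxima(m)
  if (!nrow(cands)) return(list(center = acorr$center,
                                peaks = matrix(numeric(0), 0, 2)))
  ctr <- acorr$center
  d_ctr <- sqrt((cands[, 1] - ctr[1])^2 + (cands[, 2] - ctr[2])^2)
  center <- cands[which.min(d_ctr), ]
  periph <- cands[-which.min(d_ctr), , drop = FALSE]
  if (nrow(periph)) {
    vals <- m[periph]
    periph <- periph[vals > rel_thresh * max(vals), , drop = FALSE]
  }
  if (nrow(periph)) {
    dx <- periph[, 1] - center[1]
    dy <- periph[, 2] - center[2]
    d <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx) %% (2 * pi)
    ord <- order(d, ang)
    periph <- periph[ord, , drop = FALSE]
  }
  list(center = unname(center), peaks = unname(periph))
}

# Spacing estimate: median radius of the six nearest peripheral peaks, read
# from the overlap-envelope-corrected autocorrelogram. The raw full (linear)
# autocorrelogram carries a triangular overlap envelope that pulls peak
# positions inward by 1-2 bins; dividing by the per-offset overlap count
# (n-|du|)(n-|dv|) removes that bias. Wrap (torus) autocorrelograms have no
# envelope. Falls back to the raw peak radii if correction spoils detection.
spacing_from_acorr <- function(acorr, fallback = NaN) {
  corrected <- acorr
  if (!isTRUE(acorr$wrap)) {
    n <- (nrow(acorr$values) + 1) / 2
    off <- -(n - 1):(n - 1)
    corrected$values <- acorr$values / outer(n - abs(off), n - abs(off))
  }
  pk <- find_autocorr_peaks(corrected)
  if (nrow(pk$peaks) < 6) return(fallback * acorr$bin_size)
  six <- pk$peaks[1:6, , drop = FALSE]
  d <- sqrt((six[, 1] - pk$center[1])^2 + (six[, 2] - pk$center[2])^2)
  median(d) * acorr$bin_size
}

#' Gridness score of an autocorrelogram
#'
#' The central peak is masked with a disk of radius half the distance to the
#' closest of the six nearest peripheral peaks; everything beyond 3/2 times
#' the distance to the outermost of those six is masked as well. The
#' remaining annulus is rotated by 30, 60, 90, 120 and 150 degrees (bilinear
#' interpolation about the array center) and correlated with the unrotated
#' annulus.
#'
#' @param acorr An `autocorrelogram`.
#' @return A `gridness_result` list: `score`, `center_peak`, `six_peaks`,
#'   `inner_mask_radius`, `outer_mask_radius`, `rotation_correlations`,
#'   `spacing` (meters). `score` is `NaN` when fewer than six peripheral
#'   peaks exist or the annulus is degenerate.
#' @export
gridness_score <- function(acorr) {
  pk <- find_autocorr_peaks(acorr)
  empty <- structure(list(score = NaN, center_peak = pk$center,
                          six_peaks = NULL, inner_mask_radius = NA_real_,
                          outer_mask_radius = NA_real_,
                          rotation_correlations = NULL, spacing = NaN),
                     class = "gridness_result")
  if (nrow(pk$peaks) < 6) return(empty)
  six <- pk$peaks[1:6, , drop = FALSE]
  ctr <- pk$center
  d <- sqrt((six[, 1] - ctr[1])^2 + (six[, 2] - ctr[2])^2)
  inner <- min(d) / 2
  outer <- 1.5 * max(d)
  if (outer <= inner) { empty$six_peaks <- six; return(empty) }
  m <- acorr$values
  nr <- nrow(m); nc <- ncol(m)
  ii <- row(m); jj <- col(m)
  rr <- sqrt((ii - ctr[1])^2 + (jj - ctr[2])^2)
  in_ann <- rr > inner & rr < outer
  # rotate about the array center
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  base <- m[in_ann]
  xi <- ii[in_ann] - rc
  yi <- jj[in_ann] - cc
  cors <- vapply(c(30, 60, 90, 120, 150), function(deg) {
    th <- deg * pi / 180
    # sample source coordinates under inverse rotation
    xs <- cos(th) * xi + sin(th) * yi + rc
    ys <- -sin(th) * xi + cos(th) * yi + cc
    rot <- bilinear(m, xs, ys)
    ok <- is.finite(rot)
    if (sum(ok) < 3) return(NaN)
    cor(base[ok], rot[ok])
  }, numeric(1))
  names(cors) <- c("30", "60", "90", "120", "150")
  score <- min(cors["60"], cors["120"]) - max(cors["30"], cors["90"],
                                              cors["150"])
  structure(list(score = unname(score), center_peak = ctr, six_peaks = six,
                 inner_mask_radius = inner, outer_mask_radius = outer,
                 rotation_correlations = cors,
                 spacing = spacing_from_acorr(acorr, fallback = median(d))),
            class = "gridness_result")
}

#' @export
print.gridness_result <- function(x, ...) {
  cat(sprintf("gridness %.3f, spacing %s m\n", x$score,
              ifelse(is.finite(x$spacing), sprintf("%.3f", x$spacing), "NA")))
  invisible(x)
}

#' Grid spacing from a gridness result
#'
#' Median distance from the central peak to the six surrounding peaks,
#' converted to meters.
#'
#' @param result A `gridness_result` from [gridness_score()].
#' @return Spacing in meters (`NaN` when peaks are undefined).
#' @export
grid_spacing <- function(result) result$spacing
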