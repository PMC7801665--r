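# Firing-field segmentation and the field-based statistics: the fields are
# the non-positive-curvature regions of the smoothed rate map around
# surviving peaks, with a minimum area of 9 bins.

# 5-point Laplacian with reflected edges (matches scipy.ndimage.laplace).
laplacian5 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1, seq_len(nr - 1)), , drop = FALSE]
  dn <- m[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
  lf <- m[, c(1, seq_len(nc - 1)), drop = FALSE]
  rt <- m[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  up + dn + lf + rt - 4 * m
}

# 8-connected component labeling of a logical matrix (two-pass union-find).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    nbs <- integer(0)
    if (i > 1 && mask[i - 1, j]) nbs <- c(nbs, lab[i - 1, j])
    if (j > 1) {
      if (mask[i, j - 1]) nbs <- c(nbs, lab[i, j - 1])
      if (i > 1 && mask[i - 1, j - 1]) nbs <- c(nbs, lab[i - 1, j - 1])
      if (i < nr && mask[i + 1, j - 1]) nbs <- c(nbs, lab[i + 1, j - 1])
    }
    if (!length(nbs)) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else {
      roots <- vapply(nbs, find, integer(1))
      r <- min(roots)
      lab[i, j] <- r
      for (ro in roots) parent[ro] <- r
    }
  }
  if (nxt == 0L) return(lab)
  # resolve and compact labels
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  idx <- lab > 0L
  lab[idx] <- remap[lab[idx]]
  lab
}

#' Identify firing fields in a rate map
#'
#' Procedure: (1) the global field radius is 0.7 times half the distance
#' from the autocorrelogram's central peak to its closest peak; (2) rate-map
#' peaks are found and the lower of any two peaks closer than that radius is
#' excluded; (3) bins with positive Laplacian (valleys) are excluded; (4)
#' remaining bins are labeled into 8-connected components; (5) components
#' smaller than 9 bins are dropped; (6) components containing a surviving
#' peak become fields, sorted by descending mean rate.
#'
#' @param map A [rate_map()].
#' @param acorr Optional `autocorrelogram` supplying the global field
#'   radius; if `NULL` or peakless, `fallback_radius` (bins) is used.
#' @param fallback_radius Field radius in bins when no autocorrelogram
#'   geometry is available.
#' @param min_area Minimum field area in bins.
#' @return A `field_map` list: `labels` (integer image, 0 = background),
#'   `fields` (list of `id`, `bins`, `peak`, `mean_rate`, `area`),
#'   `global_field_radius` (bins).
#' @export
identify_fields <- function(map, acorr = NULL, fallback_radius = 5,
                            min_area = 9) {
  m <- map$values
  radius <- fallback_radius
  if (!is.null(acorr)) {
    pk <- find_autocorr_peaks(acorr)
    if (nrow(pk$peaks) >= 1) {
      d1 <- sqrt(sum((pk$peaks[1, ] - pk$center)^2))
      radius <- 0.7 * d1 / 2
    }
  }
  empty <- structure(list(labels = matrix(0L, nrow(m), ncol(m)),
                          fields = list(), global_field_radius = radius),
                     class = "field_map")
  peaks <- local_maxima(m)
  if (!nrow(peaks)) return(empty)
  # drop the lower of any two peaks closer than the field radius
  ord <- order(m[peaks], decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) for (j in (i + 1):nrow(peaks)) {
      if (keep[j] &&
          sqrt(sum((peaks[i, ] - peaks[j, ])^2)) < radius) keep[j] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  lap <- laplacian5(m)
  lab <- label_components(lap <= 0 & m > 0)
  if (!max(lab)) return(empty)
  areas <- tabulate(lab[lab > 0])
  fields <- list()
  for (comp in which(areas >= min_area)) {
    in_comp <- lab == comp
    pk_in <- peaks[in_comp[peaks], , drop = FALSE]
    if (!nrow(pk_in)) next
    best <- pk_in[which.max(m[pk_in]), ]
    fields[[length(fields) + 1]] <-
      list(id = comp, bins = which(in_comp, arr.ind = TRUE),
           peak = unname(best), mean_rate = mean(m[in_comp]),
           area = areas[comp])
  }
  if (!length(fields)) return(empty)
  fields <- fields[order(vapply(fields, `[[`, numeric(1), "mean_rate"),
                         decreasing = TRUE)]
  labels <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_along(fields)) {
    labels[fields[[i]]$bins] <- i
    fields[[i]]$id <- i
  }
  structure(list(labels = labels, fields = fields,
                 global_field_radius = radius),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("field_map: %d fields, radius %.1f bins\n",
              length(x$fields), x$global_field_radius))
  invisible(x)
}

#' Mean firing rate inside and outside the firing fields
#'
#' @param spikes A [spike_train()].
#' @param traj A [trajectory()].
#' @param fieldmap A `field_map` from [identify_fields()].
#' @param bin_size Bin size matching the field map, meters.
#' @return List: `fr_in`, `fr_out` (Hz), `in_field_time`, `out_field_time`
#'   (s), `in_field_spikes`, `out_field_spikes`.
#' @export
in_out_field_rates <- function(spikes, traj, fieldmap, bin_size = 0.02) {
  n <- nrow(fieldmap$labels)
  dt <- 1 / traj$fs
  ix <- bin_index(traj$x, bin_size, n)
  iy <- bin_index(traj$y, bin_size, n)
  in_traj <- fieldmap$labels[cbind(ix, iy)] > 0
  t_in <- sum(in_traj) * dt
  t_out <- sum(!in_traj) * dt
  if (length(spikes$times)) {
    pos <- traj_interp(traj, spikes$times)
    sx <- bin_index(pos$x, bin_size, n)
    sy <- bin_index(pos$y, bin_size, n)
    in_spk <- fieldmap$labels[cbind(sx, sy)] > 0
  } else in_spk <- logical(0)
  list(fr_in = if (t_in > 0) sum(in_spk) / t_in else NaN,
       fr_out = if (t_out > 0) sum(!in_spk) / t_out else NaN,
       in_field_time = t_in, out_field_time = t_out,
       in_field_spikes = sum(in_spk), out_field_spikes = sum(!in_spk))
}

#' Spatial specificity (log10 in-field / out-of-field rate ratio)
#'
#' @param rates Result of [in_out_field_rates()], or an in-field rate when
#'   `fr_out` is given.
#' @param fr_out Out-of-field rate (Hz) when `rates` is a scalar.
#' @return `log10(fr_in / fr_out)`; `+Inf`/`-Inf` sentinels (with a warning)
#'   when one of the rates is zero.
#' @export
spatial_specificity <- function(rates, fr_out = NULL) {
  if (is.list(rates)) {
    fr_in <- rates$fr_in
    fr_out <- rates$fr_out
  } else fr_in <- rates
  if (is.na(fr_in) || is.na(fr_out)) return(NaN)
  if (fr_out == 0 && fr_in == 0) return(NaN)
  if (fr_out == 0) { warning("zero out-of-field rate"); return(Inf) }
  if (fr_in == 0) { warning("zero in-field rate"); return(-Inf) }
  log10(fr_in / fr_out)
}

#' Spatial information of a rate map
#'
#' `sum_i p_i (lambda_i / lambda) log2(lambda_i / lambda)` with `p_i` the
#' occupancy probability of bin i and `lambda` the occupancy-weighted mean
#' rate (bits per spike). `per_second = TRUE` gives the
#' `sum_i p_i lambda_i log2(lambda_i / lambda)` variant (bits per second).
#'
#' @param map A [rate_map()] (occupancy taken from the smoothed occupancy
#'   when available, else the raw one).
#' @param per_second Return the bits-per-second variant.
#' @return Non-negative information value (0 with a warning if the mean rate
#'   is zero).
#' @export
spatial_information <- function(map, per_second = FALSE) {
  occ <- if (!is.null(map$occupancy_smoothed)) map$occupancy_smoothed else
    map$occupancy
  if (is.null(occ)) occ <- matrix(1, nrow(map$values), ncol(map$values))
  tot <- sum(occ)
  if (tot <= 0) stop("total occupancy must be positive")
  p <- occ / tot
  lam <- map$values
  lbar <- sum(p * lam)
  if (lbar == 0) { warning("mean rate is zero"); return(0) }
  pos <- lam > 0
  ratio <- lam[pos] / lbar
  if (per_second)
    sum(p[pos] * lam[pos] * log2(ratio))
  else
    sum(p[pos] * ratio * log2(ratio))
}
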