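# Group-level statistics: Mann-Whitney U, animal-level permutation
# resampling, and recording-level bootstrap confidence intervals.

#' Two-sided Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()] (exact for small tie-free samples, normal
#' approximation with tie correction otherwise) and reports the U statistic.
#'
#' @param a,b Numeric samples.
#' @return List: `U`, `p`, `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Animal-level permutation resampling test
#'
#' Tests whether per-unit values differ between groups beyond what random
#' assignment of whole animals would produce: the statistic is the absolute
#' difference of group medians of unit values, and the null is built by
#' permuting animal-to-group assignments (units travel with their animal).
#' `p = (1 + #permutations >= observed) / (1 + n_perm)`.
#'
#' @param value Numeric statistic per unit.
#' @param animal Animal id per unit.
#' @param group Group label per unit (two levels, constant within animal).
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @return List: `p`, `observed`, `null` (permutation statistics).
#' @export
permutation_group_test <- function(value, animal, group, n_perm = 10000,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(value) == length(animal), length(value) == length(group))
  animals <- unique(animal)
  a_group <- vapply(animals, function(a)
    as.character(group[animal == a][1]), character(1))
  lv <- unique(a_group)
  if (length(lv) != 2) stop("exactly two groups required")
  if (min(table(a_group)) < 2)
    stop("permutation test undefined with a single animal in a group")
  stat <- function(ag) {
    g_of_unit <- ag[match(animal, animals)]
    abs(median(value[g_of_unit == lv[1]]) - median(value[g_of_unit == lv[2]]))
  }
  observed <- stat(a_group)
  null <- vapply(seq_len(n_perm), function(i) stat(sample(a_group)),
                 numeric(1))
  list(p = (1 + sum(null >= observed)) / (1 + n_perm), observed = observed,
       null = null)
}

#' Bootstrap confidence interval over recordings
#'
#' Resamples recordings (not units) with replacement and returns the
#' percentile interval of the mean of per-recording values.
#'
#' @param values_by_recording List of numeric vectors (one per recording)
#'   or a numeric vector of per-recording summaries.
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Optional RNG seed.
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values_by_recording, n_boot = 1000, level = 0.95,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.list(values_by_recording))
    values_by_recording <- as.list(values_by_recording)
  n <- length(values_by_recording)
  if (n < 2) stop("need at least 2 recordings")
  per_rec <- vapply(values_by_recording, function(v) mean(unlist(v)),
                    numeric(1))
  boots <- vapply(seq_len(n_boot), function(i)
    mean(per_rec[sample.int(n, n, replace = TRUE)]), numeric(1))
  alpha <- (1 - level) / 2
  unname(quantile(boots, c(alpha, 1 - alpha)))
}
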