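# Pairwise temporal and spatial cross-correlations and their stability.

test_that("temporal cross-correlogram has unit self-correlation at lag 0", {
  set.seed(1)
  a <- spike_train(sort(runif(800, 0, 120)), 0, 120)
  cc <- temporal_cross_correlation(a, a)
  i0 <- which(cc$lags == 0)
  expect_equal(cc$values[i0], max(cc$values))
  expect_equal(cc$values[i0], 1, tolerance = 0.01)
  expect_true(all(abs(cc$values) <= 1 + 1e-9))
  expect_equal(cc$lags, seq(-1, 1, by = 1e-3))
})

test_that("a shifted copy peaks at the positive lag (b after a)", {
  set.seed(2)
  a <- spike_train(sort(runif(600, 0, 100)), 0, 110)
  b <- spike_train(a$times + 0.05, 0, 110)
  cc <- temporal_cross_correlation(a, b)
  expect_equal(cc$lags[which.max(cc$values)], 0.05, tolerance = 2e-3)
  # independent trains decorrelate
  b2 <- spike_train(sort(runif(600, 0, 110)), 0, 110)
  cc2 <- temporal_cross_correlation(a, b2)
  expect_lt(max(abs(cc2$values)), 0.15)
  # empty train -> NaN series
  ccN <- temporal_cross_correlation(a, spike_train(numeric(0), 0, 110))
  expect_true(all(is.nan(ccN$values)))
})

test_that("spatial cross-correlation locates circular shifts exactly", {
  set.seed(3)
  m <- matrix(runif(144), 12, 12)
  sc <- spatial_cross_correlation(m, m)
  expect_equal(sc$values[sc$center[1], sc$center[2]], 1, tolerance = 1e-9)
  expect_equal(max(sc$values), 1, tolerance = 1e-9)
  # content moved by (+3, +5): peak sits at exactly that offset
  ms <- m[c(10:12, 1:9), c(8:12, 1:7)]    # ms[i, j] = m[i - 3, j - 5] (mod 12)
  sc2 <- spatial_cross_correlation(m, ms)
  pk <- which(sc2$values == max(sc2$values), arr.ind = TRUE)
  expect_equal(as.integer(pk[1, ] - sc2$center), c(3, 5))
  # FFT equals direct periodic summation after z-scoring (population sd)
  psd_ <- function(x) sqrt(mean((x - mean(x))^2))
  za <- (m - mean(m)) / psd_(m)
  zb <- (ms - mean(ms)) / psd_(ms)
  expect_equal(sc2$values, direct_xcorr_wrap(za, zb) / length(m),
               tolerance = 1e-8)
  # constant map is degenerate
  expect_true(all(is.nan(spatial_cross_correlation(
    m, matrix(1, 12, 12))$values)))
})

test_that("pairwise stability is 1 for identical sessions and symmetric", {
  traj <- generate_trajectory(duration = 300, seed = 41)
  pop <- list(ground_truth("grid", spacing = 0.4, phase = c(0.05, 0.1),
                           peak_rate = 12),
              ground_truth("grid", spacing = 0.4, phase = c(0.25, 0.18),
                           peak_rate = 12))
  spikes <- lapply(seq_along(pop), function(i)
    generate_cell_spikes(traj, pop[[i]], unit_id = paste0("u", i),
                         seed = 50 + i))
  sess <- list(trajectory = traj, spikes = spikes)
  pairs <- matrix(c(1, 2), 1, 2)
  r_same <- pairwise_stability(sess, sess, pairs, mode = "spatial")
  expect_equal(r_same, 1, tolerance = 1e-9)
  # second independent session: stability defined and symmetric
  traj2 <- generate_trajectory(duration = 300, seed = 42)
  spikes2 <- lapply(seq_along(pop), function(i)
    generate_cell_spikes(traj2, pop[[i]], unit_id = paste0("u", i),
                         seed = 60 + i))
  sess2 <- list(trajectory = traj2, spikes = spikes2)
  r_ab <- pairwise_stability(sess, sess2, pairs, mode = "spatial")
  r_ba <- pairwise_stability(sess2, sess, pairs, mode = "spatial")
  expect_equal(r_ab, r_ba, tolerance = 1e-9)
  expect_gt(r_ab, 0.5)     # same intensity maps, fresh sampling noise
})

test_that("controls preserve the stability structure without theta", {
  # On theta-free synthetic pairs the controls must not change the
  # conclusions: per-pair stabilities under each control track the
  # uncontrolled values closely. (The band-stop also strips broadband rate
  # noise, so it shifts raw values slightly upward; what matters is that
  # the pair ordering and magnitudes stay intact.)
  pop <- list(ground_truth("grid", spacing = 0.4, phase = c(0.05, 0.1),
                           peak_rate = 15),
              ground_truth("grid", spacing = 0.4, phase = c(0.22, 0.3),
                           peak_rate = 15),
              ground_truth("grid", spacing = 0.4, phase = c(0.3, 0.02),
                           peak_rate = 15))
  mk <- function(seed_base) {
    tr <- generate_trajectory(duration = 900, seed = seed_base)
    list(trajectory = tr,
         spikes = lapply(seq_along(pop), function(i)
           generate_cell_spikes(tr, pop[[i]], unit_id = paste0("u", i),
                                seed = seed_base + i)))
  }
  s1 <- mk(70)
  s2 <- mk(80)
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  r_plain <- pairwise_stability(s1, s2, pairs, mode = "temporal")
  r_bstop <- pairwise_stability(s1, s2, pairs, mode = "temporal",
                                control = "theta_bandstop")
  expect_gt(cor(r_plain, r_bstop), 0.9)
  expect_lt(max(abs(r_plain - r_bstop)), 0.2)
  r_spat <- pairwise_stability(s1, s2, pairs[1, , drop = FALSE],
                               mode = "spatial")
  r_infield <- pairwise_stability(s1, s2, pairs[1, , drop = FALSE],
                                  mode = "spatial",
                                  control = "in_field_only")
  expect_lt(abs(r_spat - r_infield), 0.2)
})
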