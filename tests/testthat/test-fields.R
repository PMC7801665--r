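# Firing-field segmentation and the field statistics.

test_that("a single broad bump yields exactly one field containing its peak", {
  n <- 40
  bump <- 5 * exp(-outer((1:n - 20)^2, (1:n - 24)^2, "+") / (2 * 16))
  fm <- identify_fields(rate_map(bump, bin_size = 0.02))
  expect_length(fm$fields, 1)
  expect_equal(fm$fields[[1]]$peak, c(20, 24))
  expect_true(fm$labels[20, 24] == 1)
  # a tiny bump (< 9 bins above the curvature criterion) yields none
  tiny <- matrix(0, 20, 20)
  tiny[10, 10] <- 1
  tiny[9, 10] <- tiny[11, 10] <- tiny[10, 9] <- tiny[10, 11] <- 0.3
  expect_length(identify_fields(rate_map(tiny, bin_size = 0.02))$fields, 0)
})

test_that("a seven-bump map yields seven non-overlapping fields", {
  # central bump plus its six hexagonal neighbors, nothing else
  n <- 50
  ctrs <- rbind(c(25, 25),
                t(sapply(0:5, function(k)
                  c(25, 25) + 16 * c(cos(k * pi / 3), sin(k * pi / 3)))))
  m <- matrix(0, n, n)
  for (r in seq_len(nrow(ctrs)))
    m <- m + exp(-outer((1:n - ctrs[r, 1])^2, (1:n - ctrs[r, 2])^2,
                        "+") / (2 * 9))
  map <- rate_map(m, bin_size = 0.02)
  fm <- identify_fields(map, compute_autocorrelogram(map))
  expect_equal(length(fm$fields), 7)
  # labels partition: no overlap, every field has >= 9 bins
  areas <- vapply(fm$fields, `[[`, numeric(1), "area")
  expect_true(all(areas >= 9))
  expect_equal(sum(fm$labels > 0), sum(areas))
  rates <- vapply(fm$fields, `[[`, numeric(1), "mean_rate")
  expect_true(all(diff(rates) <= 0))   # sorted by descending mean rate
})

test_that("in/out-field rates follow a hand-computed example", {
  # 5x5 arena; field = the single bin (2,3); dwell 0.08 s per bin
  traj <- uniform_grid_traj()
  labels <- matrix(0L, 5, 5)
  labels[2, 3] <- 1L
  fm <- structure(list(labels = labels, fields = list(list(id = 1)),
                       global_field_radius = 1),
                  class = "field_map")
  in_t <- traj$t[abs(traj$x - 0.03) < 1e-9 & abs(traj$y - 0.05) < 1e-9]
  spk <- spike_train(c(in_t[1], in_t[2], traj$t[1]), traj$t[1],
                     traj$t[length(traj$t)])
  rates <- in_out_field_rates(spk, traj, fm, bin_size = 0.02)
  expect_equal(rates$in_field_time, 0.08)
  expect_equal(rates$out_field_time, 24 * 0.08)
  expect_equal(rates$in_field_spikes, 2)
  expect_equal(rates$fr_in, 2 / 0.08)
  expect_equal(rates$fr_out, 1 / (24 * 0.08))
  # all spikes inside the field -> zero out rate
  rates2 <- in_out_field_rates(spike_train(in_t[1:2], traj$t[1],
                                           traj$t[length(traj$t)]),
                               traj, fm, bin_size = 0.02)
  expect_equal(rates2$fr_out, 0)
})

test_that("a homogeneous cell fires equally in and out of foreign fields", {
  # fields taken from an independent grid cell, so the untuned cell's rate
  # carries no selection bias toward its own noise peaks
  traj <- fix_traj()
  spk <- generate_cell_spikes(traj, ground_truth("noise", peak_rate = 5),
                              seed = 31)
  fm <- identify_fields(fix_grid_map(), fix_grid_acorr())
  rates <- in_out_field_rates(spk, traj, fm)
  expect_equal(rates$fr_in / rates$fr_out, 1, tolerance = 0.15)
})

test_that("spatial specificity is the log10 rate ratio with sentinels", {
  expect_equal(spatial_specificity(2, fr_out = 2), 0)
  expect_equal(spatial_specificity(20, fr_out = 2), 1)
  expect_equal(spatial_specificity(3.0, fr_out = 0.6), log10(5))
  expect_warning(s <- spatial_specificity(1, fr_out = 0), "out-of-field")
  expect_identical(s, Inf)
  expect_warning(s2 <- spatial_specificity(0, fr_out = 1), "in-field")
  expect_identical(s2, -Inf)
})

test_that("spatial information matches hand evaluation and its invariances", {
  # two equal-occupancy bins with rates (2, 0): exactly 1 bit
  m2 <- rate_map(matrix(c(2, 0), 1, 2), occupancy = matrix(1, 1, 2))
  expect_equal(spatial_information(m2), 1.0)
  # bits-per-second variant: p*lambda*log2(lambda/mean) = 0.5*2*1
  expect_equal(spatial_information(m2, per_second = TRUE), 1.0)
  # uniform map carries no information
  mu <- rate_map(matrix(4, 10, 10), occupancy = matrix(0.3, 10, 10))
  expect_equal(spatial_information(mu), 0)
  # occupancy rescaling leaves the value unchanged; random maps are >= 0
  set.seed(5)
  v <- matrix(rexp(100), 10, 10)
  occ <- matrix(runif(100), 10, 10)
  i1 <- spatial_information(rate_map(v, occupancy = occ))
  i2 <- spatial_information(rate_map(v, occupancy = 17 * occ))
  expect_equal(i1, i2)
  expect_gte(i1, 0)
})

test_that("raising the baseline lowers specificity and information", {
  traj <- fix_traj()
  vals <- lapply(c(0.5, 3), function(b) {
    gt <- ground_truth("grid", spacing = 0.4, phase = c(0.1, 0.2),
                       peak_rate = 15, baseline_rate = b)
    spk <- generate_grid_spikes(traj, gt, seed = 77)
    map <- compute_rate_map(spk, traj)
    fm <- identify_fields(map, compute_autocorrelogram(map))
    list(spec = spatial_specificity(in_out_field_rates(spk, traj, fm)),
         info = spatial_information(map))
  })
  expect_gt(vals[[1]]$spec, vals[[2]]$spec)
  expect_gt(vals[[1]]$info, vals[[2]]$info)
})
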