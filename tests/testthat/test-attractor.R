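# EIF attractor network: synapse normalization, connectivity geometry,
# integration accuracy, manipulations, and rate summaries.

test_that("beta synapse normalization peaks at the weight", {
  k <- beta_synapse_norm(1, 5)
  expect_equal(k$t_peak, 5 / 4 * log(5))
  # closed-form conductance peaks at exactly w at t_peak
  g <- function(t) k$K * (exp(-t / 5) - exp(-t / 1))
  expect_equal(g(k$t_peak), 1, tolerance = 1e-12)
  tt <- seq(0, 30, by = 0.001)
  expect_equal(max(g(tt)), 1, tolerance = 1e-6)
  expect_equal(tt[which.max(g(tt))], k$t_peak, tolerance = 1e-3)
  # discrete trace from the simulator matches the closed form to 1e-6
  tr <- gridnet:::beta_conductance_cpp(2.5, 1, 5, k$K, 0.01, 30)
  expect_equal(tr, 2.5 * g(seq(0, 30, by = 0.01)), tolerance = 1e-6)
  expect_error(beta_synapse_norm(5, 1), "tau_decay > tau_rise")
})

test_that("connectivity matches a brute-force torus-distance oracle", {
  cfg <- attractor_config(n_side = 20, duration = 2, settle = 1)
  conn <- build_connectivity(cfg)
  deg_ei <- diff(conn$ei_ptr)
  deg_ie <- diff(conn$ie_ptr)
  # torus symmetry: identical out-degrees
  expect_equal(length(unique(deg_ei)), 1)
  expect_equal(length(unique(deg_ie)), 1)
  # exhaustive oracle on the full 20 x 20 sheet
  pos <- gridnet:::sheet_positions(20)
  d <- gridnet:::torus_dist(pos$x, pos$y, pos$x, pos$y)
  for (src in c(1, 57, 400)) {
    expect_setequal(conn$ei_idx[(conn$ei_ptr[src] + 1):conn$ei_ptr[src + 1]],
                    which(d[src, ] > cfg$r_EI_inner &
                            d[src, ] < cfg$r_EI_outer) - 1L)
    expect_setequal(conn$ie_idx[(conn$ie_ptr[src] + 1):conn$ie_ptr[src + 1]],
                    which(d[src, ] < cfg$r_IE_outer) - 1L)
  }
  # vanishing disc keeps only the co-located unit; empty annulus errors
  cfg0 <- attractor_config(n_side = 10, r_IE_outer = 1e-6)
  expect_equal(unique(diff(build_connectivity(cfg0)$ie_ptr)), 1L)
  expect_error(attractor_config(r_EI_inner = 0.5, r_EI_outer = 0.5),
               "r_EI_outer")
})

test_that("an unconnected network without drive stays silent at rest", {
  cfg <- attractor_config(n_side = 5, g_EI = 0, g_IE = 0, p_rate = 0,
                          w_ext = 0, duration = 0.5, settle = 0.1,
                          v_init = "rest")
  res <- simulate_network(cfg, seed = 1)
  expect_equal(nrow(res$spikes), 0)
  expect_true(all(res$rates == 0))
  s <- population_rate_summary(res)
  expect_equal(unname(s$median_all), c(0, 0))
})

test_that("single-neuron rate matches a fine-step reference within 2%", {
  # EIF with 400 pA tonic current; reference: classical RK4 at dt = 1e-3 ms
  cfg <- attractor_config(n_side = 1, p_rate = 0, w_ext = 0,
                          i_const_E = 400, duration = 2, settle = 0,
                          v_init = "rest",
                          r_EI_inner = 0.1, r_EI_outer = 0.2,
                          r_IE_outer = 0.1)
  res <- simulate_network(cfg, seed = 1)
  f <- function(V) (-10 * (V + 70) + 20 * exp((min(V, 0) + 50) / 2) + 400) / 200
  dt <- 1e-3
  V <- -70; nsp <- 0; refc <- 0
  for (i in seq_len(2000 / dt)) {
    if (refc > 0) { refc <- refc - 1; next }
    k1 <- f(V); k2 <- f(V + dt / 2 * k1)
    k3 <- f(V + dt / 2 * k2); k4 <- f(V + dt * k3)
    V <- V + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (V >= 0) { nsp <- nsp + 1; V <- -70; refc <- 2 / dt }
  }
  expect_equal(res$rates[1], nsp / 2, tolerance = 0.02)
})

test_that("simulation is reproducible and rejects blow-ups gracefully", {
  cfg <- attractor_config(n_side = 10, duration = 1, settle = 0.5)
  r1 <- simulate_network(cfg, seed = 5)
  r2 <- simulate_network(cfg, seed = 5)
  expect_identical(r1$spikes, r2$spikes)
  r3 <- simulate_network(cfg, seed = 6)
  expect_false(identical(r1$spikes$t, r3$spikes$t))
})

test_that("PNN manipulations scale exactly one parameter", {
  cfg <- attractor_config()
  expect_equal(apply_pnn_manipulation(cfg, "reduced_EI", 1), cfg)
  red <- apply_pnn_manipulation(cfg, "reduced_EI", 0.7)
  expect_equal(red$g_EI, 0.7 * cfg$g_EI)
  expect_equal(red[setdiff(names(red), "g_EI")],
               cfg[setdiff(names(cfg), "g_EI")])
  cm <- apply_pnn_manipulation(cfg, "increased_Cm", 1.25)
  expect_equal(cm$eif_I$C_m, 125)
  expect_equal(cm$eif_E, cfg$eif_E)
  expect_warning(apply_pnn_manipulation(cfg, "reduced_EI", 1.3), "factor")
  expect_warning(apply_pnn_manipulation(cfg, "increased_Cm", 0.8), "factor")
  expect_error(apply_pnn_manipulation(cfg, "reduced_EI", -1))
})

test_that("uncoupled Poisson-driven units reproduce the single-unit rate", {
  cfg1 <- attractor_config(n_side = 1, g_EI = 0, g_IE = 0, p_rate = 3000,
                           w_ext = 0.4, duration = 6, settle = 1,
                           r_EI_inner = 0.1, r_EI_outer = 0.2,
                           r_IE_outer = 0.1, v_init = "rest")
  single <- simulate_network(cfg1, seed = 11)
  cfgN <- attractor_config(n_side = 8, g_EI = 0, g_IE = 0, p_rate = 3000,
                           w_ext = 0.4, duration = 6, settle = 1,
                           v_init = "rest")
  sheet <- simulate_network(cfgN, seed = 12)
  rates_e <- sheet$rates[sheet$pop == "E"]
  expect_equal(mean(rates_e), single$rates[1], tolerance = 0.15)
  expect_true(all(sheet$rates[sheet$pop == "I"] == 0))
})

test_that("sheet pattern read-out destroys order under unit shuffling", {
  # synthetic hexagonal sheet wrapped as a sim_result
  L <- 50
  sheet <- hex_lattice_map(n = L, spacing_bins = 11, sigma_bins = 2,
                           center = c(6, 9))
  counts <- round(50 * sheet)
  mk_res <- function(cnt) {
    ids <- rep(seq_len(L * L), cnt)
    structure(list(
      spikes = data.frame(id = ids, t = rep(1.5, length(ids)),
                          pop = "E"),
      rates = c(cnt, rep(0, L * L)) / 1,
      pop = rep(c("E", "I"), each = L * L),
      config = attractor_config(n_side = L, duration = 2, settle = 1)),
      class = "sim_result")
  }
  g_ord <- sheet_pattern_gridness(mk_res(as.integer(counts)))
  expect_gt(g_ord$gridness$score, 0.8)
  set.seed(9)
  g_shuf <- sheet_pattern_gridness(mk_res(sample(as.integer(counts))))
  expect_true(is.nan(g_shuf$gridness$score) || g_shuf$gridness$score < 0.2)
  expect_error(sheet_pattern_gridness(mk_res(as.integer(counts)),
                                      window = c(1.5, 1.2)), "window")
})
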