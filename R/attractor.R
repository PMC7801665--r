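# Continuous attractor network of EIF neurons on a periodic sheet.
#
# Excitatory and inhibitory populations sit on equal square grids spanning
# [0, 2*pi)^2 (torus). Each E unit excites the I units inside a doughnut
# (annulus) around it; each I unit inhibits the E units inside a disc.
# There are no E-E or I-I connections. E units receive independent Poisson
# drive. Competitive inhibition settles the sheet into a hexagonal bump
# pattern; perineuronal-net removal is emulated by scaling the E->I synaptic
# strength down or the inhibitory membrane capacitance up.

#' Peak time and normalization of the beta (difference-of-exponentials)
#' synapse
#'
#' `K` is chosen so the conductance transient peaks exactly at the synaptic
#' weight: `t_peak = tau_d*tau_r/(tau_d - tau_r) * log(tau_d/tau_r)` and
#' `K = 1 / (exp(-t_peak/tau_d) - exp(-t_peak/tau_r))`.
#'
#' @param tau_rise,tau_decay Rise and decay time constants (ms),
#'   `tau_decay > tau_rise > 0`.
#' @return List: `t_peak` (ms), `K`.
#' @export
beta_synapse_norm <- function(tau_rise, tau_decay) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  t_peak <- tau_decay * tau_rise / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  K <- 1 / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
  list(t_peak = t_peak, K = K)
}

eif_params <- function(C_m, g_L = 10, E_L = -70, V_T = -50, Delta_T = 2,
                       V_reset = -70, V_peak = 0, t_ref = 2) {
  stopifnot(Delta_T > 0, V_peak > V_T, V_reset <= V_T)
  list(C_m = C_m, g_L = g_L, E_L = E_L, V_T = V_T, Delta_T = Delta_T,
       V_reset = V_reset, V_peak = V_peak, t_ref = t_ref)
}

syn_params <- function(tau_rise = 1, tau_decay = 5, E_rev = 0, delay = 1) {
  k <- beta_synapse_norm(tau_rise, tau_decay)
  list(tau_rise = tau_rise, tau_decay = tau_decay, E_rev = E_rev,
       K = k$K, delay = delay, t_peak = k$t_peak)
}

#' Attractor network configuration
#'
#' All tunable constants of the model in one place. Defaults are the
#' calibrated control condition at 50 x 50 units per population; the radii
#' are in sheet units (the sheet spans `[0, 2*pi)` per side).
#'
#' @param n_side Units per side of each square population grid.
#' @param reference_n_side Sheet density at which `g_EI`/`g_IE` are quoted;
#'   weights are scaled by `reference_n_side/n_side` (a calibrated choice:
#'   it keeps the pattern-forming regime intact when the sheet is refined,
#'   balancing the growth of the connection count against the shrinking
#'   quantal fluctuations that sustain the bump competition).
#' @param eif_E,eif_I EIF parameter lists (see source for fields; units pF,
#'   nS, mV, ms).
#' @param syn_EI,syn_IE,syn_ext Synapse parameter lists (beta kinetics).
#' @param g_EI,g_IE Peak synaptic conductances, nS.
#' @param r_EI_inner,r_EI_outer E-to-I annulus radii (sheet units).
#' @param r_IE_outer I-to-E disc radius (sheet units).
#' @param p_rate Poisson drive rate per E unit, Hz.
#' @param w_ext External synaptic weight, nS.
#' @param dt Integration step, ms.
#' @param duration Simulated time, s.
#' @param settle Settling window excluded from rate statistics, s.
#' @return An `attractor_config` list.
#' @export
attractor_config <- function(n_side = 50,
                             eif_E = eif_params(C_m = 200),
                             eif_I = eif_params(C_m = 100),
                             syn_EI = syn_params(E_rev = 0),
                             syn_IE = syn_params(tau_decay = 10,
                                                 E_rev = -80),
                             syn_ext = syn_params(E_rev = 0),
                             g_EI = 4.5, g_IE = 30,
                             r_EI_inner = 0.50, r_EI_outer = 0.90,
                             r_IE_outer = 0.25,
                             p_rate = 3000, w_ext = 0.4,
                             dt = 0.1, duration = 4, settle = 1,
                             v_init = c("uniform", "rest"),
                             anneal_frac = 1, anneal_time = 0,
                             i_const_E = 0, i_const_I = 0,
                             reference_n_side = 50) {
  stopifnot(r_EI_inner >= 0, r_EI_outer > r_EI_inner, r_IE_outer > 0,
            dt > 0, duration > settle)
  dens <- reference_n_side / n_side
  g_EI <- g_EI * dens
  g_IE <- g_IE * dens
  structure(list(n_side = n_side, eif_E = eif_E, eif_I = eif_I,
                 syn_EI = syn_EI, syn_IE = syn_IE, syn_ext = syn_ext,
                 g_EI = g_EI, g_IE = g_IE,
                 r_EI_inner = r_EI_inner, r_EI_outer = r_EI_outer,
                 r_IE_outer = r_IE_outer,
                 p_rate = p_rate, w_ext = w_ext,
                 dt = dt, duration = duration, settle = settle,
                 v_init = match.arg(v_init),
                 anneal_frac = anneal_frac, anneal_time = anneal_time,
                 i_const_E = i_const_E, i_const_I = i_const_I),
            class = "attractor_config")
}

# torus distances between two point sets on [0, 2*pi)^2
torus_dist <- function(xa, ya, xb, yb) {
  dx <- abs(outer(xa, xb, "-"))
  dx <- pmin(dx, 2 * pi - dx)
  dy <- abs(outer(ya, yb, "-"))
  dy <- pmin(dy, 2 * pi - dy)
  sqrt(dx^2 + dy^2)
}

sheet_positions <- function(n_side) {
  u <- (seq_len(n_side) - 1) * 2 * pi / n_side
  list(x = rep(u, times = n_side), y = rep(u, each = n_side))
}

#' Build the E->I annulus and I->E disc connectivity
#'
#' E unit at (x0, y0) connects to every I unit whose periodic (torus)
#' distance lies strictly inside `(r_EI_inner, r_EI_outer)`; each I unit
#' connects to every E unit strictly inside the disc of radius
#' `r_IE_outer`.
#'
#' @param config An [attractor_config()].
#' @return List with CSR index vectors (`ei_ptr`, `ei_idx`, `ie_ptr`,
#'   `ie_idx`; 0-based indices) and the sheet `positions`.
#' @export
build_connectivity <- function(config) {
  if (config$r_EI_outer <= config$r_EI_inner) stop("empty annulus")
  L <- config$n_side
  step <- 2 * pi / L
  # lattice translation invariance: the same target-offset stencil applies
  # to every unit, so build it once and shift it around the torus
  half <- -(L %/% 2):(L %/% 2 - 1L + L %% 2)
  dd <- sqrt(outer((half * step)^2, (half * step)^2, "+"))
  csr <- function(keep) {
    offs <- which(keep, arr.ind = TRUE)
    di <- half[offs[, 1]]
    dj <- half[offs[, 2]]
    src_i <- rep(0:(L - 1L), times = L)
    src_j <- rep(0:(L - 1L), each = L)
    tg <- matrix(0L, nrow = length(di), ncol = L * L)
    for (k in seq_along(di))
      tg[k, ] <- ((src_i + di[k]) %% L) + L * ((src_j + dj[k]) %% L)
    list(ptr = as.integer(0:(L * L)) * length(di), idx = as.integer(tg))
  }
  ei <- csr(dd > config$r_EI_inner & dd < config$r_EI_outer)
  # the disc includes the co-located unit (d = 0): the "0 < r" in the
  # connectivity rule is read as the polar-coordinate domain, matching the
  # center-inclusive circular masks of NEST-style topology connections
  ie <- csr(dd < config$r_IE_outer)
  list(ei_ptr = ei$ptr, ei_idx = ei$idx, ie_ptr = ie$ptr, ie_idx = ie$idx,
       positions = sheet_positions(L))
}

#' Simulate the attractor network
#'
#' Fixed-step forward-Euler integration of all EIF units, beta-function
#' conductances with peak normalization, delayed spike delivery, and
#' independent Poisson drive onto each E unit. Fully reproducible under
#' `seed`.
#'
#' @param config An [attractor_config()].
#' @param seed Optional RNG seed.
#' @param connectivity Optional precomputed [build_connectivity()] result
#'   (rebuilt when `NULL`).
#' @return A `sim_result` list: `spikes` (data frame `id`, `t` in s, `pop`),
#'   `rates` (Hz per neuron over the analysis window), `pop` (unit
#'   population labels), `config`.
#' @export
simulate_network <- function(config, seed = NULL, connectivity = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(connectivity)) connectivity <- build_connectivity(config)
  nE <- nI <- config$n_side^2
  pk <- function(p) c(p$C_m, p$g_L, p$E_L, p$V_T, p$Delta_T, p$V_reset,
                      p$V_peak, p$t_ref)
  sk <- function(s) c(s$tau_rise, s$tau_decay, s$E_rev, s$K, s$delay)
  res <- simulate_eif_cpp(nE, nI, pk(config$eif_E), pk(config$eif_I),
                          sk(config$syn_EI), sk(config$syn_IE),
                          sk(config$syn_ext),
                          connectivity$ei_ptr, connectivity$ei_idx,
                          config$g_EI,
                          connectivity$ie_ptr, connectivity$ie_idx,
                          config$g_IE,
                          config$p_rate, config$w_ext,
                          config$dt, config$duration * 1000,
                          config$settle * 1000,
                          identical(config$v_init, "uniform"),
                          config$anneal_frac, config$anneal_time * 1000,
                          config$i_const_E, config$i_const_I)
  window <- config$duration - config$settle
  pop <- rep(c("E", "I"), each = nE)
  spikes <- data.frame(id = res$id, t = res$t / 1000,
                       pop = pop[res$id])
  structure(list(spikes = spikes, rates = res$counts_window / window,
                 counts_total = res$counts, pop = pop, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  s <- population_rate_summary(x)
  cat(sprintf(paste0("sim_result: %d+%d units, %.1f s (%.1f s analyzed); ",
                     "median rate E %.2f Hz, I %.2f Hz (active units)\n"),
              sum(x$pop == "E"), sum(x$pop == "I"), x$config$duration,
              x$config$duration - x$config$settle,
              s$median_active["E"], s$median_active["I"]))
  invisible(x)
}

#' Emulate perineuronal-net removal in the model
#'
#' `reduced_EI` scales the E-to-I peak conductance by `factor` (< 1);
#' `increased_Cm` scales the inhibitory membrane capacitance by `factor`
#' (> 1). Everything else is untouched.
#'
#' @param config An [attractor_config()].
#' @param kind `"reduced_EI"` or `"increased_Cm"`.
#' @param factor Positive scale factor.
#' @return The modified `attractor_config`.
#' @export
apply_pnn_manipulation <- function(config,
                                   kind = c("reduced_EI", "increased_Cm"),
                                   factor) {
  kind <- match.arg(kind)
  stopifnot(factor > 0)
  if (kind == "reduced_EI") {
    if (factor > 1) warning("reduced_EI expects factor < 1")
    config$g_EI <- config$g_EI * factor
  } else {
    if (factor < 1) warning("increased_Cm expects factor > 1")
    config$eif_I$C_m <- config$eif_I$C_m * factor
  }
  config
}

#' Per-population firing-rate summary
#'
#' Mean rates per neuron over the analysis window (settling time excluded),
#' with medians over all units and over active units (at least one spike).
#'
#' @param result A `sim_result`.
#' @return List: `median_all`, `median_active`, `n_active`, `rates` (list
#'   of per-neuron rates by population).
#' @export
population_rate_summary <- function(result) {
  if (result$config$duration <= result$config$settle)
    stop("empty analysis window")
  by_pop <- split(result$rates, result$pop)
  med <- function(f) vapply(by_pop, function(r) {
    r <- f(r)
    if (length(r)) median(r) else 0
  }, numeric(1))
  list(median_all = med(identity),
       median_active = med(function(r) r[r > 0]),
       n_active = vapply(by_pop, function(r) sum(r > 0), numeric(1)),
       rates = by_pop)
}

#' Sheet activity pattern and its gridness
#'
#' Spike counts of the excitatory units in a time window arranged on the
#' 2-D sheet, with the wrap-aware (torus) autocorrelogram and the gridness
#' score of the resulting pattern.
#'
#' @param result A `sim_result`.
#' @param window Numeric length-2 time window in seconds (defaults to the
#'   analysis window).
#' @return List: `sheet` (matrix of rates, Hz), `acorr`, `gridness`
#'   (a `gridness_result`).
#' @export
sheet_pattern_gridness <- function(result, window = NULL) {
  cfg <- result$config
  if (is.null(window)) window <- c(cfg$settle, cfg$duration)
  if (window[2] <= window[1] || window[2] > cfg$duration + 1e-9)
    stop("invalid window")
  nE <- cfg$n_side^2
  sp <- result$spikes
  sel <- sp$id <= nE & sp$t >= window[1] & sp$t <= window[2]
  counts <- tabulate(sp$id[sel], nbins = nE)
  sheet <- matrix(counts / diff(window), cfg$n_side, cfg$n_side)
  acorr <- compute_autocorrelogram(sheet, wrap = TRUE)
  list(sheet = sheet, acorr = acorr, gridness = gridness_score(acorr))
}
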