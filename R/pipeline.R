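# Experiment I/O and the pipeline driver: synth (write a synthetic
# experiment), analyze (per-unit metrics and classification), simulate
# (attractor runs), report (group statistics). All outputs are plain text
# (CSV / JSON) with parameters and seeds recorded.

#' Write / read a recorded session as plain-text files
#'
#' Layout per session directory: `positions.csv` (t, x, y, hd),
#' `spikes_<unit>.csv` (t), optional `lfp.csv` (t, v), `ground_truth.json`.
#'
#' @param session Session list (`label`, `trajectory`, `spikes`, optional
#'   `lfp`, `ground_truth`).
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traj <- session$trajectory
  write.csv(data.frame(t = traj$t, x = traj$x, y = traj$y,
                       hd = if (is.null(traj$hd)) NA else traj$hd),
            file.path(dir, "positions.csv"), row.names = FALSE)
  for (spk in session$spikes)
    write.csv(data.frame(t = spk$times),
              file.path(dir, sprintf("spikes_%s.csv", spk$unit_id)),
              row.names = FALSE)
  if (!is.null(session$lfp))
    write.csv(data.frame(t = lfp_times(session$lfp),
                         v = session$lfp$samples),
              file.path(dir, "lfp.csv"), row.names = FALSE)
  if (!is.null(session$ground_truth))
    jsonlite::write_json(
      list(label = session$label,
           units = lapply(session$ground_truth, unclass)),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @param fs,arena_size Trajectory metadata used when reading back.
#' @export
read_session <- function(dir, fs = 50, arena_size = 1) {
  pf <- file.path(dir, "positions.csv")
  if (!file.exists(pf)) stop("missing positions file: ", pf)
  pos <- read.csv(pf)
  traj <- trajectory(pos$t, pos$x, pos$y,
                     if (all(is.na(pos$hd))) NULL else pos$hd,
                     fs = fs, arena_size = arena_size)
  t0 <- pos$t[1]
  t1 <- pos$t[nrow(pos)]
  spike_files <- sort(list.files(dir, "^spikes_.*\\.csv$", full.names = TRUE))
  spikes <- lapply(spike_files, function(f) {
    id <- sub("^spikes_(.*)\\.csv$", "\\1", basename(f))
    tt <- read.csv(f)$t
    spike_train(pmin(pmax(tt, t0), t1), t0, t1, id)
  })
  lfp <- NULL
  lf <- file.path(dir, "lfp.csv")
  if (file.exists(lf)) {
    lv <- read.csv(lf)
    lfp <- lfp_signal(lv$v, fs = round(1 / median(diff(lv$t))),
                      t_start = lv$t[1])
  }
  gt <- NULL
  gf <- file.path(dir, "ground_truth.json")
  label <- basename(dir)
  if (file.exists(gf)) {
    meta <- jsonlite::read_json(gf, simplifyVector = FALSE)
    label <- meta$label
    gt <- lapply(meta$units, function(u) {
      u$phase <- as.numeric(unlist(u$phase))
      do.call(ground_truth, u[setdiff(names(u), "t_peak")])
    })
  }
  list(label = label, trajectory = traj, spikes = spikes, lfp = lfp,
       ground_truth = gt)
}

# default pipeline configuration; user config entries override
default_pipeline_config <- function() {
  list(
    n_grid = 4, n_hd = 1, n_speed = 1, n_noise = 1,
    duration = 600, fs = 50, arena_size = 1, mean_speed = 0.15,
    spacing = 0.4, peak_rate = 15, baseline_rate = 0.5,
    drift_sigma = 0, drift_mode = "common",
    lfp = TRUE, lfp_f0 = 8, lfp_beta_f = 2, lfp_beta_a = 1,
    bin_size = 0.02, sigma = 0.03,
    shuffle_n = 1000, shuffle_shift = 30,
    sim_n_side = 50, sim_duration = 3, sim_settle = 1,
    reduced_EI_factor = 0.7, increased_Cm_factor = 1.25
  )
}

make_population <- function(cfg, seed_phase = TRUE) {
  pop <- list()
  for (i in seq_len(cfg$n_grid))
    pop <- c(pop, list(ground_truth("grid", spacing = cfg$spacing,
                                    orientation = 0.2,
                                    phase = runif(2, 0, cfg$spacing),
                                    peak_rate = cfg$peak_rate,
                                    baseline_rate = cfg$baseline_rate)))
  for (i in seq_len(cfg$n_hd))
    pop <- c(pop, list(ground_truth("hd", hd_mu = runif(1, 0, 2 * pi),
                                    hd_kappa = 3,
                                    peak_rate = cfg$peak_rate)))
  for (i in seq_len(cfg$n_speed))
    pop <- c(pop, list(ground_truth("speed", baseline_rate = 1,
                                    peak_rate = 40, speed_slope = 20)))
  for (i in seq_len(cfg$n_noise))
    pop <- c(pop, list(ground_truth("noise", peak_rate = 3)))
  pop
}

analyze_unit <- function(spk, traj, cfg) {
  map <- compute_rate_map(spk, traj, cfg$bin_size, cfg$sigma)
  acorr <- compute_autocorrelogram(map)
  gr <- gridness_score(acorr)
  fm <- identify_fields(map, acorr)
  rates <- in_out_field_rates(spk, traj, fm, cfg$bin_size)
  spec <- suppressWarnings(spatial_specificity(rates))
  info <- spatial_information(map)
  cvw <- cv_isi(spk, method = "whole_session")
  br <- bursting_ratio(spk)
  ss <- speed_score(spk, traj)
  hd <- if (is.null(traj$hd)) list(vector_length = NaN) else
    head_direction_tuning(spk, traj)
  data.frame(unit_id = spk$unit_id, n_spikes = length(spk$times),
             mean_rate = length(spk$times) / (spk$t_stop - spk$t_start),
             gridness = gr$score, spacing = gr$spacing,
             n_fields = length(fm$fields),
             fr_in = rates$fr_in, fr_out = rates$fr_out,
             specificity = spec, spatial_information = info,
             cv = cvw$cv, bursting_ratio = br$ratio,
             speed_score = ss, hd_vector_length = hd$vector_length,
             stability = suppressWarnings(
               as.numeric(within_trial_stability(spk, traj, cfg$bin_size,
                                                 cfg$sigma))))
}

#' Run a pipeline command
#'
#' Commands: `"synth"` writes a synthetic multi-session experiment under
#' `out/experiment`; `"analyze"` computes per-unit metrics for every session
#' found there (tidy CSV + JSON summary); `"simulate"` runs paired
#' control/manipulated attractor simulations; `"report"` computes group
#' statistics from the analyze output. Each command records its parameters
#' and seed in a JSON log.
#'
#' @param command One of `"synth"`, `"analyze"`, `"simulate"`, `"report"`.
#' @param config Named list overriding the default configuration, or a path
#'   to a JSON file with such a list.
#' @param out Output directory.
#' @param seed RNG seed (recorded in outputs).
#' @return The primary result of the command, invisibly.
#' @export
run_pipeline <- function(command = c("synth", "analyze", "simulate",
                                     "report"),
                         config = list(), out = "results", seed = 1) {
  command <- match.arg(command)
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing config file: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  log_entry <- list(command = command, seed = seed, config = cfg,
                    time = format(Sys.time()))
  jsonlite::write_json(log_entry,
                       file.path(out, sprintf("log_%s.json", command)),
                       auto_unbox = TRUE, digits = NA)

  if (command == "synth") {
    pop <- make_population(cfg)
    proto <- session_protocol(durations = cfg$duration,
                              drift_sigma = cfg$drift_sigma,
                              drift_mode = cfg$drift_mode)
    bundle <- generate_session_protocol(
      proto, pop, traj_args = list(arena_size = cfg$arena_size, fs = cfg$fs,
                                   mean_speed = cfg$mean_speed))
    for (s in bundle$sessions) {
      if (isTRUE(cfg$lfp))
        s$lfp <- generate_lfp(s$trajectory, f0 = cfg$lfp_f0,
                              beta_f = cfg$lfp_beta_f,
                              beta_a = cfg$lfp_beta_a)
      write_session(s, file.path(out, "experiment", s$label))
    }
    jsonlite::write_json(unclass(proto),
                         file.path(out, "experiment", "protocol.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(bundle))
  }

  if (command == "analyze") {
    exp_dir <- file.path(out, "experiment")
    if (!dir.exists(exp_dir)) stop("missing experiment directory: ", exp_dir)
    sdirs <- list.dirs(exp_dir, recursive = FALSE)
    rows <- list()
    for (sd in sdirs) {
      sess <- read_session(sd, fs = cfg$fs, arena_size = cfg$arena_size)
      for (spk in sess$spikes) {
        row <- analyze_unit(spk, sess$trajectory, cfg)
        row$session <- sess$label
        rows[[length(rows) + 1]] <- row
      }
      if (!is.null(sess$lfp)) {
        lfp <- preprocess_lfp(sess$lfp, sess$lfp$fs)
        sc <- power_frequency_scores(lfp, sess$trajectory)
        jsonlite::write_json(sc, file.path(sd, "lfp_scores.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
    tab <- do.call(rbind, rows)
    write.csv(tab, file.path(out, "unit_metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(n_units = nrow(tab), seed = seed,
           median_gridness = median(tab$gridness, na.rm = TRUE)),
      file.path(out, "analyze_summary.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(tab))
  }

  if (command == "simulate") {
    ctrl <- attractor_config(n_side = cfg$sim_n_side,
                             duration = cfg$sim_duration,
                             settle = cfg$sim_settle)
    conn <- build_connectivity(ctrl)
    runs <- list(
      control = ctrl,
      reduced_EI = apply_pnn_manipulation(ctrl, "reduced_EI",
                                          cfg$reduced_EI_factor),
      increased_Cm = apply_pnn_manipulation(ctrl, "increased_Cm",
                                            cfg$increased_Cm_factor))
    rows <- list()
    for (nm in names(runs)) {
      res <- simulate_network(runs[[nm]], seed = seed, connectivity = conn)
      s <- population_rate_summary(res)
      g <- sheet_pattern_gridness(res)
      rows[[nm]] <- data.frame(
        condition = nm, seed = seed,
        median_E_all = s$median_all["E"], median_I_all = s$median_all["I"],
        median_E_active = s$median_active["E"],
        median_I_active = s$median_active["I"],
        sheet_gridness = g$gridness$score)
      write.csv(g$sheet, file.path(out, sprintf("sheet_%s.csv", nm)),
                row.names = FALSE)
    }
    tab <- do.call(rbind, rows)
    write.csv(tab, file.path(out, "simulation_summary.csv"),
              row.names = FALSE)
    return(invisible(tab))
  }

  # report
  mf <- file.path(out, "unit_metrics.csv")
  if (!file.exists(mf)) stop("missing metrics file (run analyze first): ", mf)
  tab <- read.csv(mf)
  metrics <- c("gridness", "specificity", "spatial_information", "cv",
               "bursting_ratio", "speed_score", "stability")
  fam <- tab[grepl("^Familiar", tab$session), ]
  nov <- tab[grepl("^Novel", tab$session), ]
  rows <- lapply(metrics, function(m) {
    a <- fam[[m]][is.finite(fam[[m]])]
    b <- nov[[m]][is.finite(nov[[m]])]
    if (length(a) && length(b)) {
      mw <- mann_whitney_u(a, b)
      data.frame(metric = m, median_familiar = median(a),
                 median_novel = median(b), U = mw$U, p = mw$p)
    }
  })
  rep_tab <- do.call(rbind, rows)
  write.csv(rep_tab, file.path(out, "group_report.csv"), row.names = FALSE)
  invisible(rep_tab)
}
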