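#!/usr/bin/env Rscript
# Generates the synthetic multi-session experiment the rest of the analysis
# operates on: a Familiar I -> Novel I-III -> Familiar II protocol with grid,
# head-direction, speed and untuned units, plus a speed-coupled theta LFP.
# Everything is written as plain-text CSV/JSON under results/experiment/.

suppressPackageStartupMessages(library(gridnet))

seed <- 20260923
cfg <- list(n_grid = 4, n_hd = 1, n_speed = 1, n_noise = 1,
            duration = 600, lfp = TRUE)
bundle <- run_pipeline("synth", cfg, out = "results", seed = seed)

n_units <- length(bundle$population)
message(sprintf("wrote %d sessions x %d units under results/experiment/",
                length(bundle$sessions), n_units))
message("unit types: ",
        paste(vapply(bundle$population, `[[`, character(1), "cell_type"),
              collapse = ", "))
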