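#!/usr/bin/env Rscript
# Stage 1: simulate the core experiments and persist their track
# tables. Everything downstream (02-05) reads these files, so the
# whole analysis is reproducible from `Rscript analysis/01_simulate.R`
# onward. One fully loaded 100 uM run, a partially loaded run, a wide
# (1.4 um) device, the 500 uM step/ramp fate experiments, and the
# seven-concentration calibration panel.

suppressMessages({library(trenchshield); library(data.table)})
seed <- 1L
dir.create("results/tracks", recursive = TRUE, showWarnings = FALSE)

say <- function(...) message(sprintf(...))

runs <- list(
  full_100 = list(cfg = sim_config(n_trenches = 200, seed = seed),
                  sch = treatment_schedule(0, 300, 100,
                                           t_min = -135, t_max = 300)),
  partial_100 = local({
    sc <- scenario("partial_loading", n_trenches = 250, seed = seed + 1L)
    list(cfg = sc$config, sch = treatment_schedule(0, 135, 100,
                                                   t_min = -30,
                                                   t_max = 135))
  }),
  wide_100 = list(cfg = sim_config(n_trenches = 200, seed = seed + 2L,
                                   trench_width = 1.4),
                  sch = treatment_schedule(0, 135, 100,
                                           t_min = -45, t_max = 135)),
  step_500 = local({
    sc <- scenario("step_500", n_trenches = 200, seed = seed + 3L)
    list(cfg = sc$config, sch = sc$schedule)
  }),
  ramp_500 = local({
    sc <- scenario("ramp_500", n_trenches = 200, seed = seed + 3L)
    list(cfg = sc$config, sch = sc$schedule)
  })
)

for (nm in names(runs)) {
  tt <- simulate_trenches(runs[[nm]]$cfg, runs[[nm]]$sch)
  occ <- tt[, .N, by = .(trench_id, frame)]
  say("%-12s %6d rows, occupancy %.2f +/- %.2f, %d deaths, %d exits",
      nm, nrow(tt), mean(occ$N), sd(occ$N),
      attr(tt, "n_dead"), attr(tt, "n_exited"))
  write_tracks(tt, sprintf("results/tracks/%s.csv", nm))
}

# calibration panel: one run per known concentration
cp <- scenario("calibration_panel", n_trenches = 40, seed = seed + 4L)
for (i in seq_along(cp$panel)) {
  cfg <- sim_config(n_trenches = 40, seed = seed * 100L + 40L + i)
  tt <- simulate_trenches(cfg, treatment_schedule(0, 300, cp$panel[i],
                                                  t_min = -30,
                                                  t_max = 300))
  write_tracks(tt, sprintf("results/tracks/panel_%g.csv", cp$panel[i]))
}
say("calibration panel written (%d concentrations: %s uM)",
    length(cp$panel), paste(cp$panel, collapse = ", "))
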