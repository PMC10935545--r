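cfg0 <- sim_config(seed = 1)

test_that("h2o2_profile matches the product-of-attenuations oracle", {
  # no barriers: first cell sees the full concentration
  one <- new_cell_state(2.6, cfg0)
  expect_equal(h2o2_profile(one, 100, cfg0)[1], 100)
  expect_identical(h2o2_profile(one[0, ], 100, cfg0), numeric(0))
  expect_error(h2o2_profile(one, -1, cfg0), "non-negative")

  # one barrier with f = 0.323 leaves 67.7 behind it: solve
  # sigma * S * scav = -log(1 - 0.323) at the cell's effective
  # scavenging level (induced part plus saturable basal part)
  cfg <- cfg0
  cells <- new_cell_state(c(2.6, 2.6), cfg, enzyme = 1)
  S <- 2 * pi * cells$radius[1] * 2.6
  basal <- cfg$enzyme_induction$basal
  scav <- (1 - basal) + basal * basal_saturation_factor(100, cfg)
  cfg$attenuation_scale <- -log(1 - 0.323) / (S * scav)
  prof <- h2o2_profile(cells, 100, cfg)
  expect_equal(prof[2], 67.7, tolerance = 1e-10)

  # six identical barriers: innermost sees 100 * 0.677^6 ~ 9.6
  cells6 <- new_cell_state(rep(2.6, 7), cfg, enzyme = 1)
  prof6 <- h2o2_profile(cells6, 100, cfg)
  oracle <- 100 * cumprod(c(1, rep(1 - 0.323, 6)))
  expect_equal(prof6, oracle, tolerance = 1e-10)
  expect_equal(prof6[7], 9.63, tolerance = 1e-3)

  # inert and dead cells do not attenuate
  cells$genotype <- c("inert", "WT")
  expect_equal(h2o2_profile(cells, 100, cfg)[2], 100)
  cells$genotype <- "WT"; cells$alive <- c(FALSE, TRUE)
  expect_equal(h2o2_profile(cells, 100, cfg)[2], 100)
})

test_that("wider trenches reduce the effective attenuation", {
  wide <- sim_config(trench_width = 1.4, mean_radius = 0.5)
  narrow <- sim_config(trench_width = 1.2, mean_radius = 0.5)
  cells <- new_cell_state(c(2.6, 2.6), narrow, enzyme = 1)
  expect_gt(h2o2_profile(cells, 100, wide)[2],
            h2o2_profile(cells, 100, narrow)[2])
  expect_equal(effective_sigma(wide) / effective_sigma(narrow),
               (1.2 / 1.4)^2)
})

test_that("step_growth follows saturating inhibition kinetics", {
  cfg <- sim_config(growth_inhibition = list(hill_k = 25, m = 2))
  # zero peroxide: pure exponential elongation
  c1 <- new_cell_state(2, cfg)
  c2 <- step_growth(c1, 0, dt = 1, cfg)
  expect_equal(c2$length, 2 * exp(cfg$base_elongation_rate))
  # Hill midpoint: growth factor one half
  expect_equal(growth_factor(25, cfg), 0.5)
  # closed-form trajectory at frozen internal concentration
  cfg_frozen <- cfg
  # no exchange or scavenging: c_int stays exactly where it is
  cfg_frozen$h2o2_transport <- list(permeation = 0, scavenge_max = 0)
  cells <- new_cell_state(2, cfg_frozen, c_int = 25)
  L <- cells$length
  for (i in 1:45) cells <- step_growth(cells, 0, 1, cfg_frozen)
  expect_equal(cells$length,
               L * exp(cfg$base_elongation_rate * 0.5 * 45),
               tolerance = 1e-9)
  # dead and inert cells do not elongate
  cells <- new_cell_state(c(2, 2), cfg, genotype = c("WT", "inert"),
                          alive = c(FALSE, TRUE))
  out <- step_growth(cells, 0, 3, cfg)
  expect_equal(out$length, c(2, 2))
})

test_that("step_response has the basal fixed point and genotype rules", {
  cfg <- sim_config(measurement_noise_sd = 0)
  # reporter intensity settles at basal production / dilution
  cells <- new_cell_state(2, cfg)
  target <- cfg$reporter_kinetics$basal_rate / cfg$base_elongation_rate
  expect_equal(cells$reporter / (2 * cells$radius * cells$length),
               target, tolerance = 1e-6)
  for (i in 1:200) {
    cells <- step_growth(cells, 0, 0.25, cfg)
    cells <- step_response(cells, 0, 0.25, cfg)
    if (cells$length >= cells$div_length) {  # keep it one cell
      cells$length <- cells$length / 2
      cells$reporter <- cells$reporter / 2
      cells$marker <- cells$marker / 2
    }
  }
  expect_equal(cells$reporter / (2 * cells$radius * cells$length),
               target, tolerance = 0.05)
  # delta_oxyR never induces: enzyme pinned at its residual level
  mut <- new_cell_state(2, cfg, genotype = "delta_oxyR")
  e0 <- mut$enzyme
  for (i in 1:50) mut <- step_response(mut, 100, 0.25, cfg,
                                       c_delayed = 100)
  expect_equal(mut$enzyme, e0)
  # negative feedback: higher enzyme lowers c_int at fixed c_local
  hiE <- new_cell_state(2, cfg, enzyme = 1.0)
  loE <- new_cell_state(2, cfg, enzyme = cfg$enzyme_induction$basal)
  for (i in 1:100) {
    hiE <- step_growth(hiE, 50, 0.25, cfg)
    loE <- step_growth(loE, 50, 0.25, cfg)
  }
  expect_lt(hiE$c_int, loE$c_int)
})

test_that("the reporter rise begins one delay after a step input", {
  # single isolated cell, engine path, saturating step at t = 0
  cfg <- sim_config(n_trenches = 1, loading_mean_cells = 1,
                    loading_sd = 0, measurement_noise_sd = 0,
                    growth_noise_sd = 0, seed = 5,
                    frame_interval = 1, substep = 0.25,
                    # disable growth inhibition so the intensity rise
                    # reflects delayed production, not reduced dilution
                    growth_inhibition = list(hill_k = 1e6, m = 2),
                    division_block_conc = Inf,
                    enzyme_induction = list(delay = 6, max_rate = 0.06,
                                            hill_k = 0.05, hill_n = 2,
                                            basal = 0.4,
                                            basal_uninduced = 0.02))
  tt <- simulate_trenches(cfg, treatment_schedule(0, 30, 100,
                                                  t_min = -10,
                                                  t_max = 30))
  m <- tt[tt$cell_index == 0, ]
  base <- mean(m$reporter[m$time < 0])
  rise <- m$time[m$time > 0][which(
    m$reporter[m$time > 0] > base * 1.05)[1]]
  # onset within one frame after the configured dead time
  expect_gte(rise, 6 - 1)
  expect_lte(rise, 6 + 2)
})

test_that("divide_and_push conserves content and stacks correctly", {
  cfg <- sim_config(partition_noise_sd = 0, division_cv = 0,
                    cell_gap = 0.5, cell_gap_sd = 0)
  # below threshold: nothing happens
  cells <- new_cell_state(c(2.0, 2.2), cfg)
  out <- divide_and_push(cells, cfg)
  expect_equal(nrow(out$cells), 2)
  expect_equal(out$cells$length, c(2.0, 2.2))
  # noise-free division conserves reporter, marker exactly
  cells$length[1] <- cells$div_length[1] + 0.01
  r0 <- cells$reporter[1]; m0 <- cells$marker[1]
  out <- divide_and_push(cells, cfg)
  expect_equal(nrow(out$cells), 3)
  expect_equal(sum(out$cells$reporter[1:2]), r0)
  expect_equal(sum(out$cells$marker[1:2]), m0)
  expect_equal(out$cells$parent_id[1:2], rep(cells$cell_id[1], 2))
  # positions restacked from the closed end with the configured gap
  expect_equal(out$cells$position,
               cumsum(c(0, out$cells$length[-3] + 0.5)))
  # cells pushed past the trench mouth exit at the open end
  long <- new_cell_state(rep(4, 8), cfg)
  out2 <- divide_and_push(long, cfg)
  expect_gt(nrow(out2$exited), 0)
  expect_true(all(out2$cells$position <= cfg$trench_length))
  # the cells that remain are the ones closest to the closed end
  expect_identical(out2$cells$cell_id,
                   long$cell_id[seq_len(nrow(out2$cells))])
})

test_that("division is blocked above the checkpoint concentration", {
  cfg <- sim_config(division_block_conc = 4)
  cells <- new_cell_state(2, cfg, c_int = 10)
  cells$length <- cells$div_length + 1
  out <- divide_and_push(cells, cfg)
  expect_equal(nrow(out$cells), 1)   # filamenting, not dividing
  cells$c_int <- 0
  out2 <- divide_and_push(cells, cfg)
  expect_equal(nrow(out2$cells), 2)
})

test_that("fate and mismatch follow the threshold and Poisson rules", {
  cfg <- sim_config(mismatch_rates = list(lambda0 = 0, lambda1 = 0))
  cells <- new_cell_state(2, cfg, c_int = 500)
  set.seed(1)
  for (i in 1:100) {
    st <- step_fate_and_mismatch(cells, 1, cfg)
    cells <- st$cells
    expect_equal(st$foci, 0L)   # lambda = 0 emits nothing, ever
  }
  expect_false(cells$alive)     # sustained lethal exposure kills
  expect_equal(cells$enzyme, 0)

  # priming: induced enzyme raises the tolerated concentration
  dr <- sim_config()$death_rule
  c_mid <- dr$lethal_conc + dr$priming_coef * 0.5
  naive <- new_cell_state(2, sim_config(), enzyme = 0.05, c_int = c_mid)
  primed <- new_cell_state(2, sim_config(), enzyme = 0.95, c_int = c_mid)
  for (i in 1:30) {
    naive <- step_fate_and_mismatch(naive, 1, sim_config())$cells
    primed <- step_fate_and_mismatch(primed, 1, sim_config())$cells
  }
  expect_false(naive$alive)
  expect_true(primed$alive)

  # Poisson mean: constant rate lambda over T across N cells
  lam <- 0.05
  cfgp <- sim_config(mismatch_rates = list(lambda0 = lam, lambda1 = 0))
  many <- new_cell_state(rep(2, 500), cfgp)
  set.seed(42)
  total <- 0
  for (i in 1:30) total <- total +
    sum(step_fate_and_mismatch(many, 1, cfgp)$foci)
  expected <- lam * 30 * 500
  expect_lt(abs(total - expected), 3 * sqrt(expected))
})

test_that("simulation is deterministic and fills trenches as loaded", {
  cfg <- sim_config(n_trenches = 8, seed = 99)
  sch <- treatment_schedule(0, 30, 100, t_min = -30, t_max = 30)
  a <- simulate_trenches(cfg, sch)
  b <- simulate_trenches(cfg, sch)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # untreated run: no induction above basal, steady occupancy
  cfg2 <- sim_config(n_trenches = 20, seed = 7)
  quiet <- simulate_trenches(cfg2, treatment_schedule(0, 1, 0,
                                                      t_min = 0,
                                                      t_max = 240))
  occ <- tapply(quiet$cell_id, list(quiet$trench_id, quiet$frame),
                length)
  expect_gt(mean(occ[, ncol(occ)]), 5)
  base <- mean(quiet$reporter[quiet$time < 60])
  late <- mean(quiet$reporter[quiet$time > 180])
  expect_lt(abs(late - base) / base, 0.1)
})
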