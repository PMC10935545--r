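# Vectorised simulation engine: all trenches advance together as flat
# state vectors kept sorted by (trench, position index from closed end).
# The exported per-cell stepping functions in simulate.R implement the
# same update rules on small data frames and serve as the reference
# implementation in tests.

init_state <- function(config) {
  cap <- floor((config$trench_length + config$cell_gap) /
                 (config$mean_birth_length + config$cell_gap))
  n0 <- pmin(pmax(round(stats::rnorm(config$n_trenches,
                                     config$loading_mean_cells,
                                     config$loading_sd)), 1L), cap)
  n <- sum(n0)
  trench <- rep(seq_len(config$n_trenches), times = n0)
  geno <- sample.int(3L, n, replace = TRUE, prob = config$genotype_mix)
  lb <- config$mean_birth_length *
    exp(stats::rnorm(n, 0, config$division_cv))
  phase <- stats::runif(n)
  L <- lb * 2^phase
  beta <- pmax(stats::rnorm(n, config$base_elongation_rate,
                            config$base_elongation_rate *
                              config$elongation_cv),
               config$base_elongation_rate * 0.2)
  beta[geno == 3L] <- 0
  radius <- pmin(pmax(stats::rnorm(n, config$mean_radius,
                                   config$mean_radius * config$radius_cv),
                      0.25), config$trench_width / 2)
  E <- rep(config$enzyme_induction$basal, n)
  E[geno == 2L] <- config$enzyme_induction$basal_uninduced
  E[geno == 3L] <- 0
  rk <- config$reporter_kinetics
  base_beta <- ifelse(beta > 0, beta, config$base_elongation_rate)
  area0 <- 2 * radius * L
  Ramt <- ifelse(geno == 1L, rk$basal_rate * area0 / base_beta, 0)
  Mamt <- config$marker_rate * area0 / base_beta
  ndelay <- max(1L, as.integer(round(config$enzyme_induction$delay /
                                       config$substep)))
  gap_by_trench <- pmax(stats::rnorm(config$n_trenches, config$cell_gap,
                                     config$cell_gap_sd), 0.05)
  st <- list(
    n = n, trench = trench, geno = geno, gap_by_trench = gap_by_trench,
    cell_id = seq_len(n), lineage_id = seq_len(n),
    parent_id = rep(NA_integer_, n),
    L = L, birth_L = lb,
    div_L = 2 * lb * exp(stats::rnorm(n, 0, config$division_cv) -
                           config$division_cv^2 / 2),
    radius = radius, beta = beta, eta = numeric(n),
    E = E, Ramt = Ramt, Mamt = Mamt,
    c_int = numeric(n), clock = numeric(n),
    alive = rep(TRUE, n), foci_accum = numeric(n),
    position = numeric(n),
    Chist = matrix(0, n, ndelay), ptr = 1L,
    next_id = n + 1L, n_exited = 0L, n_dead = 0L
  )
  restack(st, config)
}

# recompute stacked positions from the closed end; drop cells whose
# proximal edge passed the trench mouth
restack <- function(st, config) {
  if (st$n == 0L) return(st)
  occ <- st$L + st$gap_by_trench[st$trench]
  starts <- grouped_cumsum(occ, st$trench) - occ
  keep <- starts <= config$trench_length
  st$position <- starts
  if (!all(keep)) {
    st$n_exited <- st$n_exited + sum(!keep)
    st <- subset_state(st, keep)
  }
  st
}

subset_state <- function(st, keep) {
  vec <- c("trench", "geno", "cell_id", "lineage_id", "parent_id", "L",
           "birth_L", "div_L", "radius", "beta", "eta", "E", "Ramt",
           "Mamt", "c_int", "clock", "alive", "foci_accum", "position")
  for (f in vec) st[[f]] <- st[[f]][keep]
  st$Chist <- st$Chist[keep, , drop = FALSE]
  st$n <- length(st$trench)
  st
}

engine_substep <- function(st, c0, dt, config) {
  if (st$n == 0L) return(st)
  # effective scavenging: induced component plus saturable basal part
  bsat <- basal_saturation_factor(c0, config)
  basal <- config$enzyme_induction$basal
  wt <- st$geno == 1L & st$alive
  scav <- ifelse(wt, pmax(st$E - basal, 0) + basal * bsat,
                 ifelse(st$alive & st$geno != 3L, st$E * bsat, 0))
  # shielding: log attenuation summed over cells nearer the open end
  logatt <- -effective_sigma(config) * 2 * pi * st$radius * st$L * scav
  s <- grouped_total(logatt, st$trench) - grouped_cumsum(logatt, st$trench)
  c_local <- c0 * exp(s)
  st$c_int <- update_c_int(st$c_int, c_local, scav, dt, config)
  # delayed sensing through a ring buffer
  c_del <- st$Chist[, st$ptr]
  st$Chist[, st$ptr] <- st$c_int
  st$ptr <- st$ptr %% ncol(st$Chist) + 1L
  ei <- config$enzyme_induction
  rk <- config$reporter_kinetics
  he <- hill(c_del, ei$hill_k, ei$hill_n)
  hr <- hill(c_del, rk$hill_k, rk$hill_n)
  g <- growth_factor(st$c_int, config)
  gtl <- translation_factor(st$c_int, config)
  growing <- st$alive & st$geno != 3L
  beta_inst <- pmax(st$beta * g + st$eta, 0) * growing
  st$L <- st$L * exp(beta_inst * dt)
  induc <- st$geno == 1L & st$alive
  # basal OxyR drive keeps unstressed wild-type enzyme at ei$basal
  h0 <- config$base_elongation_rate * ei$basal /
    (ei$max_rate * (1 - ei$basal))
  dE <- dt * (ei$max_rate * gtl * (he + h0) * (1 - st$E) -
                beta_inst * st$E)
  st$E <- ifelse(induc, pmin(pmax(st$E + dE, 0), 1), st$E)
  # production scales with cell area, so mean intensity (amount per
  # area) is independent of cell geometry at steady state
  area <- 2 * st$radius * st$L
  st$Ramt <- st$Ramt + ifelse(induc,
    dt * (rk$basal_rate + rk$induced_rate * hr) * gtl * area, 0)
  st$Mamt <- st$Mamt + ifelse(growing,
    dt * config$marker_rate * gtl * area, 0)
  dr <- config$death_rule
  over <- st$alive & st$c_int > dr$lethal_conc + dr$priming_coef * st$E
  st$clock <- ifelse(over, st$clock + dt, 0)
  newdead <- st$alive & st$clock >= dr$sustained_min
  if (any(newdead)) {
    st$alive[newdead] <- FALSE
    st$E[newdead] <- 0
    st$n_dead <- st$n_dead + sum(newdead)
  }
  mm <- config$mismatch_rates
  st$foci_accum <- st$foci_accum +
    dt * (mm$lambda0 + mm$lambda1 * pmax(st$c_int, 0) * (1 - st$E)) *
      st$alive
  st
}

expand_state <- function(st, map) {
  vec <- c("trench", "geno", "cell_id", "lineage_id", "parent_id", "L",
           "birth_L", "div_L", "radius", "beta", "eta", "E", "Ramt",
           "Mamt", "c_int", "clock", "alive", "foci_accum", "position")
  for (f in vec) st[[f]] <- st[[f]][map]
  st$Chist <- st$Chist[map, , drop = FALSE]
  st$n <- length(map)
  st
}

engine_frame_divide <- function(st, config) {
  div <- st$alive & st$geno != 3L & st$L >= st$div_L &
    st$c_int < config$division_block_conc
  if (any(div)) {
    map <- rep(seq_len(st$n), ifelse(div, 2L, 1L))
    d1 <- which(!duplicated(map) & div[map])
    d2 <- d1 + 1L
    nd <- length(d1)
    parent_ids <- st$cell_id[div]
    halfL <- st$L[div] / 2
    # sizer target: anchored to the configured birth size with mild
    # parental memory, so neither frame-sampling overshoot nor the
    # lognormal noise can drift or diffuse across generations
    halfT <- config$mean_birth_length^0.7 * (st$div_L[div] / 2)^0.3
    parentR <- st$Ramt[div]; parentM <- st$Mamt[div]
    parentE <- st$E[div]; parentB <- st$beta[div]
    parentRad <- st$radius[div]; parentF <- st$foci_accum[div]
    st <- expand_state(st, map)
    cv <- config$division_cv
    st$L[d1] <- st$L[d2] <- halfL
    st$birth_L[d1] <- st$birth_L[d2] <- halfT
    st$div_L[d1] <- 2 * halfT * exp(stats::rnorm(nd, 0, cv) - cv^2 / 2)
    st$div_L[d2] <- 2 * halfT * exp(stats::rnorm(nd, 0, cv) - cv^2 / 2)
    part <- function() pmin(pmax(
      0.5 + stats::rnorm(nd, 0, config$partition_noise_sd), 0.3), 0.7)
    pR <- part(); pM <- part(); pE <- part()
    st$Ramt[d1] <- pR * parentR; st$Ramt[d2] <- (1 - pR) * parentR
    st$Mamt[d1] <- pM * parentM; st$Mamt[d2] <- (1 - pM) * parentM
    st$E[d1] <- pmin(2 * pE * parentE, 1)
    st$E[d2] <- pmin(2 * (1 - pE) * parentE, 1)
    base <- config$base_elongation_rate
    sdb <- base * config$elongation_cv *
      sqrt(1 - config$elongation_inherit^2)
    for (dd in list(d1, d2)) {
      st$beta[dd] <- pmax(base + config$elongation_inherit *
        (parentB - base) + stats::rnorm(nd, 0, sdb), base * 0.2)
      st$radius[dd] <- pmin(pmax(config$mean_radius +
        0.8 * (parentRad - config$mean_radius) +
        stats::rnorm(nd, 0,
                     config$radius_cv * config$mean_radius * 0.6),
        0.25), config$trench_width / 2)
    }
    st$parent_id[d1] <- st$parent_id[d2] <- parent_ids
    st$cell_id[d1] <- st$next_id + seq.int(0L, by = 2L, length.out = nd)
    st$cell_id[d2] <- st$next_id + seq.int(1L, by = 2L, length.out = nd)
    st$next_id <- st$next_id + 2L * nd
    st$foci_accum[d1] <- st$foci_accum[d2] <- parentF / 2
    st$eta[d1] <- st$eta[d2] <- 0
  }
  restack(st, config)
}

record_frame <- function(st, frame, time, c0, config) {
  idx <- as.integer(grouped_cumsum(rep(1L, st$n), st$trench) - 1L)
  area <- 2 * st$radius * st$L
  noise <- config$measurement_noise_sd
  rint <- st$Ramt / area + stats::rnorm(st$n, 0, noise)
  mint <- st$Mamt / area + stats::rnorm(st$n, 0, noise)
  foci <- stats::rpois(st$n, st$foci_accum)
  data.table::data.table(
    trench_id = st$trench, frame = frame, time = time,
    cell_index = idx, cell_id = st$cell_id,
    lineage_id = st$lineage_id, parent_id = st$parent_id,
    genotype = GENOTYPES[st$geno],
    length = st$L, area = area, position = st$position,
    reporter = rint, marker = mint, foci_count = foci,
    alive = st$alive, external_c0 = c0
  )
}

#' Simulate mother-machine trenches under an H2O2 schedule
#'
#' Runs the agent-based model: per-cell exponential growth with
#' saturating inhibition by intracellular H2O2, delayed Hill induction
#' of scavenging enzymes and of the transcriptional reporter, negative
#' feedback of scavenging on the intracellular concentration, collective
#' shielding along the trench, a division sizer with noisy content
#' partitioning, pushing and exit at the open end, sustained-excess
#' death with priming by prior induction, and Poisson mismatch foci.
#' Intensities are recorded with additive measurement noise at every
#' frame. The run is deterministic given `(config, schedule)` and
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param schedule A [treatment_schedule()].
#' @param quiet Suppress the run summary message.
#' @return A track table (`data.table`) with one row per cell per frame:
#'   `trench_id, frame, time, cell_index, cell_id, lineage_id, parent_id,
#'   genotype, length, area, position, reporter, marker, foci_count,
#'   alive, external_c0`. Frames are 0-based; time 0 is treatment start.
#'   Attributes `seed`, `config_digest`, `n_exited`, `n_dead` describe
#'   the run.
#' @export
simulate_trenches <- function(config, schedule, quiet = TRUE) {
  validate_sim_config(config)
  stopifnot(inherits(schedule, "treatment_schedule"))
  set.seed(config$seed)
  st <- init_state(config)
  times <- seq(schedule$t_min, schedule$t_max, by = config$frame_interval)
  nsub <- as.integer(round(config$frame_interval / config$substep))
  rec <- vector("list", length(times))
  rec[[1L]] <- record_frame(st, 0L, times[1L],
                            schedule_c0(schedule, times[1L]), config)
  for (k in seq_along(times)[-1L]) {
    # divisions act at the start of the frame, so a recorded change in
    # cell number is in effect during the frame that reports it
    st <- engine_frame_divide(st, config)
    st$eta <- stats::rnorm(st$n, 0, config$growth_noise_sd)
    t0 <- times[k - 1L]
    for (s in seq_len(nsub)) {
      c0 <- schedule_c0(schedule, t0 + (s - 1L) * config$substep)
      st <- engine_substep(st, c0, config$substep, config)
      # exits take effect within the sub-step they occur in, keeping
      # barrier-count bookkeeping synchronous with its physical effect
      st <- restack(st, config)
    }
    if (!all(is.finite(st$L)))
      stop("simulate_trenches: non-finite length in trench ",
           st$trench[which(!is.finite(st$L))[1]], " at frame ", k - 1L,
           call. = FALSE)
    rec[[k]] <- record_frame(st, k - 1L, times[k],
                             schedule_c0(schedule, times[k]), config)
  }
  tt <- data.table::rbindlist(rec)
  data.table::setattr(tt, "seed", config$seed)
  data.table::setattr(tt, "config_digest", config_digest(config))
  data.table::setattr(tt, "n_exited", st$n_exited)
  data.table::setattr(tt, "n_dead", st$n_dead)
  data.table::setattr(tt, "frame_interval", config$frame_interval)
  if (!quiet)
    message(sprintf(
      "simulated %d trenches, %d frames: %d exits, %d deaths (seed %d)",
      config$n_trenches, length(times), st$n_exited, st$n_dead,
      config$seed))
  tt
}
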