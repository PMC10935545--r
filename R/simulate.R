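GENOTYPES <- c("WT", "delta_oxyR", "inert")

hill <- function(c, k, n) {
  cn <- (pmax(c, 0) / k)^n
  cn / (1 + cn)
}

# cumulative sum within contiguous, pre-sorted groups
grouped_cumsum <- function(x, g) {
  if (length(x) == 0L) return(x)
  cs <- cumsum(x)
  first <- which(!duplicated(g))
  runlen <- diff(c(first, length(x) + 1L))
  offset <- rep(c(0, cs[first[-1L] - 1L]), times = runlen)
  cs - offset
}

# total within groups, replicated to each element
grouped_total <- function(x, g) {
  cs <- grouped_cumsum(x, g)
  first <- which(!duplicated(g))
  last <- c(first[-1L] - 1L, length(x))
  rep(cs[last], times = diff(c(first, length(x) + 1L)))
}

effective_sigma <- function(config) {
  config$attenuation_scale *
    (config$width_ref / config$trench_width)^config$width_exponent
}

#' Local H2O2 concentration profile along one trench
#'
#' Each scavenging cell attenuates the concentration reaching cells
#' behind it: with cells ordered from the open end, the concentration at
#' cell i is `c0 * prod_{j < i} (1 - f_j)`, where the attenuation
#' fraction of cell j is `f_j = 1 - exp(-sigma * S_j * E_j)`, with `S_j`
#' its surface area (hemisphere-capped cylinder, `S = 2 pi r L`) and
#' `E_j` its enzyme level. Inert and dead cells scavenge nothing
#' (`f = 0`), and the effective sigma shrinks in wider trenches.
#'
#' @param cells Data frame of cells ordered from the open end toward the
#'   closed end, with columns `length`, `enzyme`, and optionally `radius`
#'   (defaults to `config$mean_radius`), `genotype` (defaults `"WT"`),
#'   `alive` (defaults `TRUE`).
#' @param c0 External H2O2 concentration (uM) at the open end.
#' @param config A [sim_config()].
#' @return Numeric vector of local concentrations (uM), one per cell in
#'   input order; `numeric(0)` for an empty input.
#' @export
h2o2_profile <- function(cells, c0, config) {
  if (!is.numeric(c0) || length(c0) != 1L || c0 < 0)
    stop("h2o2_profile: c0 must be a single non-negative number",
         call. = FALSE)
  n <- nrow(cells)
  if (is.null(n) || n == 0L) return(numeric(0))
  radius <- if ("radius" %in% names(cells)) cells$radius
            else rep(config$mean_radius, n)
  genotype <- if ("genotype" %in% names(cells)) cells$genotype
              else rep("WT", n)
  alive <- if ("alive" %in% names(cells)) cells$alive else rep(TRUE, n)
  enz <- effective_scavenging(cells$enzyme, genotype, alive, config,
                              basal_saturation_factor(c0, config))
  surf <- 2 * pi * radius * cells$length
  logatt <- -effective_sigma(config) * surf * enz
  c0 * exp(c(0, cumsum(logatt)[-n]))
}

#' Per-cell attenuation fraction
#'
#' `f = 1 - exp(-sigma_eff * S * E)`: the fraction of incoming H2O2
#' removed by one cell of surface area `S` at enzyme level `E`.
#'
#' @param length,radius Cell dimensions (um).
#' @param enzyme Enzyme level in `[0, 1]`.
#' @param config A [sim_config()].
#' @return Attenuation fractions in `[0, 1)`.
#' @export
attenuation_fraction <- function(length, enzyme, config,
                                 radius = config$mean_radius) {
  1 - exp(-effective_sigma(config) * 2 * pi * radius * length *
            pmax(enzyme, 0))
}

#' Saturation factor of basal scavenging
#'
#' Basal (peroxidase-type) scavenging capacity is overwhelmed at high
#' external H2O2: the basal enzyme component is scaled by
#' `1 / (1 + (c0/K)^n)`. Induced (catalase-type) capacity above the
#' basal level is not affected.
#'
#' @param c0 External H2O2 concentration (uM).
#' @param config A [sim_config()].
#' @return Factor in (0, 1].
#' @export
basal_saturation_factor <- function(c0, config) {
  bs <- config$basal_saturation
  1 / (1 + (pmax(c0, 0) / bs$hill_k)^bs$hill_n)
}

# effective scavenging level: induced component plus saturable basal
# component; zero for inert and dead cells
effective_scavenging <- function(enzyme, genotype, alive, config,
                                 basal_sat = 1) {
  basal <- config$enzyme_induction$basal
  ifelse(genotype == "WT" & alive,
         pmax(enzyme - basal, 0) + basal * basal_sat,
         ifelse(alive & genotype != "inert", enzyme * basal_sat, 0))
}

growth_factor <- function(c_int, config) {
  1 / (1 + (pmax(c_int, 0) / config$growth_inhibition$hill_k)^
         config$growth_inhibition$m)
}

translation_factor <- function(c_int, config) {
  1 / (1 + (pmax(c_int, 0) / config$translation_inhibition$hill_k)^
         config$translation_inhibition$m)
}

update_c_int <- function(c_int, c_local, enzyme, dt, config) {
  kp <- config$h2o2_transport$permeation
  kc <- config$h2o2_transport$scavenge_max
  # implicit Euler: unconditionally stable for the fast relaxation
  (c_int + dt * kp * c_local) / (1 + dt * (kp + kc * pmax(enzyme, 0)))
}

#' Advance cell growth over one integration step
#'
#' The intracellular concentration relaxes toward the local external
#' concentration, reduced by the cell's own scavenging, and length grows
#' as `dL/dt = beta * L * g(c_int)` with the saturating inhibition
#' `g(c) = 1 / (1 + (c/K_g)^m)`. Dead and inert cells do not elongate.
#'
#' @param cells Cell-state data frame (see [new_cell_state()]).
#' @param c_local Local external H2O2 concentration (uM), scalar or
#'   per-cell vector.
#' @param dt Time step (min), must be positive.
#' @param config A [sim_config()].
#' @param rate_noise Additive perturbation of the elongation rate
#'   (1/min), scalar or per-cell; default 0 for deterministic stepping.
#' @param basal_sat Saturation factor of the basal scavenging component,
#'   from [basal_saturation_factor()]; default 1 (no saturation).
#' @return Updated cell-state data frame.
#' @export
step_growth <- function(cells, c_local, dt, config, rate_noise = 0,
                        basal_sat = 1) {
  stopifnot(dt > 0)
  scav <- effective_scavenging(cells$enzyme, cells$genotype,
                               cells$alive, config, basal_sat)
  cells$c_int <- update_c_int(cells$c_int, c_local, scav, dt, config)
  g <- growth_factor(cells$c_int, config)
  growing <- cells$alive & cells$genotype != "inert"
  beta <- pmax(cells$elongation_rate * g + rate_noise, 0) * growing
  cells$length <- cells$length * exp(beta * dt)
  cells
}

#' Advance the stress response over one integration step
#'
#' Enzyme level and reporter production follow the same delayed Hill
#' sensing of the intracellular concentration. Enzyme induction
#' `dE/dt = k_max * H_E(c_del) * (1 - E)` is balanced by growth
#' dilution; the reporter amount is produced at `basal + induced *
#' H_R(c_del)` per um of length and removed only by growth dilution and
#' division partitioning (the stored quantity is an amount; intensity is
#' amount per cell area). Production is attenuated by translation
#' inhibition at high intracellular H2O2. `delta_oxyR` cells never
#' induce and carry no reporter; larger E lowers `c_int` at fixed
#' `c_local` (negative feedback, applied in [step_growth()]).
#'
#' @inheritParams step_growth
#' @param c_delayed Delayed intracellular concentration driving the Hill
#'   terms; defaults to the current `c_int` (no delay).
#' @return Updated cell-state data frame.
#' @export
step_response <- function(cells, c_local, dt, config, c_delayed = NULL) {
  stopifnot(dt > 0)
  if (is.null(c_delayed)) c_delayed <- cells$c_int
  ei <- config$enzyme_induction
  rk <- config$reporter_kinetics
  he <- hill(c_delayed, ei$hill_k, ei$hill_n)
  hr <- hill(c_delayed, rk$hill_k, rk$hill_n)
  gtl <- translation_factor(cells$c_int, config)
  g <- growth_factor(cells$c_int, config)
  growing <- cells$alive & cells$genotype != "inert"
  beta <- cells$elongation_rate * g * growing
  induc <- cells$genotype == "WT" & cells$alive
  # basal OxyR drive keeps unstressed wild-type enzyme at ei$basal
  h0 <- config$base_elongation_rate * ei$basal /
    (ei$max_rate * (1 - ei$basal))
  dE <- dt * (ei$max_rate * gtl * (he + h0) * (1 - cells$enzyme) -
                beta * cells$enzyme)
  cells$enzyme <- ifelse(induc,
                         pmin(pmax(cells$enzyme + dE, 0), 1),
                         cells$enzyme)
  # production scales with cell area, so mean intensity (amount per
  # area) is independent of cell geometry at steady state
  area <- 2 * cells$radius * cells$length
  cells$reporter <- cells$reporter +
    ifelse(induc,
           dt * (rk$basal_rate + rk$induced_rate * hr) * gtl * area, 0)
  prodM <- cells$alive & cells$genotype != "inert"
  cells$marker <- cells$marker +
    ifelse(prodM, dt * config$marker_rate * gtl * area, 0)
  cells
}

#' Advance death and DNA-mismatch events over one step
#'
#' A cell dies once its intracellular concentration has exceeded
#' `lethal_conc + priming_coef * E` for `sustained_min` consecutive
#' minutes; death is absorbing (growth stops, the enzyme level drops to
#' zero, and the cell remains as non-scavenging mass until pushed out).
#' Mismatch foci are emitted as a Poisson process with rate
#' `lambda0 + lambda1 * c_int * (1 - E)`, producing a burst before
#' induction that subsides as E rises.
#'
#' @inheritParams step_growth
#' @return List with `cells` (updated state) and `foci` (integer vector
#'   of emitted focus counts for this step).
#' @export
step_fate_and_mismatch <- function(cells, dt, config) {
  stopifnot(dt > 0)
  dr <- config$death_rule
  over <- cells$alive &
    cells$c_int > dr$lethal_conc + dr$priming_coef * cells$enzyme
  cells$stress_clock <- ifelse(over, cells$stress_clock + dt, 0)
  newdead <- cells$alive & cells$stress_clock >= dr$sustained_min
  cells$alive[newdead] <- FALSE
  cells$enzyme[newdead] <- 0
  mm <- config$mismatch_rates
  lam <- (mm$lambda0 + mm$lambda1 * pmax(cells$c_int, 0) *
            (1 - cells$enzyme)) * cells$alive
  foci <- stats::rpois(nrow(cells), lam * dt)
  list(cells = cells, foci = foci)
}

#' Divide cells and push the stack toward the open end
#'
#' Cells in one trench (ordered from the closed end) divide once their
#' length reaches their division threshold (a sizer at twice birth
#' length with lognormal noise). Daughters split length equally;
#' reporter, marker and enzyme content are partitioned with fraction
#' `0.5 + N(0, partition_noise_sd)` (amounts are conserved exactly when
#' the noise is zero). Positions are restacked from the closed end with
#' the configured cell gap, and any cell whose proximal edge exceeds the
#' trench length exits at the open end.
#'
#' @param cells Cell-state data frame for one trench, ordered from the
#'   closed end, with non-overlapping positions.
#' @param config A [sim_config()].
#' @param next_id First unused cell id for newly created daughters.
#' @return List with `cells` (updated, restacked), `exited` (rows removed
#'   at the open end), and `next_id`.
#' @export
divide_and_push <- function(cells, config, next_id = NULL) {
  n <- nrow(cells)
  if (is.null(next_id)) next_id <- max(cells$cell_id, 0) + 1L
  div <- cells$alive & cells$genotype != "inert" &
    cells$length >= cells$div_length &
    cells$c_int < config$division_block_conc
  if (any(div)) {
    map <- rep(seq_len(n), ifelse(div, 2L, 1L))
    parent_ids <- cells$cell_id[div]
    out <- cells[map, , drop = FALSE]
    # positions of the first daughter of each dividing cell in `out`
    d1 <- which(!duplicated(map) & div[map])
    d2 <- d1 + 1L
    nd <- length(d1)
    halfL <- cells$length[div] / 2
    # sizer target: anchored to the configured birth size with mild
    # parental memory, so neither frame-sampling overshoot nor the
    # lognormal noise can drift or diffuse across generations
    halfT <- config$mean_birth_length^0.7 *
      (cells$div_length[div] / 2)^0.3
    cv <- config$division_cv
    out$length[d1] <- out$length[d2] <- halfL
    out$birth_length[d1] <- out$birth_length[d2] <- halfT
    out$div_length[d1] <- 2 * halfT *
      exp(stats::rnorm(nd, 0, cv) - cv^2 / 2)
    out$div_length[d2] <- 2 * halfT *
      exp(stats::rnorm(nd, 0, cv) - cv^2 / 2)
    part <- function() pmin(pmax(
      0.5 + stats::rnorm(nd, 0, config$partition_noise_sd), 0.3), 0.7)
    pR <- part(); pM <- part(); pE <- part()
    out$reporter[d1] <- pR * cells$reporter[div]
    out$reporter[d2] <- (1 - pR) * cells$reporter[div]
    out$marker[d1] <- pM * cells$marker[div]
    out$marker[d2] <- (1 - pM) * cells$marker[div]
    out$enzyme[d1] <- pmin(2 * pE * cells$enzyme[div], 1)
    out$enzyme[d2] <- pmin(2 * (1 - pE) * cells$enzyme[div], 1)
    base <- config$base_elongation_rate
    sdb <- base * config$elongation_cv *
      sqrt(1 - config$elongation_inherit^2)
    for (dd in list(d1, d2)) {
      out$elongation_rate[dd] <- pmax(base + config$elongation_inherit *
        (cells$elongation_rate[div] - base) + stats::rnorm(nd, 0, sdb),
        base * 0.2)
      out$radius[dd] <- pmin(pmax(config$mean_radius + 0.8 *
        (cells$radius[div] - config$mean_radius) +
        stats::rnorm(nd, 0, config$radius_cv * config$mean_radius * 0.6),
        0.25), config$trench_width / 2)
    }
    out$parent_id[d1] <- out$parent_id[d2] <- parent_ids
    out$cell_id[d1] <- next_id + seq.int(0L, by = 2L, length.out = nd)
    out$cell_id[d2] <- next_id + seq.int(1L, by = 2L, length.out = nd)
    next_id <- next_id + 2L * nd
    cells <- out
    n <- nrow(cells)
  }
  # restack from the closed end and drop cells pushed past the open end
  starts <- cumsum(c(0, cells$length[-n] + config$cell_gap))
  cells$position <- starts
  keep <- starts <= config$trench_length
  exited <- cells[!keep, , drop = FALSE]
  cells <- cells[keep, , drop = FALSE]
  rownames(cells) <- NULL
  list(cells = cells, exited = exited, next_id = next_id)
}

#' Construct a cell-state data frame
#'
#' Convenience constructor with consistent defaults for the columns the
#' stepping operations expect; primarily used in examples and tests.
#'
#' @param length Cell lengths (um).
#' @param config A [sim_config()].
#' @param genotype,enzyme,reporter,marker,c_int,alive,elongation_rate,radius
#'   Optional column overrides, recycled to `length(length)`.
#' @return Data frame with one row per cell.
#' @export
new_cell_state <- function(length, config,
                           genotype = "WT",
                           enzyme = NULL,
                           reporter = NULL, marker = NULL,
                           c_int = 0, alive = TRUE,
                           elongation_rate = config$base_elongation_rate,
                           radius = config$mean_radius) {
  n <- length(length)
  rk <- config$reporter_kinetics
  geno <- rep_len(genotype, n)
  if (is.null(enzyme)) {
    ei <- config$enzyme_induction
    enzyme <- ifelse(geno == "WT", ei$basal,
                     ifelse(geno == "delta_oxyR", ei$basal_uninduced, 0))
  }
  df <- data.frame(
    cell_id = seq_len(n), lineage_id = seq_len(n),
    parent_id = NA_integer_,
    genotype = rep_len(genotype, n),
    length = length,
    birth_length = length / 2^0.5,
    div_length = length * 2^0.5,
    radius = rep_len(radius, n),
    position = cumsum(c(0, length[-n] + config$cell_gap)),
    elongation_rate = rep_len(elongation_rate, n),
    enzyme = rep_len(enzyme, n),
    c_int = rep_len(c_int, n),
    stress_clock = 0,
    alive = rep_len(alive, n),
    stringsAsFactors = FALSE
  )
  # reporter/marker stored as amounts; defaults are the basal steady state
  area0 <- 2 * df$radius * df$length
  if (is.null(reporter))
    reporter <- rk$basal_rate * area0 / df$elongation_rate
  if (is.null(marker))
    marker <- config$marker_rate * area0 / df$elongation_rate
  df$reporter <- rep_len(reporter, n)
  df$marker <- rep_len(marker, n)
  df$reporter[df$genotype != "WT"] <- 0
  df$marker[df$genotype == "inert"] <-
    config$marker_rate * df$length[df$genotype == "inert"] /
      config$base_elongation_rate
  df$enzyme[df$genotype == "inert"] <- 0
  df$elongation_rate[df$genotype == "inert"] <- 0
  df
}
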