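#' Simulation configuration for the trench shielding model
#'
#' Builds the full parameter set for the agent-based mother-machine
#' simulator. Defaults describe wild-type *E. coli* in 25 um x 1.2 um
#' growth trenches sampled every 3 min, with per-cell H2O2 scavenging
#' calibrated so that one induced wild-type cell attenuates the local
#' concentration by roughly a third.
#'
#' Geometry and kinetics are grouped into sublists; any element can be
#' overridden by name. All rates are per minute, lengths in um,
#' concentrations in uM, intensities in arbitrary units (a.u.).
#'
#' @param trench_length Trench length (um). Cells whose proximal edge is
#'   pushed beyond this exit at the open end.
#' @param trench_width Trench width (um); 1.2 for the standard device,
#'   1.4 for the wide variant.
#' @param n_trenches Number of trenches to simulate.
#' @param frame_interval Imaging frame interval (min).
#' @param substep Euler integration step (min) inside each frame.
#' @param loading_mean_cells,loading_sd Mean and SD of the initial number
#'   of cells per trench (full loading about 8, partial about 5).
#' @param mean_birth_length Mean cell length at birth (um).
#' @param division_cv Lognormal CV of the division-length threshold.
#' @param cell_gap Effective pole-to-pole spacing between stacked cells
#'   (um); reconciles mean cell length with trench occupancy.
#' @param cell_gap_sd Trench-to-trench SD of that spacing (um): packing
#'   differs persistently between trenches, so the cumulative barrier
#'   geometry varies across trenches at equal loading.
#' @param mean_radius Mean cell radius (um); defaults to
#'   `trench_width / 2 - 0.1` so cells sit slightly narrower than the
#'   trench.
#' @param radius_cv Relative SD of cell radius across lineages.
#' @param base_elongation_rate Mean exponential elongation rate (1/min).
#' @param elongation_cv Relative SD of the per-cell elongation rate drawn
#'   at birth.
#' @param elongation_inherit Mother-to-daughter regression coefficient of
#'   the per-cell elongation rate toward the population mean.
#' @param growth_noise_sd SD (1/min) of the additive per-frame noise on
#'   the instantaneous elongation rate.
#' @param attenuation_scale Scavenging coupling sigma (1/um^2): the log
#'   attenuation contributed by one cell is `sigma * S * E` with S its
#'   surface area and E its enzyme level.
#' @param width_ref,width_exponent The effective sigma is scaled by
#'   `(width_ref / trench_width)^width_exponent`, so wider trenches let
#'   more H2O2 flux bypass the cells.
#' @param basal_saturation List: `hill_k` (uM) and `hill_n`; the basal
#'   (peroxidase-type) scavenging component is scaled by
#'   `1 / (1 + (c0/hill_k)^hill_n)` at external concentration `c0` —
#'   strong shielding below ~100 uM that collapses at 500 uM, while the
#'   induced (catalase-type) component does not saturate.
#' @param enzyme_induction List: `delay` (signalling dead time, min),
#'   `max_rate` (1/min), `hill_k` (uM), `hill_n`, `basal` (enzyme level
#'   maintained by basal OxyR activity in unstressed wild-type cells),
#'   `basal_uninduced` (residual level in delta-oxyR cells, which never
#'   induce and scavenge essentially nothing).
#' @param reporter_kinetics List: `basal_rate` and `induced_rate`
#'   (a.u. um / min per um of cell length), `hill_k` (uM), `hill_n`,
#'   `steady_state_target` (a.u.) documenting the intended open-end
#'   steady-state intensity under 100 uM.
#' @param marker_rate Constitutive marker production rate (same units as
#'   reporter rates).
#' @param h2o2_transport List: `permeation` (1/min) and `scavenge_max`
#'   (1/min at enzyme level 1) governing intracellular H2O2 relaxation.
#' @param growth_inhibition List: `hill_k` (uM) and `m`; growth is scaled
#'   by `1 / (1 + (c_int/hill_k)^m)`.
#' @param division_block_conc Intracellular concentration (uM) above
#'   which division is checkpoint-blocked: stressed cells elongate
#'   without dividing (transient filamentation) until scavenging brings
#'   the internal concentration back down.
#' @param translation_inhibition List: `hill_k` (uM) and `m`; protein
#'   production (enzyme, reporter, marker) is scaled the same way, with a
#'   higher threshold than growth.
#' @param death_rule List: `lethal_conc` (uM), `sustained_min` (min), and
#'   `priming_coef` (uM per unit enzyme level): death occurs when the
#'   intracellular concentration exceeds `lethal_conc + priming_coef * E`
#'   for `sustained_min` consecutive minutes.
#' @param mismatch_rates List: `lambda0` (foci/cell/min) and `lambda1`
#'   (foci/cell/min/uM) for the Poisson mismatch-focus process with
#'   intensity `lambda0 + lambda1 * c_int * (1 - E)`.
#' @param partition_noise_sd SD of the division partition fraction around
#'   one half for reporter, marker and enzyme content.
#' @param measurement_noise_sd SD (a.u.) of additive measurement noise on
#'   recorded intensities.
#' @param genotype_mix Named proportions over `WT`, `delta_oxyR`, `inert`;
#'   must sum to 1.
#' @param seed Integer seed; simulations are deterministic given
#'   (config, schedule, seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(trench_length = 25,
                       trench_width = 1.2,
                       n_trenches = 100,
                       frame_interval = 3,
                       substep = 0.25,
                       loading_mean_cells = 8,
                       loading_sd = 2,
                       mean_birth_length = 1.75,
                       division_cv = 0.12,
                       cell_gap = 0.6,
                       cell_gap_sd = 0.5,
                       mean_radius = NULL,
                       radius_cv = 0.15,
                       base_elongation_rate = 0.028,
                       elongation_cv = 0.07,
                       elongation_inherit = 0.5,
                       growth_noise_sd = 0.002,
                       attenuation_scale = 0.086,
                       width_ref = 1.2,
                       width_exponent = 2,
                       enzyme_induction = list(delay = 4.5, max_rate = 0.06,
                                               hill_k = 0.05, hill_n = 2,
                                               basal = 0.4,
                                               basal_uninduced = 0.02),
                       basal_saturation = list(hill_k = 150, hill_n = 3),
                       reporter_kinetics = list(basal_rate = 8.4,
                                                induced_rate = 700,
                                                hill_k = 10, hill_n = 1,
                                                steady_state_target = 7400),
                       marker_rate = 56,
                       h2o2_transport = list(permeation = 10,
                                             scavenge_max = 60),
                       growth_inhibition = list(hill_k = 10, m = 2),
                       division_block_conc = 2,
                       translation_inhibition = list(hill_k = 60, m = 4),
                       death_rule = list(lethal_conc = 60,
                                         sustained_min = 20,
                                         priming_coef = 150),
                       mismatch_rates = list(lambda0 = 2e-4, lambda1 = 1e-3),
                       partition_noise_sd = 0.02,
                       measurement_noise_sd = 20,
                       genotype_mix = c(WT = 1, delta_oxyR = 0, inert = 0),
                       seed = 1L) {
  if (is.null(mean_radius)) mean_radius <- trench_width / 2 - 0.1
  cfg <- list(
    trench_length = trench_length, trench_width = trench_width,
    n_trenches = as.integer(n_trenches),
    frame_interval = frame_interval, substep = substep,
    loading_mean_cells = loading_mean_cells, loading_sd = loading_sd,
    mean_birth_length = mean_birth_length, division_cv = division_cv,
    cell_gap = cell_gap, cell_gap_sd = cell_gap_sd,
    mean_radius = mean_radius, radius_cv = radius_cv,
    base_elongation_rate = base_elongation_rate,
    elongation_cv = elongation_cv, elongation_inherit = elongation_inherit,
    growth_noise_sd = growth_noise_sd,
    attenuation_scale = attenuation_scale,
    width_ref = width_ref, width_exponent = width_exponent,
    enzyme_induction = enzyme_induction,
    basal_saturation = basal_saturation,
    reporter_kinetics = reporter_kinetics,
    marker_rate = marker_rate,
    h2o2_transport = h2o2_transport,
    growth_inhibition = growth_inhibition,
    division_block_conc = division_block_conc,
    translation_inhibition = translation_inhibition,
    death_rule = death_rule,
    mismatch_rates = mismatch_rates,
    partition_noise_sd = partition_noise_sd,
    measurement_noise_sd = measurement_noise_sd,
    genotype_mix = genotype_mix,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants: non-negative rates, lengths and
#' concentrations, a positive frame interval, genotype proportions that
#' sum to one, and a trench at least as long as the mean birth length.
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly; errors describe the first violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pos <- c("trench_length", "trench_width", "frame_interval", "substep",
           "mean_birth_length", "mean_radius", "base_elongation_rate")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("sim_config: `", f, "` must be positive", call. = FALSE)
  }
  nonneg <- c("division_cv", "cell_gap", "cell_gap_sd", "radius_cv",
              "growth_noise_sd",
              "attenuation_scale", "partition_noise_sd",
              "measurement_noise_sd", "loading_sd")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop("sim_config: `", f, "` must be non-negative", call. = FALSE)
  }
  if (cfg$trench_length < cfg$mean_birth_length)
    stop("sim_config: trench_length must be >= mean_birth_length",
         call. = FALSE)
  gm <- cfg$genotype_mix
  if (!all(c("WT", "delta_oxyR", "inert") %in% names(gm)) ||
      any(gm < 0) || abs(sum(gm) - 1) > 1e-8)
    stop("sim_config: genotype_mix must be named proportions over ",
         "WT/delta_oxyR/inert summing to 1", call. = FALSE)
  if (cfg$substep > cfg$frame_interval)
    stop("sim_config: substep must not exceed frame_interval", call. = FALSE)
  if (cfg$frame_interval %% cfg$substep > 1e-9)
    stop("sim_config: frame_interval must be a multiple of substep",
         call. = FALSE)
  invisible(cfg)
}

#' Treatment schedule for external H2O2
#'
#' A schedule is a set of contiguous, non-overlapping segments of external
#' H2O2 concentration over time, with time 0 defined as the start of
#' treatment (pre-treatment frames carry negative times). Each segment is
#' held constant (`step`) or linearly interpolated (`ramp`) between its
#' start and end concentrations; pulse trains are expressed as alternating
#' step segments. Outside all segments the concentration is zero.
#'
#' @param start,end Segment boundaries (min); must be contiguous when more
#'   than one segment is given.
#' @param c0_start External concentration (uM) at each segment start.
#' @param c0_end Concentration at each segment end; defaults to
#'   `c0_start` (step segments).
#' @param t_min,t_max Simulated time range (min); `t_min` is typically
#'   negative (pre-treatment observation).
#' @return A list of class `treatment_schedule`.
#' @export
treatment_schedule <- function(start, end, c0_start, c0_end = c0_start,
                               t_min = -135, t_max = 135) {
  stopifnot(length(start) == length(end),
            length(c0_start) == length(start),
            length(c0_end) == length(start))
  if (any(c0_start < 0) || any(c0_end < 0))
    stop("treatment_schedule: concentrations must be >= 0", call. = FALSE)
  if (any(end <= start))
    stop("treatment_schedule: segment end must exceed start", call. = FALSE)
  o <- order(start)
  start <- start[o]; end <- end[o]
  c0_start <- c0_start[o]; c0_end <- c0_end[o]
  if (length(start) > 1 && any(start[-1] < end[-length(end)] - 1e-9))
    stop("treatment_schedule: segments must not overlap", call. = FALSE)
  if (t_max <= t_min)
    stop("treatment_schedule: t_max must exceed t_min", call. = FALSE)
  sched <- list(start = start, end = end,
                c0_start = c0_start, c0_end = c0_end,
                t_min = t_min, t_max = t_max)
  class(sched) <- "treatment_schedule"
  sched
}

#' External concentration at given times
#'
#' @param sched A `treatment_schedule`.
#' @param t Vector of times (min).
#' @return Vector of external H2O2 concentrations (uM).
#' @export
schedule_c0 <- function(sched, t) {
  stopifnot(inherits(sched, "treatment_schedule"))
  out <- numeric(length(t))
  for (i in seq_along(sched$start)) {
    inseg <- t >= sched$start[i] & t < sched$end[i]
    if (!any(inseg)) next
    frac <- (t[inseg] - sched$start[i]) / (sched$end[i] - sched$start[i])
    out[inseg] <- sched$c0_start[i] +
      frac * (sched$c0_end[i] - sched$c0_start[i])
  }
  out
}

#' Preconfigured experimental scenarios
#'
#' Returns a fully specified configuration and treatment schedule for the
#' named experiment layout: `full_loading` (standard device, 100 uM step),
#' `partial_loading` (5 +/- 2 cells per trench, 100 uM step),
#' `wide_trench` (1.4 um trench width, 100 uM step), `mixed_genotypes`
#' (wild type mixed 1:1 with a non-inducing delta-oxyR strain),
#' `step_500` (single 1 h step to 500 uM followed by recovery),
#' `ramp_500` (staircase 25 -> 100 -> 500 uM over 18 min, held 1 h,
#' then recovery), `pulse_train` (repeated 100 uM pulses), and
#' `calibration_panel` (one schedule per calibration concentration, with
#' the panel concentrations 12.5-100 uM in `$panel`).
#'
#' @param name Scenario name.
#' @param n_trenches Number of trenches (per concentration for the
#'   calibration panel).
#' @param seed Integer seed.
#' @param ... Additional overrides passed to [sim_config()].
#' @return List with `config` and `schedule` (or `schedules` and `panel`
#'   for the calibration panel).
#' @export
scenario <- function(name, n_trenches = 100, seed = 1L, ...) {
  known <- c("full_loading", "partial_loading", "wide_trench",
             "mixed_genotypes", "step_500", "ramp_500", "pulse_train",
             "calibration_panel")
  if (!name %in% known)
    stop("unknown scenario `", name, "`; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  step100 <- treatment_schedule(0, 360, 100, t_min = -135, t_max = 360)
  recovery <- 660  # post-removal observation (min), > 10 h fate window
  out <- switch(name,
    full_loading = list(
      config = sim_config(n_trenches = n_trenches, seed = seed, ...),
      schedule = step100),
    partial_loading = list(
      # treatment shortly after loading, before trenches refill, so the
      # cell number at treatment time actually varies (5 +/- 2)
      config = sim_config(n_trenches = n_trenches, seed = seed,
                          loading_mean_cells = 5, loading_sd = 2, ...),
      schedule = treatment_schedule(0, 360, 100, t_min = -30,
                                    t_max = 360)),
    wide_trench = list(
      config = sim_config(n_trenches = n_trenches, seed = seed,
                          trench_width = 1.4, ...),
      schedule = step100),
    mixed_genotypes = list(
      config = sim_config(n_trenches = n_trenches, seed = seed,
                          genotype_mix = c(WT = 0.5, delta_oxyR = 0.5,
                                           inert = 0), ...),
      schedule = step100),
    step_500 = list(
      config = sim_config(n_trenches = n_trenches, seed = seed, ...),
      schedule = treatment_schedule(0, 60, 500,
                                    t_min = -135, t_max = 60 + recovery)),
    ramp_500 = list(
      config = sim_config(n_trenches = n_trenches, seed = seed, ...),
      schedule = treatment_schedule(
        start = c(0, 6, 12), end = c(6, 12, 72),
        c0_start = c(25, 100, 500),
        t_min = -135, t_max = 72 + recovery)),
    pulse_train = list(
      config = sim_config(n_trenches = n_trenches, seed = seed, ...),
      schedule = treatment_schedule(
        start = c(0, 90, 180, 270), end = c(30, 120, 210, 300),
        c0_start = rep(100, 4),
        t_min = -135, t_max = 390)),
    calibration_panel = {
      panel <- c(12.5, 25, 37.5, 50, 62.5, 75, 100)
      list(
        config = sim_config(n_trenches = n_trenches, seed = seed, ...),
        schedules = stats::setNames(lapply(panel, function(c0)
          treatment_schedule(0, 240, c0, t_min = -60, t_max = 240)),
          paste0("c", panel)),
        panel = panel)
    })
  out$name <- name
  out
}

#' Damkohler number for cell-envelope H2O2 scavenging
#'
#' Dimensionless ratio of the intracellular scavenging rate to diffusive
#' transport across the cell envelope, `Da = k * L / v`. With the
#' catalase scavenging rate `k = 5.4e4` per second, envelope permeation
#' velocity `v = 1.6e-5` m/s, and a length scale of 1.2 um, Da is about
#' 4e3, meaning scavenging is limited by diffusion into the cell.
#'
#' @param k Volumetric scavenging rate (1/s).
#' @param v Membrane diffusion (permeation) velocity (m/s).
#' @param length_scale Length scale (um).
#' @return Dimensionless Damkohler number.
#' @export
damkohler_number <- function(k = 5.4e4, v = 1.6e-5, length_scale = 1.2) {
  stopifnot(k >= 0, v > 0, length_scale > 0)
  k * (length_scale * 1e-6) / v
}

#' Short digest of a configuration for run manifests
#'
#' Deterministic content digest of a config or any serialisable object;
#' used to tag output files so runs can be matched to their parameters.
#' @param x Object to digest.
#' @return Character scalar (8 hex digits).
#' @export
config_digest <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x, digits.d = 10,
                                                vec.len = 1e6)),
               collapse = "\n")
  # polynomial rolling hash over the printed representation
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
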