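#' Detect the post-treatment reporter peak
#'
#' Finds the first local maximum of the reporter trace after treatment
#' whose height, normalised to the trace's post-treatment range, is at
#' least `norm_threshold`, requiring a minimum separation between
#' candidate peaks. The amplitude is baseline-subtracted (mean of all
#' pre-treatment frames).
#'
#' @param time Frame times (min), treatment at 0.
#' @param reporter Reporter intensity series (a.u.).
#' @param norm_threshold Normalised height threshold (default 0.15).
#' @param min_distance Minimum separation between peaks, in frames.
#' @param window Post-treatment window (min) searched for the peak;
#'   `Inf` searches the whole post-treatment span.
#' @return List with `peak_time` (min) and `peak_amplitude` (a.u.,
#'   baseline-subtracted), both `NA` when no peak qualifies.
#' @export
detect_peak <- function(time, reporter, norm_threshold = 0.15,
                        min_distance = 2, window = Inf) {
  pre <- time < 0
  post <- which(time > 0 & time <= window)
  if (!any(pre) || length(post) < 3)
    stop("detect_peak: series must span pre-treatment and at least 3 ",
         "post-treatment frames", call. = FALSE)
  baseline <- mean(reporter[pre])
  y <- reporter[post]
  lo <- min(y); hi <- max(y)
  if (hi <= lo)
    return(list(peak_time = NA_real_, peak_amplitude = NA_real_))
  yn <- (y - lo) / (hi - lo)
  n <- length(y)
  # local maxima: strictly above the previous point, at least equal to
  # the next (plateaus resolve to their first frame)
  cand <- which(yn >= norm_threshold &
                  yn > c(-Inf, yn[-n]) & yn >= c(yn[-1], -Inf))
  if (!length(cand))
    return(list(peak_time = NA_real_, peak_amplitude = NA_real_))
  # enforce minimum distance, keeping earlier peaks
  keep <- cand[1]
  for (k in cand[-1]) if (k - keep[length(keep)] >= min_distance)
    keep <- c(keep, k)
  first <- keep[1]
  list(peak_time = time[post[first]],
       peak_amplitude = y[first] - baseline)
}

#' Reporter induction time by threshold crossing
#'
#' First post-treatment time the reporter crosses an absolute intensity
#' threshold, linearly interpolated between frames. The default
#' threshold of 1,480 a.u. corresponds to 20% of the target open-end
#' steady-state intensity under 100 uM.
#'
#' @param time Frame times (min), treatment at 0.
#' @param reporter Reporter intensity series (a.u.).
#' @param threshold Intensity threshold (a.u.).
#' @return Crossing time (min), or `NA` if the trace never crosses.
#' @export
induction_time <- function(time, reporter, threshold = 1480) {
  post <- which(time >= 0)
  if (length(post) < 2)
    stop("induction_time: need at least 2 post-treatment frames",
         call. = FALSE)
  y <- reporter[post]; tt <- time[post]
  above <- y >= threshold
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(tt[1])
  # linear interpolation between the bracketing frames
  tt[i - 1] + (threshold - y[i - 1]) / (y[i] - y[i - 1]) *
    (tt[i] - tt[i - 1])
}

#' Coefficient of variation
#'
#' SD divided by mean (the standard definition). Requires at least two
#' values and a non-zero mean.
#'
#' @param x Numeric vector.
#' @param na.rm Drop NAs first.
#' @return SD/mean.
#' @export
cv <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) < 2)
    stop("cv: need at least 2 values", call. = FALSE)
  m <- mean(x)
  if (abs(m) < .Machine$double.eps)
    stop("cv: mean is zero", call. = FALSE)
  stats::sd(x) / m
}

#' Calibrate reporter intensity against external H2O2 concentration
#'
#' Least-squares line through steady-state intensities of cells at the
#' open end of trenches exposed to known concentrations; the fitted
#' line converts any intensity into an estimated local concentration.
#'
#' @param concentration Known external concentrations (uM), one per
#'   observation; at least 3 distinct values are required.
#' @param intensity Steady-state reporter intensities (a.u.).
#' @return List of class `calibration`: `slope` (a.u./uM), `intercept`
#'   (a.u.), `r_squared`, and `to_concentration(intensity)`.
#' @export
calibrate <- function(concentration, intensity) {
  stopifnot(length(concentration) == length(intensity))
  ok <- is.finite(concentration) & is.finite(intensity)
  concentration <- concentration[ok]; intensity <- intensity[ok]
  if (length(unique(concentration)) < 3)
    stop("calibrate: need at least 3 distinct concentrations",
         call. = FALSE)
  fit <- stats::lm(intensity ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("calibrate: non-positive or undefined slope", call. = FALSE)
  out <- list(
    slope = slope, intercept = intercept,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    to_concentration = function(intensity)
      (intensity - intercept) / slope
  )
  class(out) <- "calibration"
  out
}

#' Infer the per-barrier-cell attenuation fraction
#'
#' Fits `ln c = ln c0 + B ln(1 - f)` by least squares over cells with
#' calibrated local concentrations `c` and barrier counts `B`; returns
#' `f_hat = 1 - exp(slope)` with a seeded bootstrap confidence
#' interval.
#'
#' @param concentration Calibrated local concentrations (uM), positive.
#' @param n_barrier Barrier-cell counts.
#' @param n_boot Bootstrap resamples for the confidence interval.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return List: `f_hat`, `ci` (length-2), `slope`, `n`.
#' @export
infer_attenuation <- function(concentration, n_barrier, n_boot = 1000,
                              conf = 0.95, seed = 1L) {
  ok <- is.finite(concentration) & is.finite(n_barrier)
  concentration <- concentration[ok]; n_barrier <- n_barrier[ok]
  if (any(concentration <= 0))
    stop("infer_attenuation: concentrations must be positive ",
         "(calibrate first, and drop non-positive estimates)",
         call. = FALSE)
  if (length(unique(n_barrier)) < 3)
    stop("infer_attenuation: need at least 3 distinct barrier counts",
         call. = FALSE)
  lc <- log(concentration)
  slope <- function(idx) {
    b <- n_barrier[idx]; y <- lc[idx]
    stats::cov(b, y) / stats::var(b)
  }
  s <- slope(seq_along(lc))
  f_hat <- 1 - exp(s)
  set.seed(seed)
  n <- length(lc)
  boots <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(n_barrier[idx])) < 2) return(NA_real_)
    1 - exp(slope(idx))
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE)
  list(f_hat = f_hat, ci = unname(qs), slope = s, n = n)
}

#' Steady-state gradient analysis of a simulated run
#'
#' Convenience pipeline for attenuation inference on track tables: a
#' calibration panel (outermost-cell steady-state intensities at known
#' concentrations) is fitted, mother and interior cells of the analysis
#' run are converted to local concentrations, and the per-barrier-cell
#' attenuation is inferred from their barrier counts.
#'
#' @param panel_tracks Named list of track tables, one per calibration
#'   concentration; names are ignored, concentrations are taken from
#'   the `external_c0` column.
#' @param tracks Track table of the analysis run (constant treatment).
#' @param ss_window Steady-state window (min post-treatment) for both
#'   calibration and gradient cells; default 60-180 min.
#' @param seed Seed for the bootstrap CI.
#' @return List: `calibration`, `attenuation` (from
#'   [infer_attenuation()]).
#' @export
gradient_analysis <- function(panel_tracks, tracks,
                              ss_window = c(60, 180), seed = 1L) {
  # intensities are baseline-subtracted (pre-treatment mean) on both
  # the calibration and the gradient side, so the fitted line passes
  # near the origin and its inversion is exact up to a multiplicative
  # gain -- which cancels in the log-slope of the gradient fit
  outer_ss <- function(tt) {
    dt <- data.table::as.data.table(tt)
    base <- mean(dt$reporter[dt$time < 0])
    ss <- dt[dt$time >= ss_window[1] & dt$time <= ss_window[2]]
    o <- ss[, .SD[cell_index == max(cell_index)],
            by = c("trench_id", "frame")]
    c(mean(o$reporter) - base, o$external_c0[1])
  }
  pan <- vapply(panel_tracks, outer_ss, numeric(2))
  cal <- calibrate(pan[2, ], pan[1, ])
  # the inversion applied to the gradient must be homogeneous:
  # baseline-subtracted intensity vanishes at zero peroxide, so the
  # conversion is a through-origin gain (a.u. per uM). A free
  # intercept would leak the panel's residual curvature into the
  # log-gradient as an additive offset and flatten the fitted slope.
  gain <- sum(pan[1, ] * pan[2, ]) / sum(pan[2, ]^2)
  dt <- data.table::as.data.table(tracks)
  base <- mean(dt$reporter[dt$time < 0])
  ss <- dt[dt$time >= ss_window[1] & dt$time <= ss_window[2]]
  ss[, n_in_trench := .N, by = c("trench_id", "frame")]
  # restrict the gradient fit to mother cells (they alone stay at one
  # position long enough for the reporter to equilibrate) and average
  # each mother over the window: barrier number is persistent per
  # trench, and averaging removes the measurement-noise floor that
  # would otherwise bias the log fit at high barrier counts
  mm <- ss[ss$cell_index == 0L,
           list(I = mean(reporter) - base,
                B = mean(n_in_trench) - 1),
           by = "trench_id"]
  conc <- mm$I / gain
  keep <- is.finite(conc) & conc > 0
  att <- infer_attenuation(conc[keep], mm$B[keep], seed = seed)
  list(calibration = cal, gain = gain, attenuation = att)
}

#' Cross-correlation lag between barrier count and mother reporter
#'
#' Normalised cross-correlation between per-trench barrier-count and
#' mother-reporter fluctuation series, averaged across trenches; the
#' reported lag is the location of the minimum (the correlation is
#' negative: losing a barrier raises the mother's exposure), found by a
#' local-extremum search. Positive lag means barrier-count changes
#' precede reporter changes. Series are first-differenced to remove the
#' slow accumulation trend so the extremum reflects the signalling
#' latency.
#'
#' @param tracks Track table (steady-state portion is selected with
#'   `from_time`).
#' @param max_lag Maximum lag examined (frames).
#' @param from_time Start of the steady-state window (min
#'   post-treatment), default 120.
#' @param detrend `"diff"` (default) or `"none"`.
#' @param min_frames Minimum frames per trench (error below this).
#' @return List: `lag_min` (min), `lag_frames`, `correlation` (value at
#'   the extremum), `curve` (data frame of lag vs mean correlation),
#'   `n_trenches`.
#' @export
cross_correlation_lag <- function(tracks, max_lag = 20,
                                  from_time = 120, detrend = "diff",
                                  min_frames = 20) {
  dt <- data.table::as.data.table(tracks)
  time <- cell_index <- trench_id <- reporter <- NULL
  ss <- dt[dt$time >= from_time]
  frame_int <- attr(tracks, "frame_interval")
  if (is.null(frame_int)) {
    tu <- sort(unique(ss$time))
    frame_int <- min(diff(tu))
  }
  mom <- ss[ss$cell_index == 0L,
            c("trench_id", "frame", "reporter"), with = FALSE]
  cnt <- ss[, .N, by = c("trench_id", "frame")]
  ser <- merge(mom, cnt, by = c("trench_id", "frame"))
  data.table::setorder(ser, trench_id, frame)
  nfr <- ser[, .N, by = "trench_id"]
  if (max(nfr$N) < min_frames)
    stop("cross_correlation_lag: steady-state window shorter than ",
         min_frames, " frames", call. = FALSE)
  lags <- -max_lag:max_lag
  one_trench <- function(x, y) {
    if (detrend == "diff") { x <- diff(x); y <- diff(y) }
    x <- x - mean(x); y <- y - mean(y)
    sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
    if (sx == 0 || sy == 0) return(NULL)
    n <- length(x)
    vapply(lags, function(l) {
      # positive lag: barrier count (x) leads the reporter (y)
      if (l >= 0) sum(x[seq_len(n - l)] * y[seq_len(n - l) + l])
      else sum(y[seq_len(n + l)] * x[seq_len(n + l) - l])
    }, numeric(1)) / (sx * sy)
  }
  tr_ids <- nfr$trench_id[nfr$N >= min_frames]
  curves <- lapply(tr_ids, function(id) {
    d <- ser[ser$trench_id == id, ]
    one_trench(d$N, d$reporter)
  })
  curves <- curves[!vapply(curves, is.null, logical(1))]
  if (!length(curves))
    stop("cross_correlation_lag: no usable trench series", call. = FALSE)
  cc <- colMeans(do.call(rbind, curves))
  # local minima (argrelextrema equivalent); deepest one wins
  n <- length(cc)
  locmin <- which(cc < c(Inf, cc[-n]) & cc <= c(cc[-1], Inf))
  locmin <- locmin[locmin > 1 & locmin < n]
  i <- if (length(locmin)) locmin[which.min(cc[locmin])] else
    which.min(cc)
  # parabolic sub-frame refinement around the discrete minimum (exact
  # when the two neighbours are symmetric)
  lag_est <- lags[i]
  if (i > 1 && i < n) {
    den <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (den > 0) {
      shift <- 0.5 * (cc[i - 1] - cc[i + 1]) / den
      lag_est <- lags[i] + max(-0.5, min(0.5, shift))
    }
  }
  list(lag_min = lag_est * frame_int, lag_frames = lags[i],
       correlation = cc[i],
       curve = data.frame(lag_min = lags * frame_int, correlation = cc),
       n_trenches = length(curves))
}

# generations separating each cell from an ancestor set: resolves
# parent links back `gen` generations
ancestor_at <- function(cell_id, parent_of, gen) {
  out <- cell_id
  for (i in seq_len(gen)) out <- parent_of[as.character(out)]
  out
}

#' Reporter correlation of adjacent cell pairs by lineage relation
#'
#' Pearson correlation of reporter intensities across pairs of adjacent
#' cells in the same trench, classified by the number of generations
#' back to their most recent common ancestor: sisters (1), cousins (2),
#' or unrelated (> 2). Pairs can be stratified by the barrier count of
#' the outer cell.
#'
#' @param tracks Track table.
#' @param from_time Steady-state window start (min post-treatment).
#' @param min_pairs Minimum pairs per relation; relations with fewer
#'   pairs are reported as `NA` (and noted in `n_pairs`).
#' @param strata Optional numeric breaks over the outer cell's barrier
#'   count; `NULL` pools everything.
#' @param center `"trench"` (default) removes the per-trench-frame mean
#'   intensity before correlating, so the deterministic position
#'   gradient shared by every adjacent pair does not inflate all
#'   relations alike; `"none"` correlates raw intensities.
#' @return Data frame with columns `relation`, `stratum`, `r`,
#'   `n_pairs`.
#' @export
lineage_correlations <- function(tracks, from_time = 60,
                                 min_pairs = 30, strata = NULL,
                                 center = c("trench", "none")) {
  center <- match.arg(center)
  dt <- data.table::as.data.table(tracks)
  data.table::setorder(dt, trench_id, frame, cell_index)
  ss <- dt[dt$time >= from_time]
  if (center == "trench")
    ss[, reporter := reporter - mean(reporter),
       by = c("trench_id", "frame")]
  # parent lookup across the whole table
  fam <- unique(dt[, c("cell_id", "parent_id"), with = FALSE])
  parent_of <- stats::setNames(fam$parent_id, fam$cell_id)
  # adjacent pairs: cell i (inner) with cell i+1 (outer)
  ss[, next_cell := data.table::shift(cell_id, type = "lead"),
     by = c("trench_id", "frame")]
  ss[, next_rep := data.table::shift(reporter, type = "lead"),
     by = c("trench_id", "frame")]
  ss[, n_in_trench := .N, by = c("trench_id", "frame")]
  pr <- ss[!is.na(ss$next_cell), ]
  pr[, B_outer := n_in_trench - 2L - cell_index]
  # classify relation by walking both parent chains
  gen_to_lca <- function(a, b) {
    pa <- parent_of[as.character(a)]
    pb <- parent_of[as.character(b)]
    if (!is.na(pa) && !is.na(pb) && pa == pb) return(1L)
    ga <- if (is.na(pa)) NA else parent_of[as.character(pa)]
    gb <- if (is.na(pb)) NA else parent_of[as.character(pb)]
    if (!is.na(ga) && !is.na(gb) && ga == gb) return(2L)
    3L
  }
  key <- unique(pr[, c("cell_id", "next_cell"), with = FALSE])
  key$gen <- mapply(gen_to_lca, key$cell_id, key$next_cell)
  pr <- merge(pr, key, by = c("cell_id", "next_cell"))
  pr$relation <- c("sister", "cousin", "unrelated")[pr$gen]
  if (is.null(strata)) {
    pr$stratum <- "all"
  } else {
    pr$stratum <- as.character(cut(pr$B_outer, breaks = strata))
  }
  res <- pr[, {
    if (.N >= min_pairs)
      list(r = stats::cor(reporter, next_rep), n_pairs = .N)
    else list(r = NA_real_, n_pairs = .N)
  }, by = c("relation", "stratum")]
  out <- as.data.frame(res)
  out[order(match(out$relation, c("sister", "cousin", "unrelated"))), ]
}

#' Divergence of sister-cell reporter intensities after division
#'
#' For every division, follows the two daughters and records the
#' absolute difference of their reporter intensities, normalised by the
#' parent's intensity in its last frame, as a function of time since
#' division; stratified by the barrier count of the outer sister at
#' birth. An exponential growth rate of the mean divergence is fitted
#' per stratum.
#'
#' @param tracks Track table.
#' @param follow_min How long to follow each pair (min).
#' @param from_time Only divisions after this time (min) are used.
#' @param strata Breaks over the outer sister's barrier count at birth.
#' @return List: `curves` (data frame time_since_division, stratum,
#'   mean_divergence, n), `rates` (per-stratum exponential rate of
#'   divergence growth, 1/min).
#' @export
sister_divergence <- function(tracks, follow_min = 30, from_time = 0,
                              strata = c(-1, 3, 6, 20)) {
  dt <- data.table::as.data.table(tracks)
  data.table::setorder(dt, trench_id, frame, cell_index)
  # birth frames: first appearance of each non-founder cell
  first <- dt[, list(birth_frame = min(frame)), by = "cell_id"]
  info <- merge(dt, first, by = "cell_id")
  births <- info[info$frame == info$birth_frame &
                   !is.na(info$parent_id) & info$time >= from_time, ]
  # pair daughters by parent (both born in the same frame)
  pairs <- births[, if (.N == 2)
    list(d1 = cell_id[1], d2 = cell_id[2]),
    by = c("parent_id", "frame")]
  # barrier count of the outer sister at birth
  dt[, n_in_trench := .N, by = c("trench_id", "frame")]
  dt[, B := n_in_trench - 1L - cell_index]
  binfo <- dt[, c("cell_id", "frame", "B", "reporter", "time"),
              with = FALSE]
  # parent intensity in its last frame
  last <- dt[, .SD[frame == max(frame)], by = "cell_id"]
  parent_int <- stats::setNames(last$reporter, last$cell_id)
  frame_int <- attr(tracks, "frame_interval")
  if (is.null(frame_int)) frame_int <- min(diff(sort(unique(dt$time))))
  nfollow <- ceiling(follow_min / frame_int)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k]
    i0 <- parent_int[as.character(p$parent_id)]
    if (!is.finite(i0) || abs(i0) < 1) next
    a <- binfo[binfo$cell_id == p$d1 & binfo$frame >= p$frame &
                 binfo$frame <= p$frame + nfollow, ]
    b <- binfo[binfo$cell_id == p$d2 & binfo$frame >= p$frame &
                 binfo$frame <= p$frame + nfollow, ]
    m <- merge(a, b, by = "frame")
    if (nrow(m) < 2) next
    rows[[length(rows) + 1]] <- data.frame(
      t_since = (m$frame - p$frame) * frame_int,
      divergence = abs(m$reporter.x - m$reporter.y) / abs(i0),
      B_outer = max(m$B.x[1], m$B.y[1])
    )
  }
  if (!length(rows))
    stop("sister_divergence: no sister pairs could be followed",
         call. = FALSE)
  div <- do.call(rbind, rows)
  div$stratum <- cut(div$B_outer, breaks = strata)
  agg <- stats::aggregate(divergence ~ t_since + stratum, div, mean)
  nn <- stats::aggregate(divergence ~ t_since + stratum, div, length)
  agg$n <- nn$divergence
  rates <- vapply(split(agg, agg$stratum), function(d) {
    d <- d[d$t_since > 0 & d$divergence > 0, ]
    if (nrow(d) < 3) return(NA_real_)
    unname(stats::coef(stats::lm(log(divergence) ~ t_since, d))[2])
  }, numeric(1))
  list(curves = agg, rates = rates)
}

#' Reporter decay versus growth after stress removal
#'
#' After treatment removal the reporter is produced only at the basal
#' rate and is diluted by growth, so the intensity decays exponentially
#' with a rate close to the cell's growth rate. Fits a per-mother
#' exponential decay rate and a contemporaneous area growth rate, and
#' compares the population half-life with the doubling time.
#'
#' @param tracks Track table of a run whose schedule ends before the
#'   last frame (e.g. a pulse).
#' @param removal_time Time (min) the stressor was removed.
#' @param window Fit window (min after removal), default 60.
#' @return List: `per_cell` (data frame: trench_id, decay_rate 1/min,
#'   growth_rate 1/min), `correlation` (Pearson, decay vs growth),
#'   `half_life` (min), `doubling_time` (min).
#' @export
decay_analysis <- function(tracks, removal_time, window = 60) {
  dt <- data.table::as.data.table(tracks)
  # basal intensity persists after removal, so the exponential decay
  # is fitted on the baseline-subtracted excess
  basal <- mean(dt$reporter[dt$time < 0])
  m <- dt[dt$cell_index == 0L & dt$time >= removal_time &
            dt$time <= removal_time + window, ]
  if (nrow(m) == 0)
    stop("decay_analysis: no frames after removal_time", call. = FALSE)
  fit_one <- function(d) {
    ex <- d$reporter - basal
    if (nrow(d) < 4 || any(ex <= 0) || any(d$area <= 0)) return(NULL)
    dec <- -stats::coef(stats::lm(log(ex) ~ d$time))[2]
    # growth rate from between-division increments: frames containing
    # a division (area roughly halves) are dropped, not zeroed, so
    # the elongation estimate stays unbiased
    dl <- diff(log(d$area)) / diff(d$time)
    dl <- dl[dl > -0.05]
    if (!length(dl)) return(NULL)
    gro <- mean(dl)
    data.frame(trench_id = d$trench_id[1], decay_rate = unname(dec),
               growth_rate = gro)
  }
  per <- do.call(rbind, lapply(split(m, m$trench_id), fit_one))
  if (is.null(per) || nrow(per) < 3)
    stop("decay_analysis: too few usable mother traces", call. = FALSE)
  ok <- is.finite(per$decay_rate) & is.finite(per$growth_rate)
  per <- per[ok, ]
  list(per_cell = per,
       correlation = stats::cor(per$decay_rate, per$growth_rate),
       half_life = log(2) / mean(per$decay_rate),
       doubling_time = log(2) / mean(per$growth_rate))
}

#' Classify mother-cell fate after stress removal
#'
#' A mother is dead if its rolling length growth rate stays below
#' `threshold` (default 0.012 per min) throughout `watch_hours` after
#' removal; otherwise it recovered, and the regrowth time is the first
#' time the rolling growth rate exceeds the threshold.
#'
#' @param time Frame times (min).
#' @param length Mother length series (um).
#' @param removal_time Stress removal time (min).
#' @param threshold Growth-rate threshold (1/min).
#' @param watch_hours Observation requirement (h); shorter series give
#'   fate `"undetermined"`.
#' @param roll_min Rolling fit window (min).
#' @return List: `fate` (`"recovered"`, `"dead"` or `"undetermined"`),
#'   `regrowth_time` (min after removal, `NA` if dead).
#' @export
classify_fate <- function(time, length, removal_time,
                          threshold = 0.012, watch_hours = 10,
                          roll_min = 30) {
  post <- time >= removal_time
  tt <- time[post]; ll <- length[post]
  if (length(tt) < 3 || max(tt) - removal_time < watch_hours * 60)
    return(list(fate = "undetermined", regrowth_time = NA_real_))
  dtf <- stats::median(diff(tt))
  k <- max(2L, ceiling(roll_min / dtf))
  n <- length(tt)
  # rolling growth rate: log-length slope over k-frame windows;
  # division drops are excluded by capping negative increments at 0
  dl <- pmax(diff(log(ll)), 0) / diff(tt)
  roll <- vapply(seq_len(n - k), function(i) mean(dl[i:(i + k - 1L)]),
                 numeric(1))
  above <- roll > threshold
  watch_idx <- which(tt[seq_along(roll)] <= removal_time +
                       watch_hours * 60)
  if (!any(above[watch_idx]))
    return(list(fate = "dead", regrowth_time = NA_real_))
  i <- which(above)[1]
  list(fate = "recovered",
       regrowth_time = tt[i] - removal_time)
}

#' Per-frame DNA mismatch rate and its post-treatment burst
#'
#' The mismatch rate is the total number of foci divided by the total
#' number of cells per frame, converted to per-minute units with the
#' frame interval. The burst amplitude is the peak of the
#' post-treatment rate minus the pre-treatment mean, computed per
#' barrier-count stratum (count at the treatment frame).
#'
#' @param tracks Track table with a `foci_count` column.
#' @param burst_window Window (min post-treatment) searched for the
#'   burst peak.
#' @param smooth Frames of the centred moving average applied to the
#'   rate series before peak extraction.
#' @return List: `rate` (data frame time, rate per cell per min),
#'   `burst_by_barrier` (data frame B, amplitude, n_cells).
#' @export
mismatch_rate <- function(tracks, burst_window = 60, smooth = 3) {
  dt <- data.table::as.data.table(tracks)
  if (!"foci_count" %in% names(dt))
    stop("mismatch_rate: foci_count column missing", call. = FALSE)
  frame_int <- attr(tracks, "frame_interval")
  if (is.null(frame_int)) frame_int <- min(diff(sort(unique(dt$time))))
  rate <- dt[, list(rate = sum(foci_count) / .N / frame_int),
             by = "time"]
  data.table::setorder(rate, time)
  # stratify every cell by the barrier count of its ancestor at the
  # treatment frame (descendants inherit the stratum through lineage)
  t0 <- min(dt$time[dt$time >= 0])
  dt[, n_in_trench := .N, by = c("trench_id", "frame")]
  dt[, B := n_in_trench - 1L - cell_index]
  at0 <- dt[dt$time == t0, ]
  b_at0 <- stats::setNames(at0$B, at0$cell_id)
  fam <- unique(dt[, c("cell_id", "parent_id"), with = FALSE])
  parent_of <- stats::setNames(fam$parent_id, fam$cell_id)
  # iterate parent lookups until every id resolves (or drops out)
  anc <- stats::setNames(fam$cell_id, fam$cell_id)
  for (i in 1:60) {
    unresolved <- !(as.character(anc) %in% names(b_at0)) & !is.na(anc)
    if (!any(unresolved)) break
    anc[unresolved] <- parent_of[as.character(anc[unresolved])]
  }
  strat_of <- b_at0[as.character(anc)]
  names(strat_of) <- names(anc)
  dt[, stratum := strat_of[as.character(cell_id)]]
  sm <- function(x) {
    if (smooth <= 1) return(x)
    stats::filter(x, rep(1 / smooth, smooth), sides = 2)
  }
  n_at0 <- table(at0$B)
  # pre-treatment baseline is genotype-wide (basal Poisson rate), so a
  # single global baseline serves every stratum
  pre_rate <- rate$rate[rate$time < 0]
  pre_mean <- if (length(pre_rate)) mean(pre_rate) else 0
  burst <- lapply(sort(unique(at0$B)), function(b) {
    sub <- dt[!is.na(dt$stratum) & dt$stratum == b & dt$time > 0, ]
    if (nrow(sub) < 4) return(NULL)
    rr <- sub[, list(rate = sum(foci_count) / .N / frame_int),
              by = "time"]
    data.table::setorder(rr, time)
    post <- as.numeric(sm(rr$rate))[rr$time <= burst_window]
    if (!sum(is.finite(post))) return(NULL)
    data.frame(B = b,
               amplitude = max(post, na.rm = TRUE) - pre_mean,
               n_cells = as.integer(n_at0[as.character(b)]))
  })
  list(rate = as.data.frame(rate),
       burst_by_barrier = do.call(rbind, burst))
}
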