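#' Surface-area-to-volume ratio of a capsule-shaped cell
#'
#' A cell is modelled as a cylinder capped by two hemispheres whose
#' radius follows from the projected area convention `A = 2 r L`. The
#' exact surface-to-volume ratio of that solid is
#' `12 L^3 / (A (3 L^2 - A))`, equivalently `6L / (r (3L - 2r))` with
#' `r = A / (2L)`.
#'
#' @param L Cell length (um), positive.
#' @param A Projected cell area (um^2); must satisfy `0 < A < 3 L^2`.
#' @return Surface-to-volume ratio (1/um).
#' @export
surface_to_volume <- function(L, A) {
  if (any(!is.finite(L)) || any(!is.finite(A)) ||
      any(L <= 0) || any(A <= 0))
    stop("surface_to_volume: L and A must be positive and finite",
         call. = FALSE)
  if (any(A >= 3 * L^2))
    stop("surface_to_volume: A must be < 3 L^2 (radius below 3L/2)",
         call. = FALSE)
  12 * L^3 / (A * (3 * L^2 - A))
}

#' Log-difference elongation rate
#'
#' `(ln L_t - ln L_{t-1}) / dt`, the per-minute exponential elongation
#' rate between consecutive frames; undefined (NA) at series starts.
#'
#' @param lengths Cell length series on the frame grid (um).
#' @param dt Frame interval (min).
#' @return Numeric vector of the same length; first element `NA`.
#' @export
elongation_rate_log <- function(lengths, dt) {
  if (any(lengths <= 0, na.rm = TRUE))
    stop("elongation_rate_log: lengths must be positive", call. = FALSE)
  c(NA_real_, diff(log(lengths))) / dt
}

#' Per-frame first-difference rates
#'
#' Instantaneous rates as plain first differences per frame:
#' `beta_t = l_t - l_{t-1}` and `rho_t = A_t - A_{t-1}` (per-frame
#' units), the convention used in the feature matrix.
#'
#' @param x Numeric series on the frame grid.
#' @return Vector of the same length; first element `NA`.
#' @export
frame_difference <- function(x) {
  c(NA_real_, diff(x))
}

#' Barrier statistics for a focal cell in one trench frame
#'
#' Barrier cells are the cells located between the focal cell and the
#' open end of the trench. Returns their count and the sums of their
#' lengths, areas and surface-to-volume ratios. The mother cell (index
#' 0) of an n-cell trench has `n - 1` barriers; the outermost cell has
#' none.
#'
#' @param frame_records Data frame of one trench at one frame with
#'   columns `cell_index`, `length`, `area`.
#' @param focal_index `cell_index` (0-based from the closed end) of the
#'   focal cell.
#' @return Named list: `n_barrier`, `sum_length`, `sum_area`, `sum_sav`.
#' @export
barrier_stats <- function(frame_records, focal_index) {
  if (!focal_index %in% frame_records$cell_index)
    stop("barrier_stats: focal cell index ", focal_index,
         " absent from frame", call. = FALSE)
  sel <- frame_records$cell_index > focal_index
  list(
    n_barrier = sum(sel),
    sum_length = sum(frame_records$length[sel]),
    sum_area = sum(frame_records$area[sel]),
    sum_sav = if (any(sel))
      sum(surface_to_volume(frame_records$length[sel],
                            frame_records$area[sel]))
      else 0
  )
}

#' Window summary statistics for feature construction
#'
#' The seven statistics computed over each series window: population
#' kurtosis `n * sum(d^4) / (sum(d^2))^2`, nonparametric skewness
#' `(mean - median) / population SD`, median, mean, minimum, maximum,
#' and range. Constant windows return kurtosis and skewness of 0 by
#' convention.
#'
#' @param y Numeric window, length >= 4; NAs are dropped.
#' @return Named numeric vector
#'   `c(kurtosis, skew, median, mean, min, max, range)`.
#' @export
summary_stats <- function(y) {
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 4)
    stop("summary_stats: window must contain at least 4 finite values",
         call. = FALSE)
  m <- sum(y) / n
  d <- y - m
  ss2 <- sum(d^2)
  md <- stats::median(y)
  if (ss2 < .Machine$double.eps * n * max(1, m^2)) {
    kur <- 0; skw <- 0
  } else {
    kur <- n * sum(d^4) / ss2^2
    skw <- (m - md) / sqrt(ss2 / n)
  }
  c(kurtosis = kur, skew = skw, median = md, mean = m,
    min = min(y), max = max(y), range = max(y) - min(y))
}

#' Response label: post-treatment reporter peak over baseline
#'
#' The label predicted by the regression model: the maximum reporter
#' intensity in the window (0, 60] min after treatment start, minus the
#' mean intensity over all pre-treatment frames.
#'
#' @param time Frame times (min), treatment starting at 0.
#' @param reporter Reporter intensity series (a.u.).
#' @param window Post-treatment window (min) searched for the peak.
#' @return Peak amplitude (a.u.).
#' @export
response_label <- function(time, reporter, window = 60) {
  pre <- time < 0
  post <- time > 0 & time <= window
  if (!any(pre) || !any(post))
    stop("response_label: series must span pre-treatment and (0, ",
         window, "] min", call. = FALSE)
  max(reporter[post]) - mean(reporter[pre])
}

#' Names and grouping of the feature matrix columns
#'
#' The 126 features are every combination of 7 statistics x 9 series x
#' 2 epochs. Mother series: length, area, per-frame elongation rate,
#' per-frame area rate, surface-to-volume ratio. Environment series:
#' barrier-cell count, cumulative barrier length, area and
#' surface-to-volume. Epochs: `untreated` = [-135, 0) min and `treated`
#' = [0, 135) min relative to treatment start.
#'
#' @return Data frame with columns `feature`, `series`, `stat`, `epoch`,
#'   and `group` (`mother` or `barrier`).
#' @export
feature_manifest <- function() {
  stats <- c("kurtosis", "skew", "median", "mean", "min", "max", "range")
  series <- c(mother_length = "mother", mother_area = "mother",
              mother_elong_rate = "mother", mother_area_rate = "mother",
              mother_sav = "mother",
              barrier_count = "barrier", barrier_cum_length = "barrier",
              barrier_cum_area = "barrier", barrier_cum_sav = "barrier")
  epochs <- c("untreated", "treated")
  grid <- expand.grid(stat = stats, series = names(series),
                      epoch = epochs, stringsAsFactors = FALSE)
  data.frame(
    feature = paste(grid$series, grid$stat, grid$epoch, sep = "."),
    series = grid$series, stat = grid$stat, epoch = grid$epoch,
    group = unname(series[grid$series]),
    stringsAsFactors = FALSE
  )
}

#' Build the mother-cell feature matrix
#'
#' For every trench, the mother cell (the cell at the closed end,
#' `cell_index` 0) is summarised by 126 features: the 7 window
#' statistics of [summary_stats()] applied to 9 per-frame series (5
#' describing the mother itself, 4 describing the barrier cells between
#' it and the open end) in the untreated `[-135, 0)` and treated
#' `[0, 135)` epochs, plus the response label of [response_label()].
#' Mothers whose track does not cover both epochs completely are
#' dropped.
#'
#' @param tracks A track table from [simulate_trenches()] or
#'   [read_tracks()].
#' @param label_window Post-treatment window (min) for the peak label.
#' @param epoch_span Epoch half-width (min); epochs are
#'   `[-epoch_span, 0)` and `[0, epoch_span)`.
#' @return Data frame of class `feature_matrix`: one row per retained
#'   mother, metadata columns (`trench_id`, `external_c0`), 126 feature
#'   columns, and the label column `grxa_peak`. The feature manifest is
#'   attached as attribute `manifest`.
#' @export
build_feature_matrix <- function(tracks, label_window = 60,
                                 epoch_span = 135) {
  dt <- data.table::as.data.table(tracks)
  need <- c("trench_id", "frame", "time", "cell_index", "length", "area",
            "reporter")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("build_feature_matrix: missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  # per-trench, per-frame barrier sums for the mother (index 0)
  time <- cell_index <- trench_id <- area <- reporter <- NULL
  frame <- external_c0 <- NULL
  dt <- dt[time >= -epoch_span & time < epoch_span]
  dt[, `:=`(sav = surface_to_volume(length, area))]
  env <- dt[cell_index > 0L,
            .(barrier_count = .N, barrier_cum_length = sum(length),
              barrier_cum_area = sum(area), barrier_cum_sav = sum(sav)),
            by = .(trench_id, frame, time)]
  mom <- dt[cell_index == 0L,
            .(trench_id, frame, time, mother_length = length,
              mother_area = area, mother_sav = sav, reporter,
              external_c0 = if ("external_c0" %in% names(dt))
                external_c0 else NA_real_)]
  ser <- merge(mom, env, by = c("trench_id", "frame", "time"),
               all.x = TRUE)
  # a mother alone in its trench has zero barriers, not missing ones
  for (cc in c("barrier_count", "barrier_cum_length", "barrier_cum_area",
               "barrier_cum_sav"))
    data.table::set(ser, which(is.na(ser[[cc]])), cc, 0)
  data.table::setorder(ser, trench_id, frame)
  ser[, `:=`(mother_elong_rate = frame_difference(mother_length),
             mother_area_rate = frame_difference(mother_area)),
      by = trench_id]

  man <- feature_manifest()
  frames_per_epoch <- length(unique(ser$time[ser$time >= 0]))
  pre_frames <- length(unique(ser$time[ser$time < 0]))
  series_names <- unique(man$series)
  one_mother <- function(d) {
    if (nrow(d) < frames_per_epoch + pre_frames) return(NULL)
    out <- numeric(0)
    for (ep in c("untreated", "treated")) {
      idx <- if (ep == "untreated") d$time < 0 else d$time >= 0
      for (sn in series_names) {
        y <- d[[sn]][idx]
        # rate series lose their first value at the epoch boundary
        y <- y[is.finite(y)]
        if (length(y) < 4) return(NULL)
        out <- c(out, summary_stats(y))
      }
    }
    out
  }
  split_ser <- split(ser, ser$trench_id)
  rows <- lapply(split_ser, one_mother)
  keep <- !vapply(rows, is.null, logical(1))
  n_drop <- sum(!keep)
  if (!any(keep))
    stop("build_feature_matrix: no mother cell covers both epochs",
         call. = FALSE)
  feat <- do.call(rbind, rows[keep])
  # build order (epoch outer, series, then the 7 stats) matches the
  # manifest's expand.grid order exactly
  colnames(feat) <- man$feature
  ids <- names(split_ser)[keep]
  lab <- vapply(split_ser[keep], function(d)
    response_label(d$time, d$reporter, label_window), numeric(1))
  c0 <- vapply(split_ser[keep], function(d)
    d$external_c0[which.max(d$time)], numeric(1))
  fm <- data.frame(trench_id = ids, external_c0 = c0,
                   feat, grxa_peak = lab,
                   row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (n_drop > 0)
    message("build_feature_matrix: dropped ", n_drop,
            " mother(s) with incomplete epoch coverage")
  attr(fm, "manifest") <- man
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Feature columns of a feature matrix
#' @param fm A `feature_matrix`.
#' @return Character vector of the 126 feature column names.
#' @export
feature_columns <- function(fm) {
  attr(fm, "manifest")$feature
}
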