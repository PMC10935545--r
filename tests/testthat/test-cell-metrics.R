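test_that("surface_to_volume equals the capsule geometry oracle", {
  # oracle: SA/V of a hemisphere-capped cylinder via r = A / (2L)
  oracle <- function(L, A) {
    r <- A / (2 * L)
    (2 * pi * r * L) / (pi * r^2 * (L - 2 * r) + 4 / 3 * pi * r^3)
  }
  expect_equal(surface_to_volume(2.6, 2.6), oracle(2.6, 2.6))
  expect_equal(surface_to_volume(2.6, 2.6), 4.588, tolerance = 1e-3)
  # sphere limit: r = L/2 gives SA/V = 3/r
  expect_equal(surface_to_volume(1, 1), 6)
  set.seed(3)
  L <- runif(100, 1, 5); A <- 2 * runif(100, 0.3, 0.6) * L
  expect_equal(surface_to_volume(L, A), oracle(L, A),
               tolerance = 1e-12)
  expect_error(surface_to_volume(1, 3), "3 L")
  expect_error(surface_to_volume(-1, 1), "positive")
})

test_that("rate series match their difference oracles", {
  expect_equal(elongation_rate_log(c(2, 2, 2), 3), c(NA, 0, 0))
  expect_equal(elongation_rate_log(c(2, 4), 3)[2], log(2) / 3)
  expect_error(elongation_rate_log(c(2, -1), 3), "positive")
  set.seed(4)
  x <- exp(cumsum(rnorm(50, 0.02, 0.01)))
  expect_equal(elongation_rate_log(x, 3)[-1], diff(log(x)) / 3)
  expect_equal(frame_difference(c(5, 5, 5)), c(NA, 0, 0))
  expect_equal(frame_difference(seq(0, 10, by = 2))[-1], rep(2, 5))
  y <- rnorm(30)
  expect_equal(frame_difference(y)[-1], diff(y))
})

test_that("barrier_stats sums cells between focal cell and open end", {
  fr <- data.frame(cell_index = 0:7, length = seq(2, 3.4, by = 0.2))
  fr$area <- fr$length * 1.0
  # outermost cell has no barriers
  expect_equal(barrier_stats(fr, 7),
               list(n_barrier = 0L, sum_length = 0, sum_area = 0,
                    sum_sav = 0), tolerance = 1e-12)
  # the mother of an 8-cell trench has 7 barriers
  m <- barrier_stats(fr, 0)
  expect_equal(m$n_barrier, 7L)
  expect_equal(m$sum_length, sum(fr$length[-1]))
  expect_equal(m$sum_sav, sum(surface_to_volume(fr$length[-1],
                                                fr$area[-1])))
  # brute-force accumulation for every focal cell
  for (i in fr$cell_index) {
    got <- barrier_stats(fr, i)
    sel <- fr$cell_index > i
    expect_equal(got$sum_area, sum(fr$area[sel]))
  }
  expect_error(barrier_stats(fr, 12), "absent")
})

test_that("summary_stats equals a naive reference to 1e-12", {
  naive <- function(y) {
    n <- length(y); m <- mean(y); d <- y - m
    c(kurtosis = n * sum(d^4) / sum(d^2)^2,
      skew = (m - median(y)) / sqrt(sum(d^2) / n),
      median = median(y), mean = m, min = min(y), max = max(y),
      range = max(y) - min(y))
  }
  # constant window: kurtosis and skew are 0 by convention
  expect_equal(summary_stats(rep(3, 10)),
               c(kurtosis = 0, skew = 0, median = 3, mean = 3,
                 min = 3, max = 3, range = 0))
  # symmetric window: zero skew
  expect_equal(unname(summary_stats(c(1, 2, 3, 2))["skew"]), 0)
  # hand-computed 4-point case
  y <- c(0, 0, 0, 1)
  d <- y - 0.25
  expect_equal(unname(summary_stats(y)["kurtosis"]),
               4 * sum(d^4) / sum(d^2)^2)
  set.seed(5)
  for (i in 1:20) {
    y <- rnorm(sample(4:60, 1))
    expect_equal(summary_stats(y), naive(y), tolerance = 1e-12)
  }
  expect_error(summary_stats(c(1, 2, 3)), "at least 4")
})

test_that("response_label is peak minus pre-treatment mean", {
  tt <- seq(-30, 90, by = 3)
  flat <- rep(100, length(tt))
  expect_equal(response_label(tt, flat), 0)
  stepped <- ifelse(tt >= 30, 100 + 55, 100)
  expect_equal(response_label(tt, stepped), 55)
  set.seed(6)
  y <- 100 + cumsum(rnorm(length(tt)))
  expect_equal(response_label(tt, y),
               max(y[tt > 0 & tt <= 60]) - mean(y[tt < 0]))
  expect_error(response_label(tt[tt > 0], y[tt > 0]), "span")
})

test_that("the feature matrix has exactly 126 stable columns", {
  man <- feature_manifest()
  expect_equal(nrow(man), 126)
  expect_equal(sum(man$group == "barrier"), 56)  # 7 x 4 x 2
  expect_equal(sum(man$group == "mother"), 70)   # 7 x 5 x 2
  fm <- build_feature_matrix(small_run())
  expect_equal(sum(names(fm) %in% man$feature), 126)
  expect_identical(feature_columns(fm), man$feature)
  expect_false(anyNA(fm[, man$feature]))
  expect_false(anyNA(fm$grxa_peak))
  # column names stable across runs
  fm2 <- build_feature_matrix(small_run())
  expect_identical(names(fm), names(fm2))
})

test_that("feature rows match long-hand computation on a fixture", {
  tt <- toy_tracks(n_frames = 10, frame_interval = 3, t_min = -15)
  fm <- build_feature_matrix(tt, label_window = 12, epoch_span = 15)
  expect_equal(nrow(fm), 2)
  r1 <- fm[fm$trench_id == "1", ]
  # trench 1 mother: constant length 2, constant barrier sums
  expect_equal(r1$mother_length.mean.untreated, 2)
  expect_equal(r1$mother_length.range.treated, 0)
  expect_equal(r1$barrier_count.median.treated, 2)
  expect_equal(r1$barrier_cum_length.mean.untreated, 2.1 + 2.2)
  expect_equal(r1$barrier_cum_sav.mean.treated,
               sum(surface_to_volume(c(2.1, 2.2), c(2.1, 2.2))))
  expect_equal(r1$mother_elong_rate.mean.treated, 0)
  # label: flat reporter gives zero amplitude
  expect_equal(r1$grxa_peak, 0)
  # barrier sums are permutation-safe: shuffle rows, same matrix
  set.seed(8)
  shuffled <- tt[sample(nrow(tt)), ]
  fmS <- build_feature_matrix(shuffled, label_window = 12,
                              epoch_span = 15)
  fmS <- fmS[order(fmS$trench_id), ]
  expect_equal(as.data.frame(fmS), as.data.frame(fm),
               tolerance = 1e-12)
})
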