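# Shared fixtures: built once per test run, cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small standard treated run used by several io/metrics tests
small_run <- function() fixture("small_run", function() {
  cfg <- sim_config(n_trenches = 15, seed = 101)
  simulate_trenches(cfg, treatment_schedule(0, 135, 100,
                                            t_min = -135, t_max = 135))
})

# deterministic hand-built track table: 2 trenches, constant cells
toy_tracks <- function(n_frames = 12, frame_interval = 3,
                       t_min = -9) {
  rows <- list()
  for (f in seq_len(n_frames) - 1L) {
    tme <- t_min + f * frame_interval
    for (tr in 1:2) {
      n <- 2 + tr            # trench 1: 3 cells, trench 2: 4 cells
      for (i in seq_len(n) - 1L) {
        L <- 2 + 0.1 * i
        rows[[length(rows) + 1L]] <- data.frame(
          trench_id = tr, frame = f, time = tme, cell_index = i,
          cell_id = tr * 100L + i, lineage_id = tr * 100L + i,
          parent_id = NA_integer_, genotype = "WT",
          length = L, area = L, position = i * 2.7,
          reporter = 100 + 10 * i, marker = 500, foci_count = 0L,
          alive = TRUE, external_c0 = ifelse(tme >= 0, 100, 0))
      }
    }
  }
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "frame_interval", frame_interval)
  out
}
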