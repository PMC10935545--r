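TRACK_SCHEMA_VERSION <- "1.0"

TRACK_COLUMNS <- c(
  "trench_id", "frame", "time", "cell_index", "cell_id", "lineage_id",
  "parent_id", "genotype", "length", "area", "position", "reporter",
  "marker", "foci_count", "alive", "external_c0"
)

#' Write a track table to CSV
#'
#' Deterministic plain-text serialisation: '#'-prefixed header lines
#' carry the schema version, seed and config digest, followed by a CSV
#' body in a fixed column order, sorted by (trench, frame, cell index),
#' floats at fixed precision. Missing values are written as empty
#' fields. Two writes of the same table are byte-identical.
#'
#' @param tracks Track table.
#' @param path Output file path.
#' @param digits Significant digits for floating-point columns.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, digits = 6) {
  dt <- data.table::as.data.table(tracks)
  miss <- setdiff(TRACK_COLUMNS, names(dt))
  if (length(miss))
    stop("write_tracks: missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  dt <- dt[, TRACK_COLUMNS, with = FALSE]
  data.table::setorder(dt, trench_id, frame, cell_index)
  num <- c("time", "length", "area", "position", "reporter", "marker",
           "external_c0")
  for (cc in num)
    data.table::set(dt, j = cc,
                    value = signif(dt[[cc]], digits))
  hdr <- c(
    paste0("# track_schema: ", TRACK_SCHEMA_VERSION),
    paste0("# seed: ", attr(tracks, "seed") %||% NA),
    paste0("# config_digest: ", attr(tracks, "config_digest") %||% NA),
    paste0("# frame_interval: ",
           attr(tracks, "frame_interval") %||% NA)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(dt, con, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a track table from CSV
#'
#' Parses a file written by [write_tracks()], restoring types,
#' attributes and row order, and validates the result (see
#' [validate_tracks()]); structural violations raise an error naming
#' the offending rows.
#'
#' @param path File path.
#' @param validate Run [validate_tracks()] and fail on violations.
#' @return A track table (`data.table`).
#' @export
read_tracks <- function(path, validate = TRUE) {
  if (!file.exists(path))
    stop("read_tracks: no such file: ", path, call. = FALSE)
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  ver <- meta("track_schema")
  if (is.null(ver) || ver != TRACK_SCHEMA_VERSION)
    stop("read_tracks: unsupported or missing schema version (",
         ver %||% "none", ")", call. = FALSE)
  dt <- data.table::fread(path, skip = length(hdr), sep = ",",
                          header = TRUE, na.strings = "")
  miss <- setdiff(TRACK_COLUMNS, names(dt))
  if (length(miss))
    stop("read_tracks: missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  data.table::setcolorder(dt, TRACK_COLUMNS)
  data.table::setorder(dt, trench_id, frame, cell_index)
  for (a in c("seed", "frame_interval")) {
    v <- suppressWarnings(as.numeric(meta(a)))
    if (!is.na(v)) data.table::setattr(dt, a, v)
  }
  dg <- meta("config_digest")
  if (!is.null(dg) && dg != "NA")
    data.table::setattr(dt, "config_digest", dg)
  if (validate) {
    rep <- validate_tracks(dt)
    if (nrow(rep))
      stop("read_tracks: validation failed:\n",
           paste(utils::capture.output(print(rep)), collapse = "\n"),
           call. = FALSE)
  }
  dt
}

#' Validate the structural invariants of a track table
#'
#' Checks that (trench, frame, cell_index) is unique, cell indices per
#' frame are consecutive from 0, positions are ordered and
#' non-overlapping, the time grid has no gaps, times equal
#' `t0 + frame * frame_interval`, and every daughter's `parent_id`
#' refers to a cell present in an earlier frame.
#'
#' @param tracks Track table.
#' @return Data frame of violations (`rule`, `detail`); zero rows when
#'   all invariants hold.
#' @export
validate_tracks <- function(tracks) {
  dt <- data.table::as.data.table(tracks)
  if (nrow(dt) == 0)
    return(data.frame(rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  bad <- list()
  note <- function(rule, detail)
    bad[[length(bad) + 1]] <<- data.frame(rule = rule, detail = detail,
                                          stringsAsFactors = FALSE)
  dup <- dt[, .N, by = c("trench_id", "frame", "cell_index")]
  if (any(dup$N > 1)) {
    d <- dup[dup$N > 1][1]
    note("duplicate_key", sprintf("trench %s frame %s index %s",
                                  d$trench_id, d$frame, d$cell_index))
  }
  idx <- dt[, list(ok = all(sort(cell_index) == seq_len(.N) - 1L)),
            by = c("trench_id", "frame")]
  if (any(!idx$ok)) {
    d <- idx[!idx$ok][1]
    note("index_gap", sprintf("trench %s frame %s", d$trench_id,
                              d$frame))
  }
  ord <- dt[order(trench_id, frame, cell_index),
            list(ok = .N < 2 || (all(diff(position) > 0) &&
              all(position[-1] >= (position + length)[-.N] - 1e-6)),
              n = .N),
            by = c("trench_id", "frame")]
  if (any(!ord$ok)) {
    d <- ord[!ord$ok][1]
    note("overlap_or_disorder", sprintf("trench %s frame %s",
                                        d$trench_id, d$frame))
  }
  fr <- sort(unique(dt$frame))
  if (length(fr) > 1 && !identical(fr, seq(fr[1], fr[length(fr)])))
    note("frame_gap", paste("missing frames:",
                            paste(setdiff(seq(fr[1], fr[length(fr)]),
                                          fr), collapse = ",")))
  tg <- unique(dt[, c("frame", "time"), with = FALSE])
  if (nrow(tg) > 2) {
    fitint <- stats::coef(stats::lm(time ~ frame, tg))[2]
    if (max(abs(tg$time - (min(tg$time) +
                             (tg$frame - min(tg$frame)) * fitint))) >
        1e-6)
      note("time_grid", "time is not frame * frame_interval + t0")
  }
  # lineage: every parent_id must exist as a cell_id in a prior frame
  kids <- dt[!is.na(dt$parent_id), ]
  if (nrow(kids)) {
    first <- dt[, list(f0 = min(frame)), by = "cell_id"]
    born <- merge(kids[, list(f0 = min(frame),
                              parent_id = parent_id[1]),
                       by = "cell_id"],
                  first, by.x = "parent_id", by.y = "cell_id",
                  all.x = TRUE, suffixes = c("", "_parent"))
    dangling <- born[is.na(born$f0_parent) | born$f0_parent >= born$f0]
    if (nrow(dangling))
      note("dangling_lineage",
           paste("cell_ids:", paste(utils::head(dangling$cell_id, 5),
                                    collapse = ",")))
  }
  if (!length(bad))
    return(data.frame(rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, bad)
}
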