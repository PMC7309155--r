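#' Read a participant IMU recording from CSV
#'
#' Reads one six-channel recording. The file has a header row naming the
#' seven columns `t, a_ml, a_v, a_ap, w_ml, w_v, w_ap` and may start with
#' `#` comment lines; the first comment line can declare units and rate,
#' e.g. `# unit_accel=g rate_hz=100`. Accelerations declared in g are
#' converted to m/s^2 (factor 9.80665) so that all downstream indices are
#' on the reported scale.
#'
#' Missing values are rejected by default with the offending row indices;
#' with `na_action = "interpolate"`, gaps of at most `max_gap` consecutive
#' samples (50 ms at 100 Hz) are filled linearly, longer gaps still error.
#'
#' @param path Path to the CSV file.
#' @param sampling_rate Sampling rate in Hz. Defaults to the header's
#'   `rate_hz`, else the inverse median time step.
#' @param na_action `"error"` (default) or `"interpolate"`.
#' @param max_gap Longest interpolatable run of missing samples.
#' @return An [imu_series()].
#' @export
read_imu_csv <- function(path, sampling_rate = NULL,
                         na_action = c("error", "interpolate"),
                         max_gap = 5L) {
  na_action <- match.arg(na_action)
  hdr <- character()
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(trimws(ln), "#")) break
    hdr <- c(hdr, ln)
  }
  meta <- parse_imu_header(hdr)
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("t", imu_channels())
  missing <- setdiff(need, names(dat))
  if (length(missing)) {
    abort(sprintf("IMU file %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "gaitrisk_format_error")
  }
  dat <- dat[need]
  bad_rows <- which(!stats::complete.cases(dat) |
                      !apply(is.finite(as.matrix(dat)), 1, all))
  if (length(bad_rows)) {
    if (na_action == "error") {
      abort(sprintf("missing/non-finite values at row(s) %s of %s",
                    paste(head(bad_rows, 10), collapse = ", "), path),
            class = "gaitrisk_na_error")
    }
    dat <- interpolate_gaps(dat, bad_rows, max_gap, path)
  }
  if (is.null(sampling_rate)) {
    sampling_rate <- meta$rate_hz %||% (1 / median(diff(dat$t)))
  }
  if (identical(meta$unit_accel, "g")) {
    for (cl in c("a_ml", "a_v", "a_ap")) {
      dat[[cl]] <- dat[[cl]] * standard_gravity()
    }
  }
  imu_series(a_ml = dat$a_ml, a_v = dat$a_v, a_ap = dat$a_ap,
             w_ml = dat$w_ml, w_v = dat$w_v, w_ap = dat$w_ap,
             sampling_rate = sampling_rate, t = dat$t)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_imu_header <- function(lines) {
  out <- list(unit_accel = "ms2", rate_hz = NULL)
  for (ln in lines) {
    toks <- strsplit(gsub("^#\\s*", "", ln), "[ ,;]+")[[1]]
    kv <- strsplit(toks, "=")
    for (p in kv) {
      if (length(p) == 2 && p[1] == "unit_accel") out$unit_accel <- p[2]
      if (length(p) == 2 && p[1] == "rate_hz") out$rate_hz <- as.numeric(p[2])
    }
  }
  if (!out$unit_accel %in% c("g", "ms2")) {
    abort(sprintf("unknown unit_accel '%s' (expected g or ms2)",
                  out$unit_accel), class = "gaitrisk_format_error")
  }
  out
}

interpolate_gaps <- function(dat, bad_rows, max_gap, path) {
  runs <- split(bad_rows, cumsum(c(1, diff(bad_rows) != 1)))
  too_long <- map_int(runs, length) > max_gap
  if (any(too_long)) {
    abort(sprintf("gap of > %d consecutive missing samples in %s (rows %s)",
                  max_gap, path,
                  paste(head(runs[too_long][[1]], 3), collapse = ", ")),
          class = "gaitrisk_na_error")
  }
  idx <- seq_len(nrow(dat))
  for (cl in imu_channels()) {
    y <- dat[[cl]]
    y[bad_rows] <- NA_real_
    ok <- is.finite(y)
    if (!ok[1] || !ok[length(y)]) {
      abort(sprintf("cannot interpolate missing samples at the edge of %s",
                    path), class = "gaitrisk_na_error")
    }
    dat[[cl]] <- approx(idx[ok], y[ok], xout = idx)$y
  }
  # time column: rebuild from surrounding stamps
  tt <- dat$t
  tt[bad_rows] <- NA_real_
  ok <- is.finite(tt)
  dat$t <- approx(idx[ok], tt[ok], xout = idx)$y
  dat
}

#' Write a participant IMU recording to CSV
#'
#' Inverse of [read_imu_csv()]: emits a `#` metadata comment line
#' (`unit_accel`, `rate_hz`) followed by the seven-column CSV body at full
#' double precision, so a read/write round trip is lossless to well below
#' 1e-9 in every channel.
#'
#' @param series An [imu_series()].
#' @param path Output path.
#' @param unit_accel `"ms2"` (default, values written as stored) or `"g"`
#'   (accelerations divided by 9.80665 on output).
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(series, path, unit_accel = c("ms2", "g")) {
  unit_accel <- match.arg(unit_accel)
  validate_imu_series(series)
  dat <- tibble::as_tibble(series)
  if (unit_accel == "g") {
    for (cl in c("a_ml", "a_v", "a_ap")) {
      dat[[cl]] <- dat[[cl]] / standard_gravity()
    }
  }
  hdr <- sprintf("# unit_accel=%s rate_hz=%.10g", unit_accel, imu_rate(series))
  writeLines(hdr, path)
  readr::write_csv(dat, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Split an IMU recording into fixed-duration frames
#'
#' Frames start at `0, step_s, 2*step_s, ...`; the last frame is the last
#' start time with `start + window_s <= duration`. Frames that would run
#' past the end are dropped (no padding), so the frame count is
#' `floor((duration - window) / step) + 1`. Overlapping frames
#' (`step_s < window_s`) are used to augment CNN training data; test
#' recordings use non-overlapping frames (`step_s = window_s`).
#'
#' @param series An [imu_series()].
#' @param window_s Frame duration, seconds (default 20).
#' @param step_s Step between frame starts, seconds (default `window_s`).
#' @param participant_id,label Carried into the output columns (the label
#'   is the participant's faller status, inherited by every frame).
#' @return A tibble with columns `participant_id`, `start_time`,
#'   `duration`, `data` (list of 6 x samples matrices, rows in channel
#'   order `a_ml, a_v, a_ap, w_ml, w_v, w_ap`), `label`. Zero rows plus a
#'   warning when the window exceeds the recording.
#' @export
#' @examples
#' s <- imu_series(a_ml = rnorm(6000), a_v = rnorm(6000), a_ap = rnorm(6000),
#'                 w_ml = rnorm(6000), w_v = rnorm(6000), w_ap = rnorm(6000))
#' nrow(split_frames(s, window_s = 20, step_s = 10))  # 5 frames
split_frames <- function(series, window_s = 20, step_s = window_s,
                         participant_id = NA_character_, label = NA_integer_) {
  validate_imu_series(series)
  stopifnot(step_s > 0, window_s > 0)
  rate <- imu_rate(series)
  dur <- imu_duration(series)
  wlen <- as.integer(round(window_s * rate))
  slen <- step_s * rate
  if (window_s > dur) {
    warn(sprintf("window (%g s) longer than recording (%g s); no frames",
                 window_s, dur))
    return(tibble(participant_id = character(), start_time = numeric(),
                  duration = numeric(), data = list(), label = integer()))
  }
  n_frames <- floor((dur - window_s) / step_s + 1e-9) + 1
  starts <- (seq_len(n_frames) - 1) * step_s
  mat <- t(as.matrix(tibble::as_tibble(series)[imu_channels()]))
  frames <- map(starts, function(s0) {
    i0 <- as.integer(round(s0 * rate)) + 1L
    mat[, i0:(i0 + wlen - 1L), drop = FALSE]
  })
  tibble(participant_id = participant_id, start_time = starts,
         duration = window_s, data = frames, label = label)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `participant_id, tug_s, faller,
#' imu_path`; `imu_path` is interpreted relative to the manifest location.
#'
#' @param path Manifest CSV path.
#' @return A tibble with the four columns, `imu_path` made absolute.
#' @export
read_cohort_manifest <- function(path) {
  man <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "tug_s", "faller", "imu_path")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    abort(sprintf("manifest is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "gaitrisk_format_error")
  }
  base <- dirname(normalizePath(path))
  man %>%
    mutate(participant_id = as.character(.data$participant_id),
           faller = as.integer(.data$faller),
           imu_path = ifelse(file.path(base, .data$imu_path) == .data$imu_path |
                               grepl("^(/|[A-Za-z]:)", .data$imu_path),
                             .data$imu_path,
                             file.path(base, .data$imu_path)))
}

#' Load a full cohort (manifest + recordings) into memory
#'
#' @param manifest A manifest tibble from [read_cohort_manifest()] or a
#'   path to the manifest CSV.
#' @param ... Passed to [read_imu_csv()].
#' @return A cohort tibble: `participant_id`, `tug_s`, `faller`, `series`
#'   (list column of [imu_series()]).
#' @export
load_cohort <- function(manifest, ...) {
  if (is.character(manifest)) manifest <- read_cohort_manifest(manifest)
  manifest %>%
    mutate(series = map(.data$imu_path, read_imu_csv, ...)) %>%
    select("participant_id", "tug_s", "faller", "series")
}

#' Write a cohort to per-participant CSVs plus a manifest
#'
#' @param cohort A cohort tibble (`participant_id`, `tug_s`, `faller`,
#'   `series` list column), e.g. from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("%s.csv", cohort$participant_id)
  purrr::walk2(cohort$series, file.path(dir, paths), write_imu_csv)
  man <- cohort %>%
    select("participant_id", "tug_s", "faller") %>%
    mutate(imu_path = paths)
  mp <- file.path(dir, "manifest.csv")
  readr::write_csv(man, mp)
  invisible(mp)
}
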