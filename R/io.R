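#' Read an infusion/loss schedule from CSV
#'
#' The file must have columns `time_min`, `u_ml_per_min`, `v_ml_per_min`.
#' Each row starts a segment whose rates hold until the next row's time;
#' the final row marks the end of the study (its time is the duration and
#' its rates are ignored). A minimal file therefore has two rows.
#'
#' @param path Path to a CSV file.
#' @param unit Volume unit of the rate columns: `"ml"` (default) or `"l"`
#'   (converted to ml on read).
#' @return A [fluid_schedule()].
#' @export
read_schedule <- function(path, unit = c("ml", "l")) {
  unit <- arg_match(unit)
  df <- read_checked(path, c("time_min", "u_ml_per_min", "v_ml_per_min"))
  if (nrow(df) < 2L) {
    stop_fluidshift("A schedule file needs at least two rows (segment start and study end).",
                    class = "parse")
  }
  check_increasing(df$time_min, path, "time_min")
  if (any(df$u_ml_per_min < 0) || any(df$v_ml_per_min < 0)) {
    bad <- which(df$u_ml_per_min < 0 | df$v_ml_per_min < 0)[1]
    stop_fluidshift(
      sprintf("%s: negative rate in row %d.", path, bad),
      class = "parse"
    )
  }
  scale <- if (unit == "l") 1000 else 1
  n <- nrow(df)
  fluid_schedule(
    time = df$time_min[-n],
    u = scale * df$u_ml_per_min[-n],
    v = scale * df$v_ml_per_min[-n],
    duration = df$time_min[n]
  )
}

#' Write a schedule to CSV
#'
#' Writes one row per segment plus a terminal row at the duration with zero
#' rates, the format read back by [read_schedule()].
#'
#' @param schedule A [fluid_schedule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  assert_schedule(schedule)
  out <- tibble(
    time_min = c(schedule$time, schedule_duration(schedule)),
    u_ml_per_min = c(schedule$u, 0),
    v_ml_per_min = c(schedule$v, 0)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a fractional blood-volume trace from CSV
#'
#' Expects columns `time_min` and `vb_frac`.
#'
#' @param path Path to a CSV file.
#' @param anchored Require a baseline sample (`vb_frac = 0` at time 0)?
#' @return A [volume_trace()].
#' @export
read_trace <- function(path, anchored = TRUE) {
  df <- read_checked(path, c("time_min", "vb_frac"))
  check_increasing(df$time_min, path, "time_min")
  volume_trace(df$time_min, df$vb_frac, anchored = anchored)
}

#' Write a trace to CSV
#'
#' @param trace A [volume_trace()] (or any data frame with `time`,
#'   `vb_frac`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  trace <- as_volume_trace(trace, anchored = FALSE)
  readr::write_csv(tibble(time_min = trace$time, vb_frac = trace$vb_frac), path)
  invisible(path)
}

#' Read a hemoglobin/hematocrit series from CSV
#'
#' Expects columns `time_min`, `hgb`, `hct`.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `time`, `hgb`, `hct` suitable for
#'   [hemodilution_to_volume()].
#' @export
read_hemodilution <- function(path) {
  df <- read_checked(path, c("time_min", "hgb", "hct"))
  check_increasing(df$time_min, path, "time_min")
  tibble(time = df$time_min, hgb = df$hgb, hct = df$hct)
}

#' Write model parameters to JSON / read them back
#'
#' @param params A [model_params()] object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a [model_params()].
#' @export
write_params <- function(params, path) {
  params <- as_bv_params(params)
  jsonlite::write_json(
    list(alpha = params$alpha, k = params$k, v_b0 = params$v_b0),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(c("alpha", "k", "v_b0"), names(x))
  if (length(missing)) {
    stop_fluidshift(
      sprintf("%s: missing parameter field(s) %s.", path,
              paste(missing, collapse = ", ")),
      class = "parse"
    )
  }
  model_params(x$alpha, x$k, x$v_b0)
}

read_checked <- function(path, columns) {
  if (!file.exists(path)) {
    stop_fluidshift(sprintf("File not found: %s", path), class = "parse")
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      stop_fluidshift(sprintf("%s: cannot parse as CSV (%s).", path,
                              conditionMessage(e)), class = "parse")
    }
  )
  missing <- setdiff(columns, names(df))
  if (length(missing)) {
    stop_fluidshift(
      sprintf("%s: malformed header, missing column(s) %s.", path,
              paste(missing, collapse = ", ")),
      class = "parse"
    )
  }
  not_num <- columns[!map_lgl(df[columns], is.numeric)]
  if (length(not_num)) {
    stop_fluidshift(
      sprintf("%s: column(s) %s are not numeric.", path,
              paste(not_num, collapse = ", ")),
      class = "parse"
    )
  }
  if (anyNA(df[columns])) {
    bad <- which(rowSums(is.na(df[columns])) > 0)[1]
    stop_fluidshift(sprintf("%s: missing value in row %d.", path, bad),
                    class = "parse")
  }
  df
}

check_increasing <- function(x, path, column) {
  if (length(x) > 1L && any(diff(x) <= 0)) {
    bad <- which(diff(x) <= 0)[1] + 1L
    stop_fluidshift(
      sprintf("%s: column %s must be strictly increasing (violated at row %d).",
              path, column, bad),
      class = "parse"
    )
  }
  invisible(x)
}
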