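#' Fractional blood-volume trace
#'
#' A sampled fractional blood-volume response: the blood-volume change
#' normalized by the initial blood volume, `vb_frac = dVB / v_b0`. Traces
#' come either from hemodilution measurements
#' ([hemodilution_to_volume()]) or from the model
#' ([simulate_volume_euler()], [synthetic_trace()]).
#'
#' @param time Strictly increasing sample times in minutes.
#' @param vb_frac Fractional blood volume at each sample, dimensionless,
#'   `> -1` (blood volume cannot go negative).
#' @param anchored If `TRUE` (default) the trace is anchored at baseline:
#'   the first sample must be at `t = 0` with `vb_frac = 0`.
#'
#' @return A tibble of class `"volume_trace"` with columns `time`,
#'   `vb_frac`.
#' @export
volume_trace <- function(time, vb_frac, anchored = TRUE) {
  if (!is.numeric(time) || !is.numeric(vb_frac) ||
      length(time) != length(vb_frac) || length(time) < 1L ||
      anyNA(time) || anyNA(vb_frac)) {
    stop_fluidshift("`time` and `vb_frac` must be numeric vectors of equal length without NAs.",
                    class = "input")
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1] + 1L
    stop_fluidshift(
      sprintf("Sample times must be strictly increasing (violated at sample %d).", bad),
      class = "input"
    )
  }
  if (any(vb_frac <= -1)) {
    stop_fluidshift("`vb_frac` must exceed -1: blood volume cannot be negative.",
                    class = "domain")
  }
  if (anchored && (time[1] != 0 || vb_frac[1] != 0)) {
    stop_fluidshift("An anchored trace must start with vb_frac = 0 at time 0.",
                    class = "input")
  }
  out <- tibble(time = as.numeric(time), vb_frac = as.numeric(vb_frac))
  structure(out, class = c("volume_trace", class(out)))
}

is_volume_trace <- function(x) inherits(x, "volume_trace")

as_volume_trace <- function(x, anchored = TRUE) {
  if (is_volume_trace(x)) return(x)
  if (is.data.frame(x) && all(c("time", "vb_frac") %in% names(x))) {
    return(volume_trace(x$time, x$vb_frac, anchored = anchored))
  }
  stop_fluidshift("Cannot interpret input as a volume trace (need columns time, vb_frac).",
                  class = "input")
}

#' Sampling interval of a uniformly sampled trace
#'
#' @param trace A [volume_trace()].
#' @param tol Relative tolerance on step equality.
#' @return The sampling interval `T_S` in minutes, or an error if the grid
#'   is not uniform.
#' @export
sampling_interval <- function(trace, tol = 1e-8) {
  trace <- as_volume_trace(trace, anchored = FALSE)
  if (nrow(trace) < 2L) {
    stop_fluidshift("Need at least two samples to define a sampling interval.",
                    class = "input")
  }
  steps <- diff(trace$time)
  ts <- steps[1]
  if (any(abs(steps - ts) > tol * max(ts, 1))) {
    stop_fluidshift("Trace is not uniformly sampled.", class = "input")
  }
  ts
}
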