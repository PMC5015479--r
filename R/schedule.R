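#' Piecewise-constant infusion/loss schedule
#'
#' An infusion protocol is described by segment start times and the constant
#' infusion rate `u` (ml/min) and loss rate `v` (ml/min, e.g. urine or
#' hemorrhage during the study) holding on each segment. A rate holds from
#' its segment's start time until the next segment begins; the final
#' segment's rates hold until `duration`.
#'
#' @param time Strictly increasing segment start times in minutes; the first
#'   must be 0.
#' @param u Infusion rate per segment, ml/min, `>= 0`. Recycled to the number
#'   of segments if scalar.
#' @param v Loss rate per segment, ml/min, `>= 0`. Recycled if scalar.
#' @param duration Total study time in minutes; must be at least the last
#'   segment start.
#'
#' @return A tibble of class `"fluid_schedule"` with columns `time`, `u`,
#'   `v` (one row per segment) and a `duration` attribute.
#' @examples
#' # 1875 ml of crystalloid over 30 min, observed for a further 150 min
#' fluid_schedule(time = c(0, 30), u = c(62.5, 0), v = 0, duration = 180)
#' @export
fluid_schedule <- function(time, u, v = 0, duration = max(time)) {
  if (!is.numeric(time) || length(time) < 1L || anyNA(time)) {
    stop_fluidshift("`time` must be a non-empty numeric vector.", class = "input")
  }
  if (time[1] != 0) {
    stop_fluidshift("The first segment must start at time 0.", class = "input")
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop_fluidshift("Segment start times must be strictly increasing.", class = "input")
  }
  n <- length(time)
  u <- vctrs_recycle(u, n, "u")
  v <- vctrs_recycle(v, n, "v")
  if (anyNA(u) || any(u < 0)) {
    stop_fluidshift("Infusion rates `u` must be non-negative.", class = "input")
  }
  if (anyNA(v) || any(v < 0)) {
    stop_fluidshift("Loss rates `v` must be non-negative.", class = "input")
  }
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration < time[n]) {
    stop_fluidshift("`duration` must be a single number >= the last segment start.",
                    class = "input")
  }
  out <- tibble(time = as.numeric(time), u = as.numeric(u), v = as.numeric(v))
  structure(out,
            class = c("fluid_schedule", class(out)),
            duration = as.numeric(duration))
}

vctrs_recycle <- function(x, n, name) {
  if (length(x) == 1L) rep(as.numeric(x), n)
  else if (length(x) == n) as.numeric(x)
  else stop_fluidshift(
    sprintf("`%s` must have length 1 or %d (one rate per segment), got %d.",
            name, n, length(x)),
    class = "input"
  )
}

#' @export
print.fluid_schedule <- function(x, ...) {
  cat(sprintf("<fluid_schedule> %d segment(s), duration %.4g min\n",
              nrow(x), schedule_duration(x)))
  NextMethod()
}

#' Total study duration of a schedule
#'
#' @param schedule A [fluid_schedule()].
#' @return Duration in minutes.
#' @export
schedule_duration <- function(schedule) {
  attr(schedule, "duration", exact = TRUE)
}

is_fluid_schedule <- function(x) inherits(x, "fluid_schedule")

assert_schedule <- function(schedule) {
  if (!is_fluid_schedule(schedule)) {
    stop_fluidshift("`schedule` must be a fluid_schedule object.", class = "input")
  }
  invisible(schedule)
}

#' Infusion and loss rates at given times
#'
#' Rates are right-continuous step functions: at a segment start the new
#' segment's rate applies. Times at or beyond `duration` return the final
#' segment's rates (the schedule's last segment extends to `duration`);
#' negative times return 0.
#'
#' @param schedule A [fluid_schedule()].
#' @param t Times in minutes.
#' @return A tibble with columns `time`, `u`, `v`.
#' @export
schedule_rates <- function(schedule, t) {
  assert_schedule(schedule)
  idx <- findInterval(t, schedule$time)
  u <- ifelse(idx == 0, 0, schedule$u[pmax(idx, 1L)])
  v <- ifelse(idx == 0, 0, schedule$v[pmax(idx, 1L)])
  tibble(time = as.numeric(t), u = u, v = v)
}

#' Cumulative net fluid input
#'
#' Exact integral of `u - v` from 0 to `t` for the piecewise-constant
#' schedule (closed form per segment, no quadrature error).
#'
#' @param schedule A [fluid_schedule()].
#' @param t Times in minutes, within `[0, duration]`.
#' @return Net input volume in ml at each `t`.
#' @export
cumulative_net_input <- function(schedule, t) {
  assert_schedule(schedule)
  dur <- schedule_duration(schedule)
  if (any(t < 0 | t > dur)) {
    stop_fluidshift(
      sprintf("Times must lie within [0, %g] min.", dur),
      class = "range"
    )
  }
  brk <- schedule$time
  net <- schedule$u - schedule$v
  # net input accumulated up to each segment start
  seg_len <- diff(c(brk, dur))
  cum_at_start <- c(0, head(cumsum(net * seg_len), -1L))
  idx <- pmax(findInterval(t, brk), 1L)
  cum_at_start[idx] + net[idx] * (t - brk[idx])
}

#' Target blood-volume change
#'
#' The feedback controller steers the blood-volume change toward the target
#' `r_B(t)`, defined as the `1/(1 + alpha)` fraction of the net fluid volume
#' accumulated up to `t`:
#' \deqn{r_B(t) = \frac{1}{1+\alpha}\int_0^t [u(\tau)-v(\tau)]\,d\tau.}
#' The remaining `alpha/(1 + alpha)` fraction is destined for the
#' interstitium at steady state.
#'
#' @param schedule A [fluid_schedule()].
#' @param alpha Target volume ratio, `> 0`.
#' @param t Times in minutes, within `[0, duration]`.
#' @return Target change `r_B(t)` in ml.
#' @examples
#' s <- fluid_schedule(0, u = 30, v = 0, duration = 60)
#' target_blood_volume_change(s, alpha = 2, t = 30)  # (1/3) * 900 = 300 ml
#' @export
target_blood_volume_change <- function(schedule, alpha, t) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop_fluidshift("`alpha` must be a single positive number.", class = "domain")
  }
  cumulative_net_input(schedule, t) / (1 + alpha)
}
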