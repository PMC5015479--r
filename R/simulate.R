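#' Simulate the blood-volume response to an infusion/loss schedule
#'
#' Integrates the two-compartment feedback model
#' \deqn{\dot{\Delta V_B} = u - v + K\,(r_B - \Delta V_B), \qquad
#'       \dot{r}_B = \frac{u - v}{1+\alpha},}
#' with \eqn{\Delta V_B(0) = r_B(0) = 0}. The fluid shift is
#' \eqn{q = -K e_B} with discrepancy \eqn{e_B = r_B - \Delta V_B}; positive
#' `q` moves fluid from the intravascular to the interstitial compartment.
#'
#' Because the inputs are piecewise constant the linear system is solved
#' exactly, segment by segment, in closed form: on a segment with constant
#' net rate `c` the discrepancy decays as `exp(-K t)` toward
#' `-c alpha / (K (1+alpha))` while `r_B` grows linearly. There is no
#' truncation error; the first-order state-space form avoids differentiating
#' the (discontinuous) inputs.
#'
#' @param params A [model_params()] object.
#' @param schedule A [fluid_schedule()].
#' @param times Evaluation times, minutes: non-negative, strictly
#'   increasing, starting at 0, within the schedule duration.
#'
#' @return A tibble of class `"bv_simulation"` with columns
#'   `time` (min), `dVB` (blood-volume change, ml), `vb_frac`
#'   (`dVB / v_b0`), `rB` (target change, ml), `eB` (`rB - dVB`, ml),
#'   `q` (inter-compartment flow, ml/min) and `dVISF` (interstitial volume
#'   change, ml, from volume conservation). The generating `params` and
#'   `schedule` are carried as attributes.
#' @examples
#' p <- model_params(alpha = 2.35, k = 0.047, v_b0 = 5560)
#' s <- fluid_schedule(c(0, 30), u = c(62.5, 0), v = 0, duration = 240)
#' sim <- simulate_volume(p, s, times = seq(0, 240, by = 10))
#' head(sim)
#' @export
simulate_volume <- function(params, schedule, times) {
  params <- as_bv_params(params)
  assert_schedule(schedule)
  if (!is.numeric(times) || length(times) < 1L || anyNA(times)) {
    stop_fluidshift("`times` must be a non-empty numeric vector.", class = "input")
  }
  if (times[1] != 0 || (length(times) > 1L && any(diff(times) <= 0))) {
    stop_fluidshift("`times` must start at 0 and be strictly increasing.",
                    class = "input")
  }
  dur <- schedule_duration(schedule)
  if (max(times) > dur) {
    stop_fluidshift(
      sprintf("`times` must lie within the schedule duration [0, %g] min.", dur),
      class = "range"
    )
  }

  alpha <- params$alpha; k <- params$k
  brk <- schedule$time
  cnet <- schedule$u - schedule$v
  seg_end <- c(brk[-1], dur)

  n <- length(times)
  dVB <- numeric(n); rB <- numeric(n)
  x <- 0; r <- 0  # state at the current segment start
  zinf <- function(cs) cs * alpha / (k * (1 + alpha))
  for (s in seq_along(brk)) {
    tl <- brk[s]; tr <- seg_end[s]; cs <- cnet[s]
    z0 <- x - r
    last_seg <- s == length(brk)
    idx <- which(times >= tl & (times < tr | last_seg))
    if (length(idx)) {
      dt <- times[idx] - tl
      rr <- r + cs * dt / (1 + alpha)
      zz <- z0 * exp(-k * dt) + zinf(cs) * (1 - exp(-k * dt))
      rB[idx] <- rr
      dVB[idx] <- rr + zz
    }
    if (!last_seg) {
      dt <- tr - tl
      r_new <- r + cs * dt / (1 + alpha)
      z_new <- z0 * exp(-k * dt) + zinf(cs) * (1 - exp(-k * dt))
      r <- r_new
      x <- r_new + z_new
    }
  }

  eB <- rB - dVB
  cum <- cumulative_net_input(schedule, times)
  out <- tibble(
    time = as.numeric(times),
    dVB = dVB,
    vb_frac = dVB / params$v_b0,
    rB = rB,
    eB = eB,
    q = -k * eB,
    dVISF = cum - dVB
  )
  structure(out,
            class = c("bv_simulation", class(out)),
            params = params,
            schedule = schedule)
}

#' Reconstruct the interstitial volume change from the fluid-shift flow
#'
#' Numerically integrates the inter-compartment flow `q` over time
#' (cumulative trapezoidal rule) to estimate the interstitial volume change
#' \eqn{\hat{\Delta V}_{ISF}(t) = \int_0^t q\,d\tau}. Volume conservation
#' requires `dVB + dVISF` to equal the cumulative net input at every sample,
#' up to quadrature error.
#'
#' @param sim A `"bv_simulation"` from [simulate_volume()], or any data
#'   frame with columns `time` and `q`.
#' @return A tibble with columns `time` and `dVISF` (ml).
#' @export
reconstruct_interstitial <- function(sim) {
  if (!is.data.frame(sim) || !all(c("time", "q") %in% names(sim))) {
    stop_fluidshift("`sim` must contain columns `time` and `q`.", class = "input")
  }
  tibble(
    time = sim$time,
    dVISF = as.numeric(pracma::cumtrapz(sim$time, sim$q))
  )
}

#' Simulate via the first-order Euler difference equation
#'
#' Discretizes the second-order input-output form of the model,
#' \deqn{\ddot{\breve V}_B + K\dot{\breve V}_B =
#'   \frac{\dot u - \dot v}{V_{B0}} + \frac{K\,(u - v)}{V_{B0}(1+\alpha)},}
#' with Euler differences at sampling interval `t_s`:
#' \deqn{\breve V_B(i) = 2\breve V_B(i\!-\!1) - \breve V_B(i\!-\!2)
#'  - K T_S [\breve V_B(i\!-\!1) - \breve V_B(i\!-\!2)]
#'  + \frac{T_S}{V_{B0}}\Delta[u - v](i\!-\!1)
#'  + \frac{K T_S^2}{V_{B0}(1+\alpha)} [u(i\!-\!2) - v(i\!-\!2)].}
#' Startup uses \eqn{\breve V_B(0) = \breve V_B(-1) = 0} and zero inputs
#' before time 0 (baseline anchoring). The recursion converges to
#' [simulate_volume()] at first order in `t_s`.
#'
#' @param params A [model_params()] object.
#' @param schedule A [fluid_schedule()]; inputs are sampled at `i * t_s`
#'   (right-continuous).
#' @param t_s Sampling interval, minutes, `> 0`.
#' @param n Number of steps (`>= 3`); the returned trace has `n + 1` samples
#'   at times `0, t_s, ..., n * t_s`.
#'
#' @return A [volume_trace()] with the discrete fractional response.
#' @export
simulate_volume_euler <- function(params, schedule, t_s, n) {
  params <- as_bv_params(params)
  assert_schedule(schedule)
  if (!is.numeric(t_s) || length(t_s) != 1L || !is.finite(t_s) || t_s <= 0) {
    stop_fluidshift("`t_s` must be a single positive number (minutes).", class = "input")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 3L) {
    stop_fluidshift("`n` must be an integer >= 3.", class = "input")
  }
  if (params$k * t_s >= 2) {
    warn(sprintf(
      "K * T_S = %.3g >= 2: the Euler recursion is outside its stability margin.",
      params$k * t_s
    ), class = "fluidshift_warning_stability")
  }
  alpha <- params$alpha; k <- params$k; v_b0 <- params$v_b0

  # inputs at sample indices -1..n-1 (zero before time 0)
  kk <- -1:(n - 1L)
  tt <- pmin(kk * t_s, schedule_duration(schedule))
  rates <- schedule_rates(schedule, tt)
  uu <- ifelse(kk < 0, 0, rates$u)
  vv <- ifelse(kk < 0, 0, rates$v)
  net <- uu - vv  # net[j] is u - v at index j - 2

  V <- numeric(n + 2L)  # V[j] holds sample index j - 2; V(-1) = V(0) = 0
  c1 <- t_s / v_b0
  c2 <- k * t_s^2 / (v_b0 * (1 + alpha))
  for (i in seq_len(n)) {
    j <- i + 2L
    V[j] <- 2 * V[j - 1L] - V[j - 2L] -
      k * t_s * (V[j - 1L] - V[j - 2L]) +
      c1 * (net[i + 1L] - net[i]) +
      c2 * net[i]
  }
  volume_trace(time = (0:n) * t_s, vb_frac = V[-1L])
}
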