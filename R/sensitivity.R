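#' Frequency response of the model
#'
#' The transfer function from the net input `u - v` (ml/min) to the
#' fractional blood-volume response is
#' \deqn{G(j\omega) = \frac{j\omega + K/(1+\alpha)}
#'   {V_{B0}\; j\omega\,(j\omega + K)}.}
#' The model integrates its input (a pole at the origin), so `omega = 0` is
#' rejected. At low frequency the gain behaves as
#' \eqn{1/((1+\alpha) V_{B0} \omega)}; at high frequency as
#' \eqn{1/(V_{B0}\omega)} — fast input changes initially stay in the
#' intravascular compartment, while slow ones are split `1 : alpha` with
#' the interstitium.
#'
#' @param params A [model_params()] object.
#' @param omega Angular frequencies, rad/min, strictly positive.
#' @return Complex frequency response, same length as `omega`.
#' @export
transfer_function <- function(params, omega) {
  params <- as_bv_params(params)
  if (!is.numeric(omega) || length(omega) < 1L || anyNA(omega) || any(omega <= 0)) {
    stop_fluidshift(
      "`omega` must be strictly positive: the model has an integrator pole at omega = 0.",
      class = "domain"
    )
  }
  s <- 1i * omega
  (s + params$k / (1 + params$alpha)) / (params$v_b0 * s * (s + params$k))
}

#' Normalized parametric sensitivity spectra
#'
#' Normalized partial derivatives of the frequency response with respect to
#' each parameter, \eqn{S_p(j\omega) = (p / G)\,\partial G/\partial p}:
#' \deqn{S_{V_{B0}} = -1, \qquad
#'   S_K = \frac{-\alpha K\, j\omega}{((1+\alpha) j\omega + K)(j\omega + K)},
#'   \qquad
#'   S_\alpha = \frac{-\alpha K}{(1+\alpha)\,((1+\alpha) j\omega + K)}.}
#' `S_VB0` is exactly -1 at all frequencies (the gain scales as
#' `1 / V_B0`). `|S_K|` vanishes at both frequency extremes with a
#' mid-frequency maximum, and `|S_alpha|` rises to `alpha / (1 + alpha)` as
#' `omega` tends to 0 — so the transient response is shaped mainly by
#' `V_B0` (and moderately by `K`) while the steady state is shaped
#' comparably by `V_B0` and `alpha`.
#'
#' @param params A [model_params()] object.
#' @param omega Angular frequency grid, rad/min, strictly positive and
#'   increasing. Default: 200 log-spaced points over `[1e-4, 1]`.
#' @return A tibble of class `"bv_sensitivity"` with columns `omega`, `G`,
#'   `S_vb0`, `S_k`, `S_alpha` (complex). Supports [ggplot2::autoplot()]
#'   (Bode magnitude plot).
#' @examples
#' p <- model_params(alpha = 2.35, k = 0.047, v_b0 = 5560)
#' spec <- sensitivity_spectra(p)
#' all(spec$S_vb0 == -1)
#' @export
sensitivity_spectra <- function(params, omega = default_omega_grid()) {
  params <- as_bv_params(params)
  if (!is.numeric(omega) || length(omega) < 1L || anyNA(omega) ||
      any(omega <= 0) || (length(omega) > 1L && any(diff(omega) <= 0))) {
    stop_fluidshift("`omega` must be strictly positive and increasing.", class = "domain")
  }
  a <- params$alpha; k <- params$k
  s <- 1i * omega
  out <- tibble(
    omega = as.numeric(omega),
    G = transfer_function(params, omega),
    S_vb0 = complex(real = rep(-1, length(omega)), imaginary = 0),
    S_k = -a * k * s / (((1 + a) * s + k) * (s + k)),
    S_alpha = -a * k / ((1 + a) * ((1 + a) * s + k))
  )
  structure(out,
            class = c("bv_sensitivity", class(out)),
            params = params)
}

#' Default log-spaced frequency grid
#'
#' @param n Number of points.
#' @param range Frequency range in rad/min.
#' @return Numeric vector of `n` log-spaced frequencies.
#' @export
default_omega_grid <- function(n = 200L, range = c(1e-4, 1)) {
  10^seq(log10(range[1]), log10(range[2]), length.out = n)
}
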