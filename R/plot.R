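#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   scale_x_log10 scale_y_log10 facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a simulated blood-volume response
#'
#' Shows the intravascular (`dVB`) and interstitial (`dVISF`) volume
#' changes together with the target change `rB` over time.
#'
#' @param object A `"bv_simulation"` from [simulate_volume()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bv_simulation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("time", "dVB", "dVISF", "rB")],
    cols = c("dVB", "dVISF", "rB"),
    names_to = "compartment", values_to = "volume"
  )
  ggplot(long, aes(x = .data$time, y = .data$volume,
                   colour = .data$compartment)) +
    geom_line() +
    labs(x = "time (min)", y = "volume change (ml)", colour = NULL) +
    theme_minimal()
}

#' Plot a fitted model against the measured trace
#'
#' @param object A `"bv_fit"` from [fit_blood_volume()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bv_fit <- function(object, ...) {
  ggplot(object$fitted, aes(x = .data$time)) +
    geom_point(aes(y = .data$observed), shape = 1) +
    geom_line(aes(y = .data$fitted)) +
    labs(
      x = "time (min)", y = "fractional blood volume",
      title = sprintf("alpha* = %.3g, K* = %.3g /min, V_B0* = %.3g ml (RMSNE %.2g%%)",
                      object$params$alpha, object$params$k,
                      object$params$v_b0, object$rmsne)
    ) +
    theme_minimal()
}

#' Bode magnitude plot of the sensitivity spectra
#'
#' @param object A `"bv_sensitivity"` from [sensitivity_spectra()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bv_sensitivity <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble(
      omega = object$omega,
      `|S_VB0|` = Mod(object$S_vb0),
      `|S_K|` = Mod(object$S_k),
      `|S_alpha|` = Mod(object$S_alpha)
    ),
    cols = -"omega", names_to = "sensitivity", values_to = "magnitude"
  )
  ggplot(long, aes(x = .data$omega, y = .data$magnitude,
                   colour = .data$sensitivity)) +
    geom_line() +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = "angular frequency (rad/min)", y = "|S|", colour = NULL) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
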