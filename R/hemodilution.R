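#' Convert hemoglobin/hematocrit series to a fractional blood-volume trace
#'
#' Hemoglobin acts as an endogenous tracer: if its total mass is constant,
#' an increase in blood volume dilutes its concentration. The fractional
#' blood-volume change is recovered from paired hemoglobin-concentration and
#' hematocrit measurements as
#' \deqn{\breve V_B(t) = \frac{1}{1-\mathrm{Hct}(t)}\,
#'   \frac{\mathrm{Hgb}(0)-\mathrm{Hgb}(t)}{\mathrm{Hgb}(t)}.}
#'
#' @param series A data frame with columns `time` (min, strictly increasing,
#'   containing a baseline sample at 0), `hgb` (hemoglobin concentration,
#'   `> 0`) and `hct` (hematocrit fraction in `(0, 1)`).
#' @param hct Which hematocrit enters the `1/(1 - Hct)` factor:
#'   `"measured"` (default) uses the concurrent `Hct(t)`;
#'   `"baseline"` uses `Hct(0)` throughout, the classical hemodilution
#'   convention.
#' @param hgb_unit Unit of `hgb`, `"g_l"` (default) or `"g_dl"`. The formula
#'   uses only the concentration ratio, so the unit affects validation
#'   messages, not the result.
#'
#' @return A [volume_trace()] anchored at `vb_frac = 0` at time 0.
#' @examples
#' h <- data.frame(time = c(0, 30), hgb = c(140, 120), hct = c(0.43, 0.40))
#' hemodilution_to_volume(h)
#' @export
hemodilution_to_volume <- function(series,
                                   hct = c("measured", "baseline"),
                                   hgb_unit = c("g_l", "g_dl")) {
  hct <- arg_match(hct)
  hgb_unit <- arg_match(hgb_unit)
  if (!is.data.frame(series) || !all(c("time", "hgb", "hct") %in% names(series))) {
    stop_fluidshift("`series` must have columns time, hgb, hct.", class = "input")
  }
  tt <- series$time; hgb <- series$hgb; hcts <- series$hct
  if (anyNA(tt) || anyNA(hgb) || anyNA(hcts)) {
    stop_fluidshift("Hemodilution series must not contain NAs.", class = "input")
  }
  if (length(tt) > 1L && any(diff(tt) <= 0)) {
    stop_fluidshift("Times must be strictly increasing.", class = "input")
  }
  if (tt[1] != 0) {
    stop_fluidshift("A baseline sample at time 0 is required (Hgb(0) anchors the trace).",
                    class = "input")
  }
  if (any(hgb <= 0)) {
    stop_fluidshift("Hemoglobin concentrations must be positive.", class = "domain")
  }
  plausible <- if (hgb_unit == "g_l") c(30, 250) else c(3, 25)
  if (any(hgb < plausible[1] | hgb > plausible[2])) {
    warn(sprintf("Some hgb values fall outside the plausible %s range [%g, %g].",
                 gsub("_", "/", hgb_unit), plausible[1], plausible[2]),
         class = "fluidshift_warning_units")
  }
  if (any(hcts <= 0 | hcts >= 1)) {
    stop_fluidshift("Hematocrit must be a fraction strictly between 0 and 1.",
                    class = "domain")
  }
  hct_used <- if (hct == "baseline") rep(hcts[1], length(tt)) else hcts
  vb <- (1 / (1 - hct_used)) * (hgb[1] - hgb) / hgb
  volume_trace(time = tt, vb_frac = vb)
}

#' Synthesize a hemoglobin series from a fractional blood-volume trace
#'
#' Inverts the hemodilution relation at a fixed hematocrit, giving
#' `Hgb(t) = Hgb(0) / (1 + (1 - Hct) * vb_frac)`. Useful for generating
#' synthetic laboratory series from simulated traces and for round-trip
#' checks of the conversion.
#'
#' @param trace A [volume_trace()].
#' @param hgb0 Baseline hemoglobin concentration, `> 0`.
#' @param hct Hematocrit fraction in `(0, 1)`, held constant.
#' @return A tibble with columns `time`, `hgb`, `hct`.
#' @export
hemoglobin_from_volume <- function(trace, hgb0, hct) {
  trace <- as_volume_trace(trace)
  if (!is.numeric(hgb0) || length(hgb0) != 1L || hgb0 <= 0) {
    stop_fluidshift("`hgb0` must be a single positive number.", class = "domain")
  }
  if (!is.numeric(hct) || length(hct) != 1L || hct <= 0 || hct >= 1) {
    stop_fluidshift("`hct` must be a fraction strictly between 0 and 1.", class = "domain")
  }
  tibble(
    time = trace$time,
    hgb = hgb0 / (1 + (1 - hct) * trace$vb_frac),
    hct = hct
  )
}
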