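#' Model parameters: target volume ratio, feedback gain, initial blood volume
#'
#' The model is fully characterized by three subject-specific parameters:
#'
#' * `alpha` — the target volume ratio, i.e. the steady-state ratio of
#'   interstitial to intravascular volume change that the hypothetical
#'   feedback controller enforces (dimensionless). Crystalloids typically
#'   give `alpha` in the 2–4.5 range; colloids, being retained in the
#'   vasculature, give `alpha` below 1.
#' * `k` — the feedback gain setting the speed of the trans-capillary fluid
#'   shift, in 1/min. The shift rate is `q = -k * (r_B - dVB)`, proportional
#'   to the discrepancy between the target and actual blood-volume change.
#' * `v_b0` — the initial (baseline) blood volume in ml, used to normalize
#'   the volume change into the fractional response `vb_frac = dVB / v_b0`.
#'
#' @param alpha Target volume ratio, dimensionless, `> 0`. Values below 1 are
#'   legal and typical of colloids.
#' @param k Feedback gain, 1/min, `> 0`.
#' @param v_b0 Initial blood volume, ml, `> 0`.
#'
#' @return An object of class `"bv_params"`: a named list with elements
#'   `alpha`, `k`, `v_b0`.
#' @examples
#' model_params(alpha = 2.35, k = 0.047, v_b0 = 5560)
#' @export
model_params <- function(alpha, k, v_b0) {
  for (nm in c("alpha", "k", "v_b0")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      stop_fluidshift(
        sprintf("`%s` must be a single finite positive number, got %s.",
                nm, deparse(val)),
        class = "domain"
      )
    }
  }
  structure(list(alpha = alpha, k = k, v_b0 = v_b0), class = "bv_params")
}

#' @export
print.bv_params <- function(x, ...) {
  cat("<bv_params>\n")
  cat(sprintf("  alpha (target volume ratio) : %.4g\n", x$alpha))
  cat(sprintf("  k     (feedback gain, 1/min): %.4g\n", x$k))
  cat(sprintf("  v_b0  (blood volume, ml)    : %.4g\n", x$v_b0))
  invisible(x)
}

#' @export
as_tibble.bv_params <- function(x, ...) {
  tibble(
    term = c("alpha", "k", "v_b0"),
    estimate = c(x$alpha, x$k, x$v_b0),
    unit = c("1", "1/min", "ml")
  )
}

is_bv_params <- function(x) inherits(x, "bv_params")

as_bv_params <- function(x) {
  if (is_bv_params(x)) return(x)
  if (is.list(x) && all(c("alpha", "k", "v_b0") %in% names(x))) {
    return(model_params(x$alpha, x$k, x$v_b0))
  }
  if (is.numeric(x) && length(x) == 3L && !is.null(names(x))) {
    return(model_params(x[["alpha"]], x[["k"]], x[["v_b0"]]))
  }
  stop_fluidshift("Cannot interpret input as model parameters.", class = "domain")
}
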