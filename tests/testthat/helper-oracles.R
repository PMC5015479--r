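# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths.

# Analytic solution for a constant net input c (ml/min) switched on at t = 0
# with zero initial state:
#   dVB(t) = c t / (1 + alpha) + (c alpha / (K (1 + alpha))) (1 - exp(-K t))
oracle_const_infusion <- function(alpha, k, c, t) {
  c * t / (1 + alpha) + (c * alpha / (k * (1 + alpha))) * (1 - exp(-k * t))
}

# Numerical normalized sensitivity of the frequency response: 4th-order
# central differences in the parameter with relative step 1e-3 (truncation
# O(h^4) ~ 1e-12 relative, roundoff ~ eps/h ~ 1e-13; measured agreement with
# the closed forms is ~1e-9).
oracle_sensitivity <- function(params, omega, which = c("alpha", "k", "v_b0"),
                               h_rel = 1e-3) {
  which <- match.arg(which)
  p0 <- unlist(params[c("alpha", "k", "v_b0")])
  h <- p0[[which]] * h_rel
  g_at <- function(delta) {
    p <- p0
    p[[which]] <- p[[which]] + delta
    transfer_function(model_params(p[["alpha"]], p[["k"]], p[["v_b0"]]), omega)
  }
  d1 <- (-g_at(2 * h) + 8 * g_at(h) - 8 * g_at(-h) + g_at(-2 * h)) / (12 * h)
  p0[[which]] / g_at(0) * d1
}

# A standard two-segment bolus: 1875 ml over 30 min, observed to 240 min
# (25 ml/kg at 75 kg, as in the crystalloid reference protocols).
bolus_schedule <- function(rate = 62.5, infusion_min = 30, duration = 240,
                           v = 0) {
  fluid_schedule(time = c(0, infusion_min), u = c(rate, 0), v = v,
                 duration = duration)
}

saline_params <- function() model_params(alpha = 2.35, k = 0.047, v_b0 = 5560)

table2_param_sets <- function() {
  ref <- reference_params()
  lapply(seq_len(nrow(ref)), function(i) {
    model_params(alpha = ref$alpha[i], k = ref$k[i], v_b0 = 1000 * ref$v_b0_l[i])
  })
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
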