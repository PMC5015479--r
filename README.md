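# fluidshift

Simulation and subject-specific identification of a three-parameter
lumped model of the fluid shift between the intravascular and
interstitial compartments after intravenous fluid infusion.

When a crystalloid or colloid bolus is infused, blood volume rises and
then partially redistributes into the interstitium. `fluidshift` models
that redistribution macroscopically, as a proportional feedback
controller that regulates the intravascular:interstitial volume-change
ratio at a target value 1:α:

```
dΔV_B/dt = u − v − q,     q = −K e_B,     e_B = r_B − ΔV_B,
r_B(t) = 1/(1+α) ∫₀ᵗ [u(τ) − v(τ)] dτ,
```

with infusion rate `u` and loss rate `v` (ml/min) as inputs and the
blood-volume change `ΔV_B` (ml) — usually reported as the fractional
response `V̆_B = ΔV_B / V_B0` — as output. Three parameters characterize
an individual completely: the **target volume ratio α**
(dimensionless; 2–4.5 for crystalloids, below 1 for colloids), the
**feedback gain K** (1/min, the speed of the trans-capillary shift) and
the **initial blood volume V_B0** (ml). The package is for researchers
and engineers working with volume kinetics / hemodilution data who need
a model simple enough to fit per subject yet structured enough to
expose interpretable physiology.

It provides:

* **Simulation** — exact piecewise closed-form solution for
  piecewise-constant schedules (`simulate_volume()`), the classical
  first-order Euler difference equation (`simulate_volume_euler()`),
  and reconstruction of the interstitial volume change by integrating
  the shift flow (`reconstruct_interstitial()`).
* **Hemodilution conversion** — paired hemoglobin/hematocrit series to
  fractional blood-volume traces,
  `V̆_B = [1/(1−Hct)] · [Hgb(0)−Hgb(t)]/Hgb(t)`
  (`hemodilution_to_volume()`).
* **Estimation** — bounded multistart nonlinear least squares for
  (α, K, V_B0) with a linear-regression initializer and normalized
  error metrics (`fit_blood_volume()`, `regression_design()`,
  `goodness_of_fit()`), with broom-style `tidy()`/`glance()` and
  `autoplot()` methods.
* **Sensitivity analysis** — the frequency response
  `G(jω) = (jω + K/(1+α)) / (V_B0 jω (jω + K))` and closed-form
  normalized parameter sensitivities (`sensitivity_spectra()`), with a
  Bode-magnitude `autoplot()`.
* **Reference fixtures** — seven published crystalloid/colloid bolus
  protocols and their fitted parameter sets
  (`protocol_table()`, `reference_params()`, `protocol_schedule()`), a
  seeded synthetic-trace generator (`synthetic_trace()`) and
  parameter-recovery experiments (`recovery_experiment()`).
* **A command line** — `inst/cli/fluidshift.R` with subcommands
  `simulate`, `fit`, `convert`, `sense`, `recover` over CSV/JSON files.

## Worked example

Generate a noisy synthetic saline-bolus response (25 ml/kg at 75 kg,
infused over 30 min, observed to 240 min) and refit the model:

```r
library(fluidshift)

p  <- model_params(alpha = 2.35, k = 0.047, v_b0 = 5560)
s  <- fluid_schedule(time = c(0, 30), u = c(62.5, 0), v = 0, duration = 240)
tr <- synthetic_trace(p, s, t_s = 10, noise_sd = 0.005, seed = 42)

fit <- fit_blood_volume(tr, s)
fit
#> <bv_fit> lumped-parameter blood-volume model
#>   alpha* = 2.285   K* = 0.04253 /min   V_B0* = 5711 ml
#>   RMSNE 5.32%  (objective 0.000911, 25 samples, best start 2/8)
```

The estimates sit within a few percent of the generating values
(α 2.35, K 0.047, V_B0 5560): measurement noise of sd 0.005 on a
fractional response that peaks near 0.15 leaves that much uncertainty in
25 samples. `RMSNE` is the root-mean-squared misfit normalized by the
trace's time-average, in percent. The simulated trajectories show the
redistribution explicitly:

```r
simulate_volume(p, s, seq(0, 240, 60))
#> # A tibble: 5 × 7
#>    time   dVB vb_frac    rB        eB       q dVISF
#>   <dbl> <dbl>   <dbl> <dbl>     <dbl>   <dbl> <dbl>
#> 1     0    0    0        0     0      0          0
#> 2    60  732.   0.132  560. -172.     8.09    1143.
#> 3   120  570.   0.103  560.  -10.3    0.482   1305.
#> 4   180  560.   0.101  560.   -0.612  0.0287  1315.
#> 5   240  560.   0.101  560.   -0.0365 0.00171 1315.
```

Of the 1875 ml infused, `ΔV_B` settles at 560 ml = 1875/(1+2.35) — the
1/(1+α) share retained intravascularly — while `ΔV_ISF` absorbs the
remaining 1315 ml, α times as much; the shift flow `q` decays to zero as
the controller closes the gap `e_B` between target and actual change.
`autoplot(fit)` and `autoplot(simulate_volume(...))` draw the fit and
the compartment trajectories; `autoplot(sensitivity_spectra(p))` draws
the Bode magnitudes of the parameter sensitivities (|S_VB0| ≡ 1 at all
frequencies, |S_α| → α/(1+α) at low frequency, |S_K| peaking mid-band).

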