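#' Linear-regression form of the model for identifiability and starting values
#'
#' The input-output form of the model can be rewritten as a linear
#' regression in which the second derivative of the fractional response is
#' explained by three regressors:
#' \deqn{\ddot{\breve V}_B = \theta^\top \phi, \qquad
#'   \phi = [\,\dot{\breve V}_B,\; \dot u - \dot v,\; u - v\,]^\top,}
#' with \eqn{\theta = [K,\; 1/V_{B0},\; K/(V_{B0}(1+\alpha))]^\top} (the
#' first regressor carries coefficient \eqn{-K}; the gain is reported with
#' its physical positive sign). Because the regression is linear, `theta` —
#' and hence all three model parameters — is uniquely determined by least
#' squares whenever the data are informative.
#'
#' Derivatives of the trace are approximated by central differences on the
#' uniform grid. Input derivatives are zero inside segments; at a sample
#' where the rate changes, the backward difference `(u(i) - u(i-1)) / T_S`
#' is used so that the impulse carried by the input derivative lands on the
#' same sample at which the central second difference of the trace picks up
#' the slope discontinuity.
#'
#' This estimator amplifies measurement noise through the numerical
#' derivatives; it is intended as an initializer for [fit_blood_volume()],
#' not as the final estimator.
#'
#' @param trace A uniformly sampled [volume_trace()] with at least 5 samples.
#' @param schedule The [fluid_schedule()] on the same clock.
#'
#' @return A list of class `"bv_regression"` with elements
#'   `theta` (length-3 least-squares estimate, first element reported as
#'   `K > 0`), `params` (the implied [model_params()], or `NULL` if
#'   inadmissible), `design` (tibble of response and regressor rows) and
#'   `t_s`.
#' @export
regression_design <- function(trace, schedule) {
  trace <- as_volume_trace(trace, anchored = FALSE)
  assert_schedule(schedule)
  if (nrow(trace) < 5L) {
    stop_fluidshift("Need at least 5 samples for the regression form.", class = "input")
  }
  t_s <- sampling_interval(trace)  # errors on non-uniform grids
  vb <- trace$vb_frac
  n <- nrow(trace)
  rates <- schedule_rates(schedule, trace$time)
  net <- rates$u - rates$v

  i <- 2:(n - 1L)
  d1 <- (vb[i + 1L] - vb[i - 1L]) / (2 * t_s)
  d2 <- (vb[i + 1L] - 2 * vb[i] + vb[i - 1L]) / t_s^2
  dnet <- (net[i] - net[i - 1L]) / t_s
  design <- tibble(
    time = trace$time[i],
    response = d2,
    vb_dot = d1,
    net_dot = dnet,
    net = net[i]
  )

  X <- cbind(design$vb_dot, design$net_dot, design$net)
  informative <- sum(abs(design$response)) > 0 && qr(X)$rank == 3L
  if (!informative) {
    stop_fluidshift(
      "Degenerate regression design: the data are not informative enough to identify the parameters.",
      class = "noninformative"
    )
  }
  theta_raw <- qr.solve(X, design$response)
  theta <- c(abs(theta_raw[1]), theta_raw[2], theta_raw[3])
  params <- tryCatch(params_from_theta(theta), fluidshift_error = function(e) NULL)
  structure(
    list(theta = theta, params = params, design = design, t_s = t_s),
    class = "bv_regression"
  )
}

#' @export
print.bv_regression <- function(x, ...) {
  cat("<bv_regression>\n")
  cat("  theta:", format(x$theta, digits = 4), "\n")
  if (is.null(x$params)) cat("  implied parameters: inadmissible\n")
  else cat(sprintf("  implied: alpha = %.4g, k = %.4g, v_b0 = %.4g\n",
                   x$params$alpha, x$params$k, x$params$v_b0))
  invisible(x)
}

#' Map a regression coefficient vector to model parameters
#'
#' Inverts the regression parameterization: `K = |theta[1]|`,
#' `V_B0 = 1 / theta[2]`, `alpha = K * theta[2] / theta[3] - 1`.
#'
#' @param theta Numeric length-3 coefficient vector.
#' @return A [model_params()] object.
#' @examples
#' params_from_theta(c(0.05, 2.5e-4, 3.125e-6))  # alpha 3, K 0.05, V_B0 4000
#' @export
params_from_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 3L || anyNA(theta)) {
    stop_fluidshift("`theta` must be a numeric vector of length 3.", class = "input")
  }
  if (any(theta == 0)) {
    stop_fluidshift("All elements of `theta` must be nonzero.", class = "domain")
  }
  if (theta[2] <= 0) {
    stop_fluidshift("theta[2] = 1 / V_B0 must be positive.", class = "inadmissible")
  }
  k <- abs(theta[1])
  v_b0 <- 1 / theta[2]
  alpha <- k * theta[2] / theta[3] - 1
  if (alpha <= 0) {
    stop_fluidshift(
      sprintf("Implied target volume ratio alpha = %.4g is not positive; the regression is physically inadmissible.", alpha),
      class = "inadmissible"
    )
  }
  model_params(alpha = alpha, k = k, v_b0 = v_b0)
}

#' Regression coefficient vector implied by model parameters
#'
#' @param params A [model_params()] object.
#' @return Numeric length-3 vector `c(K, 1/V_B0, K/(V_B0 (1+alpha)))`.
#' @export
theta_from_params <- function(params) {
  params <- as_bv_params(params)
  c(params$k, 1 / params$v_b0, params$k / (params$v_b0 * (1 + params$alpha)))
}

#' Options controlling the nonlinear least-squares fit
#'
#' @param lower,upper Named bounds for `alpha` (dimensionless), `k` (1/min)
#'   and `v_b0` (ml). Defaults: `alpha` in (1e-3, 50], `k` in (1e-4, 10],
#'   `v_b0` in [500, 10000].
#' @param n_starts Number of optimizer start points (`>= 1`): the
#'   regression-based initializer first, then seeded random starts drawn
#'   log-uniformly within the bounds.
#' @param seed RNG seed for the random starts.
#' @param forward Forward model used in the residuals: `"exact"` (piecewise
#'   closed-form solution, default) or `"euler"` (the difference equation,
#'   requiring `t_s`).
#' @param t_s Sampling interval for the Euler forward model; defaults to the
#'   trace's own interval.
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances.
#' @param max_iter Iteration cap per start.
#' @return A list of class `"fit_options"`.
#' @export
fit_options <- function(lower = c(alpha = 1e-3, k = 1e-4, v_b0 = 500),
                        upper = c(alpha = 50, k = 10, v_b0 = 10000),
                        n_starts = 8L,
                        seed = 20160831L,
                        forward = c("exact", "euler"),
                        t_s = NULL,
                        ftol = 1e-12,
                        ptol = 1e-12,
                        max_iter = 300L) {
  forward <- arg_match(forward)
  nm <- c("alpha", "k", "v_b0")
  lower <- lower[nm]; upper <- upper[nm]
  if (anyNA(lower) || anyNA(upper) || any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper) || any(lower <= 0)) {
    stop_fluidshift("Bounds must be finite, positive and ordered for alpha, k, v_b0.",
                    class = "input")
  }
  n_starts <- as.integer(n_starts)
  if (is.na(n_starts) || n_starts < 1L) {
    stop_fluidshift("`n_starts` must be >= 1.", class = "input")
  }
  structure(
    list(lower = lower, upper = upper, n_starts = n_starts,
         seed = as.integer(seed), forward = forward, t_s = t_s,
         ftol = ftol, ptol = ptol, max_iter = as.integer(max_iter)),
    class = "fit_options"
  )
}

#' Fit the model to a fractional blood-volume trace
#'
#' Estimates the subject-specific parameter triple
#' \eqn{\Theta^* = \{\alpha^*, K^*, V_{B0}^*\}} by bounded nonlinear least
#' squares,
#' \deqn{\Theta^* = \arg\min_\Theta \sum_{i=1}^N
#'   [\breve V_B(i) - \hat{\breve V}_B(i, \Theta)]^2,}
#' where the predicted response is the model's forward simulation under the
#' trace's own infusion/loss schedule. Optimization uses
#' Levenberg-Marquardt with box constraints ([minpack.lm::nls.lm()]) from
#' multiple start points: a regression-form initializer
#' ([regression_design()]) first, then seeded random starts; the start
#' reaching the lowest sum of squares wins.
#'
#' @param trace The measured [volume_trace()] (at least 6 samples).
#' @param schedule The [fluid_schedule()] on the same clock.
#' @param options A [fit_options()] list.
#'
#' @return An object of class `"bv_fit"` with elements `params`
#'   (the estimated [model_params()]), `fitted` (tibble of `time`,
#'   `observed`, `fitted`, `residual`, `e_pct`), `rmsne` (percent),
#'   `objective` (raw sum of squared residuals), `diagnostics` (one row per
#'   start: initial and final objective, convergence info, iterations),
#'   `options`, `schedule` and `trace`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' p <- model_params(alpha = 2.35, k = 0.047, v_b0 = 5560)
#' s <- fluid_schedule(c(0, 30), u = c(62.5, 0), v = 0, duration = 240)
#' tr <- synthetic_trace(p, s, t_s = 10, noise_sd = 0, seed = 1)
#' fit <- fit_blood_volume(tr, s, fit_options(n_starts = 2))
#' tidy(fit)
#' @export
fit_blood_volume <- function(trace, schedule, options = fit_options()) {
  trace <- as_volume_trace(trace, anchored = FALSE)
  assert_schedule(schedule)
  if (!inherits(options, "fit_options")) {
    stop_fluidshift("`options` must come from fit_options().", class = "input")
  }
  n <- nrow(trace)
  if (n < 6L) {
    stop_fluidshift("Need at least 6 samples to fit three parameters with margin.",
                    class = "input")
  }
  if (all(trace$vb_frac == 0) || sd(trace$vb_frac) == 0) {
    stop_fluidshift("Flat trace: the data are not informative (no response to fit).",
                    class = "noninformative")
  }

  forward <- make_forward(trace, schedule, options)
  residual_fn <- function(par) {
    trace$vb_frac - forward(model_params(par[1], par[2], par[3]))
  }

  starts <- fit_start_points(trace, schedule, options)
  runs <- map(seq_along(starts), function(s) {
    par0 <- starts[[s]]
    sse0 <- sum(residual_fn(par0)^2)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = options$lower, upper = options$upper,
        fn = residual_fn,
        control = minpack.lm::nls.lm.control(
          ftol = options$ftol, ptol = options$ptol, maxiter = options$max_iter)
      ),
      error = function(e) NULL
    )
    list(start = s, par0 = par0, sse0 = sse0, res = res)
  })
  ok <- purrr::keep(runs, ~ !is.null(.x$res))
  if (length(ok) == 0L) {
    stop_fluidshift("No optimizer start converged.", class = "optim",
                    diagnostics = runs)
  }
  sse <- map_dbl(ok, ~ .x$res$deviance)
  best <- ok[[which.min(sse)]]
  par_star <- setNames(as.numeric(best$res$par), c("alpha", "k", "v_b0"))
  params <- model_params(par_star[1], par_star[2], par_star[3])

  vb_hat <- forward(params)
  gof <- goodness_of_fit(trace$vb_frac, vb_hat)
  diagnostics <- list_rbind(map(runs, function(r) {
    tibble(
      start = r$start,
      alpha0 = r$par0[1], k0 = r$par0[2], v_b00 = r$par0[3],
      objective_start = r$sse0,
      objective = if (is.null(r$res)) NA_real_ else r$res$deviance,
      info = if (is.null(r$res)) NA_integer_ else r$res$info,
      iterations = if (is.null(r$res)) NA_integer_ else r$res$niter,
      converged = if (is.null(r$res)) FALSE else r$res$info %in% 1:4
    )
  }))

  structure(
    list(
      params = params,
      fitted = tibble(
        time = trace$time,
        observed = trace$vb_frac,
        fitted = vb_hat,
        residual = trace$vb_frac - vb_hat,
        e_pct = gof$e
      ),
      rmsne = gof$rmsne,
      objective = best$res$deviance,
      best_start = best$start,
      diagnostics = diagnostics,
      options = options,
      schedule = schedule,
      trace = trace
    ),
    class = "bv_fit"
  )
}

make_forward <- function(trace, schedule, options) {
  if (options$forward == "exact") {
    function(params) simulate_volume(params, schedule, trace$time)$vb_frac
  } else {
    t_s <- options$t_s %||% sampling_interval(trace)
    n_steps <- ceiling(max(trace$time) / t_s)
    function(params) {
      tr <- simulate_volume_euler(params, schedule, t_s, n_steps)
      approx(tr$time, tr$vb_frac, xout = trace$time, rule = 2)$y
    }
  }
}

fit_start_points <- function(trace, schedule, options) {
  lo <- options$lower; hi <- options$upper
  clip <- function(p) pmin(pmax(p, lo), hi)
  starts <- list()
  reg <- tryCatch(regression_design(trace, schedule), fluidshift_error = function(e) NULL)
  if (!is.null(reg) && !is.null(reg$params)) {
    starts <- list(clip(c(alpha = reg$params$alpha, k = reg$params$k,
                          v_b0 = reg$params$v_b0)))
  } else {
    starts <- list(clip(sqrt(lo * hi)))  # geometric mid-bounds fallback
  }
  n_random <- options$n_starts - 1L
  if (n_random > 0L) {
    rand <- with_preserved_seed(options$seed, {
      map(seq_len(n_random), function(i) {
        exp(runif(3, log(lo), log(hi)))
      })
    })
    starts <- c(starts, map(rand, ~ setNames(.x, c("alpha", "k", "v_b0"))))
  }
  starts
}

# Evaluate `code` under a set.seed() without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Normalized goodness-of-fit metrics
#'
#' Per-sample errors and the root-mean-squared error between a measured and
#' a model-reproduced fractional blood-volume response, both normalized by
#' the time-average of the measured response and reported in percent:
#' \deqn{e(i) = \frac{\breve V_B(i) - \hat{\breve V}_B(i)}{\bar{\breve V}_B},
#' \qquad \mathrm{RMSNE} = \frac{1}{\bar{\breve V}_B}
#'   \sqrt{\frac{1}{N}\sum_i [\breve V_B(i) - \hat{\breve V}_B(i)]^2}.}
#'
#' @param observed Measured trace: a [volume_trace()] or numeric vector.
#' @param modeled Model-reproduced trace on the same clock.
#' @return A list with `e` (per-sample normalized errors, percent) and
#'   `rmsne` (percent).
#' @examples
#' goodness_of_fit(rep(0.10, 5), rep(0.09, 5))  # every e(i) = 10%, RMSNE 10%
#' @export
goodness_of_fit <- function(observed, modeled) {
  obs <- if (is.data.frame(observed)) as_volume_trace(observed, anchored = FALSE)$vb_frac else observed
  mod <- if (is.data.frame(modeled)) as_volume_trace(modeled, anchored = FALSE)$vb_frac else modeled
  if (is.data.frame(observed) && is.data.frame(modeled)) {
    if (nrow(observed) != nrow(modeled) ||
        any(abs(observed$time - modeled$time) > 1e-9)) {
      stop_fluidshift("Traces must share the same sample times.", class = "input")
    }
  }
  if (length(obs) != length(mod)) {
    stop_fluidshift("Traces must have equal length.", class = "input")
  }
  vbar <- mean(obs)
  if (vbar == 0) {
    stop_fluidshift("The measured trace has zero mean: normalized errors are undefined.",
                    class = "domain")
  }
  diffs <- obs - mod
  list(
    e = 100 * diffs / vbar,
    rmsne = 100 * sqrt(mean(diffs^2)) / vbar
  )
}

#' @export
print.bv_fit <- function(x, ...) {
  cat("<bv_fit> lumped-parameter blood-volume model\n")
  cat(sprintf("  alpha* = %.4g   K* = %.4g /min   V_B0* = %.4g ml\n",
              x$params$alpha, x$params$k, x$params$v_b0))
  cat(sprintf("  RMSNE %.3g%%  (objective %.3g, %d samples, best start %d/%d)\n",
              x$rmsne, x$objective, nrow(x$fitted), x$best_start,
              nrow(x$diagnostics)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bv_fit <- function(x, ...) {
  as_tibble(x$params)
}

#' @export
glance.bv_fit <- function(x, ...) {
  tibble(
    rmsne = x$rmsne,
    objective = x$objective,
    n = nrow(x$fitted),
    n_starts = nrow(x$diagnostics),
    best_start = x$best_start,
    converged = any(x$diagnostics$converged),
    iterations = x$diagnostics$iterations[x$best_start]
  )
}

#' @export
tidy.bv_params <- function(x, ...) as_tibble(x)
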