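#' Attack-scenario protocol
#'
#' Two protocols are simulated, both starting from the no-hydrolysis steady
#' state reached by a burn-in:
#' * `"bomb"` (mustard oil bomb, tissue disruption): hydrolysis on
#'   (`alpha = 1`) for `pulse_duration` minutes, then off until `horizon`.
#' * `"sustained"` (cell-autonomous hydrolysis, e.g. biotrophic infection):
#'   hydrolysis held on for the whole `horizon`.
#'
#' Time zero is hydrolysis onset (the end of burn-in).
#'
#' @param kind `"bomb"` or `"sustained"`.
#' @param pulse_duration Pulse length in minutes (bomb only; default 1).
#' @param burn_in Burn-in duration in minutes with `alpha = 0` (default 3000).
#' @param horizon Minutes simulated after hydrolysis onset; defaults to
#'   1440 (24 h) for bomb, 5000 for sustained.
#' @param output_step Output grid spacing, minutes (default 0.1).
#' @return An object of class `i3g_scenario`.
#' @export
hydrolysis_scenario <- function(kind = c("bomb", "sustained"),
                                pulse_duration = 1,
                                burn_in = 3000,
                                horizon = NULL,
                                output_step = 0.1) {
  kind <- match.arg(kind)
  horizon <- horizon %||% if (kind == "bomb") 1440 else 5000
  pulse_duration <- ensure_scalar(pulse_duration, "pulse_duration",
                                  positive = TRUE)
  burn_in <- ensure_scalar(burn_in, "burn_in", positive = TRUE)
  horizon <- ensure_scalar(horizon, "horizon", positive = TRUE)
  output_step <- ensure_scalar(output_step, "output_step", positive = TRUE)
  if (kind == "bomb" && pulse_duration >= horizon) {
    abort("`pulse_duration` must be smaller than `horizon`.")
  }
  structure(
    list(kind = kind, pulse_duration = pulse_duration, burn_in = burn_in,
         horizon = horizon, output_step = output_step),
    class = "i3g_scenario"
  )
}

#' @export
print.i3g_scenario <- function(x, ...) {
  cat(sprintf(
    "<i3g_scenario> %s: burn-in %g min, horizon %g min, step %g min%s\n",
    x$kind, x$burn_in, x$horizon, x$output_step,
    if (x$kind == "bomb") sprintf(", pulse %g min", x$pulse_duration) else ""
  ))
  invisible(x)
}

deSolve_rhs <- function(t, y, parms) {
  list(model_rhs(y, parms$params, parms$alpha))
}

# One constant-alpha integration leg; the integrator is restarted at every
# alpha switch, so no internal step ever straddles the discontinuity.
integrate_leg <- function(y0, times, params, alpha, rtol, atol) {
  out <- tryCatch(
    deSolve::ode(
      y = y0, times = times, func = deSolve_rhs,
      parms = list(params = params, alpha = alpha),
      method = "lsoda", rtol = rtol, atol = atol
    ),
    warning = function(w) {
      abort(sprintf("Integration failed after t = %.6g min: %s",
                    times[1], conditionMessage(w)))
    }
  )
  out <- as.data.frame(out)
  names(out) <- c("time", state_vars)
  out
}

time_grid <- function(from, to, by) {
  g <- seq(from, to, by = by)
  if (tail(g, 1L) < to) g <- c(g, to)
  g
}

#' Integrate to the no-hydrolysis steady state
#'
#' Runs the model from the all-zero state with `alpha = 0` for `duration`
#' minutes (default 3000, the published burn-in protocol) and returns the
#' final state. Errors if the result does not sit at the analytic baseline
#' (within 1% on free IAA), which would indicate broken tolerances or
#' degenerate parameters. The zero-theta case (baseline exactly zero) is
#' checked absolutely.
#'
#' @param params An `i3g_params` object.
#' @param duration Burn-in duration, minutes (> 0).
#' @param rtol,atol Solver tolerances (see [simulate_scenario()]).
#' @return Named state vector at the end of burn-in.
#' @export
burn_in <- function(params, duration = 3000, rtol = 1e-8, atol = 1e-16) {
  stopifnot(inherits(params, "i3g_params"))
  duration <- ensure_scalar(duration, "duration", positive = TRUE)
  leg <- integrate_leg(as_state(rep(0, 5)), c(0, duration / 2, duration),
                       params, alpha = 0, rtol = rtol, atol = atol)
  y <- as_state(unlist(leg[nrow(leg), state_vars]))
  ref <- baseline_state(params)
  if (ref[["iaa"]] > 0) {
    if (abs(y[["iaa"]] - ref[["iaa"]]) / ref[["iaa"]] > 0.01) {
      abort(sprintf(
        "Burn-in did not converge: free IAA %.6g uM vs analytic %.6g uM.",
        y[["iaa"]], ref[["iaa"]]))
    }
  } else if (any(abs(y) > 1e-9)) {
    abort("Burn-in did not converge to the zero baseline.")
  }
  y
}

new_trajectory <- function(df, params, scenario, baseline) {
  out <- as_tibble(df)
  class(out) <- c("i3g_trajectory", class(out))
  attr(out, "params") <- params
  attr(out, "scenario") <- scenario
  attr(out, "baseline") <- baseline
  out
}

#' Simulate an attack scenario
#'
#' Burns the model in at `alpha = 0`, then integrates the scenario protocol
#' with a stiff solver (lsoda). The system spans ~6 decades of rates
#' (receptor off-rates ~1.25e3 min^-1 against tau_IAA = 2.4e-3 min^-1), so
#' an implicit stiff method and a very small absolute tolerance are
#' required: the TIR1 complexes live at ~1e-8 uM and would otherwise drown
#' in solver noise. For the bomb protocol the integrator is restarted at
#' the pulse end so no step straddles the alpha switch.
#'
#' @param params An `i3g_params` object.
#' @param scenario An [hydrolysis_scenario()]; default bomb.
#' @param init How to obtain the pre-hydrolysis state: `"integrate"` runs
#'   the burn-in protocol (default, and a cross-check of the analytic
#'   fixed point); `"analytic"` uses [analytic_baseline()] directly.
#' @param keep_burn_in If `TRUE`, the burn-in leg is included at negative
#'   times (only with `init = "integrate"`).
#' @param rtol,atol Relative/absolute solver tolerances (defaults 1e-8 and
#'   1e-16 uM).
#' @return A tibble of class `i3g_trajectory` with columns `time` (min,
#'   0 = hydrolysis onset), `ian`, `ant`, `iaa`, `tir1_iaa`, `tir1_ant`
#'   (uM), and attributes `params`, `scenario`, `baseline`.
#' @examples
#' \donttest{
#' traj <- simulate_scenario(default_parameters(),
#'                           hydrolysis_scenario("bomb", horizon = 120),
#'                           init = "analytic")
#' compute_metrics(traj)
#' }
#' @export
simulate_scenario <- function(params,
                              scenario = hydrolysis_scenario("bomb"),
                              init = c("integrate", "analytic"),
                              keep_burn_in = FALSE,
                              rtol = 1e-8, atol = 1e-16) {
  stopifnot(inherits(params, "i3g_params"), inherits(scenario, "i3g_scenario"))
  init <- match.arg(init)

  burn_leg <- NULL
  if (init == "integrate") {
    if (keep_burn_in) {
      grid <- time_grid(0, scenario$burn_in, scenario$output_step)
      burn_leg <- integrate_leg(as_state(rep(0, 5)), grid, params, 0,
                                rtol, atol)
      y0 <- as_state(unlist(burn_leg[nrow(burn_leg), state_vars]))
      burn_leg$time <- burn_leg$time - scenario$burn_in
      burn_leg <- burn_leg[-nrow(burn_leg), ]
    } else {
      y0 <- burn_in(params, scenario$burn_in, rtol = rtol, atol = atol)
    }
  } else {
    y0 <- baseline_state(params)
  }

  step <- scenario$output_step
  if (scenario$kind == "sustained") {
    main <- integrate_leg(y0, time_grid(0, scenario$horizon, step),
                          params, alpha = 1, rtol = rtol, atol = atol)
  } else {
    pulse <- integrate_leg(y0, time_grid(0, scenario$pulse_duration, step),
                           params, alpha = 1, rtol = rtol, atol = atol)
    y1 <- as_state(unlist(pulse[nrow(pulse), state_vars]))
    relax <- integrate_leg(
      y1, time_grid(scenario$pulse_duration, scenario$horizon, step),
      params, alpha = 0, rtol = rtol, atol = atol)
    main <- bind_rows(pulse, relax[-1L, ])
  }

  df <- if (is.null(burn_leg)) main else bind_rows(burn_leg, main)
  new_trajectory(df, params, scenario, baseline = y0)
}

#' Steady state under a fixed hydrolysis switch
#'
#' Integrates with constant `alpha` over at least `20 / tau_iaa` minutes,
#' then keeps extending the horizon until the componentwise derivative
#' satisfies `|dy/dt| < 1e-9 * max(|y|, 1e-12)` per minute.
#'
#' @param params An `i3g_params` object.
#' @param alpha Hydrolysis switch, 0 or 1.
#' @param rtol,atol Solver tolerances.
#' @param max_chunks Safety cap on horizon extensions before a convergence
#'   error is raised.
#' @return Named state vector at steady state.
#' @export
steady_state <- function(params, alpha, rtol = 1e-8, atol = 1e-16,
                         max_chunks = 10L) {
  stopifnot(inherits(params, "i3g_params"))
  if (!alpha %in% c(0, 1)) abort("`alpha` must be 0 or 1.")
  horizon <- max(20 / max(params$tau_iaa, 1e-6), 5000)
  y <- as_state(rep(0, 5))
  converged <- function(y) {
    d <- model_rhs(y, params, alpha)
    all(abs(d) < 1e-9 * pmax(abs(y), 1e-12))
  }
  for (i in seq_len(max_chunks)) {
    leg <- integrate_leg(y, c(0, horizon / 2, horizon), params, alpha,
                         rtol, atol)
    y <- as_state(unlist(leg[nrow(leg), state_vars]))
    if (converged(y)) return(y)
  }
  abort(sprintf(
    "Steady state not reached within %g min (alpha = %g).",
    horizon * max_chunks, alpha))
}

#' @export
print.i3g_trajectory <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("<i3g_trajectory> %s scenario, %d time points (t %g to %g min)\n",
              if (is.null(sc)) "?" else sc$kind, nrow(x),
              min(x$time), max(x$time)))
  NextMethod()
}

#' One-row trajectory summary
#'
#' @param x An `i3g_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: scenario kind, number of points, time range,
#'   baseline and final TIR1:IAA, and free-IAA range.
#' @export
glance.i3g_trajectory <- function(x, ...) {
  sc <- attr(x, "scenario")
  base <- attr(x, "baseline")
  tibble(
    scenario = if (is.null(sc)) NA_character_ else sc$kind,
    n = nrow(x),
    t_min = min(x$time), t_max = max(x$time),
    baseline_tir1_iaa = if (is.null(base)) x$tir1_iaa[x$time == 0][1]
                        else base[["tir1_iaa"]],
    final_tir1_iaa = x$tir1_iaa[nrow(x)],
    iaa_min = min(x$iaa), iaa_max = max(x$iaa)
  )
}

#' Long-format view of a trajectory
#'
#' @param x An `i3g_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `species`, `concentration`.
#' @export
tidy.i3g_trajectory <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"time",
                      names_to = "species", values_to = "concentration")
}
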