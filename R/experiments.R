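new_sweep <- function(df, scenario, axes) {
  out <- as_tibble(df)
  class(out) <- c("i3g_sweep", class(out))
  attr(out, "scenario") <- scenario
  attr(out, "axes") <- axes
  out
}

#' @export
print.i3g_sweep <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("<i3g_sweep> axes: %s; scenario: %s\n",
              paste(attr(x, "axes"), collapse = ", "),
              if (is.null(sc)) "?" else sc$kind))
  NextMethod()
}

# One sweep cell: simulate, reduce to metrics, never abort the sweep on an
# engine error -- the failure is recorded in the `error` column instead.
run_cell <- function(params, scenario, init, recovery_fraction = 0.05) {
  tryCatch({
    traj <- simulate_scenario(params, scenario, init = init)
    m <- tidy(compute_metrics(traj, recovery_fraction))
    m$baseline_crossing <- baseline_crossing_time(traj)
    m$ian_peak <- max(traj$ian[traj$time >= 0])
    m$ant_peak <- max(traj$ant[traj$time >= 0])
    m$error <- NA_character_
    m
  }, error = function(e) {
    tibble(baseline = NA_real_, min_value = NA_real_, min_time = NA_real_,
           drop_amplitude = NA_real_, fold_decrease = NA_real_,
           recovery_time = NA_real_, overshoot_peak = NA_real_,
           overshoot_time = NA_real_, final_value = NA_real_,
           final_fold_vs_baseline = NA_real_,
           baseline_crossing = NA_real_,
           ian_peak = NA_real_, ant_peak = NA_real_,
           error = conditionMessage(e))
  })
}

#' Sweep the nitrile-specifier fraction beta
#'
#' One simulation plus response metrics per beta value. Low beta routes
#' hydrolysis into the antagonist branch (large TIR1:IAA drop); beta = 1
#' produces no antagonist at all. The default grid covers the two values
#' highlighted in the source data (0.01 and the Col-0 seedling value 0.8).
#'
#' @param params Base parameters (default [default_parameters()]).
#' @param betas Beta grid, each in `[0, 1]`.
#' @param scenario An [hydrolysis_scenario()].
#' @param init Passed to [simulate_scenario()].
#' @return An `i3g_sweep` tibble: one row per beta with metric columns plus
#'   `ian_peak` / `ant_peak`.
#' @export
beta_sweep <- function(params = default_parameters(),
                       betas = c(0.01, 0.2, 0.5, 0.8, 0.99),
                       scenario = hydrolysis_scenario("bomb"),
                       init = "integrate") {
  if (any(betas < 0 | betas > 1)) abort("every `beta` must lie in [0, 1]")
  rows <- map_dfr(betas, function(b) {
    p <- params
    p$beta <- b
    run_cell(p, scenario, init)
  })
  new_sweep(bind_cols(tibble(beta = betas), rows), scenario, "beta")
}

#' Fold sweep over MYR, I3G or NIT concentration
#'
#' Scales one concentration (enzyme abundance or substrate pool) by each
#' fold factor and records the response metrics, emulating the locally
#' enriched myrosin-cell / S-cell environments.
#'
#' @param params Base parameters.
#' @param which `"myr"`, `"i3g"` or `"nit"`.
#' @param folds Positive fold factors; defaults 1/10/100/1000 for MYR and
#'   I3G, 1/10/100 for NIT.
#' @param scenario An [hydrolysis_scenario()].
#' @param init Passed to [simulate_scenario()].
#' @return An `i3g_sweep` tibble, one row per fold.
#' @export
fold_sweep <- function(params = default_parameters(),
                       which = c("myr", "i3g", "nit"),
                       folds = NULL,
                       scenario = hydrolysis_scenario("bomb"),
                       init = "integrate") {
  which <- match.arg(which)
  folds <- folds %||% if (which == "nit") c(1, 10, 100) else c(1, 10, 100, 1000)
  if (length(folds) == 0L) abort("`folds` must contain at least one value.")
  if (any(folds <= 0)) abort("every fold must be > 0")
  rows <- map_dfr(folds, function(f) {
    run_cell(scale_parameter(params, which, f), scenario, init)
  })
  out <- bind_cols(tibble(which = which, fold = folds), rows)
  new_sweep(out, scenario, "fold")
}

#' MYR x I3G synergy heatmap
#'
#' Bomb-scenario drop amplitude (uM) on a grid of simultaneous MYR and I3G
#' fold increases. MYR fold increases the drop throughout; the I3G effect
#' saturates because the hydrolysis flux is Michaelis-Menten in I3G
#' (Km = 245 uM for the default TGG4).
#'
#' @param params Base parameters.
#' @param myr_folds,i3g_folds Positive fold grids.
#' @param scenario An [hydrolysis_scenario()] (default bomb).
#' @param init Passed to [simulate_scenario()].
#' @return An `i3g_sweep` tibble, one row per `(myr_fold, i3g_fold)` cell.
#' @export
myr_i3g_heatmap <- function(params = default_parameters(),
                            myr_folds = c(1, 10, 100, 1000),
                            i3g_folds = c(1, 10, 100, 1000),
                            scenario = hydrolysis_scenario("bomb"),
                            init = "integrate") {
  if (any(myr_folds <= 0) || any(i3g_folds <= 0)) {
    abort("every fold must be > 0")
  }
  grid <- tidyr::expand_grid(myr_fold = myr_folds, i3g_fold = i3g_folds)
  rows <- map_dfr(seq_len(nrow(grid)), function(i) {
    p <- scale_parameter(params, "myr", grid$myr_fold[i])
    p <- scale_parameter(p, "i3g", grid$i3g_fold[i])
    run_cell(p, scenario, init)
  })
  new_sweep(bind_cols(grid, rows), scenario, c("myr_fold", "i3g_fold"))
}

#' Enzyme isoform panel
#'
#' One run per registered myrosinase or nitrilase isoform, swapping in the
#' isoform's full (abundance, Vmax, Km) triple with all other parameters at
#' their defaults, as the published isoform comparisons do.
#'
#' @param params Base parameters.
#' @param kind `"myr"` or `"nit"`.
#' @param scenario An [hydrolysis_scenario()].
#' @param init Passed to [simulate_scenario()].
#' @return An `i3g_sweep` tibble, one row per isoform.
#' @export
isoform_panel <- function(params = default_parameters(),
                          kind = c("myr", "nit"),
                          scenario = hydrolysis_scenario("bomb"),
                          init = "integrate") {
  kind <- match.arg(kind)
  registry <- if (kind == "myr") myr_isoforms() else nit_isoforms()
  swap <- if (kind == "myr") with_myr_isoform else with_nit_isoform
  rows <- map_dfr(registry$name, function(nm) {
    run_cell(swap(params, nm), scenario, init)
  })
  new_sweep(bind_cols(tibble(isoform = registry$name), rows),
            scenario, "isoform")
}

#' Antagonist panel
#'
#' One run per docking-characterised antagonist (see [tir1_ligands()]),
#' swapping in its TIR1 dissociation constant. Tighter binders (lower K_D)
#' produce stronger TIR1:IAA inhibition; under sustained hydrolysis the
#' strongest ones hold signaling at a new lower steady state.
#'
#' @param params Base parameters.
#' @param scenario An [hydrolysis_scenario()].
#' @param init Passed to [simulate_scenario()].
#' @param names Which registry ligands to run (default: all antagonists).
#' @return An `i3g_sweep` tibble, one row per antagonist, including its
#'   `kd_tir1`.
#' @export
antagonist_panel <- function(params = default_parameters(),
                             scenario = hydrolysis_scenario("bomb"),
                             init = "integrate",
                             names = NULL) {
  reg <- tir1_ligands()
  names <- names %||% reg$name[reg$antagonist]
  bad <- setdiff(names, reg$name)
  if (length(bad) > 0) {
    abort(sprintf("Unknown antagonist(s): %s.", paste(bad, collapse = ", ")))
  }
  rows <- map_dfr(names, function(nm) {
    run_cell(with_antagonist(params, nm), scenario, init)
  })
  kd <- reg$kd_tir1[match(names, reg$name)]
  new_sweep(bind_cols(tibble(antagonist = names, kd_tir1 = kd), rows),
            scenario, "antagonist")
}
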