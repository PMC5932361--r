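state_vars <- c("ian", "ant", "iaa", "tir1_iaa", "tir1_ant")

as_state <- function(x) {
  stopifnot(is.numeric(x), length(x) == 5L)
  setNames(as.numeric(x), state_vars)
}

#' Michaelis-Menten enzymatic flux
#'
#' Flux of an enzyme pool on a substrate: `abundance * vmax * S / (km + S)`.
#' Units resolve to uM/min: (mg/L) x (umol/min/mg) = umol/L/min = uM/min.
#'
#' @param enzyme An [enzyme_kinetics()] record.
#' @param substrate Substrate concentration, uM (>= 0; vectorised).
#' @return Flux in uM/min.
#' @examples
#' mm_rate(enzyme_kinetics("TGG4", 0.37, 12.2, 245), 100)
#' @export
mm_rate <- function(enzyme, substrate) {
  stopifnot(inherits(enzyme, "i3g_enzyme"))
  if (!is.numeric(substrate) || any(!is.finite(substrate)) ||
      any(substrate < 0)) {
    abort("`substrate` must be finite and >= 0.")
  }
  enzyme$abundance * enzyme$vmax * substrate / (enzyme$km + substrate)
}

#' Right-hand side of the hydrolysis/signaling ODE system
#'
#' The five coupled equations, with hydrolysis gated by the scenario switch
#' `alpha` (0 = no hydrolysis, 1 = hydrolysis on):
#'
#' \deqn{dIAN/dt = \beta \alpha F_{MYR} - \tau_{IAN} IAN}
#' \deqn{dAnt/dt = (1-\beta)\alpha F_{MYR} - \tau_{Ant} Ant
#'       - k_{on}^{Ant} T_f Ant + k_{off}^{Ant} [TIR1{:}Ant]}
#' \deqn{dIAA/dt = \theta + F_{NIT}(IAN) - \tau_{IAA} IAA
#'       - k_{on}^{IAA} T_f IAA + k_{off}^{IAA} [TIR1{:}IAA]}
#' \deqn{d[TIR1{:}IAA]/dt = k_{on}^{IAA} T_f IAA - k_{off}^{IAA} [TIR1{:}IAA]}
#' \deqn{d[TIR1{:}Ant]/dt = k_{on}^{Ant} T_f Ant - k_{off}^{Ant} [TIR1{:}Ant]}
#'
#' where `F_MYR = mm_rate(myr, i3g)`, `F_NIT(IAN) = mm_rate(nit, IAN)` and
#' the free receptor is `T_f = tir1_total - tir1_iaa - tir1_ant`. The I3G
#' pool is a constant parameter (no depletion equation); MYR, NIT and TIR1
#' protein levels are constant.
#'
#' @param state Named numeric vector `(ian, ant, iaa, tir1_iaa, tir1_ant)`,
#'   uM.
#' @param params An `i3g_params` object.
#' @param alpha Hydrolysis switch, 0 or 1 (scenario-level, not a state).
#' @return Named numeric derivative vector, uM/min.
#' @export
model_rhs <- function(state, params, alpha) {
  stopifnot(inherits(params, "i3g_params"))
  if (!alpha %in% c(0, 1)) abort("`alpha` must be 0 or 1.")
  y <- as_state(state)
  free <- params$tir1_total - y[["tir1_iaa"]] - y[["tir1_ant"]]
  hyd <- alpha * mm_rate(params$myr, params$i3g)
  nit_flux <- mm_rate(params$nit, max(y[["ian"]], 0))
  kon_i <- params$binding_iaa$kon
  koff_i <- params$binding_iaa$koff
  kon_a <- params$binding_ant$kon
  koff_a <- params$binding_ant$koff
  bind_i <- kon_i * free * y[["iaa"]] - koff_i * y[["tir1_iaa"]]
  bind_a <- kon_a * free * y[["ant"]] - koff_a * y[["tir1_ant"]]
  c(
    ian = params$beta * hyd - params$tau_ian * y[["ian"]],
    ant = (1 - params$beta) * hyd - params$tau_ant * y[["ant"]] - bind_a,
    iaa = params$theta + nit_flux - params$tau_iaa * y[["iaa"]] - bind_i,
    tir1_iaa = bind_i,
    tir1_ant = bind_a
  )
}

#' Quasi-equilibrium receptor occupancy
#'
#' Partitioning of total TIR1 among two competing ligands when binding is
#' much faster than production and decay (here the total receptor,
#' 1.595e-5 uM, is also at least four orders of magnitude below the ligand
#' scales, so ligand sequestration by the receptor is negligible):
#' `tir1_iaa = T * (iaa/kd_iaa) / (1 + iaa/kd_iaa + ant/kd_ant)` and
#' analogously for the antagonist complex. This is the analytic oracle the
#' simulated complexes are expected to track.
#'
#' @param iaa,ant Free ligand concentrations, uM (>= 0; vectorised).
#' @param params An `i3g_params` object.
#' @return A tibble with columns `tir1_iaa`, `tir1_ant` (uM).
#' @export
equilibrium_occupancy <- function(iaa, ant, params) {
  stopifnot(inherits(params, "i3g_params"))
  if (any(iaa < 0) || any(ant < 0)) abort("ligand concentrations must be >= 0")
  x <- iaa / params$binding_iaa$kd
  z <- ant / params$binding_ant$kd
  denom <- 1 + x + z
  tibble(
    tir1_iaa = params$tir1_total * x / denom,
    tir1_ant = params$tir1_total * z / denom
  )
}

#' Closed-form steady state without hydrolysis
#'
#' With `alpha = 0` nothing feeds the IAN or antagonist pools, so both decay
#' to zero and free IAA settles at `theta / tau_iaa`; the receptor complexes
#' follow from [equilibrium_occupancy()]. This is an exact fixed point of
#' [model_rhs()] and the reference state every simulation starts from.
#' With the default parameters it reproduces the measured ~0.02 uM free IAA
#' of unchallenged seedlings.
#'
#' @param params An `i3g_params` object.
#' @return Named state vector `(ian, ant, iaa, tir1_iaa, tir1_ant)` as a
#'   list with numeric fields.
#' @examples
#' analytic_baseline(default_parameters())$iaa  # 0.0208333...
#' @export
analytic_baseline <- function(params) {
  stopifnot(inherits(params, "i3g_params"))
  if (params$tau_iaa <= 0) {
    abort("`tau_iaa` must be > 0 for a finite baseline (degenerate parameters).")
  }
  iaa <- params$theta / params$tau_iaa
  occ <- equilibrium_occupancy(iaa, 0, params)
  list(ian = 0, ant = 0, iaa = iaa,
       tir1_iaa = occ$tir1_iaa, tir1_ant = occ$tir1_ant)
}

baseline_state <- function(params) {
  b <- analytic_baseline(params)
  as_state(c(b$ian, b$ant, b$iaa, b$tir1_iaa, b$tir1_ant))
}
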