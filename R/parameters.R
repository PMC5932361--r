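ensure_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  as.numeric(x)
}

#' Enzyme kinetics record
#'
#' Bundles the abundance and Michaelis-Menten constants of one myrosinase
#' (MYR) or nitrilase (NIT) isoform. The enzymatic flux on a substrate pool
#' `S` is `abundance * vmax * S / (km + S)`; with abundance in mg enzyme/L
#' and vmax in umol/min/mg enzyme the flux comes out in uM/min.
#'
#' @param name Isoform label (e.g. `"TGG4"`).
#' @param abundance Enzyme abundance, mg enzyme per litre of tissue (>= 0).
#' @param vmax Maximum reaction velocity, umol per minute per mg enzyme (>= 0).
#' @param km Michaelis-Menten constant, uM (> 0).
#' @return An object of class `i3g_enzyme`.
#' @examples
#' tgg4 <- enzyme_kinetics("TGG4", abundance = 0.37, vmax = 12.2, km = 245)
#' mm_rate(tgg4, substrate = 100)
#' @export
enzyme_kinetics <- function(name, abundance, vmax, km) {
  stopifnot(is.character(name), length(name) == 1L)
  out <- list(
    name = name,
    abundance = ensure_scalar(abundance, "abundance", nonneg = TRUE),
    vmax = ensure_scalar(vmax, "vmax", nonneg = TRUE),
    km = ensure_scalar(km, "km", positive = TRUE)
  )
  structure(out, class = "i3g_enzyme")
}

#' @export
print.i3g_enzyme <- function(x, ...) {
  cat(sprintf(
    "<i3g_enzyme> %s: abundance %g mg/L, Vmax %g umol/min/mg, Km %g uM\n",
    x$name, x$abundance, x$vmax, x$km
  ))
  invisible(x)
}

#' Receptor binding parameters from a dissociation constant
#'
#' Binding of a ligand to the TIR1 receptor is parameterised by its
#' dissociation constant K_D = k_off / k_on. The on-rate is taken as
#' diffusion-fast (1 uM^-1 s^-1 = 60 uM^-1 min^-1 by default, much faster
#' than the minutes timescale of production and decay), and the off-rate is
#' derived as `koff = kd * kon`.
#'
#' @param kd Dissociation constant, uM (> 0).
#' @param kon On-rate, uM^-1 min^-1 (> 0); default 60.
#' @return An object of class `i3g_binding` with fields `kd`, `kon`, `koff`.
#' @examples
#' binding_parameters(kd = 20.86)            # TIR1:IAA
#' derive_binding(12.48, kon = 60)           # TIR1:antagonist
#' @export
binding_parameters <- function(kd, kon = 60) {
  kd <- ensure_scalar(kd, "kd", positive = TRUE)
  kon <- ensure_scalar(kon, "kon", positive = TRUE)
  structure(list(kd = kd, kon = kon, koff = kd * kon), class = "i3g_binding")
}

#' @rdname binding_parameters
#' @export
derive_binding <- function(kd, kon = 60) binding_parameters(kd, kon)

#' @export
print.i3g_binding <- function(x, ...) {
  cat(sprintf(
    "<i3g_binding> KD %g uM (kon %g /uM/min, koff %g /min)\n",
    x$kd, x$kon, x$koff
  ))
  invisible(x)
}

#' Full model parameter set
#'
#' Collects every parameter of the five-variable hydrolysis/signaling model:
#' the constant I3G substrate pool, one MYR and one NIT isoform, the
#' nitrile-specifier fraction beta, total TIR1 receptor, binding parameters
#' for IAA and for the antagonist pool, first-order decay rates, and the
#' basal IAA synthesis rate theta.
#'
#' @param i3g I3G pool, uM (constant; the model has no dI3G/dt).
#' @param myr,nit [enzyme_kinetics()] records for the active isoforms.
#' @param beta Fraction of hydrolysis routed to the nitrile (IAN) branch,
#'   in `[0, 1]`; `1 - beta` feeds the antagonist branch.
#' @param tir1_total Total TIR1 receptor concentration, uM (> 0).
#' @param binding_iaa,binding_ant [binding_parameters()] for TIR1:IAA and
#'   TIR1:antagonist.
#' @param tau_ian,tau_iaa,tau_ant First-order degradation rates, min^-1.
#' @param theta Basal IAA synthesis from non-I3G sources, uM min^-1.
#' @return An object of class `i3g_params`.
#' @seealso [default_parameters()] for the published default set.
#' @export
model_parameters <- function(i3g, myr, nit, beta, tir1_total,
                             binding_iaa, binding_ant,
                             tau_ian, tau_iaa, tau_ant, theta) {
  stopifnot(inherits(myr, "i3g_enzyme"), inherits(nit, "i3g_enzyme"),
            inherits(binding_iaa, "i3g_binding"),
            inherits(binding_ant, "i3g_binding"))
  beta <- ensure_scalar(beta, "beta")
  if (beta < 0 || beta > 1) abort("`beta` must lie in [0, 1].")
  out <- list(
    i3g = ensure_scalar(i3g, "i3g", nonneg = TRUE),
    myr = myr, nit = nit, beta = beta,
    tir1_total = ensure_scalar(tir1_total, "tir1_total", positive = TRUE),
    binding_iaa = binding_iaa, binding_ant = binding_ant,
    tau_ian = ensure_scalar(tau_ian, "tau_ian", nonneg = TRUE),
    tau_iaa = ensure_scalar(tau_iaa, "tau_iaa", nonneg = TRUE),
    tau_ant = ensure_scalar(tau_ant, "tau_ant", nonneg = TRUE),
    theta = ensure_scalar(theta, "theta", nonneg = TRUE)
  )
  structure(out, class = "i3g_params")
}

#' @export
print.i3g_params <- function(x, ...) {
  cat("<i3g_params>\n")
  cat(sprintf("  I3G pool: %g uM   beta: %g   TIR1 total: %g uM\n",
              x$i3g, x$beta, x$tir1_total))
  cat(sprintf("  MYR %s (%g mg/L, Vmax %g, Km %g)\n",
              x$myr$name, x$myr$abundance, x$myr$vmax, x$myr$km))
  cat(sprintf("  NIT %s (%g mg/L, Vmax %g, Km %g)\n",
              x$nit$name, x$nit$abundance, x$nit$vmax, x$nit$km))
  cat(sprintf("  KD TIR1:IAA %g uM, TIR1:Ant %g uM (kon %g /uM/min)\n",
              x$binding_iaa$kd, x$binding_ant$kd, x$binding_iaa$kon))
  cat(sprintf("  tau IAN %g, IAA %g, Ant %g /min; theta %g uM/min\n",
              x$tau_ian, x$tau_iaa, x$tau_ant, x$theta))
  invisible(x)
}

#' Myrosinase isoform registry
#'
#' Root-tissue abundances and sinigrin-derived kinetic constants for the
#' classical myrosinases TGG1/TGG4/TGG5 and the atypical myrosinases
#' PEN2/PYK10.
#'
#' @return A tibble with columns `name`, `abundance` (mg enzyme/L),
#'   `vmax` (umol/min/mg), `km` (uM).
#' @export
myr_isoforms <- function() {
  tibble(
    name = c("TGG1", "TGG4", "TGG5", "PEN2", "PYK10"),
    abundance = c(0.0022, 0.37, 0.26, 0.12, 25.53),
    vmax = c(2.3, 12.2, 48.1, 7.50, 0.00063),
    km = c(45, 245, 547, 722, 82)
  )
}

#' Nitrilase isoform registry
#'
#' NIT1-NIT3 only: NIT4 does not convert IAN to IAA and is excluded.
#'
#' @return A tibble with columns `name`, `abundance`, `vmax`, `km`.
#' @export
nit_isoforms <- function() {
  tibble(
    name = c("NIT1", "NIT2", "NIT3"),
    abundance = c(0.67, 0.62, 0.20),
    vmax = c(0.038, 0.018, 0.015),
    km = c(11100, 7400, 30100)
  )
}

#' TIR1 ligand registry (docking-derived dissociation constants)
#'
#' Dissociation constants of I3G hydrolysis products (and, for reference,
#' IAA and IAN) for the free TIR1 receptor and for the TIR1:IAA:IAA7
#' complex, estimated by molecular docking. Only `kd_tir1` enters the
#' dynamic model; `kd_tir1_iaa7` is reference data on whether the ligand can
#' be accommodated once the IAA7 degron is bound. The decay rate `tau`
#' (0.125 min^-1, measured for ascorbigen) is applied to every antagonist.
#'
#' @return A tibble with columns `name`, `kd_tir1` (uM), `kd_tir1_iaa7`
#'   (uM), `tau` (min^-1) and `antagonist` (logical: usable with
#'   [with_antagonist()] as the competing ligand pool).
#' @export
tir1_ligands <- function() {
  tibble(
    name = c("IAA", "IAN", "I3C", "I3M-cysteine", "I3M-ascorbate",
             "I3M-glutathione", "I3M-I3M-cysteine", "I3M-I3M-glutathione"),
    kd_tir1 = c(20.86, 29.37, 49.06, 24.75, 12.48, 6.30, 14.81, 1.14),
    kd_tir1_iaa7 = c(1.35, 1.60, 6.30, 6.30, 115.41, 69.08, 81.97, 1.11e9),
    tau = 0.125,
    antagonist = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
}

#' Default (published) parameter set
#'
#' The starred defaults: TGG4 myrosinase, NIT1 nitrilase, I3G 100 uM,
#' beta 0.8, TIR1 1.595e-5 uM, K_D(TIR1:IAA) 20.86 uM, antagonist =
#' I3M-ascorbate (ascorbigen, K_D 12.48 uM), tau_IAN 0.1, tau_IAA 0.0024,
#' tau_Ant 0.125 min^-1, theta 5e-5 uM/min, k_on 60 uM^-1 min^-1.
#'
#' @return An `i3g_params` object.
#' @examples
#' p <- default_parameters()
#' analytic_baseline(p)$iaa  # ~0.0208 uM free IAA
#' @export
default_parameters <- function() {
  myr <- myr_isoforms()
  nit <- nit_isoforms()
  tgg4 <- myr[myr$name == "TGG4", ]
  nit1 <- nit[nit$name == "NIT1", ]
  model_parameters(
    i3g = 100,
    myr = enzyme_kinetics(tgg4$name, tgg4$abundance, tgg4$vmax, tgg4$km),
    nit = enzyme_kinetics(nit1$name, nit1$abundance, nit1$vmax, nit1$km),
    beta = 0.8,
    tir1_total = 1.595e-5,
    binding_iaa = binding_parameters(20.86, kon = 60),
    binding_ant = binding_parameters(12.48, kon = 60),
    tau_ian = 0.1, tau_iaa = 0.0024, tau_ant = 0.125,
    theta = 5e-5
  )
}

lookup_isoform <- function(registry, name, what) {
  hit <- registry[registry$name == name, ]
  if (nrow(hit) != 1L) {
    abort(sprintf("Unknown %s isoform '%s'. Valid names: %s.",
                  what, name, paste(registry$name, collapse = ", ")))
  }
  enzyme_kinetics(hit$name, hit$abundance, hit$vmax, hit$km)
}

#' Swap in a named antagonist, myrosinase or nitrilase
#'
#' `with_antagonist()` replaces the antagonist dissociation constant with
#' the docking value for the named ligand (K_D for free TIR1); the
#' antagonist decay rate is unchanged, since the ascorbigen-derived
#' 0.125 min^-1 is applied to all antagonists. `with_myr_isoform()` and
#' `with_nit_isoform()` swap the full (abundance, Vmax, Km) triple of the
#' named isoform.
#'
#' @param params An `i3g_params` object.
#' @param name Registry name (see [tir1_ligands()], [myr_isoforms()],
#'   [nit_isoforms()]).
#' @return A modified copy of `params`.
#' @examples
#' p <- with_antagonist(default_parameters(), "I3M-I3M-glutathione")
#' p$binding_ant$kd  # 1.14 uM
#' @export
with_antagonist <- function(params, name) {
  stopifnot(inherits(params, "i3g_params"))
  reg <- tir1_ligands()
  hit <- reg[reg$name == name, ]
  if (nrow(hit) != 1L) {
    abort(sprintf("Unknown antagonist '%s'. Valid names: %s.",
                  name, paste(reg$name, collapse = ", ")))
  }
  params$binding_ant <- binding_parameters(hit$kd_tir1,
                                           kon = params$binding_ant$kon)
  params
}

#' @rdname with_antagonist
#' @export
with_myr_isoform <- function(params, name) {
  stopifnot(inherits(params, "i3g_params"))
  params$myr <- lookup_isoform(myr_isoforms(), name, "myrosinase")
  params
}

#' @rdname with_antagonist
#' @export
with_nit_isoform <- function(params, name) {
  stopifnot(inherits(params, "i3g_params"))
  params$nit <- lookup_isoform(nit_isoforms(), name, "nitrilase")
  params
}

#' Scale a concentration-like parameter by a fold factor
#'
#' Multiplies the named pool or protein concentration by `fold`, leaving
#' kinetic constants (Vmax, Km, K_D, rates) untouched. Used for the local
#' enrichment experiments (myrosin cells and S-cells hold far more MYR and
#' I3G than the seedling average).
#'
#' @param params An `i3g_params` object.
#' @param which One of `"myr"`, `"nit"` (enzyme abundance), `"i3g"`
#'   (substrate pool), `"tir1"` (total receptor).
#' @param fold Positive multiplier.
#' @return A modified copy of `params`.
#' @examples
#' scale_parameter(default_parameters(), "myr", 100)$myr$abundance  # 37
#' @export
scale_parameter <- function(params, which = c("myr", "nit", "i3g", "tir1"),
                            fold) {
  stopifnot(inherits(params, "i3g_params"))
  which <- match.arg(which)
  fold <- ensure_scalar(fold, "fold", positive = TRUE)
  switch(which,
    myr = { params$myr$abundance <- params$myr$abundance * fold },
    nit = { params$nit$abundance <- params$nit$abundance * fold },
    i3g = { params$i3g <- params$i3g * fold },
    tir1 = { params$tir1_total <- params$tir1_total * fold }
  )
  params
}

#' Tissue concentration from amount and volume
#'
#' Converts a measured amount (nmol) in a tissue volume (uL, assuming a
#' density of ~1 g/mL so that mg fresh weight ~ uL) to a concentration in
#' uM: nmol/uL = mmol/L, i.e. `amount / volume * 1000` uM. The published
#' I3G pool follows from ~0.1 nmol in a ~1 uL (5-day-old) seedling.
#'
#' @param amount_nmol Amount in nmol (>= 0).
#' @param volume_ul Volume in uL (> 0).
#' @return Concentration in uM.
#' @examples
#' tissue_concentration(0.1, 1)  # 100 uM
#' @export
tissue_concentration <- function(amount_nmol, volume_ul) {
  if (!is.numeric(amount_nmol) || any(amount_nmol < 0)) {
    abort("`amount_nmol` must be numeric and >= 0.")
  }
  if (!is.numeric(volume_ul) || any(volume_ul <= 0)) {
    abort("`volume_ul` must be numeric and > 0.")
  }
  amount_nmol / volume_ul * 1000
}

# ---- config serialization ---------------------------------------------------

params_to_list <- function(params) {
  list(
    i3g = params$i3g,
    beta = params$beta,
    tir1_total = params$tir1_total,
    theta = params$theta,
    tau_ian = params$tau_ian,
    tau_iaa = params$tau_iaa,
    tau_ant = params$tau_ant,
    kon = params$binding_iaa$kon,
    kd_iaa = params$binding_iaa$kd,
    kd_ant = params$binding_ant$kd,
    myr = list(name = params$myr$name, abundance = params$myr$abundance,
               vmax = params$myr$vmax, km = params$myr$km),
    nit = list(name = params$nit$name, abundance = params$nit$abundance,
               vmax = params$nit$vmax, km = params$nit$km)
  )
}

params_from_list <- function(x) {
  allowed <- c("i3g", "beta", "tir1_total", "theta", "tau_ian", "tau_iaa",
               "tau_ant", "kon", "kd_iaa", "kd_ant", "myr", "nit")
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown parameter key(s): %s. Allowed keys: %s.",
                  paste(unknown, collapse = ", "),
                  paste(allowed, collapse = ", ")))
  }
  missing <- setdiff(allowed, names(x))
  if (length(missing) > 0) {
    abort(sprintf("Missing parameter key(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  model_parameters(
    i3g = x$i3g,
    myr = enzyme_kinetics(x$myr$name, x$myr$abundance, x$myr$vmax, x$myr$km),
    nit = enzyme_kinetics(x$nit$name, x$nit$abundance, x$nit$vmax, x$nit$km),
    beta = x$beta,
    tir1_total = x$tir1_total,
    binding_iaa = binding_parameters(x$kd_iaa, kon = x$kon),
    binding_ant = binding_parameters(x$kd_ant, kon = x$kon),
    tau_ian = x$tau_ian, tau_iaa = x$tau_iaa, tau_ant = x$tau_ant,
    theta = x$theta
  )
}

#' Read and write parameter sets as YAML
#'
#' The YAML keys mirror the published parameter names (`i3g`, `beta`,
#' `tir1_total`, `theta`, `tau_ian`, `tau_iaa`, `tau_ant`, `kon`, `kd_iaa`,
#' `kd_ant`, and nested `myr`/`nit` blocks). Unknown or missing keys are
#' hard errors: a silently ignored typo in a parameter name would corrupt a
#' simulation. Values are written with 15 significant digits so a
#' round-trip reproduces the numbers.
#'
#' @param params An `i3g_params` object.
#' @param path File path.
#' @return `read_params()` returns an `i3g_params`; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "i3g_params"))
  writeLines(yaml::as.yaml(params_to_list(params), precision = 15), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  params_from_list(yaml::read_yaml(path))
}
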