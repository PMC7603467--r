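#' Assemble a whole-body PBTK model
#'
#' Combines a species physiology, a compound and an administration
#' protocol into a perfusion-limited whole-body model with 29 state
#' variables: 15 organs, three blood pools (venous, arterial, portal),
#' eight gut lumen segments and three sinks (metabolized, urine, faeces).
#' All derived quantities — absolute dose, organ blood flows, cardiac
#' output, partition coefficients, lumen geometry and transit rates — are
#' recomputed from scratch from the current parameter values, so a model
#' rebuilt after any parameter change carries no stale caches.
#'
#' The absolute dose is `dose_per_kg * body_weight / molecular_weight`
#' converted to umol; organ blood flow is `specific_blood_flow * volume`;
#' cardiac output is the sum of all arterial-fed inflows (every organ
#' except the lung, whose flow is the cardiac output itself). Portal
#' draining organs (spleen, stomach, small and large intestine walls)
#' feed the portal vein, which perfuses the liver together with the
#' hepatic artery.
#'
#' @param species a [species_physiology()].
#' @param compound a [compound()].
#' @param protocol an [admin_protocol()].
#' @param validate validate the species invariants first (default `TRUE`;
#'   perturbation rebuilds switch this off so that one-at-a-time
#'   perturbations are not renormalized away).
#' @return an object of class `pbtk_model`.
#' @examples
#' m <- build_model(species_template("rabbit"),
#'                  compound("x", 200, 0.5, specific_hepatic_clearance = 0.3),
#'                  admin_protocol("iv_bolus", 10))
#' m
#' @export
build_model <- function(species, compound, protocol, validate = TRUE) {
  stopifnot(inherits(species, "species_physiology"),
            inherits(compound, "compound"),
            inherits(protocol, "admin_protocol"))
  if (validate) validate_species(species)
  if (protocol$route == "oral" && length(species$lumen) == 0)
    stop("oral administration requires a gut lumen")

  dose_mg <- protocol$dose_per_kg * species$body_weight
  dose_umol <- dose_mg / compound$molecular_weight * 1000

  part <- partition_coefficients(species, compound)
  BP <- part$BP
  org <- species$organs[ORGAN_NAMES]
  V <- vapply(org, `[[`, 0, "volume")
  Q <- vapply(org, `[[`, 0, "specific_blood_flow") * V
  drains <- vapply(org, function(o) o$drains_to == "portal", NA)
  # cardiac output = sum of arterial inflows; the lung carries it in series
  CO <- sum(Q[ORGAN_NAMES != "lung"])
  Q["lung"] <- CO
  Q_pv <- sum(Q[drains])

  # gut lumen geometry and effective transit
  lum <- species$lumen
  rbar <- vapply(lum, function(s) (s$proximal_radius + s$distal_radius) / 2, 0)
  len <- vapply(lum, `[[`, 0, "length")
  sef <- vapply(lum, `[[`, 0, "surface_enhancement_factor")
  fill <- vapply(lum, `[[`, 0, "fill_fraction")
  pH_l <- vapply(lum, `[[`, 0, "pH")
  rate <- vapply(lum, `[[`, 0, "transit_rate")
  SA <- 2 * pi * rbar * len * sef                       # cm^2
  V_lum <- pi * rbar^2 * len * fill / 1000              # L
  ref <- species$transit_time_ref
  k_out <- rate
  k_out["stomach"] <- 1 / species$gastric_emptying_time
  k_out[SI_SEGMENTS] <- rate[SI_SEGMENTS] *
    (ref[["si"]] / species$small_intestinal_transit_time)
  k_out[LI_SEGMENTS] <- rate[LI_SEGMENTS] *
    (ref[["li"]] / species$large_intestinal_transit_time)
  fn_l <- neutral_fraction(compound$ionization, pH_l)
  # umol/min per (umol/L): Peff [cm/min] * SA [cm^2] -> cm^3/min -> /1000 L/min
  a_lum <- compound$effective_permeability * SA * fn_l / 1000
  a_lum["stomach"] <- 0 # the stomach does not absorb

  fu <- compound$fraction_unbound_plasma
  Kp <- part$organs$Kp_total
  names(Kp) <- part$organs$organ
  e_met <- compound$specific_hepatic_clearance * V[["liver"]] * fu /
    Kp[["liver"]]
  e_sec <- compound$specific_tubular_secretion * V[["kidney"]] * fu /
    Kp[["kidney"]]
  e_filt <- compound$gfr_fraction * species$specific_gfr * V[["kidney"]] *
    fu / BP

  bv <- species$blood_volumes
  parms <- c(
    CO, bv$venous, bv$arterial, bv$portal, e_met, e_sec, e_filt, Q_pv,
    compound$solubility,
    V, Q, Kp / BP, as.numeric(drains),
    k_out, a_lum, V_lum
  )
  names(parms) <- NULL

  derived <- list(
    dose_umol = dose_umol, BP = BP, partition = part$organs,
    flows = Q, cardiac_output = CO, portal_inflow = Q_pv,
    lumen = list(surface_area = SA, volume = V_lum, exit_rate = k_out,
                 neutral_fraction = fn_l),
    elimination = c(hepatic = unname(e_met), secretion = unname(e_sec),
                    filtration = unname(e_filt)),
    parms = parms
  )

  structure(list(
    species = species, compound = compound, protocol = protocol,
    derived = derived, parameter_paths = parameter_paths(species)
  ), class = "pbtk_model")
}

#' @export
print.pbtk_model <- function(x, ...) {
  cat(sprintf("<pbtk_model> %s in %s (%s, %.3g mg/kg)\n",
              x$compound$name, x$species$name, x$protocol$route,
              x$protocol$dose_per_kg))
  cat(sprintf("  dose %.4g umol, cardiac output %.3g L/min, BP %.3g\n",
              x$derived$dose_umol, x$derived$cardiac_output, x$derived$BP))
  cat(sprintf("  %d states, %d perturbable physiological parameters\n",
              N_STATES, length(x$parameter_paths)))
  invisible(x)
}

#' Cross-species extrapolation of a PBTK model
#'
#' Replaces every physiological parameter of the model's species by the
#' corresponding parameter of the target species, leaving the compound
#' and the relative dose (mg/kg) untouched; the absolute dose and all
#' derived quantities are rebuilt from the target physiology.
#'
#' @param model a [build_model()] result.
#' @param target a [species_physiology()] for the target species.
#' @return a new `pbtk_model` for the target species.
#' @export
extrapolate <- function(model, target) {
  stopifnot(inherits(model, "pbtk_model"),
            inherits(target, "species_physiology"))
  build_model(target, model$compound, model$protocol)
}
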