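#' Ionization specification of a compound
#'
#' Describes the acid/base character used for pH-dependent partitioning and
#' gut absorption. Only the neutral microspecies is assumed to permeate
#' membranes and to partition into lipid.
#'
#' @param kind one of `"neutral"`, `"monoprotic_acid"`, `"monoprotic_base"`.
#' @param pKa dissociation constant; required unless `kind = "neutral"`.
#' @return an object of class `ionization_spec`.
#' @examples
#' ionization_spec("monoprotic_acid", pKa = 4.2)
#' @export
ionization_spec <- function(kind = c("neutral", "monoprotic_acid",
                                     "monoprotic_base"), pKa = NULL) {
  kind <- match.arg(kind)
  if (kind == "neutral") {
    if (!is.null(pKa)) stop("pKa must be absent for a neutral compound")
  } else {
    if (is.null(pKa) || !is.finite(pKa) || pKa <= 0 || pKa >= 14)
      stop("pKa is required and must lie in (0, 14) for an ionizable compound")
  }
  structure(list(kind = kind, pKa = pKa), class = "ionization_spec")
}

#' Neutral (un-ionized) fraction at a given pH
#'
#' Henderson-Hasselbalch neutral fraction: 1 for neutral species,
#' `1/(1 + 10^(pH - pKa))` for a monoprotic acid and
#' `1/(1 + 10^(pKa - pH))` for a monoprotic base.
#'
#' @param ion an [ionization_spec()].
#' @param pH pH value(s); vectorized.
#' @return neutral fraction in (0, 1].
#' @examples
#' neutral_fraction(ionization_spec("monoprotic_acid", 7.4), 7.4) # 0.5
#' @export
neutral_fraction <- function(ion, pH) {
  stopifnot(inherits(ion, "ionization_spec"), is.numeric(pH), all(is.finite(pH)))
  switch(ion$kind,
    neutral = rep(1, length(pH)),
    monoprotic_acid = 1 / (1 + 10^(pH - ion$pKa)),
    monoprotic_base = 1 / (1 + 10^(ion$pKa - pH))
  )
}

#' Define a compound
#'
#' The physicochemical, binding and clearance properties of a small
#' molecule, strictly separated from any species physiology. Clearance
#' inputs are "specific", i.e. normalized per litre of eliminating organ,
#' so that they transfer across species of different size.
#'
#' @param name compound name.
#' @param molecular_weight g/mol.
#' @param logP octanol:water log partition coefficient.
#' @param ionization an [ionization_spec()].
#' @param fraction_unbound_plasma fu, in (0, 1].
#' @param effective_permeability intestinal permeability, cm/min.
#' @param specific_hepatic_clearance 1/min per L liver (plasma clearance
#'   scale).
#' @param specific_tubular_secretion 1/min per L kidney.
#' @param gfr_fraction fraction of the glomerular filtration rate that
#'   filters unbound drug, in `[0, 1]`.
#' @param solubility aqueous solubility in umol/L; `Inf` for unbounded.
#' @return an object of class `compound`.
#' @examples
#' compound("caffeine-like", 194.2, 0.1,
#'          fraction_unbound_plasma = 0.65,
#'          specific_hepatic_clearance = 0.5)
#' @export
compound <- function(name, molecular_weight, logP,
                     ionization = ionization_spec("neutral"),
                     fraction_unbound_plasma = 1,
                     effective_permeability = 5e-3,
                     specific_hepatic_clearance = 0,
                     specific_tubular_secretion = 0,
                     gfr_fraction = 0,
                     solubility = Inf) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(molecular_weight) || molecular_weight <= 0)
    stop("molecular_weight must be positive")
  if (!is.finite(logP)) stop("logP must be finite")
  if (!inherits(ionization, "ionization_spec"))
    stop("ionization must be an ionization_spec")
  if (!is.finite(fraction_unbound_plasma) ||
      fraction_unbound_plasma <= 0 || fraction_unbound_plasma > 1)
    stop("fraction_unbound_plasma must lie in (0, 1]")
  if (effective_permeability < 0) stop("effective_permeability must be >= 0")
  if (specific_hepatic_clearance < 0 || specific_tubular_secretion < 0)
    stop("clearances must be >= 0")
  if (gfr_fraction < 0 || gfr_fraction > 1)
    stop("gfr_fraction must lie in [0, 1]")
  if (!(is.infinite(solubility) || (is.finite(solubility) && solubility > 0)))
    stop("solubility must be positive or Inf")
  structure(list(
    name = name, molecular_weight = molecular_weight, logP = logP,
    ionization = ionization,
    fraction_unbound_plasma = fraction_unbound_plasma,
    effective_permeability = effective_permeability,
    specific_hepatic_clearance = specific_hepatic_clearance,
    specific_tubular_secretion = specific_tubular_secretion,
    gfr_fraction = gfr_fraction, solubility = solubility
  ), class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s\n", x$name))
  cat(sprintf("  MW %.1f g/mol, logP %.2f, %s, fu %.2f\n",
              x$molecular_weight, x$logP, x$ionization$kind,
              x$fraction_unbound_plasma))
  cat(sprintf("  CLh %.3g /min/L liver, CLsec %.3g /min/L kidney, GFR fraction %.2f\n",
              x$specific_hepatic_clearance, x$specific_tubular_secretion,
              x$gfr_fraction))
  cat(sprintf("  Peff %.3g cm/min, solubility %s umol/L\n",
              x$effective_permeability,
              if (is.infinite(x$solubility)) "unbounded"
              else format(x$solubility)))
  invisible(x)
}

#' Compartment affinity of a compound for a tissue phase
#'
#' Affinity of one well-mixed compartment (plasma, interstitial, red blood
#' cells, or the cellular phase of an organ) for a compound, combining
#' aqueous retention of the ionized species, lipid partitioning of the
#' neutral species, and a protein-binding term:
#' `a = f_water / fn(pH) + 10^logP * f_lipid + binding_term`.
#' Partition coefficients between compartments are ratios of affinities.
#'
#' @param comp composition list with `f_water`, `f_lipid`, `f_protein`.
#' @param pH pH of the compartment.
#' @param compound a [compound()] (only `logP` and ionization are used).
#' @param binding_term non-negative protein-binding contribution.
#' @return scalar affinity (> 0).
#' @export
compartment_affinity <- function(comp, pH, compound, binding_term = 0) {
  stopifnot(binding_term >= 0)
  fn <- neutral_fraction(compound$ionization, pH)
  a <- comp$f_water / fn + 10^compound$logP * comp$f_lipid + binding_term
  if (!is.finite(a) || a <= 0)
    stop("non-positive compartment affinity: invalid physiology/composition")
  a
}
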