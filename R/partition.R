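#' Tissue:plasma partition coefficients from composition and ionization
#'
#' Derives equilibrium partition coefficients for every organ from the
#' water/lipid/protein composition and pH of each compartment. The plasma
#' protein-binding term `B_p` is back-calibrated from the measured
#' fraction unbound so that
#' `fu = (f_w,p/fn_p) / (f_w,p/fn_p + 10^logP * f_l,p + B_p)`;
#' tissue binding scales with the local protein fraction,
#' `B_x = B_p * f_prot,x / f_prot,p` (zero when plasma protein is zero).
#' Cell:plasma, interstitial:plasma and erythrocyte:plasma coefficients
#' are ratios of [compartment_affinity()] values; the blood:plasma ratio
#' is the haematocrit-weighted mixture
#' `BP = (1 - HCT) + HCT * K_ery` and the total tissue:plasma coefficient
#' is the volume-weighted mixture of vascular, interstitial and cellular
#' phases.
#'
#' When `fu = 1` no binding term can be represented; `B_p` is floored at
#' zero (silently for `fu = 1`, with a warning when a stated `fu < 1` is
#' unreachable given the plasma lipid content).
#'
#' @param species a [species_physiology()].
#' @param compound a [compound()].
#' @return a list with `BP` (blood:plasma ratio), `B_p` (plasma binding
#'   term) and `organs`, a data frame with one row per organ and columns
#'   `Kp_total`, `K_cell`, `K_int`.
#' @export
partition_coefficients <- function(species, compound) {
  fu <- compound$fraction_unbound_plasma
  lip <- 10^compound$logP
  pc <- species$plasma_composition
  fn_p <- neutral_fraction(compound$ionization, species$plasma_pH)
  aq_p <- pc$f_water / fn_p
  B_p <- aq_p * (1 / fu - 1) - lip * pc$f_lipid
  if (B_p < 0) {
    if (fu < 1)
      warning(sprintf(paste0("stated fu = %.3g is not reachable with the ",
                             "plasma composition; binding term floored at 0"),
                      fu))
    B_p <- 0
  }
  a_plasma <- aq_p + lip * pc$f_lipid + B_p

  bind_scale <- function(f_prot)
    if (pc$f_protein > 0) B_p * f_prot / pc$f_protein else 0

  aff <- function(comp, pH)
    compartment_affinity(comp, pH, compound, bind_scale(comp$f_protein))

  a_int <- aff(species$interstitial_composition, species$plasma_pH)
  a_rbc <- aff(species$rbc_composition, species$rbc_pH)
  K_int <- a_int / a_plasma
  K_ery <- a_rbc / a_plasma
  hct <- species$haematocrit
  BP <- (1 - hct) + hct * K_ery

  org <- species$organs[ORGAN_NAMES]
  K_cell <- vapply(org, function(o)
    aff(o$cellular_composition, o$intracellular_pH) / a_plasma, 0)
  fv <- vapply(org, `[[`, 0, "fraction_vascular")
  fi <- vapply(org, `[[`, 0, "fraction_interstitial")
  Kp_total <- fv * BP + fi * K_int + (1 - fv - fi) * K_cell
  if (any(!is.finite(Kp_total)) || any(Kp_total <= 0))
    stop("non-positive partition coefficient: invalid physiology")

  list(BP = BP, B_p = B_p, K_int = K_int, K_ery = K_ery,
       organs = data.frame(organ = ORGAN_NAMES, Kp_total = Kp_total,
                           K_cell = K_cell, K_int = rep(K_int, length(org)),
                           row.names = NULL))
}
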