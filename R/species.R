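#' Tissue composition
#'
#' Volume fractions of water, lipid and protein in a compartment. Fractions
#' may sum to less than one (solids, minerals and other phases are treated
#' as inert for partitioning).
#'
#' @param f_water,f_lipid,f_protein volume fractions in `[0, 1]`;
#'   `f_water` must be positive and the three must sum to at most 1.
#' @return a list of class `composition`.
#' @export
composition <- function(f_water, f_lipid, f_protein) {
  vals <- c(f_water, f_lipid, f_protein)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("composition fractions must lie in [0, 1]")
  if (f_water <= 0) stop("f_water must be positive")
  if (sum(vals) > 1 + 1e-12)
    stop("composition fractions must sum to at most 1")
  structure(list(f_water = f_water, f_lipid = f_lipid,
                 f_protein = f_protein), class = "composition")
}

#' Organ specification
#'
#' One perfusion-limited organ: its size, perfusion, cellular composition
#' and sub-compartment fractions.
#'
#' @param name organ name (one of the fixed organ inventory).
#' @param volume L.
#' @param specific_blood_flow L blood / min / L organ.
#' @param cellular_composition a [composition()].
#' @param intracellular_pH pH of the cellular phase.
#' @param fraction_vascular,fraction_interstitial volume fractions of the
#'   vascular and interstitial sub-compartments; their sum must be < 1.
#' @param peripheral_blood_flow_fraction weight of this organ's venous
#'   outflow in the peripheral venous plasma observer, in `[0, 1]`.
#' @param drains_to `"venous"` or `"portal"`.
#' @return a list of class `organ_spec`.
#' @export
organ_spec <- function(name, volume, specific_blood_flow,
                       cellular_composition, intracellular_pH = 7.0,
                       fraction_vascular = 0.05,
                       fraction_interstitial = 0.15,
                       peripheral_blood_flow_fraction = 0,
                       drains_to = c("venous", "portal")) {
  drains_to <- match.arg(drains_to)
  if (!is.finite(volume) || volume <= 0) stop("organ volume must be > 0")
  if (!is.finite(specific_blood_flow) || specific_blood_flow < 0)
    stop("specific_blood_flow must be >= 0")
  if (!inherits(cellular_composition, "composition"))
    stop("cellular_composition must be a composition")
  if (fraction_vascular < 0 || fraction_interstitial < 0 ||
      fraction_vascular + fraction_interstitial >= 1)
    stop("fraction_vascular + fraction_interstitial must be < 1")
  if (peripheral_blood_flow_fraction < 0 || peripheral_blood_flow_fraction > 1)
    stop("peripheral_blood_flow_fraction must lie in [0, 1]")
  structure(list(
    name = name, volume = volume, specific_blood_flow = specific_blood_flow,
    cellular_composition = cellular_composition,
    intracellular_pH = intracellular_pH,
    fraction_vascular = fraction_vascular,
    fraction_interstitial = fraction_interstitial,
    peripheral_blood_flow_fraction = peripheral_blood_flow_fraction,
    drains_to = drains_to
  ), class = "organ_spec")
}

#' Gastrointestinal lumen segment
#'
#' Geometry, pH and transit of one segment of the gut lumen. The segments
#' follow the fixed anatomical order stomach, duodenum, upper/lower
#' jejunum, upper/lower ileum, caecum, colon.
#'
#' @param name segment name.
#' @param length cm.
#' @param proximal_radius,distal_radius cm.
#' @param surface_enhancement_factor effective surface area enhancement
#'   (folds/villi), >= 1.
#' @param pH luminal pH.
#' @param fill_fraction fractional steady-state fill level of the lumen,
#'   in (0, 1]; scales the luminal fluid volume.
#' @param transit_rate first-order exit rate, 1/min; `NA` to initialize
#'   from the regional transit times when the species is assembled.
#' @return a list of class `git_segment`.
#' @export
git_segment <- function(name, length, proximal_radius, distal_radius,
                        surface_enhancement_factor = 1, pH = 6.5,
                        fill_fraction = 0.5, transit_rate = NA_real_) {
  if (!name %in% LUMEN_SEGMENTS) stop("unknown lumen segment: ", name)
  if (length <= 0 || proximal_radius <= 0 || distal_radius <= 0)
    stop("segment length and radii must be > 0")
  if (surface_enhancement_factor < 1)
    stop("surface_enhancement_factor must be >= 1")
  if (fill_fraction <= 0 || fill_fraction > 1)
    stop("fill_fraction must lie in (0, 1]")
  if (!is.na(transit_rate) && transit_rate < 0)
    stop("transit_rate must be >= 0")
  structure(list(
    name = name, length = length, proximal_radius = proximal_radius,
    distal_radius = distal_radius,
    surface_enhancement_factor = surface_enhancement_factor, pH = pH,
    fill_fraction = fill_fraction, transit_rate = transit_rate
  ), class = "git_segment")
}

#' Assemble a species physiology
#'
#' The substance-independent half of a PBTK model: organs, blood pools,
#' gut lumen, compositions and clearance physiology. Per-segment transit
#' rates left `NA` are initialized from the regional transit times
#' (gastric emptying, small- and large-intestinal transit), with segment
#' residence proportional to segment length within its region; the region
#' times used for that initialization are retained as reference metadata
#' so that regional times and per-segment rates remain independently
#' perturbable afterwards.
#'
#' @param name species name.
#' @param body_weight kg (1 kg/L density convention: organ plus blood
#'   volumes must sum to `body_weight` within 2 percent).
#' @param haematocrit volume fraction of red blood cells in (0, 1).
#' @param plasma_pH,rbc_pH pH of plasma and of red blood cells.
#' @param plasma_composition,interstitial_composition,rbc_composition
#'   [composition()] objects.
#' @param organs named list of [organ_spec()]; must contain the full fixed
#'   organ inventory.
#' @param lumen named list of [git_segment()] in anatomical order.
#' @param gastric_emptying_time min.
#' @param small_intestinal_transit_time,large_intestinal_transit_time min.
#' @param specific_gfr glomerular filtration rate, 1/min per L kidney.
#' @param blood_volumes list with `venous`, `arterial`, `portal` (L).
#' @param validate run the full invariant validation (default `TRUE`).
#' @return an object of class `species_physiology`.
#' @export
species_physiology <- function(name, body_weight, haematocrit,
                               plasma_pH, rbc_pH,
                               plasma_composition, interstitial_composition,
                               rbc_composition, organs, lumen,
                               gastric_emptying_time,
                               small_intestinal_transit_time,
                               large_intestinal_transit_time,
                               specific_gfr, blood_volumes,
                               validate = TRUE) {
  sp <- structure(list(
    name = name, body_weight = body_weight, haematocrit = haematocrit,
    plasma_pH = plasma_pH, rbc_pH = rbc_pH,
    plasma_composition = plasma_composition,
    interstitial_composition = interstitial_composition,
    rbc_composition = rbc_composition,
    organs = organs, lumen = lumen,
    gastric_emptying_time = gastric_emptying_time,
    small_intestinal_transit_time = small_intestinal_transit_time,
    large_intestinal_transit_time = large_intestinal_transit_time,
    specific_gfr = specific_gfr, blood_volumes = blood_volumes,
    transit_time_ref = NULL
  ), class = "species_physiology")
  sp <- init_transit_rates(sp)
  if (validate) validate_species(sp)
  sp
}

# fill NA per-segment transit rates from region transit times; record the
# region times used as the reference for the rate <-> time coupling
init_transit_rates <- function(sp) {
  si_len <- sum(vapply(sp$lumen[SI_SEGMENTS], `[[`, 0, "length"))
  li_len <- sum(vapply(sp$lumen[LI_SEGMENTS], `[[`, 0, "length"))
  for (s in SI_SEGMENTS) {
    if (is.na(sp$lumen[[s]]$transit_rate)) {
      tau <- sp$small_intestinal_transit_time * sp$lumen[[s]]$length / si_len
      sp$lumen[[s]]$transit_rate <- 1 / tau
    }
  }
  for (s in LI_SEGMENTS) {
    if (is.na(sp$lumen[[s]]$transit_rate)) {
      tau <- sp$large_intestinal_transit_time * sp$lumen[[s]]$length / li_len
      sp$lumen[[s]]$transit_rate <- 1 / tau
    }
  }
  # stomach empties first order with the gastric emptying time
  if (is.na(sp$lumen$stomach$transit_rate))
    sp$lumen$stomach$transit_rate <- 1 / sp$gastric_emptying_time
  if (is.null(sp$transit_time_ref))
    sp$transit_time_ref <- c(si = sp$small_intestinal_transit_time,
                             li = sp$large_intestinal_transit_time)
  sp
}

#' Validate a species physiology
#'
#' Checks the structural invariants: complete organ inventory, anatomical
#' lumen order, bounded fractions, positive volumes and the volume-weight
#' closure (organ plus blood volumes equal to body weight within 2 percent
#' at 1 kg/L).
#'
#' @param sp a [species_physiology()].
#' @return `sp`, invisibly; errors describe the offending parameter path.
#' @export
validate_species <- function(sp) {
  stopifnot(inherits(sp, "species_physiology"))
  if (!is.finite(sp$body_weight) || sp$body_weight <= 0)
    stop("Organism|Weight must be > 0")
  if (!is.finite(sp$haematocrit) || sp$haematocrit <= 0 || sp$haematocrit >= 1)
    stop("Organism|Haematocrit must lie in (0, 1)")
  for (comp in c("plasma_composition", "interstitial_composition",
                 "rbc_composition"))
    if (!inherits(sp[[comp]], "composition")) stop(comp, " is not a composition")
  missing <- setdiff(ORGAN_NAMES, names(sp$organs))
  if (length(missing))
    stop("missing mandatory organ(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(sp$organs), ORGAN_NAMES)
  if (length(unknown))
    stop("unknown organ(s): ", paste(unknown, collapse = ", "))
  for (o in sp$organs) {
    if (!inherits(o, "organ_spec")) stop("organ entries must be organ_spec")
    if (o$volume <= 0) stop("Organism|", ORGAN_DISPLAY[[o$name]],
                            "|Volume must be > 0")
  }
  if (!identical(names(sp$lumen), LUMEN_SEGMENTS))
    stop("lumen segments must appear in anatomical order: ",
         paste(LUMEN_SEGMENTS, collapse = ", "))
  for (s in sp$lumen)
    if (!inherits(s, "git_segment")) stop("lumen entries must be git_segment")
  if (sp$gastric_emptying_time <= 0 || sp$small_intestinal_transit_time <= 0 ||
      sp$large_intestinal_transit_time <= 0)
    stop("transit times must be > 0")
  if (sp$specific_gfr < 0) stop("Organism|Kidney|GFR (specific) must be >= 0")
  bv <- sp$blood_volumes
  if (!all(c("venous", "arterial", "portal") %in% names(bv)) ||
      any(unlist(bv[c("venous", "arterial", "portal")]) <= 0))
    stop("blood volumes (venous, arterial, portal) must be > 0")
  vtot <- sum(vapply(sp$organs, `[[`, 0, "volume")) +
    bv$venous + bv$arterial + bv$portal
  if (abs(vtot - sp$body_weight) / sp$body_weight > 0.02)
    stop(sprintf(paste0("organ + blood volumes (%.4g L) must equal body ",
                        "weight (%.4g kg at 1 kg/L) within 2%%"),
                 vtot, sp$body_weight))
  invisible(sp)
}

#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("<species_physiology> %s\n", x$name))
  cat(sprintf("  body weight %.4g kg, haematocrit %.2f\n",
              x$body_weight, x$haematocrit))
  cat(sprintf("  %d organs, %d lumen segments, %d perturbable parameters\n",
              length(x$organs), length(x$lumen),
              length(parameter_paths(x))))
  invisible(x)
}
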