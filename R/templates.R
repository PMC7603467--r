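# Packaged species templates.
#
# These are literature-plausible approximate parameterizations for seven
# mammalian species spanning 0.02-73 kg, intended as starting points for
# scaling, extrapolation and synthetic-data generation. They are NOT a
# curated, validated physiology database. All templates share one
# structural skeleton (a reference parameterization at 73 kg) from which
# organ volumes are set per-species as fractions of body weight, specific
# blood flows are scaled with BW^-0.2 (so that cardiac output lands near
# measured values from mouse to human), gut geometry follows the packaged
# allometric exponents, and transit times scale with BW^0.25.

TEMPLATE_BW <- c(mouse = 0.02, rat = 0.25, rabbit = 2.5, monkey = 5,
                 beagle = 12, minipig = 30, human = 73)

# reference organ-volume fractions of body weight (rest closes the sum)
BASE_ORGAN_FRACTIONS <- c(
  lung = 0.011, liver = 0.026, kidney = 0.0044, muscle = 0.40,
  skin = 0.047, adipose = 0.19, brain = 0.020, heart = 0.0047,
  gonads = 0.0005, bone = 0.10, spleen = 0.0026, stomach_wall = 0.0021,
  small_intestine_wall = 0.0086, large_intestine_wall = 0.0053
)
BASE_BLOOD_FRACTIONS <- c(venous = 0.045, arterial = 0.020, portal = 0.0075)

# per-species overrides of selected volume fractions
SPECIES_FRACTION_OVERRIDES <- list(
  mouse   = c(liver = 0.055, kidney = 0.016, brain = 0.016, adipose = 0.06,
              muscle = 0.38, skin = 0.14),
  rat     = c(liver = 0.040, kidney = 0.008, brain = 0.006, adipose = 0.07,
              muscle = 0.40, skin = 0.19),
  rabbit  = c(liver = 0.028, kidney = 0.006, brain = 0.0036, adipose = 0.06,
              muscle = 0.48, skin = 0.08),
  monkey  = c(liver = 0.025, kidney = 0.005, brain = 0.014, adipose = 0.08,
              muscle = 0.42, skin = 0.07),
  beagle  = c(liver = 0.032, kidney = 0.005, brain = 0.0067, adipose = 0.10,
              muscle = 0.44, skin = 0.07),
  minipig = c(liver = 0.022, kidney = 0.004, brain = 0.002, adipose = 0.30,
              muscle = 0.35, skin = 0.06),
  human   = c()
)

# specific blood flow at the 73 kg reference, L blood / min / L organ
BASE_SPECIFIC_FLOWS <- c(
  lung = 0, liver = 0.30, kidney = 3.8, muscle = 0.037, skin = 0.10,
  adipose = 0.025, brain = 0.55, heart = 0.75, gonads = 0.10, bone = 0.03,
  spleen = 1.3, stomach_wall = 0.55, small_intestine_wall = 0.95,
  large_intestine_wall = 0.65, rest = 0.12
)

# cellular composition (water, lipid, protein) and organ fractions
BASE_TISSUE_TABLE <- data.frame(
  organ = ORGAN_NAMES,
  f_water = c(0.78, 0.70, 0.76, 0.75, 0.70, 0.15, 0.77, 0.73, 0.80, 0.40,
              0.78, 0.75, 0.75, 0.75, 0.74),
  f_lipid = c(0.013, 0.049, 0.028, 0.022, 0.060, 0.80, 0.107, 0.026, 0.020,
              0.070, 0.025, 0.045, 0.065, 0.055, 0.050),
  f_protein = c(0.15, 0.18, 0.17, 0.19, 0.20, 0.03, 0.08, 0.16, 0.12, 0.25,
                0.17, 0.16, 0.15, 0.15, 0.16),
  fraction_vascular = c(0.10, 0.11, 0.10, 0.03, 0.03, 0.02, 0.03, 0.06,
                        0.03, 0.04, 0.20, 0.06, 0.07, 0.06, 0.04),
  fraction_interstitial = c(0.19, 0.16, 0.20, 0.12, 0.35, 0.13, 0.04, 0.14,
                            0.14, 0.10, 0.15, 0.22, 0.24, 0.23, 0.15),
  peripheral_blood_flow_fraction = c(0, 0, 0, 0.60, 0.40, 0, 0, 0, 0, 0, 0,
                                     0, 0, 0, 0)
)

# gut lumen geometry at the 73 kg reference
BASE_LUMEN_TABLE <- data.frame(
  segment = LUMEN_SEGMENTS,
  length = c(25, 25, 60, 60, 60, 60, 15, 120),
  proximal_radius = c(5.0, 1.50, 1.40, 1.35, 1.30, 1.20, 3.0, 1.8),
  distal_radius = c(4.0, 1.40, 1.35, 1.30, 1.20, 1.10, 2.5, 1.7),
  surface_enhancement_factor = c(1.2, 10, 10, 10, 9, 9, 2, 2),
  pH = c(2.0, 6.0, 6.2, 6.6, 7.0, 7.4, 6.0, 6.5),
  fill_fraction = c(0.5, 0.3, 0.3, 0.3, 0.3, 0.3, 0.7, 0.7)
)

BASE_TRANSIT <- c(gastric = 30, si = 200, li = 1700) # min, at 73 kg

SPECIES_TWEAKS <- list(
  mouse   = list(haematocrit = 0.42, specific_gfr = 0.90, stomach_pH = 3.0,
                 caecum_factor = 1.5),
  rat     = list(haematocrit = 0.43, specific_gfr = 0.90, stomach_pH = 3.2,
                 caecum_factor = 1.8),
  rabbit  = list(haematocrit = 0.39, specific_gfr = 0.75, stomach_pH = 1.9,
                 caecum_factor = 3.0),
  monkey  = list(haematocrit = 0.40, specific_gfr = 0.55, stomach_pH = 2.8,
                 caecum_factor = 1.0),
  beagle  = list(haematocrit = 0.45, specific_gfr = 0.60, stomach_pH = 1.5,
                 caecum_factor = 1.0),
  minipig = list(haematocrit = 0.42, specific_gfr = 0.45, stomach_pH = 2.2,
                 caecum_factor = 1.5),
  human   = list(haematocrit = 0.44, specific_gfr = 0.39, stomach_pH = 2.0,
                 caecum_factor = 1.0)
)

#' Names of the packaged species templates
#' @return character vector of the seven packaged species.
#' @export
template_species_names <- function() names(TEMPLATE_BW)

#' Packaged species template
#'
#' Builds the approximate physiology of one of the seven packaged
#' mammalian species (mouse, rat, rabbit, monkey, beagle, minipig,
#' human). The default mouse body weight is 0.02 kg, the lower end of the
#' packaged 0.02-73 kg span; 0.23 kg is an equally citable laboratory
#' mouse convention and can be requested through `body_weight`.
#'
#' @param species one of [template_species_names()].
#' @param body_weight optional body weight override, kg.
#' @param settings [scaling_settings()] used for the gut geometry.
#' @return a validated [species_physiology()].
#' @examples
#' species_template("rabbit")
#' @export
species_template <- function(species, body_weight = NULL,
                             settings = scaling_settings()) {
  species <- match.arg(species, names(TEMPLATE_BW))
  bw <- if (is.null(body_weight)) TEMPLATE_BW[[species]] else body_weight
  if (!is.finite(bw) || bw <= 0) stop("body_weight must be > 0")
  tweaks <- SPECIES_TWEAKS[[species]]
  r <- bw / 73

  fr <- BASE_ORGAN_FRACTIONS
  ov <- SPECIES_FRACTION_OVERRIDES[[species]]
  fr[names(ov)] <- ov
  rest_fr <- 1 - sum(fr) - sum(BASE_BLOOD_FRACTIONS)
  stopifnot(rest_fr > 0)
  fr <- c(fr, rest = rest_fr)

  flow_mult <- r^-0.2
  organs <- lapply(ORGAN_NAMES, function(o) {
    row <- BASE_TISSUE_TABLE[BASE_TISSUE_TABLE$organ == o, ]
    organ_spec(
      name = o, volume = fr[[o]] * bw,
      specific_blood_flow = BASE_SPECIFIC_FLOWS[[o]] * flow_mult,
      cellular_composition = composition(row$f_water, row$f_lipid,
                                         row$f_protein),
      intracellular_pH = 7.0,
      fraction_vascular = row$fraction_vascular,
      fraction_interstitial = row$fraction_interstitial,
      peripheral_blood_flow_fraction = row$peripheral_blood_flow_fraction,
      drains_to = if (o %in% PORTAL_ORGANS) "portal" else "venous"
    )
  })
  names(organs) <- ORGAN_NAMES

  f_len <- r^(2 * settings$git_surface_exponent - settings$git_volume_exponent)
  f_rad <- r^(settings$git_volume_exponent - settings$git_surface_exponent)
  lumen <- lapply(LUMEN_SEGMENTS, function(s) {
    row <- BASE_LUMEN_TABLE[BASE_LUMEN_TABLE$segment == s, ]
    len_mult <- if (s == "caecum") tweaks$caecum_factor else 1
    pH <- if (s == "stomach") tweaks$stomach_pH else row$pH
    git_segment(
      name = s, length = row$length * f_len * len_mult,
      proximal_radius = row$proximal_radius * f_rad,
      distal_radius = row$distal_radius * f_rad,
      surface_enhancement_factor = row$surface_enhancement_factor,
      pH = pH, fill_fraction = row$fill_fraction
    )
  })
  names(lumen) <- LUMEN_SEGMENTS

  tmult <- r^0.25
  species_physiology(
    name = species, body_weight = bw, haematocrit = tweaks$haematocrit,
    plasma_pH = 7.4, rbc_pH = 7.2,
    plasma_composition = composition(0.92, 0.004, 0.07),
    interstitial_composition = composition(0.94, 0.004, 0.025),
    rbc_composition = composition(0.64, 0.004, 0.33),
    organs = organs, lumen = lumen,
    gastric_emptying_time = BASE_TRANSIT[["gastric"]] * tmult,
    small_intestinal_transit_time = BASE_TRANSIT[["si"]] * tmult,
    large_intestinal_transit_time = BASE_TRANSIT[["li"]] * tmult,
    specific_gfr = tweaks$specific_gfr,
    blood_volumes = as.list(BASE_BLOOD_FRACTIONS * bw)
  )
}

#' All packaged species templates
#'
#' @param settings [scaling_settings()] used for the gut geometry.
#' @return named list of the seven [species_template()] physiologies,
#'   ordered by body weight (mouse lightest, human 73 kg heaviest).
#' @export
species_template_set <- function(settings = scaling_settings()) {
  out <- lapply(names(TEMPLATE_BW), species_template, settings = settings)
  names(out) <- names(TEMPLATE_BW)
  out
}
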