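# Pipe-delimited parameter paths ("Organism|Lumen|UpperIleum|pH").
# Every numeric physiological leaf of a species is addressable by exactly
# one path; compound and protocol fields never appear here.

ORGAN_LEAVES <- c("Volume", "Specific blood flow rate", "Vf (lipids)",
                  "Vf (proteins)", "Vf (water)", "pH (intracellular)",
                  "Fraction vascular", "Fraction interstitial",
                  "Peripheral blood flow fraction")

LUMEN_LEAVES <- c("Length", "Proximal radius", "Distal radius",
                  "Effective surface area enhancement factor", "pH",
                  "Fractional steady-state fill level",
                  "Intestinal transit rate")

#' Enumerate the perturbable parameter paths of a species
#'
#' Returns the ordered list of pipe-delimited paths addressing every
#' numeric physiological leaf: organism-level scalars, compartment
#' compositions, per-organ parameters, blood-pool volumes and the gut
#' lumen. Compound and administration parameters are never included.
#'
#' @param sp a [species_physiology()].
#' @return character vector of parameter paths.
#' @examples
#' sp <- species_template("rabbit")
#' head(parameter_paths(sp))
#' @export
parameter_paths <- function(sp) {
  stopifnot(inherits(sp, "species_physiology"))
  paths <- c(
    "Organism|Weight", "Organism|Haematocrit",
    "Organism|pH (plasma)", "Organism|pH (blood cells)",
    paste0("Organism|Plasma|", COMPOSITION_DISPLAY),
    paste0("Organism|Interstitial|", COMPOSITION_DISPLAY),
    paste0("Organism|BloodCells|", COMPOSITION_DISPLAY),
    "Organism|Kidney|GFR (specific)",
    "Organism|Lumen|Stomach|Gastric emptying time",
    "Organism|SmallIntestine|Small intestinal transit time",
    "Organism|LargeIntestine|Large intestinal transit time",
    "Organism|VenousBlood|Volume", "Organism|ArterialBlood|Volume",
    "Organism|PortalVein|Volume"
  )
  for (o in ORGAN_NAMES)
    paths <- c(paths, paste0("Organism|", ORGAN_DISPLAY[[o]], "|", ORGAN_LEAVES))
  for (s in LUMEN_SEGMENTS) {
    leaves <- if (s == "stomach") setdiff(LUMEN_LEAVES, "Intestinal transit rate")
              else LUMEN_LEAVES
    paths <- c(paths, paste0("Organism|Lumen|", LUMEN_DISPLAY[[s]], "|", leaves))
  }
  paths
}

# resolve a path to an accessor descriptor; errors on malformed paths
parse_parameter_path <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  parts <- strsplit(path, "|", fixed = TRUE)[[1]]
  if (length(parts) < 2L || parts[1] != "Organism")
    stop("malformed parameter path: ", path)
  comp_field <- function(display) names(COMPOSITION_DISPLAY)[
    match(display, COMPOSITION_DISPLAY)]
  if (length(parts) == 2L) {
    field <- switch(parts[2],
      "Weight" = "body_weight", "Haematocrit" = "haematocrit",
      "pH (plasma)" = "plasma_pH", "pH (blood cells)" = "rbc_pH",
      stop("malformed parameter path: ", path))
    return(list(kind = "organism", field = field))
  }
  if (length(parts) == 3L) {
    if (parts[2] %in% c("Plasma", "Interstitial", "BloodCells")) {
      f <- comp_field(parts[3])
      if (is.na(f)) stop("malformed parameter path: ", path)
      slot <- c(Plasma = "plasma_composition",
                Interstitial = "interstitial_composition",
                BloodCells = "rbc_composition")[[parts[2]]]
      return(list(kind = "composition", slot = slot, field = f))
    }
    if (parts[2] == "Kidney" && parts[3] == "GFR (specific)")
      return(list(kind = "organism", field = "specific_gfr"))
    if (parts[2] == "SmallIntestine" &&
        parts[3] == "Small intestinal transit time")
      return(list(kind = "organism", field = "small_intestinal_transit_time"))
    if (parts[2] == "LargeIntestine" &&
        parts[3] == "Large intestinal transit time")
      return(list(kind = "organism", field = "large_intestinal_transit_time"))
    if (parts[3] == "Volume" &&
        parts[2] %in% c("VenousBlood", "ArterialBlood", "PortalVein")) {
      pool <- c(VenousBlood = "venous", ArterialBlood = "arterial",
                PortalVein = "portal")[[parts[2]]]
      return(list(kind = "blood", pool = pool))
    }
    organ <- names(ORGAN_DISPLAY)[match(parts[2], ORGAN_DISPLAY)]
    if (!is.na(organ) && parts[3] %in% ORGAN_LEAVES) {
      field <- switch(parts[3],
        "Volume" = "volume", "Specific blood flow rate" = "specific_blood_flow",
        "pH (intracellular)" = "intracellular_pH",
        "Fraction vascular" = "fraction_vascular",
        "Fraction interstitial" = "fraction_interstitial",
        "Peripheral blood flow fraction" = "peripheral_blood_flow_fraction",
        comp_field(parts[3]))
      comp <- parts[3] %in% COMPOSITION_DISPLAY
      return(list(kind = "organ", organ = organ, field = field,
                  in_composition = comp))
    }
    stop("malformed parameter path: ", path)
  }
  if (length(parts) == 4L && parts[2] == "Lumen") {
    seg <- names(LUMEN_DISPLAY)[match(parts[3], LUMEN_DISPLAY)]
    if (is.na(seg)) stop("malformed parameter path: ", path)
    if (seg == "stomach" && parts[4] == "Gastric emptying time")
      return(list(kind = "organism", field = "gastric_emptying_time"))
    field <- switch(parts[4],
      "Length" = "length", "Proximal radius" = "proximal_radius",
      "Distal radius" = "distal_radius",
      "Effective surface area enhancement factor" = "surface_enhancement_factor",
      "pH" = "pH", "Fractional steady-state fill level" = "fill_fraction",
      "Intestinal transit rate" = "transit_rate",
      stop("malformed parameter path: ", path))
    return(list(kind = "lumen", segment = seg, field = field))
  }
  stop("malformed parameter path: ", path)
}

#' Read a physiological parameter by path
#'
#' @param sp a [species_physiology()].
#' @param path pipe-delimited parameter path, e.g.
#'   `"Organism|Lumen|UpperIleum|pH"`.
#' @return the numeric leaf value.
#' @export
get_parameter <- function(sp, path) {
  d <- parse_parameter_path(path)
  switch(d$kind,
    organism = sp[[d$field]],
    composition = sp[[d$slot]][[d$field]],
    blood = sp$blood_volumes[[d$pool]],
    organ = if (isTRUE(d$in_composition))
      sp$organs[[d$organ]]$cellular_composition[[d$field]]
    else sp$organs[[d$organ]][[d$field]],
    lumen = sp$lumen[[d$segment]][[d$field]]
  )
}

#' Set a physiological parameter by path
#'
#' Writes one numeric leaf and returns the modified species. Only cheap
#' per-leaf checks are applied (finite value, positivity where structural):
#' the full closure invariants are deliberately not re-validated, so that
#' one-at-a-time perturbations do not trigger renormalization of dependent
#' parameters.
#'
#' @inheritParams get_parameter
#' @param value new numeric value.
#' @return the modified `species_physiology`.
#' @export
set_parameter <- function(sp, path, value) {
  if (!is.finite(value)) stop("parameter value must be finite: ", path)
  d <- parse_parameter_path(path)
  switch(d$kind,
    organism = { sp[[d$field]] <- value },
    composition = { sp[[d$slot]][[d$field]] <- value },
    blood = { sp$blood_volumes[[d$pool]] <- value },
    organ = {
      if (isTRUE(d$in_composition))
        sp$organs[[d$organ]]$cellular_composition[[d$field]] <- value
      else sp$organs[[d$organ]][[d$field]] <- value
    },
    lumen = { sp$lumen[[d$segment]][[d$field]] <- value }
  )
  sp
}
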