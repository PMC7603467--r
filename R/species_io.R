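# Species, compound and protocol file I/O (JSON or YAML).
#
# The on-disk layout mirrors the in-memory objects with a fixed canonical
# key order, so that writing the same object twice produces byte-identical
# files. JSON is written with full double precision and round-trips every
# numeric leaf exactly; YAML is written with 17 significant digits.

SPECIES_TOP_KEYS <- c(
  "name", "body_weight", "haematocrit", "plasma_pH", "rbc_pH",
  "plasma_composition", "interstitial_composition", "rbc_composition",
  "organs", "lumen", "gastric_emptying_time",
  "small_intestinal_transit_time", "large_intestinal_transit_time",
  "specific_gfr", "blood_volumes", "transit_time_ref")

ORGAN_KEYS <- c("name", "volume", "specific_blood_flow",
                "cellular_composition", "intracellular_pH",
                "fraction_vascular", "fraction_interstitial",
                "peripheral_blood_flow_fraction", "drains_to")

LUMEN_KEYS <- c("name", "length", "proximal_radius", "distal_radius",
                "surface_enhancement_factor", "pH", "fill_fraction",
                "transit_rate")

strip_class <- function(x) {
  if (is.list(x)) { x <- lapply(x, strip_class); attributes(x) <- list(names = names(x)) }
  x
}

species_to_list <- function(sp) {
  out <- strip_class(unclass(sp))
  out$transit_time_ref <- as.list(sp$transit_time_ref)
  out[SPECIES_TOP_KEYS]
}

check_keys <- function(x, expected, where) {
  unknown <- setdiff(names(x), expected)
  if (length(unknown))
    stop("unknown key(s) at ", where, ": ", paste(unknown, collapse = ", "))
  missing <- setdiff(expected, names(x))
  if (length(missing))
    stop("missing key(s) at ", where, ": ", paste(missing, collapse = ", "))
}

num1 <- function(x, where) {
  if (!is.numeric(x) || length(x) != 1L)
    stop("expected a single number at ", where)
  as.numeric(x)
}

list_to_composition <- function(x, where) {
  check_keys(x, c("f_water", "f_lipid", "f_protein"), where)
  composition(num1(x$f_water, where), num1(x$f_lipid, where),
              num1(x$f_protein, where))
}

species_from_list <- function(x) {
  check_keys(x, SPECIES_TOP_KEYS, "Organism")
  organs <- lapply(names(x$organs), function(o) {
    ox <- x$organs[[o]]
    where <- paste0("Organism|", o)
    check_keys(ox, ORGAN_KEYS, where)
    organ_spec(ox$name, num1(ox$volume, where),
               num1(ox$specific_blood_flow, where),
               list_to_composition(ox$cellular_composition, where),
               num1(ox$intracellular_pH, where),
               num1(ox$fraction_vascular, where),
               num1(ox$fraction_interstitial, where),
               num1(ox$peripheral_blood_flow_fraction, where),
               ox$drains_to)
  })
  names(organs) <- names(x$organs)
  lumen <- lapply(names(x$lumen), function(s) {
    sx <- x$lumen[[s]]
    where <- paste0("Organism|Lumen|", s)
    check_keys(sx, LUMEN_KEYS, where)
    git_segment(sx$name, num1(sx$length, where),
                num1(sx$proximal_radius, where),
                num1(sx$distal_radius, where),
                num1(sx$surface_enhancement_factor, where),
                num1(sx$pH, where), num1(sx$fill_fraction, where),
                num1(sx$transit_rate, where))
  })
  names(lumen) <- names(x$lumen)
  sp <- species_physiology(
    name = x$name, body_weight = num1(x$body_weight, "Organism|Weight"),
    haematocrit = num1(x$haematocrit, "Organism|Haematocrit"),
    plasma_pH = num1(x$plasma_pH, "Organism|pH (plasma)"),
    rbc_pH = num1(x$rbc_pH, "Organism|pH (blood cells)"),
    plasma_composition = list_to_composition(x$plasma_composition,
                                             "Organism|Plasma"),
    interstitial_composition = list_to_composition(
      x$interstitial_composition, "Organism|Interstitial"),
    rbc_composition = list_to_composition(x$rbc_composition,
                                          "Organism|BloodCells"),
    organs = organs, lumen = lumen,
    gastric_emptying_time = num1(x$gastric_emptying_time,
                                 "Organism|Lumen|Stomach|Gastric emptying time"),
    small_intestinal_transit_time = num1(
      x$small_intestinal_transit_time,
      "Organism|SmallIntestine|Small intestinal transit time"),
    large_intestinal_transit_time = num1(
      x$large_intestinal_transit_time,
      "Organism|LargeIntestine|Large intestinal transit time"),
    specific_gfr = num1(x$specific_gfr, "Organism|Kidney|GFR (specific)"),
    blood_volumes = lapply(x$blood_volumes, num1, "Organism|Blood"),
    validate = FALSE)
  sp$transit_time_ref <- c(si = num1(x$transit_time_ref$si, "transit_time_ref"),
                           li = num1(x$transit_time_ref$li, "transit_time_ref"))
  validate_species(sp)
  sp
}

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml" else "json"
}

write_doc <- function(x, path) {
  if (file_format(path) == "yaml") {
    txt <- yaml::as.yaml(x, precision = 17L)
  } else {
    txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                            pretty = TRUE, null = "null")
  }
  writeLines(txt, path)
  invisible(path)
}

read_doc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file_format(path) == "yaml") yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
}

#' Write a species physiology to a JSON or YAML file
#'
#' Canonical key order and full double precision: identical species
#' produce byte-identical files, and a JSON round trip preserves every
#' numeric leaf exactly.
#'
#' @param species a [species_physiology()].
#' @param path output path; extension `.json` (default) or `.yaml`.
#' @return `path`, invisibly.
#' @export
write_species_file <- function(species, path) {
  stopifnot(inherits(species, "species_physiology"))
  write_doc(species_to_list(species), path)
}

#' Read and validate a species physiology file
#'
#' All structural invariants are validated on load; unknown keys are
#' rejected with an error naming the offending parameter path.
#'
#' @param path a file written by [write_species_file()] (JSON or YAML).
#' @return a validated [species_physiology()].
#' @export
read_species_file <- function(path) {
  species_from_list(read_doc(path))
}

#' Write a compound file
#' @param x a [compound()].
#' @param path output path (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_compound_file <- function(x, path) {
  stopifnot(inherits(x, "compound"))
  out <- strip_class(unclass(x))
  if (is.infinite(out$solubility)) out$solubility <- "unbounded"
  write_doc(out, path)
}

#' Read a compound file
#' @param path a file written by [write_compound_file()].
#' @return a [compound()].
#' @export
read_compound_file <- function(path) {
  x <- read_doc(path)
  check_keys(x, c("name", "molecular_weight", "logP", "ionization",
                  "fraction_unbound_plasma", "effective_permeability",
                  "specific_hepatic_clearance", "specific_tubular_secretion",
                  "gfr_fraction", "solubility"), "compound")
  sol <- if (identical(x$solubility, "unbounded")) Inf
         else num1(x$solubility, "compound|solubility")
  compound(x$name, x$molecular_weight, x$logP,
           ionization_spec(x$ionization$kind, x$ionization$pKa),
           x$fraction_unbound_plasma, x$effective_permeability,
           x$specific_hepatic_clearance, x$specific_tubular_secretion,
           x$gfr_fraction, sol)
}

#' Write an administration protocol file
#' @param x an [admin_protocol()].
#' @param path output path (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_protocol_file <- function(x, path) {
  stopifnot(inherits(x, "admin_protocol"))
  write_doc(strip_class(unclass(x)), path)
}

#' Read an administration protocol file
#' @param path a file written by [write_protocol_file()].
#' @return an [admin_protocol()].
#' @export
read_protocol_file <- function(path) {
  x <- read_doc(path)
  check_keys(x, c("route", "dose_per_kg", "start_time"), "protocol")
  admin_protocol(x$route, x$dose_per_kg, x$start_time)
}

#' Export a simulated profile as CSV
#'
#' @param profile a [observe()] profile.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "conc_profile"))
  utils::write.csv(data.frame(time = profile$times,
                              site = site_label(profile$site),
                              concentration = profile$concentrations),
                   path, row.names = FALSE)
  invisible(path)
}
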