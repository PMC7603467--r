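#' Workflow context for building a new species model
#'
#' Describes the planned model for a novel target species: the chosen
#' template, the target body weight, the administration routes of
#' interest, any tox organs whose intracellular exposure matters, and
#' which parameter groups already have species-specific data.
#'
#' @param target_species_name name of the new species.
#' @param template_species name of the reference template species.
#' @param target_bw target body weight, kg.
#' @param routes non-empty subset of `c("iv", "oral")`.
#' @param tox_organs organ names of toxicological interest (may be empty).
#' @param has_species_specific_data named logical vector keyed by
#'   parameter group; groups flagged `TRUE` are marked "use
#'   species-specific value" in the checklist.
#' @return an object of class `workflow_context`.
#' @export
workflow_context <- function(target_species_name, template_species,
                             target_bw, routes = c("iv", "oral"),
                             tox_organs = character(),
                             has_species_specific_data = logical()) {
  routes <- unique(match.arg(routes, c("iv", "oral"), several.ok = TRUE))
  if (length(routes) == 0) stop("routes must be non-empty")
  if (!is.finite(target_bw) || target_bw <= 0)
    stop("target_bw must be > 0")
  unknown <- setdiff(tox_organs, ORGAN_NAMES)
  if (length(unknown))
    stop("unknown tox organ(s): ", paste(unknown, collapse = ", "))
  structure(list(target_species_name = target_species_name,
                 template_species = template_species,
                 target_bw = target_bw, routes = routes,
                 tox_organs = tox_organs,
                 has_species_specific_data = has_species_specific_data),
            class = "workflow_context")
}

source_note <- function(ctx, group) {
  if (isTRUE(ctx$has_species_specific_data[group]))
    "use species-specific value"
  else "literature / scaling / experiment"
}

#' Build the best-practice checklist for a new species model
#'
#' Renders the development workflow for a PBTK model of a novel species
#' as an ordered, executable checklist: template choice, allometric
#' scaling, route decision, gut (GIT) parameters (required only when
#' oral dosing is of interest — for i.v.-only questions the template's
#' GIT can be kept unchanged), the always-required non-GIT parameters
#' (plasma parameters; volume of distribution and clearance), the
#' tox-organ decision and per-organ parameter steps, and final
#' validation against observed data with a fold-error threshold
#' (typically 2).
#'
#' @param ctx a [workflow_context()].
#' @return an object of class `checklist` (ordered list of steps, each
#'   with `id`, `title`, `required`, `groups`/`parameters`, `status` and
#'   `rationale`).
#' @export
build_checklist <- function(ctx) {
  stopifnot(inherits(ctx, "workflow_context"))
  oral <- "oral" %in% ctx$routes
  steps <- list()
  add <- function(id, title, required, groups = character(),
                  parameters = character(), status = "", rationale = "") {
    steps[[length(steps) + 1L]] <<- list(
      id = id, title = title, required = required, groups = groups,
      parameters = parameters, status = status, rationale = rationale)
  }
  add("template", sprintf("Choose template model (%s -> %s)",
                          ctx$template_species, ctx$target_species_name),
      TRUE, status = "advisory",
      rationale = paste("Pick an established species model of similar",
                        "physiology and weight; for oral questions a",
                        "similar food spectrum matters because it shapes",
                        "the gastrointestinal tract."))
  add("allometric_scaling",
      sprintf("Allometrically scale template to %.3g kg", ctx$target_bw),
      TRUE, status = "automatic",
      rationale = paste("Organ volumes scale linearly to the target body",
                        "weight; GIT volume with BW^1.06 and GIT surface",
                        "with BW^0.76."))
  add("route_decision",
      sprintf("Route(s) of administration: %s",
              paste(ctx$routes, collapse = ", ")),
      TRUE, status = "decided",
      rationale = paste("If oral absorption is not of interest the",
                        "template GIT can be kept without any parameter",
                        "changes."))
  for (g in c("git_transit_times", "git_pH", "git_geometry"))
    add(g, switch(g,
                  git_transit_times = "Identify intestinal transit times",
                  git_pH = "Identify intestinal pH",
                  git_geometry = "Identify intestinal geometry"),
        required = oral, groups = g,
        status = if (oral) source_note(ctx, g) else "not required (no oral route)",
        rationale = "GIT parameters drive oral bioavailability.")
  add("plasma_parameters", "Identify plasma parameters",
      TRUE, groups = "plasma_parameters",
      status = source_note(ctx, "plasma_parameters"),
      rationale = paste("Haematocrit and pH values govern partitioning;",
                        "often comparable across mammals."))
  add("volume_distribution_clearance",
      "Identify volume-of-distribution and clearance parameters",
      TRUE, groups = "volume_distribution_clearance",
      status = source_note(ctx, "volume_distribution_clearance"),
      rationale = paste("Liver/kidney/muscle volumes, kidney perfusion,",
                        "GFR and compositions set exposure and clearance."))
  add("tox_organ_decision",
      if (length(ctx$tox_organs))
        sprintf("Tox organs declared: %s",
                paste(ctx$tox_organs, collapse = ", "))
      else "No tox organs declared",
      TRUE, status = "decided",
      rationale = paste("Organ-specific exposure predictions need",
                        "organ-specific parameterization."))
  for (org in ctx$tox_organs)
    add(paste0("tox_organ_", org),
        sprintf("Parameterize tox organ: %s", org),
        TRUE, groups = "tox_organ",
        parameters = paste0("Organism|", ORGAN_DISPLAY[[org]], "|",
                            c("Volume", "Specific blood flow rate",
                              "Vf (lipids)", "Vf (proteins)", "Vf (water)")),
        status = source_note(ctx, "tox_organ"),
        rationale = "Volume, specific blood flow and tissue composition.")
  add("validation", "Validate against observed data in the target species",
      TRUE, status = "pending",
      rationale = paste("Compare simulation with observations; inspect the",
                        "model when prediction and mean observation differ",
                        "by more than a factor of 2 (threshold adjustable",
                        "to measurement uncertainty). Reference precedent:",
                        "6 compounds / 8 datasets qualified the rabbit",
                        "model; the number needed is case specific."))
  structure(list(context = ctx, steps = steps), class = "checklist")
}

#' @export
format.checklist <- function(x, ...) {
  lines <- c(sprintf("# PBTK model development checklist: %s",
                     x$context$target_species_name), "")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    lines <- c(lines,
               sprintf("%d. %s[%s] %s", i,
                       if (s$required) "" else "(optional) ",
                       s$status, s$title))
    if (length(s$groups) && nzchar(s$groups[1]))
      lines <- c(lines, sprintf("   groups: %s",
                                paste(s$groups, collapse = ", ")))
    if (length(s$parameters))
      lines <- c(lines, paste0("   - ", s$parameters))
    lines <- c(lines, sprintf("   %s", s$rationale))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.checklist <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Checklist as a plain list for JSON export
#' @param x a [build_checklist()] result.
#' @return list suitable for `jsonlite::toJSON`.
#' @export
checklist_as_list <- function(x) {
  stopifnot(inherits(x, "checklist"))
  list(target_species = x$context$target_species_name,
       template_species = x$context$template_species,
       routes = x$context$routes, tox_organs = x$context$tox_organs,
       steps = x$steps)
}

#' Factor-of-n validation of predictions against observations
#'
#' Operationalizes "mean observation versus model" as the geometric mean
#' fold error: predictions are linearly interpolated onto the observation
#' times and the fold error is `exp(|mean(log(pred/obs))|)` (>= 1 and
#' symmetric in the two profiles). The verdict passes when the fold
#' error does not exceed the threshold (default 2).
#'
#' @param predicted a model profile ([observe()]).
#' @param observed an observed profile (positive concentrations; times
#'   within the predicted span).
#' @param threshold acceptance fold threshold (default 2).
#' @return an object of class `validation_result` with `fold_error`,
#'   `threshold`, `verdict` and `notes`.
#' @export
validate_model <- function(predicted, observed, threshold = 2) {
  stopifnot(inherits(predicted, "conc_profile"),
            inherits(observed, "conc_profile"))
  if (length(observed$times) == 0) stop("empty observation profile")
  if (any(observed$concentrations <= 0))
    stop("observations must be strictly positive")
  if (any(observed$times < min(predicted$times) |
          observed$times > max(predicted$times)))
    stop("observation times outside the predicted span")
  pred <- stats::approx(predicted$times, predicted$concentrations,
                        observed$times)$y
  if (any(pred <= 0))
    stop("prediction non-positive at observation times")
  fold <- exp(abs(mean(log(pred / observed$concentrations))))
  verdict <- fold <= threshold
  structure(list(fold_error = fold, threshold = threshold,
                 verdict = if (verdict) "pass" else "fail",
                 notes = sprintf(
                   "geometric mean fold error %.3g over %d observations",
                   fold, length(observed$times))),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> %s: fold error %.3g (threshold %.3g)\n",
              x$verdict, x$fold_error, x$threshold))
  invisible(x)
}
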