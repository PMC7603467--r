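#' Pipeline configuration
#'
#' Configuration of an end-to-end sensitivity run. Exactly one of
#' `models` (explicit species/compound/protocol file triplets) or `seed`
#' (the packaged synthetic reference ensemble) must be given.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed selecting the synthetic reference ensemble.
#' @param models list of `list(species =, compound =, protocol =)` file
#'   paths.
#' @param protocols optional subset of [reference_protocols()] names for
#'   the synthetic branch (e.g. a 2-protocol toy ensemble).
#' @param species optional subset of [template_species_names()] for the
#'   synthetic branch.
#' @param sites observation sites (defaults to the standard three).
#' @param thresholds a [classification_thresholds()].
#' @param tox_organs organs treated as tox organs in the grouping.
#' @param top_k length of the ranked head in the report.
#' @param verbose print progress to stderr.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = NULL, models = NULL,
                            protocols = NULL, species = NULL,
                            sites = default_sensitivity_sites(),
                            thresholds = classification_thresholds(),
                            tox_organs = c("brain", "gonads"),
                            top_k = 20, verbose = FALSE) {
  if (is.null(seed) == is.null(models))
    stop("exactly one of 'seed' or 'models' must be provided")
  structure(list(out_dir = out_dir, seed = seed, models = models,
                 protocols = protocols, species = species, sites = sites,
                 thresholds = thresholds, tox_organs = tox_organs,
                 top_k = top_k, verbose = verbose),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys mirroring [pipeline_config()]
#'   (`out_dir`, `seed` or `models`, optional `protocols`, `species`,
#'   `tox_organs`, `top_k`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    out_dir = x$out_dir %||% dirname(path),
    seed = x$seed, models = x$models,
    protocols = x$protocols, species = x$species,
    tox_organs = x$tox_organs %||% c("brain", "gonads"),
    top_k = x$top_k %||% 20, verbose = isTRUE(x$verbose))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  keep <- config[c("seed", "protocols", "species", "tox_organs", "top_k")]
  keep$models <- config$models
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_models <- function(config) {
  if (!is.null(config$models)) {
    models <- lapply(config$models, function(m) {
      build_model(read_species_file(m$species),
                  read_compound_file(m$compound),
                  read_protocol_file(m$protocol))
    })
    names(models) <- vapply(models, model_id, "")
    return(models)
  }
  models <- make_reference_ensemble(synthetic_config(seed = config$seed,
                                                     jitter_cv = 0))
  if (!is.null(config$protocols)) {
    keep <- paste0(rep(config$protocols, each = length(TEMPLATE_BW)), "|",
                   rep(names(TEMPLATE_BW), length(config$protocols)))
    models <- models[names(models) %in% keep]
  }
  if (!is.null(config$species))
    models <- models[sub("^.*\\|", "", names(models)) %in% config$species]
  models
}

#' Run the full sensitivity pipeline
#'
#' Builds (or loads) the model ensemble, runs the ensemble sensitivity
#' analysis, classifies and groups the per-parameter maxima, and writes
#' `sens.csv` (all records), `summary.json` (classification summary plus
#' provenance) and `report.md` (human-readable report with the ranked
#' head and a log-spaced histogram of the maxima). Regenerating with the
#' same configuration produces byte-identical artifacts.
#'
#' @param config a [pipeline_config()] or the path to a YAML config.
#' @return the report structure, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  models <- pipeline_models(config)
  if (length(models) == 0) stop("pipeline stage 'models': empty ensemble")
  settings <- sensitivity_settings(sites = config$sites)
  tab <- ensemble_sensitivity(models, settings, progress = config$verbose)
  summ <- summarize_sensitivities(tab$max_by_parameter, config$thresholds,
                                  top_k = config$top_k)
  groups <- group_parameter(names(tab$max_by_parameter),
                            tox_organs = config$tox_organs)

  write_sensitivity_csv(tab, file.path(config$out_dir, "sens.csv"))

  provenance <- list(package = "pbtkcross",
                     version = as.character(utils::packageVersion("pbtkcross")),
                     seed = config$seed, config_hash = config_hash(config))
  summary_out <- list(
    n_models = length(models),
    n_parameters = summ$n,
    n_records = nrow(tab$records),
    counts = as.list(summ$counts),
    fractions_pct = as.list(stats::setNames(summ$fractions_pct,
                                            names(summ$counts))),
    above_dose = summ$above_dose,
    max_sensitivity = summ$max_value,
    top = as.list(summ$top),
    top_groups = as.list(stats::setNames(
      group_parameter(names(summ$top), config$tox_organs), names(summ$top))),
    histogram = summ$histogram,
    provenance = provenance)
  writeLines(jsonlite::toJSON(summary_out, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(config$out_dir, "summary.json"))

  md <- c(
    "# Ensemble sensitivity report", "",
    sprintf("- models: %d; parameters: %d; sensitivity records: %d",
            length(models), summ$n, nrow(tab$records)),
    sprintf("- provenance: pbtkcross %s, seed %s, config %s",
            provenance$version, provenance$seed %||% "(files)",
            provenance$config_hash),
    "", "## Classification of per-parameter maxima", "",
    sprintf("| class | count | fraction |"),
    "|---|---|---|",
    sprintf("| %s | %d | %.1f%% |", names(summ$counts), summ$counts,
            summ$fractions_pct),
    sprintf("| above dose effect (>1) | %d | |", summ$above_dose),
    "", "## Top-ranked parameters", "",
    "| parameter | max sensitivity | group |", "|---|---|---|",
    sprintf("| %s | %.4g | %s |", names(summ$top), summ$top,
            group_parameter(names(summ$top), config$tox_organs)),
    "", "## Histogram of maxima (log-spaced bins)", "",
    sprintf("- (%.3g, %.3g]: %d", utils::head(summ$histogram$breaks, -1),
            utils::tail(summ$histogram$breaks, -1), summ$histogram$counts))
  writeLines(md, file.path(config$out_dir, "report.md"))

  invisible(list(models = names(models), table = tab, summary = summ,
                 groups = groups, provenance = provenance))
}
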