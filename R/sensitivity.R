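#' Sensitivity analysis settings
#'
#' One-at-a-time multiplicative perturbation of a single physiological
#' parameter, normalized against the effect of perturbing the dose by the
#' same relative amount (both 5 percent reductions by default).
#'
#' @param perturbation_factor multiplicative factor applied to the
#'   parameter (default 0.95).
#' @param dose_factor multiplicative factor applied to the dose
#'   (default 0.95).
#' @param sites list of [observation_site()]s; defaults to peripheral
#'   venous plasma (the superficial-vein sampling site of real PK data,
#'   which also makes the peripheral blood flow fractions functionally
#'   active) and the intracellular space of brain and gonads (the tox
#'   organs). Central venous plasma can be requested instead.
#' @return an object of class `sensitivity_settings`.
#' @export
sensitivity_settings <- function(perturbation_factor = 0.95,
                                 dose_factor = 0.95,
                                 sites = default_sensitivity_sites()) {
  for (f in c(perturbation_factor, dose_factor))
    if (!is.finite(f) || f <= 0 || f == 1)
      stop("perturbation factors must be positive and != 1")
  stopifnot(length(sites) >= 1,
            all(vapply(sites, inherits, NA, "observation_site")))
  structure(list(perturbation_factor = perturbation_factor,
                 dose_factor = dose_factor, sites = sites),
            class = "sensitivity_settings")
}

#' Default observation sites for the sensitivity analysis
#' @return list of [observation_site()]: peripheral venous plasma, brain
#'   and gonads intracellular.
#' @export
default_sensitivity_sites <- function() {
  list(observation_site("peripheral_venous_plasma"),
       observation_site("organ_intracellular", organ = "brain"),
       observation_site("organ_intracellular", organ = "gonads"))
}

#' Root-mean-square deviation between two profiles
#'
#' `sqrt(mean((a - b)^2))` on the linear concentration scale over the
#' shared uniform grid.
#'
#' @param a,b [observe()] profiles on identical time grids and sites.
#' @return RMSD in umol/L.
#' @export
rmsd <- function(a, b) {
  stopifnot(inherits(a, "conc_profile"), inherits(b, "conc_profile"))
  if (!isTRUE(all.equal(a$times, b$times, tolerance = 0)) ||
      length(a$times) != length(b$times))
    stop("profiles are on different time grids")
  if (site_label(a$site) != site_label(b$site))
    stop("profiles observe different sites")
  sqrt(mean((a$concentrations - b$concentrations)^2))
}

# simulate the dose-perturbed model
perturb_dose <- function(model, factor) {
  proto <- model$protocol
  proto$dose_per_kg <- proto$dose_per_kg * factor
  build_model(model$species, model$compound, proto, validate = FALSE)
}

# simulate the parameter-perturbed model; all derived quantities are
# rebuilt from the perturbed species (no stale caches, no renormalization
# of dependent parameters)
perturb_parameter <- function(model, path, factor) {
  sp <- set_parameter(model$species, path, get_parameter(model$species, path)
                      * factor)
  build_model(sp, model$compound, model$protocol, validate = FALSE)
}

#' Dose-normalized sensitivity of one parameter
#'
#' Simulates the baseline curve `c0`, the curve `ci` with the parameter
#' multiplied by the perturbation factor (0.95 by default, all derived
#' quantities rebuilt), and the curve `cdose` with the dose reduced by
#' the same relative amount, then reports
#' `sens_rmsd = rmsd(c0, ci) / rmsd(c0, cdose)` per observation site,
#' together with the cmax-based alternative
#' `sens_cmax = |cmax(ci) - cmax(c0)| / |cmax(cdose) - cmax(c0)|`.
#'
#' The special path `"Application|Dose"` perturbs the dose itself, for
#' which the ratio is identically 1; it is accepted here but never listed
#' among a model's physiological `parameter_paths`.
#'
#' @param model a [build_model()] result.
#' @param path a parameter path from `model$parameter_paths` (or
#'   `"Application|Dose"`).
#' @param settings a [sensitivity_settings()].
#' @param sim a [sim_settings()] or `NULL` for route defaults.
#' @param baseline optional precomputed list from
#'   [sensitivity_baseline()] to avoid re-simulating `c0` and `cdose`.
#' @return data frame with one row per site: `parameter_path`,
#'   `model_id`, `site`, `sens_rmsd`, `sens_cmax`.
#' @export
sensitivity_for_parameter <- function(model, path,
                                      settings = sensitivity_settings(),
                                      sim = NULL, baseline = NULL) {
  stopifnot(inherits(model, "pbtk_model"))
  if (path != DOSE_PATH && !path %in% model$parameter_paths)
    stop("unknown parameter path: ", path)
  if (is.null(baseline)) baseline <- sensitivity_baseline(model, settings, sim)
  res_i <- if (path == DOSE_PATH) baseline$res_dose else
    simulate_pbtk(perturb_parameter(model, path,
                                    settings$perturbation_factor), sim)
  rows <- lapply(seq_along(settings$sites), function(k) {
    site <- settings$sites[[k]]
    c0 <- baseline$c0[[k]]; cd <- baseline$cdose[[k]]
    ci <- observe(res_i, site, role = "ci")
    den <- rmsd(c0, cd)
    if (den == 0)
      stop("degenerate normalization: dose change does not affect ",
           site_label(site))
    den_cmax <- abs(summary_metrics(cd)$cmax - summary_metrics(c0)$cmax)
    num_cmax <- abs(summary_metrics(ci)$cmax - summary_metrics(c0)$cmax)
    data.frame(parameter_path = path, model_id = model_id(model),
               site = site_label(site),
               sens_rmsd = rmsd(c0, ci) / den,
               sens_cmax = if (den_cmax > 0) num_cmax / den_cmax else NA_real_)
  })
  do.call(rbind, rows)
}

#' Baseline and dose-perturbed simulations for sensitivity runs
#'
#' @inheritParams sensitivity_for_parameter
#' @return list with observed `c0` and `cdose` profiles per site (cached
#'   once per model) and the dose-perturbed result `res_dose`.
#' @export
sensitivity_baseline <- function(model, settings = sensitivity_settings(),
                                 sim = NULL) {
  res0 <- simulate_pbtk(model, sim)
  res_dose <- simulate_pbtk(perturb_dose(model, settings$dose_factor), sim)
  list(
    c0 = lapply(settings$sites, function(s) observe(res0, s, role = "c0")),
    cdose = lapply(settings$sites, function(s)
      observe(res_dose, s, role = "cdose")),
    res_dose = res_dose
  )
}

model_id <- function(model) {
  paste0(model$compound$name, "_",
         if (model$protocol$route == "oral") "po" else "iv", "|",
         model$species$name)
}

#' Ensemble sensitivity analysis
#'
#' Runs the dose-normalized sensitivity for every physiological parameter
#' of every model at every observation site, and aggregates the maximum
#' sensitivity each parameter exhibits across all models and sites.
#' Parameters absent from a model (or with baseline value zero, for which
#' a multiplicative perturbation is a no-op) contribute no record for
#' that model; zero-baseline skips are reported once per run.
#'
#' @param models list of [build_model()] results.
#' @param settings a [sensitivity_settings()].
#' @param sim a [sim_settings()] or `NULL` for per-route defaults.
#' @param progress print a progress line per model.
#' @return an object of class `sensitivity_table`: `records` (data frame
#'   with `parameter_path`, `model_id`, `site`, `sens_rmsd`, `sens_cmax`,
#'   `route`) and `max_by_parameter` (named vector sorted decreasing).
#' @export
ensemble_sensitivity <- function(models, settings = sensitivity_settings(),
                                 sim = NULL, progress = FALSE) {
  if (length(models) == 0) stop("empty model list")
  stopifnot(all(vapply(models, inherits, NA, "pbtk_model")))
  skipped <- character()
  chunks <- vector("list", length(models))
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    if (progress)
      message(sprintf("[%d/%d] %s", mi, length(models), model_id(model)))
    baseline <- sensitivity_baseline(model, settings, sim)
    rows <- lapply(model$parameter_paths, function(path) {
      if (get_parameter(model$species, path) == 0) {
        skipped <<- c(skipped, path)
        return(NULL)
      }
      sensitivity_for_parameter(model, path, settings, sim, baseline)
    })
    chunk <- do.call(rbind, rows)
    chunk$route <- model$protocol$route
    chunks[[mi]] <- chunk
  }
  records <- do.call(rbind, chunks)
  if (length(skipped))
    message("skipped ", length(skipped), " zero-baseline parameter(s): ",
            paste(unique(skipped), collapse = ", "))
  mx <- tapply(records$sens_rmsd, records$parameter_path, max)
  mx <- mx[order(-mx, names(mx))]
  structure(list(records = records,
                 max_by_parameter = stats::setNames(as.numeric(mx), names(mx))),
            class = "sensitivity_table")
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("<sensitivity_table> %d records, %d parameters\n",
              nrow(x$records), length(x$max_by_parameter)))
  top <- utils::head(x$max_by_parameter, 5)
  for (i in seq_along(top))
    cat(sprintf("  %-60s %.3g\n", names(top)[i], top[i]))
  invisible(x)
}

#' Sensitivity classification thresholds
#'
#' @param insensitive_below,low_below,moderate_max,above_dose strictly
#'   increasing class boundaries (defaults 0.01, 0.1, 0.4, 1).
#' @return an object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(insensitive_below = 0.01,
                                      low_below = 0.1, moderate_max = 0.4,
                                      above_dose = 1.0) {
  v <- c(insensitive_below, low_below, moderate_max, above_dose)
  if (any(diff(v) <= 0)) stop("thresholds must be strictly increasing")
  structure(list(insensitive_below = insensitive_below,
                 low_below = low_below, moderate_max = moderate_max,
                 above_dose = above_dose),
            class = "classification_thresholds")
}

#' Classify sensitivities into relevance classes
#'
#' `insensitive` below 0.01, `low` in `[0.01, 0.1)`, `moderate` in
#' `[0.1, 0.4]`, `sensitive` above 0.4 (boundaries from the default
#' [classification_thresholds()]). Values above 1 additionally exceed
#' the effect of the dose change itself; see the `above_dose` flag in
#' [summarize_sensitivities()].
#'
#' @param sens non-negative sensitivity value(s); vectorized.
#' @param thresholds a [classification_thresholds()].
#' @return character vector of class labels.
#' @export
classify_sensitivity <- function(sens, thresholds = classification_thresholds()) {
  if (any(!is.finite(sens)) || any(sens < 0))
    stop("sensitivities must be finite and non-negative")
  th <- thresholds
  ifelse(sens < th$insensitive_below, "insensitive",
    ifelse(sens < th$low_below, "low",
      ifelse(sens <= th$moderate_max, "moderate", "sensitive")))
}

#' Functional group of a physiological parameter
#'
#' Maps a pipe-delimited parameter path to the functional groups used to
#' prioritize parameter identification when building a new species model:
#' gut transit times, gut pH, gut geometry, plasma parameters, volume of
#' distribution and clearance, tox-organ parameters, or other.
#'
#' @param path parameter path(s); vectorized.
#' @param tox_organs organ names declared as tox organs; their volume,
#'   specific blood flow and tissue composition map to `tox_organ`.
#' @return character vector of group labels.
#' @examples
#' group_parameter("Organism|Lumen|UpperIleum|pH")
#' group_parameter("Organism|Brain|Volume", tox_organs = "brain")
#' @export
group_parameter <- function(path, tox_organs = character()) {
  stopifnot(all(tox_organs %in% ORGAN_NAMES))
  vapply(path, function(p) {
    parts <- strsplit(p, "|", fixed = TRUE)[[1]]
    parse_parameter_path(p) # malformed paths error here
    leaf <- parts[length(parts)]
    lumen <- length(parts) == 4L && parts[2] == "Lumen"
    organ <- if (length(parts) == 3L)
      names(ORGAN_DISPLAY)[match(parts[2], ORGAN_DISPLAY)] else NA
    if (!is.na(organ) && organ %in% tox_organs &&
        leaf %in% c("Volume", "Specific blood flow rate",
                    COMPOSITION_DISPLAY))
      return("tox_organ")
    if (leaf %in% c("Gastric emptying time", "Intestinal transit rate",
                    "Small intestinal transit time",
                    "Large intestinal transit time"))
      return("git_transit_times")
    if (lumen && leaf == "pH") return("git_pH")
    if (lumen && leaf %in% c("Length", "Proximal radius", "Distal radius",
                             "Effective surface area enhancement factor",
                             "Fractional steady-state fill level"))
      return("git_geometry")
    if (leaf %in% c("Haematocrit", "pH (plasma)", "pH (blood cells)",
                    "pH (intracellular)"))
      return("plasma_parameters")
    if (leaf == "GFR (specific)" || leaf %in% COMPOSITION_DISPLAY)
      return("volume_distribution_clearance")
    if (leaf == "Specific blood flow rate")
      return("volume_distribution_clearance")
    if (leaf == "Volume" && !is.na(organ) &&
        organ %in% c("liver", "kidney", "muscle"))
      return("volume_distribution_clearance")
    "other"
  }, "", USE.NAMES = FALSE)
}

#' Load an externally supplied maximum-sensitivity table
#'
#' Re-analysis entry point for a per-parameter maximum-sensitivity list
#' exported as CSV/TSV. Two layouts are accepted: long (a parameter-path
#' column plus one `max`-like sensitivity column) and wide (a path column
#' plus one column per model; the row-wise maximum over non-blank cells
#' is taken, so parameters absent from some models use only the models
#' where they exist).
#'
#' @param path CSV or TSV file.
#' @return named numeric vector: parameter path to maximum sensitivity.
#' @export
load_max_sensitivity_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("table needs a path column and sensitivity column(s)")
  paths <- as.character(df[[1]])
  if (anyDuplicated(paths))
    stop("duplicated parameter path(s): ",
         paste(unique(paths[duplicated(paths)]), collapse = ", "))
  vals <- df[-1]
  nonnum <- !vapply(vals, is.numeric, NA)
  if (any(nonnum))
    stop("non-numeric sensitivity column(s): ",
         paste(names(vals)[nonnum], collapse = ", "))
  mx <- names(vals)[tolower(names(vals)) %in% c("max", "max_sensitivity",
                                                "maximum")]
  out <- if (length(mx) == 1) vals[[mx]]
         else apply(as.matrix(vals), 1, max, na.rm = TRUE)
  if (any(!is.finite(out)))
    stop("rows with no finite sensitivity value")
  stats::setNames(as.numeric(out), paths)
}

#' Summarize a maximum-sensitivity map
#'
#' @param max_map named vector from [load_max_sensitivity_table()] or
#'   `max_by_parameter` of an [ensemble_sensitivity()] table.
#' @param thresholds a [classification_thresholds()].
#' @param top_k number of top-ranked parameters to list.
#' @param bins histogram bin edges on the sensitivity axis; defaults to
#'   log-spaced bins spanning the data.
#' @return an object of class `sensitivity_summary`: class `counts` (a
#'   partition of the total), `fractions_pct` (percent, 1 decimal),
#'   `above_dose` count, `top` (ranked head, ties broken by path),
#'   `max_value` and `histogram`.
#' @export
summarize_sensitivities <- function(max_map,
                                    thresholds = classification_thresholds(),
                                    top_k = 20, bins = NULL) {
  if (length(max_map) == 0) stop("empty sensitivity map")
  cls <- factor(classify_sensitivity(max_map, thresholds),
                levels = c("insensitive", "low", "moderate", "sensitive"))
  counts <- table(cls)
  ord <- order(-max_map, names(max_map))
  if (is.null(bins)) {
    lo <- max(min(max_map[max_map > 0], 1e-6), 1e-12)
    hi <- max(max_map) * 1.0001 + 1e-12
    bins <- exp(seq(log(lo), log(hi), length.out = 13))
    bins[1] <- 0
  }
  hist_counts <- table(cut(max_map, breaks = bins, include.lowest = TRUE))
  structure(list(
    n = length(max_map),
    counts = stats::setNames(as.integer(counts), names(counts)),
    fractions_pct = round(100 * as.integer(counts) / length(max_map), 1),
    above_dose = sum(max_map > thresholds$above_dose),
    top = max_map[utils::head(ord, top_k)],
    max_value = unname(max_map[ord[1]]),
    histogram = list(breaks = bins, counts = as.integer(hist_counts))
  ), class = "sensitivity_summary")
}

#' @export
print.sensitivity_summary <- function(x, ...) {
  cat(sprintf("<sensitivity_summary> %d parameters\n", x$n))
  for (i in seq_along(x$counts))
    cat(sprintf("  %-12s %4d (%.1f%%)\n", names(x$counts)[i], x$counts[i],
                x$fractions_pct[i]))
  cat(sprintf("  above dose effect (>1): %d; max %.3g\n",
              x$above_dose, x$max_value))
  invisible(x)
}

#' Cross-species overlap of sensitive non-GIT parameters
#'
#' For each species, collects the set of non-GIT parameters whose maximum
#' sensitivity (over that species' models, at the given sites) exceeds
#' the sensitive threshold, and reports the Jaccard overlap of these sets
#' for every species pair. The reference finding is that non-GIT
#' sensitivity is qualitatively stable across species while GIT
#' sensitivity is not; the overlap quantifies that stability without a
#' hard threshold.
#'
#' @param table an [ensemble_sensitivity()] result whose `model_id`s end
#'   in `"|species"`.
#' @param thresholds a [classification_thresholds()]; the sensitive
#'   boundary (`moderate_max`) is used.
#' @param sites optional character vector of site labels to restrict to
#'   (e.g. `"peripheral_venous_plasma"`).
#' @return list with the per-species `sets`, the pairwise `jaccard`
#'   matrix and their `mean_jaccard`.
#' @export
nongit_sensitivity_overlap <- function(table,
                                       thresholds = classification_thresholds(),
                                       sites = NULL) {
  stopifnot(inherits(table, "sensitivity_table"))
  rec <- table$records
  if (!is.null(sites)) rec <- rec[rec$site %in% sites, ]
  rec$species <- sub("^.*\\|", "", rec$model_id)
  grp <- group_parameter(rec$parameter_path)
  rec <- rec[!grp %in% c("git_transit_times", "git_pH", "git_geometry"), ]
  sets <- lapply(split(rec, rec$species), function(d) {
    mx <- tapply(d$sens_rmsd, d$parameter_path, max)
    names(mx)[mx > thresholds$moderate_max]
  })
  nsp <- length(sets)
  jac <- matrix(1, nsp, nsp, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(nsp)) for (j in seq_len(nsp)) if (i != j) {
    u <- union(sets[[i]], sets[[j]])
    jac[i, j] <- if (length(u)) length(intersect(sets[[i]], sets[[j]])) /
      length(u) else 1
  }
  list(sets = sets, jaccard = jac,
       mean_jaccard = mean(jac[upper.tri(jac)]))
}

#' Write ensemble sensitivity records to CSV
#' @param table a [ensemble_sensitivity()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(table, path) {
  stopifnot(inherits(table, "sensitivity_table"))
  utils::write.csv(table$records, path, row.names = FALSE)
  invisible(path)
}
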