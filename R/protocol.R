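#' Administration protocol
#'
#' Doses are always given per kilogram of body weight so that the same
#' protocol transfers across species of different size; the absolute dose
#' is recomputed from the target species when a model is built or
#' extrapolated.
#'
#' @param route `"iv_bolus"` or `"oral"`.
#' @param dose_per_kg mg/kg, > 0.
#' @param start_time administration time, min (default 0).
#' @return an object of class `admin_protocol`.
#' @export
admin_protocol <- function(route = c("iv_bolus", "oral"), dose_per_kg,
                           start_time = 0) {
  route <- match.arg(route)
  if (!is.finite(dose_per_kg) || dose_per_kg <= 0)
    stop("dose_per_kg must be > 0")
  if (!is.finite(start_time) || start_time < 0)
    stop("start_time must be >= 0")
  structure(list(route = route, dose_per_kg = dose_per_kg,
                 start_time = start_time), class = "admin_protocol")
}

#' Observation site
#'
#' Where a concentration-time profile is read off a simulation: central
#' venous plasma, flow-weighted peripheral venous plasma, or the
#' intracellular space of a named organ (e.g. a tox organ such as brain
#' or gonads).
#'
#' @param site `"venous_plasma"`, `"peripheral_venous_plasma"` or
#'   `"organ_intracellular"`.
#' @param organ organ name; required iff `site = "organ_intracellular"`.
#' @return an object of class `observation_site`.
#' @export
observation_site <- function(site = c("venous_plasma",
                                      "peripheral_venous_plasma",
                                      "organ_intracellular"),
                             organ = NULL) {
  site <- match.arg(site)
  if (site == "organ_intracellular") {
    if (is.null(organ)) stop("organ is required for organ_intracellular")
  } else if (!is.null(organ)) {
    stop("organ must be absent unless site is organ_intracellular")
  }
  structure(list(site = site, organ = organ), class = "observation_site")
}

site_label <- function(site) {
  if (site$site == "organ_intracellular")
    paste0("intracellular_", site$organ)
  else site$site
}

#' Simulation settings
#'
#' @param t_end simulation end, min. Defaults (when `NULL` and resolved
#'   against a protocol) to 24 h for i.v. bolus and 48 h for oral dosing.
#' @param n_samples number of uniform output samples (>= 50).
#' @param rel_tol,abs_tol solver tolerances.
#' @return an object of class `sim_settings`.
#' @export
sim_settings <- function(t_end = NULL, n_samples = 240, rel_tol = 1e-8,
                         abs_tol = 1e-10) {
  if (!is.null(t_end) && (!is.finite(t_end) || t_end <= 0))
    stop("t_end must be > 0")
  if (n_samples < 50) stop("n_samples must be >= 50")
  structure(list(t_end = t_end, n_samples = as.integer(n_samples),
                 rel_tol = rel_tol, abs_tol = abs_tol),
            class = "sim_settings")
}

resolve_settings <- function(settings, protocol) {
  if (is.null(settings)) settings <- sim_settings()
  if (is.null(settings$t_end))
    settings$t_end <- if (protocol$route == "oral") 2880 else 1440
  settings
}
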