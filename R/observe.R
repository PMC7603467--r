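#' Read a concentration-time profile off a simulation
#'
#' Converts the amount trajectories of a simulation into the
#' concentration observed at a site:
#' * `venous_plasma`: venous blood concentration divided by the
#'   blood:plasma ratio;
#' * `peripheral_venous_plasma`: flow-weighted mean of organ outflow
#'   plasma concentrations, weighted by each organ's peripheral blood
#'   flow fraction times its blood flow (typically muscle and skin — the
#'   superficial sampling site of a venous catheter);
#' * `organ_intracellular`: cellular concentration of an organ,
#'   `K_cell/Kp_total` times the total organ concentration.
#'
#' @param result a [simulate_pbtk()] result.
#' @param site an [observation_site()].
#' @param role profile role annotation (baseline `"c0"`, perturbed
#'   `"ci"`, dose-perturbed `"cdose"`, or `"observed"`).
#' @return an object of class `conc_profile` with uniform `times` (min)
#'   and `concentrations` (umol/L).
#' @export
observe <- function(result, site, role = "c0") {
  stopifnot(inherits(result, "sim_result"),
            inherits(site, "observation_site"))
  model <- result$model
  sp <- model$species
  A <- result$amounts
  conc <- switch(site$site,
    venous_plasma = A[, "venous_blood"] / sp$blood_volumes$venous /
      model$derived$BP,
    peripheral_venous_plasma = {
      w <- vapply(sp$organs[ORGAN_NAMES], `[[`, 0,
                  "peripheral_blood_flow_fraction")
      wq <- w * model$derived$flows
      if (sum(wq) <= 0)
        stop("no organ carries peripheral blood flow weight")
      Kp <- model$derived$partition$Kp_total
      V <- vapply(sp$organs[ORGAN_NAMES], `[[`, 0, "volume")
      # outflow plasma concentration of organ o: (A/V)/Kp
      cp <- sweep(A[, ORGAN_NAMES, drop = FALSE], 2, V * Kp, "/")
      drop(cp %*% wq) / sum(wq)
    },
    organ_intracellular = {
      if (!site$organ %in% names(sp$organs))
        stop("organ '", site$organ, "' is absent from species ", sp$name)
      i <- match(site$organ, model$derived$partition$organ)
      ratio <- model$derived$partition$K_cell[i] /
        model$derived$partition$Kp_total[i]
      A[, site$organ] / sp$organs[[site$organ]]$volume * ratio
    })
  structure(list(site = site, times = result$times,
                 concentrations = unname(conc), role = role),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> %s (%s): %d samples, cmax %.4g umol/L\n",
              site_label(x$site), x$role, length(x$times),
              max(x$concentrations)))
  invisible(x)
}

#' Summary exposure metrics of a profile
#'
#' @param profile a [observe()] profile.
#' @return list with `cmax` (umol/L), `tmax` (min, earliest argmax) and
#'   `auc` (umol*min/L, trapezoidal).
#' @export
summary_metrics <- function(profile) {
  stopifnot(inherits(profile, "conc_profile"))
  cc <- profile$concentrations
  tt <- profile$times
  if (length(cc) == 0) stop("empty profile")
  i <- which.max(cc)
  auc <- sum(diff(tt) * (cc[-length(cc)] + cc[-1]) / 2)
  list(cmax = cc[i], tmax = tt[i], auc = auc)
}
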