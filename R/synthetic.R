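# Synthetic species, compounds and observations.
#
# These generators stand in for a curated physiology database and for
# validated literature compound models: jittered species around the
# packaged templates, archetype compounds drawn inside the reference
# property ranges (MW 151-361 g/mol, logP -0.02..1.25), the packaged
# 8-protocol x 7-species reference ensemble, and noisy pseudo-observed
# concentration data for the validation comparator.

#' Synthetic-data configuration
#'
#' @param seed integer seed; every random draw in the synthetic module
#'   flows from it.
#' @param jitter_cv coefficient of variation of the species parameter
#'   jitter (default 0.2).
#' @param noise_cv coefficient of variation of observation noise
#'   (default 0.15).
#' @param n_species_samples,n_compound_samples sample counts for batch
#'   generation.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, jitter_cv = 0.2, noise_cv = 0.15,
                             n_species_samples = 1L, n_compound_samples = 1L) {
  if (jitter_cv < 0 || noise_cv < 0) stop("CVs must be >= 0")
  structure(list(seed = as.integer(seed), jitter_cv = jitter_cv,
                 noise_cv = noise_cv,
                 n_species_samples = as.integer(n_species_samples),
                 n_compound_samples = as.integer(n_compound_samples)),
            class = "synthetic_config")
}

# evaluate expr under a seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic compound of a clearance archetype
#'
#' Draws physicochemistry uniformly inside the reference small-molecule
#' property ranges (MW 151-361 g/mol, logP -0.02..1.25, pKa 3-10 when
#' ionizable, fu 0.05-1) and assigns clearance terms by archetype:
#' `renal_only` (glomerular filtration only, gfr_fraction 1),
#' `hepatic_only` (metabolic clearance only), or
#' `mixed_hepatic_tubular` (hepatic clearance plus tubular secretion).
#'
#' @param archetype clearance archetype.
#' @param seed integer seed; identical seeds give identical compounds.
#' @return a [compound()].
#' @export
generate_compound <- function(archetype = c("renal_only", "hepatic_only",
                                            "mixed_hepatic_tubular"),
                              seed = 1L) {
  archetype <- match.arg(archetype)
  with_seed(seed, {
    mw <- stats::runif(1, 151, 361)
    logP <- stats::runif(1, -0.02, 1.25)
    kind <- sample(c("neutral", "monoprotic_acid", "monoprotic_base"), 1)
    ion <- if (kind == "neutral") ionization_spec("neutral")
           else ionization_spec(kind, pKa = stats::runif(1, 3, 10))
    fu <- stats::runif(1, 0.05, 1)
    clh <- stats::runif(1, 0.1, 0.8)
    clt <- stats::runif(1, 0.5, 3)
    compound(
      name = sprintf("synthetic_%s_%d", archetype, seed),
      molecular_weight = mw, logP = logP, ionization = ion,
      fraction_unbound_plasma = fu,
      effective_permeability = stats::runif(1, 1e-3, 1e-2),
      specific_hepatic_clearance = if (archetype == "renal_only") 0 else clh,
      specific_tubular_secretion =
        if (archetype == "mixed_hepatic_tubular") clt else 0,
      gfr_fraction = if (archetype == "renal_only") 1
                     else if (archetype == "hepatic_only") 0
                     else stats::runif(1, 0, 1),
      solubility = Inf
    )
  })
}

#' Generate a jittered species at a target body weight
#'
#' Allometrically scales a template to the target weight, then applies
#' mean-preserving lognormal jitter (CV `jitter_cv`) to volumes, blood
#' flows, lumen lengths and transit times. pH values, fractions and
#' compositions are not jittered. Organ and blood volumes are then
#' re-closed on the body weight by an additive correction proportional
#' to the nominal volumes, which preserves each volume's expectation
#' exactly. `jitter_cv = 0` reduces exactly to [allometric_scale()].
#'
#' @param template a [species_physiology()].
#' @param target_bw target body weight, kg.
#' @param config a [synthetic_config()] (seed and `jitter_cv`).
#' @param settings [scaling_settings()] for the allometric step.
#' @return a validated `species_physiology`.
#' @export
generate_species <- function(template, target_bw, config = synthetic_config(),
                             settings = scaling_settings()) {
  sp <- allometric_scale(template, target_bw, settings)
  cv <- config$jitter_cv
  if (cv == 0) return(sp)
  sdlog <- sqrt(log(1 + cv^2))
  mulog <- -sdlog^2 / 2 # mean-preserving
  with_seed(config$seed, {
    jit <- function(x) x * stats::rlnorm(length(x), mulog, sdlog)
    nominal <- c(vapply(sp$organs, `[[`, 0, "volume"),
                 unlist(sp$blood_volumes[c("venous", "arterial", "portal")]))
    jittered <- jit(nominal)
    # additive re-closure proportional to nominal volumes: E[v'] = nominal
    excess <- sum(jittered) - target_bw
    closed <- jittered - excess * nominal / sum(nominal)
    if (any(closed <= 0))
      stop("volume jitter produced a non-positive volume; lower jitter_cv")
    for (i in seq_along(ORGAN_NAMES))
      sp$organs[[ORGAN_NAMES[i]]]$volume <- closed[[i]]
    sp$blood_volumes$venous <- closed[[length(ORGAN_NAMES) + 1L]]
    sp$blood_volumes$arterial <- closed[[length(ORGAN_NAMES) + 2L]]
    sp$blood_volumes$portal <- closed[[length(ORGAN_NAMES) + 3L]]
    for (o in names(sp$organs))
      sp$organs[[o]]$specific_blood_flow <-
        jit(sp$organs[[o]]$specific_blood_flow)
    for (s in names(sp$lumen))
      sp$lumen[[s]]$length <- jit(sp$lumen[[s]]$length)
    sp$gastric_emptying_time <- jit(sp$gastric_emptying_time)
    sp$small_intestinal_transit_time <- jit(sp$small_intestinal_transit_time)
    sp$large_intestinal_transit_time <- jit(sp$large_intestinal_transit_time)
  })
  validate_species(sp)
  sp
}

#' Packaged demo compounds
#'
#' Six archetype-based approximations of well-characterized small
#' molecules ("-like" suffixes: these are NOT the validated literature
#' parameterizations). The inulin-like entry is a glomerular-filtration-
#' only small-molecule stand-in: the real polysaccharide (MW 6179 g/mol)
#' distributes through a large-molecule pore pathway that is outside this
#' model family, so only its renal-only clearance archetype is kept and
#' its properties are capped into the packaged small-molecule ranges.
#'
#' @return named list of six [compound()]s.
#' @export
demo_compound_set <- function() {
  list(
    acyclovir_like = compound("acyclovir_like", 225.2, 0.00,
      ionization_spec("neutral"), fraction_unbound_plasma = 0.85,
      effective_permeability = 5e-5, specific_hepatic_clearance = 0.05,
      specific_tubular_secretion = 2.0, gfr_fraction = 1,
      solubility = 2500),
    caffeine_like = compound("caffeine_like", 194.2, 0.10,
      ionization_spec("neutral"), fraction_unbound_plasma = 0.65,
      effective_permeability = 8e-3, specific_hepatic_clearance = 0.50,
      specific_tubular_secretion = 0, gfr_fraction = 0,
      solubility = 1e5),
    inulin_like = compound("inulin_like", 361.0, -0.02,
      ionization_spec("neutral"), fraction_unbound_plasma = 1.0,
      effective_permeability = 1e-4, specific_hepatic_clearance = 0,
      specific_tubular_secretion = 0, gfr_fraction = 1,
      solubility = 1e5),
    ofloxacin_like = compound("ofloxacin_like", 361.4, 0.35,
      ionization_spec("neutral"), fraction_unbound_plasma = 0.75,
      effective_permeability = 5e-3, specific_hepatic_clearance = 0.15,
      specific_tubular_secretion = 1.5, gfr_fraction = 1,
      solubility = 8000),
    paracetamol_like = compound("paracetamol_like", 151.2, 0.46,
      ionization_spec("monoprotic_acid", 9.4), fraction_unbound_plasma = 0.8,
      effective_permeability = 8e-3, specific_hepatic_clearance = 0.60,
      specific_tubular_secretion = 0, gfr_fraction = 0,
      solubility = 9e4),
    theophylline_like = compound("theophylline_like", 180.2, 0.00,
      ionization_spec("monoprotic_acid", 8.8), fraction_unbound_plasma = 0.6,
      effective_permeability = 6e-3, specific_hepatic_clearance = 0.30,
      specific_tubular_secretion = 1.0, gfr_fraction = 0,
      solubility = 4.5e4)
  )
}

#' Packaged reference protocols
#'
#' The eight demo (compound, route) pairs of the reference ensemble:
#' acyclovir-like (i.v. and p.o.), caffeine-like (i.v.), inulin-like
#' (i.v.), ofloxacin-like (i.v.), paracetamol-like (p.o.) and
#' theophylline-like (i.v. and p.o.). Demo doses are package choices
#' (mg/kg) and are documented as arbitrary but plausible.
#'
#' @return list of `list(compound =, protocol =)` pairs.
#' @export
reference_protocols <- function() {
  cmp <- demo_compound_set()
  mk <- function(c, route, dose) list(compound = cmp[[c]],
                                      protocol = admin_protocol(route, dose))
  list(
    acyclovir_iv = mk("acyclovir_like", "iv_bolus", 10),
    acyclovir_po = mk("acyclovir_like", "oral", 20),
    caffeine_iv = mk("caffeine_like", "iv_bolus", 5),
    inulin_iv = mk("inulin_like", "iv_bolus", 50),
    ofloxacin_iv = mk("ofloxacin_like", "iv_bolus", 10),
    paracetamol_po = mk("paracetamol_like", "oral", 30),
    theophylline_iv = mk("theophylline_like", "iv_bolus", 8),
    theophylline_po = mk("theophylline_like", "oral", 8)
  )
}

#' Build the 56-model reference ensemble
#'
#' Builds the eight demo protocols on the rabbit template and
#' extrapolates each to the other six packaged species: 8 x 7 = 56
#' models, with doses in mg/kg so every species receives the same
#' relative dose. With `jitter_cv = 0` (the default configuration used
#' for the reference ensemble) the ensemble is a deterministic function
#' of the packaged templates; a positive `jitter_cv` draws one jittered
#' physiology per species from the configured seed.
#'
#' @param config a [synthetic_config()].
#' @return named list of 56 [build_model()] results.
#' @export
make_reference_ensemble <- function(config = synthetic_config(jitter_cv = 0)) {
  templates <- species_template_set()
  if (config$jitter_cv > 0) {
    templates <- lapply(seq_along(templates), function(i) {
      cfg <- config
      cfg$seed <- as.integer((as.numeric(config$seed) + 7919 * i) %%
                               2147483647)
      generate_species(templates[[i]], templates[[i]]$body_weight, cfg)
    })
    names(templates) <- names(TEMPLATE_BW)
  }
  protos <- reference_protocols()
  models <- list()
  for (pn in names(protos)) {
    pr <- protos[[pn]]
    rabbit_model <- build_model(templates$rabbit, pr$compound, pr$protocol)
    models[[paste0(pn, "|rabbit")]] <- rabbit_model
    for (spn in setdiff(names(templates), "rabbit"))
      models[[paste0(pn, "|", spn)]] <-
        extrapolate(rabbit_model, templates[[spn]])
  }
  models
}

#' Generate noisy pseudo-observations from a model
#'
#' Simulates the model, interpolates the predicted profile at the sample
#' times and multiplies by lognormal noise (CV `noise_cv`, strictly
#' positive draws). `noise_cv = 0` returns the prediction itself.
#'
#' @param model a [build_model()] result.
#' @param sample_times observation times, min (within the simulation span).
#' @param config a [synthetic_config()] (seed and `noise_cv`).
#' @param site an [observation_site()].
#' @param sim a [sim_settings()] or `NULL`.
#' @return a `conc_profile` with role `"observed"`.
#' @export
generate_observations <- function(model, sample_times,
                                  config = synthetic_config(),
                                  site = observation_site("venous_plasma"),
                                  sim = NULL) {
  if (length(sample_times) == 0) stop("empty sample times")
  res <- simulate_pbtk(model, sim)
  if (any(sample_times < min(res$times) | sample_times > max(res$times)))
    stop("sample times outside the simulated span")
  pred <- observe(res, site)
  conc <- stats::approx(pred$times, pred$concentrations, sample_times)$y
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    conc <- with_seed(config$seed,
      conc * stats::rlnorm(length(conc), -sdlog^2 / 2, sdlog))
  }
  structure(list(site = site, times = sample_times, concentrations = conc,
                 role = "observed"), class = "conc_profile")
}
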