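test_that("model assembly: states, dose, flows and parameter scope", {
  m <- test_model_iv()
  res <- simulate_pbtk(m, sim_settings(t_end = 60, n_samples = 50))
  # 15 organs + 3 blood pools + 8 lumen segments + 3 sinks
  expect_identical(ncol(res$amounts), 29L)

  mouse <- species_template("mouse", body_weight = 0.23)
  m2 <- build_model(mouse, test_compound(), admin_protocol("iv_bolus", 10))
  expect_equal(m2$derived$dose_umol * 200 / 1000, 2.3) # 10 mg/kg x 0.23 kg

  # cardiac output equals the sum of arterial inflows (all but the lung)
  q <- m$derived$flows
  expect_equal(m$derived$cardiac_output, sum(q[names(q) != "lung"]))

  # physiological paths only: no compound or application leaves
  expect_false(any(grepl("Application|Dose|logP|Clearance|Permeability",
                         m$parameter_paths)))
  expect_true(all(c("Organism|Haematocrit", "Organism|Lumen|UpperIleum|pH",
                    "Organism|Kidney|GFR (specific)") %in%
                    m$parameter_paths))
  # every path resolves and round-trips through get/set
  sp <- m$species
  for (p in m$parameter_paths) {
    v <- get_parameter(sp, p)
    expect_true(is.finite(v), info = p)
    expect_identical(get_parameter(set_parameter(sp, p, v * 2), p), v * 2)
  }
  expect_error(get_parameter(sp, "Organism|Gallbladder|Volume"), "malformed")

  broken <- species_template("rabbit")
  broken$organs$liver <- NULL
  expect_error(build_model(broken, test_compound(),
                           admin_protocol("iv_bolus", 1)), "liver")
})

test_that("one-compartment degenerate model matches (D/V) exp(-kt)", {
  fx <- one_compartment_fixture()
  m <- build_model(fx$species, fx$compound, fx$protocol)
  res <- simulate_pbtk(m, sim_settings(t_end = 720, n_samples = 240,
                                       rel_tol = 1e-10, abs_tol = 1e-12))
  prof <- observe(res, observation_site("venous_plasma"))
  exact <- fx$dose_umol / fx$V * exp(-fx$k * prof$times)
  expect_lt(max(abs(prof$concentrations - exact) / exact), 1e-6)
})

test_that("dose linearity and determinism under unbounded solubility", {
  m1 <- test_model_iv(dose = 5)
  m2 <- test_model_iv(dose = 10)
  st <- sim_settings(abs_tol = 1e-12)
  r1 <- simulate_pbtk(m1, st)
  r2 <- simulate_pbtk(m2, st)
  expect_lt(max(abs(2 * r1$amounts - r2$amounts)) / max(r2$amounts), 1e-8)
  # bit-identical repetition
  expect_identical(r1$amounts, simulate_pbtk(m1, st)$amounts)
})

test_that("i.v. bolus never populates the lumen", {
  res <- simulate_pbtk(test_model_iv())
  lum <- res$amounts[, grep("^lumen_", colnames(res$amounts))]
  expect_identical(max(abs(lum)), 0)
  expect_identical(max(res$amounts[, "faeces"]), 0)
})

test_that("compiled and R right-hand sides agree", {
  sp <- species_template("rabbit")
  pr <- reference_protocols()$theophylline_po
  m <- build_model(sp, pr$compound, pr$protocol)
  a <- simulate_pbtk(m, engine = "compiled")
  b <- simulate_pbtk(m, engine = "R")
  expect_lt(max(abs(a$amounts - b$amounts)) / max(a$amounts), 1e-7)
})

test_that("mass balance holds for i.v. and oral routes", {
  for (pn in c("caffeine_iv", "acyclovir_po")) {
    pr <- reference_protocols()[[pn]]
    m <- build_model(species_template("rabbit"), pr$compound, pr$protocol)
    expect_lt(max(mass_balance_error(simulate_pbtk(m))), 1e-6)
  }
})

test_that("delayed administration enters at start_time", {
  sp <- species_template("rabbit")
  m <- build_model(sp, test_compound(),
                   admin_protocol("iv_bolus", 5, start_time = 60))
  res <- simulate_pbtk(m, sim_settings(t_end = 240, n_samples = 241))
  tot <- rowSums(res$amounts)
  expect_equal(unname(tot[res$times < 60]),
               rep(0, sum(res$times < 60)))
  expect_lt(max(mass_balance_error(res)[res$times > 60]), 1e-6)
})

test_that("cross-species extrapolation replaces physiology only", {
  rabbit <- species_template("rabbit")
  mouse <- species_template("mouse")
  m <- test_model_iv()
  back <- extrapolate(extrapolate(m, mouse), rabbit)
  expect_identical(simulate_pbtk(m)$amounts, simulate_pbtk(back)$amounts)

  mm <- extrapolate(m, mouse)
  expect_identical(mm$compound, m$compound)
  expect_identical(mm$protocol$dose_per_kg, m$protocol$dose_per_kg)
  expect_equal(mm$derived$dose_umol,
               m$protocol$dose_per_kg * mouse$body_weight / 200 * 1000)
})

test_that("observation sites and summary metrics", {
  m <- test_model_iv()
  res <- simulate_pbtk(m)
  # all peripheral weight on muscle: the peripheral profile is the muscle
  # outflow plasma concentration
  sp2 <- m$species
  sp2$organs$skin$peripheral_blood_flow_fraction <- 0
  m2 <- build_model(sp2, m$compound, m$protocol)
  res2 <- simulate_pbtk(m2)
  per <- observe(res2, observation_site("peripheral_venous_plasma"))
  i <- match("muscle", m2$derived$partition$organ)
  muscle_out <- res2$amounts[, "muscle"] / sp2$organs$muscle$volume /
    m2$derived$partition$Kp_total[i]
  expect_equal(per$concentrations, muscle_out, tolerance = 1e-12)

  # fv = fi = 0 makes intracellular equal total organ concentration
  sp3 <- m$species
  sp3$organs$brain$fraction_vascular <- 0
  sp3$organs$brain$fraction_interstitial <- 0
  m3 <- build_model(sp3, m$compound, m$protocol)
  res3 <- simulate_pbtk(m3)
  ic <- observe(res3, observation_site("organ_intracellular", "brain"))
  expect_equal(ic$concentrations,
               res3$amounts[, "brain"] / sp3$organs$brain$volume,
               tolerance = 1e-12)

  expect_error(observe(res, observation_site("organ_intracellular",
                                             "gallbladder")), "absent")

  prof <- make_profile(c(0, 10, 20), c(0, 3, 1))
  sm <- summary_metrics(prof)
  expect_equal(sm$cmax, 3)
  expect_equal(sm$tmax, 10)
  expect_equal(sm$auc, 35)
  # strictly decreasing i.v. profile peaks at the first grid point
  iv <- observe(res, observation_site("venous_plasma"))
  expect_equal(summary_metrics(iv)$tmax, 0)
})

test_that("closed system equilibrates to a uniform concentration", {
  sp <- uniform_species()
  cmp <- compound("inert", 200, 0.3)
  m <- build_model(sp, cmp, admin_protocol("iv_bolus", 5))
  res <- simulate_pbtk(m, sim_settings(t_end = 4320, n_samples = 200))
  n <- nrow(res$amounts)
  v <- c(vapply(sp$organs[ORGAN_ORDER], `[[`, 0, "volume"),
         unlist(sp$blood_volumes))
  conc <- res$amounts[n, c(ORGAN_ORDER, "venous_blood", "arterial_blood",
                           "portal_vein")] / v
  expect_equal(unname(conc), rep(m$derived$dose_umol / sum(v), 18),
               tolerance = 1e-4)
})
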