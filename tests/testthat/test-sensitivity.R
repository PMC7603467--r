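test_that("rmsd on matched grids", {
  a <- make_profile(c(0, 10), c(1, 1))
  b <- make_profile(c(0, 10), c(2, 2))
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, b), 1)
  expect_equal(rmsd(make_profile(c(0, 10), c(0, 0)),
                    make_profile(c(0, 10), c(3, 4))), sqrt(25 / 2))
  expect_error(rmsd(a, make_profile(c(0, 20), c(2, 2))), "grids")
})

test_that("the dose parameter has sensitivity exactly one", {
  for (m in list(test_model_iv(),
                 build_model(species_template("rabbit"),
                             demo_compound_set()$acyclovir_like,
                             admin_protocol("oral", 20)))) {
    rec <- sensitivity_for_parameter(m, "Application|Dose")
    expect_identical(rec$sens_rmsd, rep(1, 3))
    expect_identical(rec$sens_cmax, rep(1, 3))
  }
})

test_that("lumen parameters are structurally silent under i.v. dosing", {
  m <- test_model_iv()
  base <- sensitivity_baseline(m)
  for (p in sample(lumen_paths_of(m), 8)) {
    rec <- sensitivity_for_parameter(m, p, baseline = base)
    expect_lt(max(rec$sens_rmsd), 1e-6)
  }
})

test_that("sensitivity matches a closed-form brute-force oracle", {
  fx <- one_compartment_fixture()
  m <- build_model(fx$species, fx$compound, fx$protocol)
  st <- sim_settings(t_end = 720, n_samples = 240, rel_tol = 1e-10,
                     abs_tol = 1e-12)
  settings <- sensitivity_settings(sites = list(observation_site("venous_plasma")))
  rec <- sensitivity_for_parameter(m, "Organism|Kidney|GFR (specific)",
                                   settings, sim = st)
  # independent evaluation from the analytic solution on a dense grid:
  # c0 = (D/V) e^(-kt), ci = (D/V) e^(-0.95 k t), cdose = 0.95 c0
  tt <- seq(0, 720, length.out = 240)
  c0 <- fx$dose_umol / fx$V * exp(-fx$k * tt)
  ci <- fx$dose_umol / fx$V * exp(-0.95 * fx$k * tt)
  oracle <- sqrt(mean((c0 - ci)^2)) / sqrt(mean((0.05 * c0)^2))
  expect_equal(rec$sens_rmsd, oracle, tolerance = 1e-4)
  oracle_cmax <- abs(max(ci) - max(c0)) / abs(max(0.95 * c0) - max(c0))
  expect_equal(rec$sens_cmax, oracle_cmax, tolerance = 1e-4)
})

test_that("sensitivities are dose-invariant under linear kinetics", {
  paths <- c("Organism|Liver|Volume", "Organism|Haematocrit",
             "Organism|Muscle|Specific blood flow rate")
  st <- sim_settings(rel_tol = 1e-11, abs_tol = 1e-13)
  r1 <- lapply(paths, function(p)
    sensitivity_for_parameter(test_model_iv(5), p, sim = st)$sens_rmsd)
  r2 <- lapply(paths, function(p)
    sensitivity_for_parameter(test_model_iv(10), p, sim = st)$sens_rmsd)
  for (i in seq_along(paths))
    expect_equal(r1[[i]], r2[[i]], tolerance = 1e-8)
})

test_that("classification boundaries and partition", {
  expect_identical(classify_sensitivity(0.005), "insensitive")
  expect_identical(classify_sensitivity(0.01), "low")
  expect_identical(classify_sensitivity(0.25), "moderate")
  expect_identical(classify_sensitivity(0.4), "moderate")
  expect_identical(classify_sensitivity(0.401), "sensitive")
  expect_error(classify_sensitivity(-0.1), "non-negative")
  expect_error(classification_thresholds(0.2, 0.1, 0.4, 1), "increasing")

  set.seed(42)
  x <- stats::setNames(rexp(500, 5), paste0("p", 1:500))
  s <- summarize_sensitivities(x)
  expect_identical(sum(s$counts), 500L)
  expect_identical(sum(s$histogram$counts), 500L)
  cls <- classify_sensitivity(x)
  expect_identical(unname(s$counts),
                   c(sum(cls == "insensitive"), sum(cls == "low"),
                     sum(cls == "moderate"), sum(cls == "sensitive")))
})

test_that("summaries report fractions and a deterministic top list", {
  x <- c(a = 0.005, b = 0.05, c = 0.2, d = 0.5)
  s <- summarize_sensitivities(x)
  expect_identical(unname(s$counts), rep(1L, 4))
  expect_identical(unname(s$fractions_pct), rep(25.0, 4))
  expect_identical(s$max_value, 0.5)
  # ties broken lexicographically by path
  y <- c(b2 = 0.3, a2 = 0.3, c2 = 0.1)
  expect_identical(names(summarize_sensitivities(y, top_k = 2)$top),
                   c("a2", "b2"))
  expect_error(summarize_sensitivities(numeric()), "empty")
})

test_that("functional parameter grouping", {
  expect_identical(group_parameter("Organism|Lumen|UpperIleum|pH"), "git_pH")
  expect_identical(
    group_parameter("Organism|Lumen|Stomach|Gastric emptying time"),
    "git_transit_times")
  expect_identical(
    group_parameter("Organism|SmallIntestine|Small intestinal transit time"),
    "git_transit_times")
  expect_identical(group_parameter("Organism|Lumen|LowerJejunum|Length"),
                   "git_geometry")
  expect_identical(group_parameter("Organism|Kidney|GFR (specific)"),
                   "volume_distribution_clearance")
  expect_identical(group_parameter("Organism|Haematocrit"),
                   "plasma_parameters")
  expect_identical(group_parameter("Organism|Muscle|Vf (lipids)"),
                   "volume_distribution_clearance")
  expect_identical(group_parameter("Organism|Brain|Volume"), "other")
  expect_identical(group_parameter("Organism|Brain|Volume",
                                   tox_organs = "brain"), "tox_organ")
  expect_error(group_parameter("NotAPath"), "malformed")
  # every enumerated path maps to exactly one group
  g <- group_parameter(parameter_paths(species_template("rat")))
  expect_true(all(g %in% c("git_transit_times", "git_pH", "git_geometry",
                           "plasma_parameters",
                           "volume_distribution_clearance", "tox_organ",
                           "other")))
})

test_that("external maximum-sensitivity tables load in both layouts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("parameter,max", "Organism|A|Volume,0.2", "Organism|B|pH,0.05"),
             f)
  m <- load_max_sensitivity_table(f)
  expect_identical(length(m), 2L)
  expect_equal(unname(m["Organism|A|Volume"]), 0.2)

  # wide layout with blanks: row-wise max over present cells
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("parameter,model1,model2", "Organism|A|Volume,0.1,0.5",
               "Organism|Gallbladder|pH,,0.3"), f2)
  m2 <- load_max_sensitivity_table(f2)
  expect_equal(unname(m2), c(0.5, 0.3))

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("parameter,max", "Organism|A|Volume,0.2",
               "Organism|A|Volume,0.3"), f3)
  expect_error(load_max_sensitivity_table(f3), "duplicated")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("parameter,max", "Organism|A|Volume,high"), f4)
  expect_error(load_max_sensitivity_table(f4), "non-numeric")
})

test_that("ensemble tables aggregate maxima over models and sites", {
  sp <- species_template("rabbit")
  m1 <- build_model(sp, test_compound(), admin_protocol("iv_bolus", 5))
  m2 <- build_model(species_template("mouse"), test_compound(),
                    admin_protocol("iv_bolus", 5))
  tab <- suppressMessages(ensemble_sensitivity(list(m1, m2)))
  n_active <- function(m) sum(vapply(m$parameter_paths, function(p)
    get_parameter(m$species, p) != 0, NA))
  expect_identical(nrow(tab$records), 3L * (n_active(m1) + n_active(m2)))
  agg <- tapply(tab$records$sens_rmsd, tab$records$parameter_path, max)
  expect_equal(unname(tab$max_by_parameter[names(agg)]),
               as.vector(agg))
  expect_true(all(diff(unname(tab$max_by_parameter)) <= 0))
  expect_error(ensemble_sensitivity(list()), "empty")
})
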