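test_that("checklist reflects routes, tox organs and data availability", {
  ctx_iv <- workflow_context("fox", "rabbit", 5, routes = "iv")
  cl_iv <- build_checklist(ctx_iv)
  req <- function(cl) vapply(cl$steps, `[[`, NA, "required")
  ids <- function(cl) vapply(cl$steps, `[[`, "", "id")
  git <- c("git_transit_times", "git_pH", "git_geometry")
  expect_false(any(req(cl_iv)[ids(cl_iv) %in% git]))

  ctx_po <- workflow_context("fox", "rabbit", 5, routes = c("iv", "oral"))
  cl_po <- build_checklist(ctx_po)
  expect_true(all(req(cl_po)[ids(cl_po) %in% git]))
  # non-GIT steps always required
  for (cl in list(cl_iv, cl_po))
    expect_true(all(req(cl)[ids(cl) %in% c("plasma_parameters",
                                           "volume_distribution_clearance")]))

  ctx_tox <- workflow_context("fox", "rabbit", 5, routes = "iv",
                              tox_organs = "brain")
  cl_tox <- build_checklist(ctx_tox)
  step <- cl_tox$steps[[match("tox_organ_brain", ids(cl_tox))]]
  expect_true(all(c("Organism|Brain|Volume",
                    "Organism|Brain|Specific blood flow rate",
                    "Organism|Brain|Vf (lipids)") %in% step$parameters))
  expect_error(workflow_context("fox", "rabbit", 5, tox_organs = "gallbladder"),
               "unknown tox organ")

  # species-specific data flips the step status
  ctx_dat <- workflow_context("fox", "rabbit", 5, routes = "oral",
    has_species_specific_data = c(git_pH = TRUE))
  cl_dat <- build_checklist(ctx_dat)
  expect_identical(cl_dat$steps[[match("git_pH", ids(cl_dat))]]$status,
                   "use species-specific value")
  expect_identical(cl_dat$steps[[match("git_geometry", ids(cl_dat))]]$status,
                   "literature / scaling / experiment")

  # determinism and monotonicity: identical contexts agree; adding a route
  # or a tox organ never removes a step
  expect_identical(build_checklist(ctx_po), cl_po)
  expect_true(all(ids(cl_iv) %in% ids(cl_po)))
  expect_true(all(ids(cl_iv) %in% ids(cl_tox)))
  expect_true(is.character(format(cl_po)))
  expect_true(length(checklist_as_list(cl_po)$steps) == length(cl_po$steps))
})

test_that("fold-error comparator: closed forms, threshold and symmetry", {
  tt <- seq(0, 100, by = 10)
  pred <- make_profile(tt, 100 * exp(-0.03 * tt))
  same <- make_profile(tt, pred$concentrations, role = "observed")
  v <- validate_model(pred, same)
  expect_equal(v$fold_error, 1)
  expect_identical(v$verdict, "pass")

  up <- make_profile(tt, pred$concentrations * 2.5, role = "observed")
  v2 <- validate_model(pred, up)
  expect_equal(v2$fold_error, 2.5, tolerance = 1e-12)
  expect_identical(v2$verdict, "fail")

  near <- make_profile(tt, pred$concentrations * 1.9, role = "observed")
  expect_identical(validate_model(pred, near)$verdict, "pass")
  down <- make_profile(tt, pred$concentrations / 1.9, role = "observed")
  expect_identical(validate_model(pred, down)$verdict, "pass")

  # symmetry of the geometric fold error
  obs <- make_profile(tt, pred$concentrations * runif(11, 0.5, 2),
                      role = "observed")
  expect_equal(validate_model(pred, obs)$fold_error,
               validate_model(obs, pred)$fold_error, tolerance = 1e-12)

  bad <- make_profile(tt, c(rep(1, 10), 0), role = "observed")
  expect_error(validate_model(pred, bad), "positive")
  expect_error(validate_model(pred, make_profile(numeric(), numeric())),
               "empty")
})

test_that("validation recovers the generating model and rejects a wrong one", {
  m <- test_model_iv()
  res <- simulate_pbtk(m)
  pred <- observe(res, observation_site("venous_plasma"))
  tt <- c(15, 30, 60, 120, 240, 480, 720, 1080, 1440)

  # observations from the same model, within-noise: should pass
  pass <- vapply(1:200, function(s) {
    obs <- generate_observations(m, tt, synthetic_config(seed = s,
                                                         noise_cv = 0.3))
    validate_model(pred, obs)$verdict == "pass"
  }, NA)
  expect_gte(mean(pass), 0.95)

  # observations from a model with 5x hepatic clearance: should fail
  wrong_cmp <- m$compound
  wrong_cmp$specific_hepatic_clearance <-
    5 * wrong_cmp$specific_hepatic_clearance
  m_wrong <- build_model(m$species, wrong_cmp, m$protocol)
  fail <- vapply(1:200, function(s) {
    obs <- generate_observations(m_wrong, tt, synthetic_config(seed = s,
                                                               noise_cv = 0.3))
    validate_model(pred, obs)$verdict == "fail"
  }, NA)
  expect_gte(mean(fail), 0.95)
})
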