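test_that("species files round-trip exactly and deterministically", {
  sp <- species_template("beagle")
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_species_file(sp, f1)
  write_species_file(sp, f2)
  expect_identical(readLines(f1), readLines(f2))

  sp2 <- read_species_file(f1)
  pp <- parameter_paths(sp)
  expect_identical(vapply(pp, function(p) get_parameter(sp2, p), 0),
                   vapply(pp, function(p) get_parameter(sp, p), 0))
  expect_identical(names(sp2$organs), names(sp$organs))

  fy <- withr::local_tempfile(fileext = ".yaml")
  write_species_file(sp, fy)
  spy <- read_species_file(fy)
  expect_equal(vapply(pp, function(p) get_parameter(spy, p), 0),
               vapply(pp, function(p) get_parameter(sp, p), 0),
               tolerance = 1e-14)
})

test_that("species file schema violations are rejected by path", {
  sp <- species_template("rat")
  f <- withr::local_tempfile(fileext = ".json")
  write_species_file(sp, f)
  doc <- jsonlite::fromJSON(f, simplifyDataFrame = FALSE)

  d1 <- doc; d1$haematocrit <- NULL
  f1 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(d1, auto_unbox = TRUE, digits = I(17)), f1)
  expect_error(read_species_file(f1), "haematocrit")

  d2 <- doc; d2$organs$liver$volume <- -1
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(d2, auto_unbox = TRUE, digits = I(17)), f2)
  expect_error(read_species_file(f2), "volume")

  d3 <- doc; d3$unexpected_key <- 1
  f3 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(d3, auto_unbox = TRUE, digits = I(17)), f3)
  expect_error(read_species_file(f3), "unknown key")
})

test_that("compound and protocol files round-trip", {
  cmp <- demo_compound_set()$theophylline_like
  f <- withr::local_tempfile(fileext = ".json")
  write_compound_file(cmp, f)
  expect_equal(read_compound_file(f), cmp)
  # unbounded solubility survives the trip
  cmp2 <- test_compound()
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_compound_file(cmp2, f2)
  expect_identical(read_compound_file(f2)$solubility, Inf)

  pr <- admin_protocol("oral", 12.5)
  f3 <- withr::local_tempfile(fileext = ".json")
  write_protocol_file(pr, f3)
  expect_equal(read_protocol_file(f3), pr)
})

test_that("packaged templates are valid and ordered by weight", {
  tpl <- species_template_set()
  expect_identical(names(tpl)[1], "mouse")
  expect_identical(names(tpl)[7], "human")
  bw <- vapply(tpl, `[[`, 0, "body_weight")
  expect_true(all(diff(bw) > 0))
  expect_equal(unname(bw[["human"]]), 73)
  for (sp in tpl) expect_silent(validate_species(sp))
})

test_that("allometric scaling hits the gut exponents exactly", {
  sp <- species_template("rabbit")
  lum_vol <- function(s) {
    r <- vapply(s$lumen, function(x) (x$proximal_radius + x$distal_radius) / 2, 0)
    l <- vapply(s$lumen, `[[`, 0, "length")
    f <- vapply(s$lumen, `[[`, 0, "fill_fraction")
    sum(pi * r^2 * l * f)
  }
  lum_surf <- function(s) {
    r <- vapply(s$lumen, function(x) (x$proximal_radius + x$distal_radius) / 2, 0)
    l <- vapply(s$lumen, `[[`, 0, "length")
    e <- vapply(s$lumen, `[[`, 0, "surface_enhancement_factor")
    sum(2 * pi * r * l * e)
  }
  s2 <- allometric_scale(sp, 2 * sp$body_weight)
  expect_equal(lum_vol(s2) / lum_vol(sp), 2^1.06, tolerance = 1e-12)
  expect_equal(lum_surf(s2) / lum_surf(sp), 2^0.76, tolerance = 1e-12)
  for (r in c(0.37, 5.1)) {
    sr <- allometric_scale(sp, r * sp$body_weight)
    expect_equal(lum_vol(sr) / lum_vol(sp), r^1.06, tolerance = 1e-12)
    expect_equal(lum_surf(sr) / lum_surf(sp), r^0.76, tolerance = 1e-12)
  }
})

test_that("scaled volumes close on the target weight; scaling idempotent", {
  sp <- species_template("minipig")
  tot_vol <- function(s) sum(vapply(s$organs, `[[`, 0, "volume")) +
    s$blood_volumes$venous + s$blood_volumes$arterial + s$blood_volumes$portal
  s2 <- allometric_scale(sp, 5.5)
  expect_equal(tot_vol(s2), 5.5, tolerance = 1e-9)
  # identity and exact idempotence
  same <- allometric_scale(sp, sp$body_weight)
  expect_identical(vapply(parameter_paths(sp),
                          function(p) get_parameter(same, p), 0),
                   vapply(parameter_paths(sp),
                          function(p) get_parameter(sp, p), 0))
  expect_identical(allometric_scale(s2, 5.5), s2)
  # intensive parameters untouched
  expect_identical(s2$haematocrit, sp$haematocrit)
  expect_identical(s2$lumen$upper_ileum$pH, sp$lumen$upper_ileum$pH)
  expect_identical(s2$specific_gfr, sp$specific_gfr)
  expect_error(allometric_scale(sp, -1), "> 0")
})
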