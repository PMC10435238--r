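test_that("temperature factor logistics evaluate to their printed midpoints", {
  expect_equal(temperature_factors(31.724, "AMPA")$rho_f, 10.273 / 2, tolerance = 1e-6)
  expect_equal(temperature_factors(30.668, "VGCC")$rho_f, 2.503 - 0.304 / 2,
               tolerance = 1e-6)
  expect_equal(temperature_factors(45.475, "CaMKII")$rho_b, 162.171 - 161.426 / 2,
               tolerance = 1e-6)
  # single-factor mechanisms return 1 for the missing side
  expect_identical(temperature_factors(35, "GABA")$rho_f, 1)
  expect_identical(temperature_factors(35, "CaMKII")$rho_f, 1)
  expect_error(temperature_factors(35, "nonsense"), "unknown mechanism")
})

test_that("temperature factors are positive and monotone over the fitted range", {
  grid <- seq(16, 44, by = 0.5)
  sign_of <- function(x) sign(diff(x))
  for (mech in c("AMPA", "NMDA", "GABA", "VGCC", "SK", "CaMKII", "CaN")) {
    f <- vapply(grid, function(T) temperature_factors(T, mech)$rho_f, numeric(1))
    b <- vapply(grid, function(T) temperature_factors(T, mech)$rho_b, numeric(1))
    expect_true(all(f > 0), info = mech)
    expect_true(all(b > 0), info = mech)
    # each printed logistic is monotone (a constant factor of 1 is allowed)
    expect_true(all(sign_of(f) == sign_of(f)[1]) || all(diff(f) == 0), info = mech)
    expect_true(all(sign_of(b) == sign_of(b)[1]) || all(diff(b) == 0), info = mech)
  }
})

test_that("effective factors are anchored at physiological temperature", {
  for (mech in c("NMDA", "CaMKII", "CaN")) {
    tf <- spinesim:::effective_factors(35, mech)
    expect_equal(tf$rho_f, 1, tolerance = 1e-12)
    expect_equal(tf$rho_b, 1, tolerance = 1e-12)
  }
  # GABA closing-time multiplier: ~0.51 at 35 C, smaller (slower closing) at 25 C
  g35 <- spinesim:::effective_factors(35, "GABA")$rho_b
  g25 <- spinesim:::effective_factors(25, "GABA")$rho_b
  expect_lt(g25, g35)
})

test_that("NMDAr subunit split follows the developmental ratio with exact rounding", {
  expect_identical(nmda_subunit_counts(25.102, noise = 0),
                   c(glun2a = 8, glun2b = 7))
  expect_identical(nmda_subunit_counts(1e6, noise = 0),
                   c(glun2a = 10, glun2b = 5))
  # stair-shaped, deterministic and near-complete at zero noise
  ages <- seq(1, 80, by = 0.25)
  counts <- t(vapply(ages, nmda_subunit_counts, numeric(2), noise = 0))
  expect_true(all(rowSums(counts) %in% 14:16))
  expect_identical(counts, t(vapply(ages, nmda_subunit_counts, numeric(2), noise = 0)))
  # piecewise constant: few distinct levels over a fine age grid
  expect_lt(length(unique(counts[, 1])), 10)
})

test_that("chloride reversal potential follows the fitted development curve", {
  expect_equal(erev_chloride(0.691), -92.649 + 243.515 / 2, tolerance = 1e-6)
  expect_equal(erev_chloride(1e5), -92.649, tolerance = 1e-3)
  expect_equal(erev_chloride(21), -59.5, tolerance = 0.1)
  ages <- seq(0, 90, by = 1)
  expect_true(all(diff(erev_chloride(ages)) < 0))
})

test_that("calcium-dependent NMDAr conductance matches its fitted logistic", {
  expect_equal(gamma_nmda(2.701), 33.949 + 58.388 / 2, tolerance = 1e-6)
  expect_equal(gamma_nmda(1.8), 90.79, tolerance = 0.01)
  expect_equal(gamma_nmda(100), 33.949, tolerance = 1e-3)
  cas <- seq(0.5, 5, by = 0.1)
  expect_true(all(diff(gamma_nmda(cas)) < 0))
})

test_that("distance factor and age-dependent BaP step behave as fitted", {
  expect_equal(phi_dist(230.3), 0.8, tolerance = 1e-6)
  expect_equal(phi_dist(0), 1.486, tolerance = 1e-3)
  expect_equal(phi_dist(1e5), 0.1, tolerance = 1e-6)
  expect_true(all(diff(phi_dist(seq(0, 500, 10))) < 0))
  # printed per-(pA ms) magnitudes, converted to the package's per-second units
  expect_equal(bap_age_step(16.482), 1e3 * 1.391e-4 / 2, tolerance = 1e-6)
  expect_equal(bap_age_step(0), 1e3 * 1.391e-4 / (1 + exp(-2.225)), tolerance = 1e-4)
  expect_equal(bap_age_step(1e5), 0, tolerance = 1e-9)
  expect_true(all(diff(vapply(seq(1, 60, 2), bap_age_step, numeric(1))) < 0))
})

test_that("conditions are validated and out-of-range temperatures warn", {
  expect_warning(experimental_conditions(temperature = 10), "validity range")
  expect_error(experimental_conditions(ca_o = 0))
  expect_error(experimental_conditions(age = -1))
  expect_error(experimental_conditions(deterministic_sources = "ampar"),
               "unknown deterministic source")
  cond <- experimental_conditions(deterministic_sources = "all")
  expect_true(all(c("ampa", "nmda", "vgcc", "release") %in%
                    cond$deterministic_sources))
})

test_that("parameter set resolves conditions and accepts overrides", {
  p <- synapse_params(the_cond)
  expect_s3_class(p, "synapse_params")
  expect_equal(p$gamma_nmda_ns, gamma_nmda(2.5) / 1e3)
  expect_equal(p$phi_dist, phi_dist(200))
  # neck conductance identity from the electrical constants
  expect_equal(p$g_neck, 7.85e-3 / (0.2 * 1e-2), tolerance = 0.01)
  p2 <- synapse_params(the_cond, overrides = list(gamma_sk = 0))
  expect_identical(p2$gamma_sk, 0)
  expect_error(synapse_params(the_cond, overrides = list(nope = 1)),
               "unknown parameter override")
})

test_that("condition files load with overrides applied", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "conditions:",
    "  age_days: 21",
    "  temperature_C: 30",
    "  ca_o_mM: 1.8",
    "  mg_o_mM: 1.2",
    "  evoked_ap: true",
    "parameters:",
    "  gamma_sk: 0"
  ), path)
  got <- read_conditions_yaml(path)
  expect_equal(got$conditions$age, 21)
  expect_equal(got$conditions$temperature, 30)
  expect_true(got$conditions$evoked_ap)
  expect_equal(got$params$gamma_sk, 0)
  expect_equal(got$params$erev_cl, erev_chloride(21))
})

test_that("scalar parameters round-trip through YAML", {
  skip_if_not_installed("yaml")
  p <- synapse_params(the_cond)
  scal <- p[vapply(p, function(x) is.numeric(x) && length(x) == 1, logical(1))]
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(scal, path, precision = 12)
  back <- yaml::read_yaml(path)
  expect_equal(back[names(scal)], scal, tolerance = 1e-9)
})
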