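test_that("growth context closes competing carbon uptakes, keeps exports open", {
  m <- build_toy_model()
  # add a second sugar exchange the context must close to uptake
  m <- add_to_model(
    m,
    metabolites = tibble::tibble(id = "xyl_e", name = "xylose", compartment = "e",
                                 formula = "C5H10O5", charge = NA_integer_),
    reactions = tibble::tibble(id = "EX_xyl", name = "xylose exchange",
                               lower_bound = -10, upper_bound = default_bound(),
                               kind = "exchange"),
    stoichiometry = tibble::tibble(reaction = "EX_xyl", metabolite = "xyl_e",
                                   coefficient = -1))
  ctx <- apply_growth_context(m, ngam = 2)
  rx <- ctx$reactions
  expect_equal(rx$lower_bound[rx$id == "EX_xyl"], 0)       # uptake closed
  expect_equal(rx$upper_bound[rx$id == "EX_xyl"], default_bound())
  expect_equal(rx$lower_bound[rx$id == "EX_glc"], -10)     # glucose untouched
  expect_equal(rx$lower_bound[rx$id == "EX_o2"], -default_bound())
  expect_equal(rx$lower_bound[rx$id == "EX_etoh"], 0)      # ethanol export open
  expect_equal(rx$upper_bound[rx$id == "EX_etoh"], default_bound())
  expect_equal(rx$lower_bound[rx$id == "ATPM"], 2)
  expect_error(apply_growth_context(m, maintenance = "NOPE"), "NOPE")
})

test_that("maintenance alone sets the glucose floor: ngam / ATP-per-glucose", {
  cfg <- toy_model_config()
  m <- apply_growth_context(build_toy_model(cfg), ngam = 0)
  m <- fix_flux(m, "BIOMASS", 0)
  expect_equal(predict_min_glucose(m)$q_glc_pred, 0, tolerance = 1e-9)

  m2 <- apply_growth_context(build_toy_model(cfg), ngam = 3.6)
  m2 <- fix_flux(m2, "BIOMASS", 0)
  expect_equal(predict_min_glucose(m2)$q_glc_pred, 3.6 / cfg$atp_per_glucose,
               tolerance = 1e-8)
})

test_that("titer conversion follows the stated arithmetic in both modes", {
  expect_equal(titer_to_specific_rate(0, molar_mass = 192.3), 0)
  expect_equal(
    titer_to_specific_rate(19.23, biomass_conc = 5, culture_time = 72,
                           molar_mass = 192.3),
    19.23 / (5 * 72 * 192.3), tolerance = 1e-12)
  expect_equal(
    titer_to_specific_rate(19.23, biomass_conc = 5, culture_time = 72,
                           molar_mass = 192.3),
    2.7778e-4, tolerance = 1e-4)
  # endpoint and growth-coupled agree when mu = 1 / culture_time
  expect_equal(
    titer_to_specific_rate(12, biomass_conc = 4, culture_time = 50,
                           molar_mass = 192.3),
    titer_to_specific_rate(12, biomass_conc = 4, mu = 1 / 50,
                           molar_mass = 192.3, mode = "growth_coupled"),
    tolerance = 1e-12)
  expect_error(titer_to_specific_rate(10, molar_mass = 192.3), "biomass_conc")
})

test_that("strain constraints carry provenance and honour the tolerance width", {
  ext <- extended_toy()
  meas <- tibble::tibble(strain_id = "s1", mu = 0.2, q_co2 = 8,
                         biomass_conc = 5, total_carotenoids = 10,
                         frac_beta_carotene = 0.8, frac_lycopene = 0.15,
                         frac_phytoene = 0.05, ionone_titer = 6,
                         culture_time = 72, glucose_uptake_exp = NA_real_)
  ctx <- constrain_strain(ext, meas, tol_frac = 0.05)
  cons <- ctx$constraints
  expect_true(all(nzchar(cons$source)))
  expect_true(all(cons$lower <= cons$upper))
  centred <- cons[cons$upper > 0, ]
  mid <- (centred$lower + centred$upper) / 2
  expect_equal((centred$upper - centred$lower) / 2, 0.05 * mid, tolerance = 1e-9)
  # growth and CO2 from the measurement itself
  expect_match(cons$source[cons$reaction == "BIOMASS"], "measurement: mu")
  expect_match(cons$source[cons$reaction == "EX_co2"], "measurement: q_co2")
  # carotenoid sinks get growth-coupled converted rates
  bc <- cons[cons$reaction == "SK_bcarotene", ]
  expect_equal((bc$lower + bc$upper) / 2,
               yield_to_specific_rate(10 * 0.8, 0.2, molar_mass("C40H56")),
               tolerance = 1e-9)
  io <- cons[cons$reaction == "EX_bionone", ]
  expect_equal((io$lower + io$upper) / 2,
               titer_to_specific_rate(6, 5, 72, molar_mass = molar_mass("C13H20O")),
               tolerance = 1e-9)
})

test_that("constraint construction is idempotent", {
  ext <- extended_toy()
  meas <- tibble::tibble(strain_id = "s1", mu = 0.2, q_co2 = 8,
                         biomass_conc = 5, total_carotenoids = 4,
                         frac_beta_carotene = 1, frac_lycopene = 0,
                         frac_phytoene = 0, ionone_titer = 2,
                         culture_time = 72, glucose_uptake_exp = NA_real_)
  once <- constrain_strain(ext, meas)
  twice <- constrain_strain(once$model, meas)
  expect_equal(twice$model$reactions, once$model$reactions)
  expect_equal(twice$constraints, once$constraints)
})

test_that("a measurement with no products constrains only growth and CO2", {
  ext <- extended_toy()
  meas <- tibble::tibble(strain_id = "s0", mu = 0.25, q_co2 = 9,
                         total_carotenoids = 0, ionone_titer = NA_real_)
  ctx <- constrain_strain(ext, meas)
  expect_setequal(ctx$constraints$reaction, c("BIOMASS", "EX_co2", "EX_bionone"))
  io <- ctx$constraints[ctx$constraints$reaction == "EX_bionone", ]
  expect_equal(c(io$lower, io$upper), c(0, 0))
})

test_that("missing rates fall back to flagged literature defaults", {
  ext <- extended_toy()
  meas <- tibble::tibble(strain_id = "fx", total_carotenoids = 4,
                         biomass_conc = NA_real_, mu = NA_real_,
                         q_co2 = NA_real_, ionone_titer = NA_real_)
  ctx <- constrain_strain(ext, meas, use_default_rates = TRUE)
  expect_match(ctx$constraints$source[ctx$constraints$reaction == "BIOMASS"],
               "default: literature")
  expect_error(constrain_strain(ext, meas, use_default_rates = FALSE), "lacks mu")
})

test_that("internally consistent synthetic measurements stay feasible at tol >= noise", {
  ext <- extended_toy(toy_model_config(fpp_capacity = 3, glucose_uptake_max = 20))
  truth <- list(mu = 0.15, ngam = 1, sink_bcarotene = 0.05,
                cleavage_double = 0.03)
  for (seed in 1:5) {
    meas <- simulate_measurements(ext, truth, n_strains = 1,
                                  noise_cv = 0.03, seed = seed)
    ctx <- constrain_strain(ext, meas[1, ], tol_frac = 0.15)
    sol <- optimize_flux(ctx$model, "EX_glc", "max")
    expect_equal(sol$status, "optimal", info = sprintf("seed %d", seed))
  }
})

test_that("measurement tables round-trip and violations are reported", {
  meas <- tibble::tibble(strain_id = c("a", "b"), mu = c(0.2, NA),
                         q_co2 = c(8, NA), biomass_conc = c(5, NA),
                         total_carotenoids = c(4, 3),
                         frac_beta_carotene = c(0.7, NA),
                         frac_lycopene = c(0.2, NA), frac_phytoene = c(0.1, NA),
                         ionone_titer = c(2, NA), culture_time = c(72, 72),
                         glucose_uptake_exp = c(10, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(meas, path)
  back <- read_measurements(path)
  expect_equal(back$mu, meas$mu)
  expect_equal(back$ionone_titer, meas$ionone_titer)
  expect_identical(nrow(validate_measurements(back)), 0L)

  bad <- meas
  bad$frac_beta_carotene[1] <- 0.9   # fractions now sum to 1.2
  expect_true(any(validate_measurements(bad)$rule == "profile_fractions"))
  bad2 <- meas
  bad2$biomass_conc[1] <- NA         # titer no longer convertible
  expect_true(any(validate_measurements(bad2)$rule == "titer_convertibility"))
  bad3 <- meas
  bad3$mu[1] <- -0.1
  expect_true(any(validate_measurements(bad3)$rule == "nonnegative"))
})
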