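test_that("minimal glucose prediction matches the closed form and is monotone", {
  cfg <- toy_model_config()
  base <- apply_growth_context(build_toy_model(cfg), ngam = 1.5)
  mu0 <- 0.3
  m <- fix_flux(base, "BIOMASS", mu0)
  got <- predict_min_glucose(m)
  expect_equal(got$q_glc_pred, toy_min_glucose(cfg, mu0, 1.5), tolerance = 1e-7)
  expect_true(got$solution$parsimonious)

  # a forced product drain strictly increases the requirement
  ext <- extended_toy(cfg, ngam = 1.5)
  ext <- fix_flux(ext, "BIOMASS", mu0)
  ext <- set_bounds(ext, "SK_bcarotene", lower = 0.02, upper = 0.02)
  expect_gt(predict_min_glucose(ext)$q_glc_pred, got$q_glc_pred)

  # nothing to pay for: mu = 0, ngam = 0, no products
  idle <- apply_growth_context(build_toy_model(cfg), ngam = 0)
  idle <- fix_flux(idle, "BIOMASS", 0)
  expect_equal(predict_min_glucose(idle)$q_glc_pred, 0, tolerance = 1e-9)
})

test_that("yield duality: min-glucose and max-growth agree on maintenance-free toys", {
  for (cfg in list(toy_model_config(),
                   toy_model_config(atp_per_glucose = 10, carbon_per_biomass = 30,
                                    gam_atp = 45))) {
    m <- apply_growth_context(build_toy_model(cfg), ngam = 0)
    mu0 <- 0.25
    q <- predict_min_glucose(fix_flux(m, "BIOMASS", mu0))$q_glc_pred
    m2 <- set_bounds(m, "EX_glc", lower = -q, upper = -q)
    mu_back <- optimize_flux(m2, "BIOMASS", "max")$objective_value
    expect_equal(mu_back / q, mu0 / q, tolerance = 1e-6)
    expect_equal(mu_back, mu0, tolerance = 1e-6)
  }
})

test_that("relative error is the plain percent deviation", {
  expect_equal(relative_error(10, 10), 0)
  expect_equal(relative_error(11, 10), 10)
  expect_equal(relative_error(9, 10), 10)
  errs <- relative_error(c(10.2, 9.7, 10.33), c(10, 10, 10))
  expect_equal(mean(errs), mean(c(2, 3, 3.3)), tolerance = 1e-9)
  expect_error(relative_error(1, 0), "positive")
})

test_that("carbon recovery is 100% when every output is measured", {
  ext <- extended_toy(toy_model_config(include_fermentation_branch = FALSE))
  meas <- simulate_measurements(ext, list(mu = 0.2, ngam = 1,
                                          sink_bcarotene = 0.01,
                                          cleavage_double = 0.004),
                                n_strains = 1, noise_cv = 0, seed = 3)
  ctx <- constrain_strain(ext, meas[1, ], tol_frac = 0)
  pred <- predict_min_glucose(ctx$model)
  expect_equal(carbon_recovery(pred$solution, meas[1, ], ctx$model), 100,
               tolerance = 1e-4)
})

test_that("carbon recovery is 50% when the unmeasured route carries half the carbon", {
  # mu = 0, ATPM = 12: forced FERM 1.5 gives 3 ethanol (6 C) + 3 CO2 + 3 ATP,
  # leaving 9 ATP to respiration (0.5 glucose, 3 CO2). Of 12 C consumed,
  # 6 C leaves as CO2 (measured) and 6 C as ethanol (unmeasured) -> 50%.
  cfg <- toy_model_config()
  m <- apply_growth_context(build_toy_model(cfg), ngam = 12)
  m <- fix_flux(m, "BIOMASS", 0)
  m <- set_bounds(m, "EX_glc", lower = -2, upper = -2)
  m <- set_bounds(m, "ATPM", lower = 12, upper = 12)
  m <- fix_flux(m, "FERM", 1.5)
  sol <- optimize_flux(m, "BIOMASS", "max")
  expect_equal(sol$status, "optimal")
  meas <- tibble::tibble(strain_id = "half", glucose_uptake_exp = 2)
  expect_equal(carbon_recovery(sol, meas, m, measured_reactions = character(0)),
               50, tolerance = 1e-6)
  # counting the ethanol exchange closes the balance
  expect_equal(carbon_recovery(sol, meas, m, measured_reactions = "EX_etoh"),
               100, tolerance = 1e-6)
  expect_error(carbon_recovery(sol, tibble::tibble(strain_id = "x"), m),
               "glucose_uptake_exp")
})

test_that("double-cleavage-only counterfactual gives the 1:2 stoichiometric optimum", {
  sc <- recovery_scenario(f = 1, c_pot = 0.5)
  meas <- simulate_measurements(sc$model,
                                list(mu = sc$mu, ngam = sc$ngam, sink_bcarotene = 0,
                                     cleavage_double = sc$c_true, q_glc = sc$q_glc),
                                n_strains = 1, noise_cv = 0, seed = 1)
  cf <- counterfactual_max_ionone(sc$model, meas[1, ], tol_frac = 0)
  expect_equal(cf$q_ionone_max, 2 * cf$divertible_carbon / 40, tolerance = 1e-5)
  expect_equal(cf$c14_ionone_ratio, 0.5, tolerance = 1e-6)
  expect_equal(cf$c14_ionone_ratio_range[["min"]], 0.5, tolerance = 1e-6)
  expect_equal(cf$c14_ionone_ratio_range[["max"]], 0.5, tolerance = 1e-6)
  # the strain cleaved everything available: departure 0
  expect_equal(cf$departure_pct, 0, tolerance = 0.1)
})

test_that("departure recovers the injected cleavage fraction exactly at zero noise", {
  for (f in c(0.3, 0.7)) {
    sc <- recovery_scenario(f = f, c_pot = 1)
    meas <- simulate_measurements(sc$model,
                                  list(mu = sc$mu, ngam = sc$ngam, sink_bcarotene = 0,
                                       cleavage_double = sc$c_true, q_glc = sc$q_glc),
                                  n_strains = 1, noise_cv = 0, seed = 1)
    rep <- interrogate_strains(sc$model, meas, tol_frac = 0)
    expect_equal(rep$departure_pct, (1 - f) * 100, tolerance = 0.05)
    expect_equal(rep$divertible_carbon, 40 * sc$c_pot, tolerance = 1e-3)
  }
})

test_that("raising the measured titer never increases the departure", {
  sc <- recovery_scenario(f = 0.5, c_pot = 1)
  meas <- simulate_measurements(sc$model,
                                list(mu = sc$mu, ngam = sc$ngam, sink_bcarotene = 0,
                                     cleavage_double = sc$c_true, q_glc = sc$q_glc),
                                n_strains = 1, noise_cv = 0, seed = 1)
  base_titer <- meas$ionone_titer[1]
  deps <- vapply(c(0.6, 0.8, 1, 1.2, 1.4), function(scale) {
    m <- meas[1, ]
    m$ionone_titer <- base_titer * scale
    counterfactual_max_ionone(sc$model, m, tol_frac = 0)$departure_pct
  }, numeric(1))
  expect_true(all(diff(deps) <= 1e-6))
})

test_that("cleavage carbon is conserved through CCD1 in the counterfactual optimum", {
  sc <- recovery_scenario(f = 0.4, c_pot = 0.8)
  meas <- simulate_measurements(sc$model,
                                list(mu = sc$mu, ngam = sc$ngam, sink_bcarotene = 0,
                                     cleavage_double = sc$c_true, q_glc = sc$q_glc),
                                n_strains = 1, noise_cv = 0, seed = 2)
  cf <- counterfactual_max_ionone(sc$model, meas[1, ], tol_frac = 0)
  fx <- cf$solution$fluxes
  carbon_in <- 40 * fx[["CCD1_DOUBLE"]]
  carbon_out <- 13 * fx[["EX_bionone"]] + 14 * fx[["SK_c14dial"]]
  expect_equal(carbon_in, carbon_out, tolerance = 1e-8)
})

test_that("single-site cleavage halves the attainable ionone per carotene", {
  cfg <- toy_model_config(fpp_capacity = 3, glucose_uptake_max = 20,
                          include_fermentation_branch = FALSE)
  ext <- extended_toy(cfg, ngam = 1, allow_single_cleavage = TRUE)
  # knock out the double cleavage: only the single-site route remains
  ext_single <- set_bounds(ext, "CCD1_DOUBLE", lower = 0, upper = 0)
  truth <- list(mu = 0.1, ngam = 1, sink_bcarotene = 0, cleavage_double = 0,
                cleavage_single = 0.5)
  meas <- simulate_measurements(ext_single, truth, n_strains = 1,
                                noise_cv = 0, seed = 1)
  cf <- counterfactual_max_ionone(ext_single, meas[1, ], tol_frac = 0)
  expect_equal(cf$q_ionone_max, cf$divertible_carbon / 40, tolerance = 1e-4)
  expect_equal(cf$c14_ionone_ratio, 0, tolerance = 1e-8)
  expect_equal(cf$departure_pct, 0, tolerance = 0.1)
})

test_that("measurements beyond the model optimum are flagged, not crashed", {
  ext <- extended_toy(toy_model_config(fpp_capacity = 0.1))
  meas <- tibble::tibble(strain_id = "impossible", mu = 0.2, q_co2 = 8,
                         biomass_conc = 5, total_carotenoids = 500,
                         frac_beta_carotene = 1, frac_lycopene = 0,
                         frac_phytoene = 0, ionone_titer = NA_real_,
                         culture_time = 72, glucose_uptake_exp = NA_real_)
  cf <- counterfactual_max_ionone(ext, meas, tol_frac = 0.05)
  expect_true(is.na(cf$departure_pct) || grepl("exceeds|infeasible", cf$note))
})
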