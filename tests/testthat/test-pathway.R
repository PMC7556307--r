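test_that("every pathway reaction is elementally balanced; boundaries are skipped", {
  for (single in c(FALSE, TRUE)) {
    spec <- build_pathway_spec(allow_single_cleavage = single)
    rep <- balance_report(spec, elements = c("C", "H", "O", "P"))
    expect_false(any(rep$status == "imbalanced"),
                 info = paste(rep$reaction[rep$status == "imbalanced"], collapse = ","))
    expect_setequal(rep$status[grepl("^(SK_|EX_)", rep$reaction)], "skipped")
    expect_setequal(rep$status[!grepl("^(SK_|EX_)", rep$reaction)], "balanced")
  }
})

test_that("double cleavage carbon bookkeeping: 40 = 13 + 13 + 14", {
  spec <- build_pathway_spec()
  f <- function(id) spec$metabolites$formula[spec$metabolites$id == id]
  expect_identical(carbon_count(f("bcarotene_c")), 40L)
  expect_identical(carbon_count(f("bionone_c")), 13L)
  expect_identical(carbon_count(f("c14dial_c")), 14L)
  expect_identical(2L * carbon_count(f("bionone_c")) + carbon_count(f("c14dial_c")),
                   carbon_count(f("bcarotene_c")))
  # the full C/H/O balance pins the dialdehyde formula to C14H16O2
  expect_identical(f("c14dial_c"), "C14H16O2")
  sto <- spec$stoichiometry[spec$stoichiometry$reaction == "CCD1_DOUBLE", ]
  expect_equal(sort(sto$coefficient), c(-2, -1, 1, 2))
})

test_that("the lumped desaturation moves 8 H onto 4 FAD", {
  spec <- build_pathway_spec()
  imb <- check_elemental_balance(spec, "CRTI")
  expect_identical(attr(imb, "status"), "balanced")
  expect_length(imb, 0L)
  # phytoene C40H64 -> lycopene C40H56: 8 H onto 4 FADH2
  f <- function(id) parse_formula(spec$metabolites$formula[spec$metabolites$id == id])
  expect_equal(f("phytoene_c")[["H"]] - f("lycopene_c")[["H"]], 8)
})

test_that("a corrupted cleavage stoichiometry is caught with the right imbalance", {
  spec <- build_pathway_spec()
  i <- which(spec$stoichiometry$reaction == "CCD1_DOUBLE" &
             spec$stoichiometry$metabolite == "o2_c")
  spec$stoichiometry$coefficient[i] <- -1   # 1 O2 instead of 2
  imb <- check_elemental_balance(spec, "CCD1_DOUBLE")
  expect_identical(attr(imb, "status"), "imbalanced")
  expect_equal(imb[["O"]], 2)
  # boundary reactions are exempt
  skipped <- check_elemental_balance(spec, "EX_bionone")
  expect_identical(attr(skipped, "status"), "skipped")
})

test_that("molar masses match the formula sums used for unit conversion", {
  spec <- build_pathway_spec()
  expect_equal(spec$molar_masses[["bionone_c"]], 192.30, tolerance = 1e-4)
  expect_equal(spec$molar_masses[["bcarotene_c"]], 536.89, tolerance = 1e-4)
  expect_equal(spec$molar_masses[["bcarotene_c"]],
               molar_mass("C40H56"), tolerance = 1e-12)
})

test_that("extension adds exactly the pathway, refuses collisions and bad hosts", {
  host <- build_toy_model()
  spec <- build_pathway_spec(allow_single_cleavage = TRUE)
  ext <- extend_model(host, spec)
  expect_identical(nrow(validate_model(ext)), 0L)
  expect_setequal(setdiff(ext$reactions$id, host$reactions$id), spec$reactions$id)
  expect_setequal(setdiff(ext$metabolites$id, host$metabolites$id),
                  spec$metabolites$id[spec$metabolites$role == "pathway"])
  # added sinks all start closed
  added_sinks <- spec$reactions$id[spec$reactions$kind %in% c("sink", "exchange")]
  sk <- ext$reactions[ext$reactions$id %in% added_sinks, ]
  expect_true(all(sk$lower_bound == 0 & sk$upper_bound == 0))

  expect_error(extend_model(ext, spec), "collision")
  crippled <- host
  keep <- crippled$metabolites$id != "fpp_c"
  crippled$metabolites <- crippled$metabolites[keep, ]
  crippled$stoichiometry <-
    crippled$stoichiometry[crippled$stoichiometry$metabolite != "fpp_c", ]
  expect_error(extend_model(crippled, spec), "fpp_c")
})

test_that("carotene production is capped by the host FPP supply", {
  cfg <- toy_model_config(fpp_capacity = 0.5)
  ext <- extended_toy(cfg, ngam = 0)
  ext <- set_bounds(ext, "SK_bcarotene", lower = 0, upper = default_bound())
  sol <- optimize_flux(ext, "SK_bcarotene", "max")
  # 2 GGPP (hence 2 FPP) per carotene: max = fpp_capacity / 2
  expect_equal(sol$objective_value, 0.25, tolerance = 1e-8)

  none <- extended_toy(toy_model_config(fpp_capacity = 0), ngam = 0)
  none <- set_bounds(none, "SK_bcarotene", lower = 0, upper = default_bound())
  expect_equal(optimize_flux(none, "SK_bcarotene", "max")$objective_value, 0,
               tolerance = 1e-10)
})

test_that("forced double cleavage yields exactly 2 ionone and 1 C14 per carotene", {
  ext <- extended_toy(ngam = 0)
  for (f in c(0.02, 0.1)) {
    m <- fix_flux(ext, "CCD1_DOUBLE", f)
    m <- set_bounds(m, "EX_bionone", lower = 0, upper = default_bound())
    m <- set_bounds(m, "SK_c14dial", lower = 0, upper = default_bound())
    sol <- pfba(m, "EX_bionone", "max")
    expect_equal(sol$fluxes[["EX_bionone"]], 2 * f, tolerance = 1e-8)
    expect_equal(sol$fluxes[["SK_c14dial"]], f, tolerance = 1e-8)
  }
})

test_that("pathway carbon entering at GGPP equals carbon leaving via sinks", {
  ext <- extended_toy(allow_single_cleavage = TRUE, ngam = 0)
  ext <- fix_flux(ext, "CCD1_DOUBLE", 0.01)
  ext <- fix_flux(ext, "CCD1_SINGLE", 0.02)
  ext <- set_bounds(ext, "SK_bcarotene", lower = 0.03, upper = 0.03)
  ext <- set_bounds(ext, "SK_phytoene", lower = 0.005, upper = 0.005)
  for (r in c("EX_bionone", "SK_c14dial", "SK_c27apo", "SK_lycopene")) {
    ext <- set_bounds(ext, r, lower = 0, upper = default_bound())
  }
  sol <- pfba(ext, "EX_bionone", "max")
  expect_equal(sol$status, "optimal")
  fx <- sol$fluxes
  carbon_in <- 20 * fx[["CRTE"]]    # GGPP is C20
  carbon_out <- 40 * (fx[["SK_phytoene"]] + fx[["SK_lycopene"]] + fx[["SK_bcarotene"]]) +
    13 * fx[["EX_bionone"]] + 14 * fx[["SK_c14dial"]] + 27 * fx[["SK_c27apo"]]
  expect_equal(carbon_in, carbon_out, tolerance = 1e-7)
})

test_that("yield conversion is mu * Y / M with linear behaviour", {
  expect_equal(yield_to_specific_rate(0, 0.35, 536.89), 0)
  expect_equal(yield_to_specific_rate(32, 0.35, 536.87), 0.35 * 32 / 536.87,
               tolerance = 1e-12)
  expect_equal(yield_to_specific_rate(32, 0.35, 536.87), 0.020862, tolerance = 1e-4)
  expect_equal(yield_to_specific_rate(10, 0.4, 100),
               2 * yield_to_specific_rate(10, 0.2, 100))
  expect_error(yield_to_specific_rate(1, 0.1, 0), "positive")
})

test_that("a pathway spec serializes to a readable JSON fragment", {
  spec <- build_pathway_spec(allow_single_cleavage = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_pathway_spec(spec, path)
  frag <- jsonlite::read_json(path)
  expect_equal(length(frag$reactions), nrow(spec$reactions))
  ids <- vapply(frag$reactions, `[[`, "", "id")
  expect_setequal(ids, spec$reactions$id)
  ccd <- frag$reactions[[which(ids == "CCD1_DOUBLE")]]
  expect_equal(ccd$metabolites$bionone_c, 2)
  expect_true(frag$options$allow_single_cleavage)
})
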