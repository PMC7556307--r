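test_that("a hand-built COBRA-style JSON model loads with bounds intact", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "id": "mini", "description": "three-reaction fixture",
    "metabolites": [
      {"id": "glc_e", "compartment": "e", "formula": "C6H12O6"},
      {"id": "glc_c", "compartment": "c", "formula": "C6H12O6"}
    ],
    "reactions": [
      {"id": "EX_glc", "metabolites": {"glc_e": -1},
       "lower_bound": -7.5, "upper_bound": 1000, "objective_coefficient": 0},
      {"id": "GLCt", "metabolites": {"glc_e": -1, "glc_c": 1},
       "lower_bound": 0, "upper_bound": 1000},
      {"id": "DM_glc", "metabolites": {"glc_c": -1},
       "lower_bound": 0, "upper_bound": 3, "objective_coefficient": 1}
    ]
  }', path)
  m <- read_model(path)
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$reactions), 3L)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_glc"], -7.5)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "DM_glc"], 3)
  expect_equal(m$objective, "DM_glc")
  # kind inference from COBRA id conventions
  expect_equal(m$reactions$kind[m$reactions$id == "EX_glc"], "exchange")
  expect_equal(m$reactions$kind[m$reactions$id == "DM_glc"], "sink")
  expect_equal(
    m$metabolites$formula[m$metabolites$id == "glc_e"], "C6H12O6")
})

test_that("models round-trip structurally through JSON and SBML", {
  configs <- list(
    toy_model_config(),
    toy_model_config(atp_per_glucose = 12, carbon_per_biomass = 35,
                     fpp_capacity = 2, include_fermentation_branch = FALSE),
    toy_model_config(gam_atp = 30, glucose_uptake_max = 5)
  )
  for (cfg in configs) {
    m <- build_toy_model(cfg)
    m <- extend_model(m, build_pathway_spec(allow_single_cleavage = TRUE))
    for (fmt in c("json", "sbml")) {
      path <- withr::local_tempfile(fileext = if (fmt == "json") ".json" else ".xml")
      write_model(m, path, format = fmt)
      back <- read_model(path)
      expect_equal(back$metabolites, m$metabolites, ignore_attr = TRUE)
      expect_equal(back$reactions, m$reactions, ignore_attr = TRUE)
      expect_equal(
        dplyr::arrange(back$stoichiometry, reaction, metabolite),
        dplyr::arrange(m$stoichiometry, reaction, metabolite),
        ignore_attr = TRUE)
      expect_equal(back$objective, m$objective)
    }
  }
})

test_that("format is detected from extension and content", {
  m <- build_toy_model()
  pj <- withr::local_tempfile(fileext = ".json")
  px <- withr::local_tempfile(fileext = ".sbml")
  write_model(m, pj)
  write_model(m, px)
  expect_equal(read_model(pj)$objective, "BIOMASS")
  expect_equal(read_model(px)$objective, "BIOMASS")
})

test_that("an SBML reaction naming an undeclared species is rejected", {
  path <- withr::local_tempfile(fileext = ".xml")
  m <- build_toy_model()
  write_model(m, path, format = "sbml")
  txt <- readLines(path)
  txt <- gsub('species="glc_c"', 'species="ghost_c"', txt, fixed = TRUE)
  writeLines(txt, path)
  expect_error(read_model(path), "ghost_c")
})

test_that("duplicate ids and missing objectives are descriptive errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": [{"id": "a"}, {"id": "a"}],
               "reactions": [{"id": "r", "metabolites": {"a": -1},
                              "lower_bound": 0, "upper_bound": 1}]}', path)
  expect_error(read_model(path), "duplicate metabolite")
  writeLines('{"metabolites": [{"id": "a"}],
               "reactions": [{"id": "r", "metabolites": {"a": -1},
                              "lower_bound": 0, "upper_bound": 1}]}', path)
  expect_error(read_model(path), "objective")
})

test_that("writing an empty model is refused", {
  m <- build_toy_model()
  m$reactions <- m$reactions[0, ]
  m$stoichiometry <- m$stoichiometry[0, ]
  m$objective <- "BIOMASS"
  class(m) <- "metabolic_model"
  expect_error(write_model(m, tempfile(fileext = ".json")), "no reactions")
})

test_that("validate_model reports constructed defects and passes clean models", {
  m <- build_toy_model()
  expect_identical(nrow(validate_model(m)), 0L)

  # internal reaction losing one carbon
  bad <- m
  i <- which(bad$stoichiometry$reaction == "PREC" &
             bad$stoichiometry$metabolite == "cmol_c")
  bad$stoichiometry$coefficient[i] <- 5
  rep <- validate_model(bad)
  expect_true(any(rep$rule == "carbon_balance" & rep$id == "PREC"))
  expect_match(rep$detail[rep$id == "PREC"], "-1")

  # exchange touching two metabolites
  bad2 <- m
  bad2$stoichiometry <- dplyr::bind_rows(
    bad2$stoichiometry,
    tibble::tibble(reaction = "EX_glc", metabolite = "glc_c", coefficient = 1))
  rep2 <- validate_model(bad2)
  expect_true(any(rep2$rule == "boundary_arity" & rep2$id == "EX_glc"))

  # crossed bounds
  bad3 <- m
  bad3$reactions$lower_bound[1] <- 5
  bad3$reactions$upper_bound[1] <- -5
  expect_true(any(validate_model(bad3)$rule == "bounds"))
})

test_that("structural invariants are enforced at construction", {
  expect_error(
    metabolic_model(
      metabolites = tibble::tibble(id = "a"),
      reactions = tibble::tibble(id = "r"),
      stoichiometry = tibble::tibble(reaction = "r", metabolite = "ghost",
                                     coefficient = -1),
      objective = "r"),
    "undeclared metabolite")
  expect_error(
    metabolic_model(
      metabolites = tibble::tibble(id = "a"),
      reactions = tibble::tibble(id = "r"),
      stoichiometry = tibble::tibble(reaction = "r", metabolite = "a",
                                     coefficient = -1),
      objective = "nope"),
    "objective")
})
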