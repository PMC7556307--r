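# Synthetic data: toy host networks with closed-form optima, simulated
# strain measurements, and the packaged table of published shake-flask values.

#' Configuration for the toy host model
#'
#' The toy network is a deliberately small stand-in for a genome-scale
#' yeast reconstruction: lumped glycolysis/respiration with a stated ATP
#' stoichiometry, a biomass pseudo-reaction with stated carbon content, a
#' capacity-bounded FPP/IPP (mevalonate) supply, a FAD redox cycle, and an
#' optional fermentation branch. Every optimum used as a test oracle has a
#' closed form documented in the emitted model description.
#'
#' @param atp_per_glucose mol ATP produced per mol glucose respired
#'   (default 18, a lumped P/O-style yield).
#' @param carbon_per_biomass mmol carbon per gDCW of biomass (default 40,
#'   i.e. ~48% carbon by weight).
#' @param gam_atp Growth-associated ATP demand, mmol ATP/gDCW (default 60).
#' @param fpp_capacity Upper bound on the FPP-supply flux, mmol/gDCW/h
#'   (default 0.5); caps the whole carotenoid pathway.
#' @param include_fermentation_branch Include a glucose -> 2 ethanol +
#'   2 CO2 + 2 ATP branch (default `TRUE`).
#' @param glucose_uptake_max Structural cap on glucose uptake,
#'   mmol/gDCW/h (default 10).
#' @param seed Integer seed recorded in the config (the builder itself is
#'   deterministic; the seed matters for downstream simulation).
#' @return A `toy_model_config` list.
#' @export
toy_model_config <- function(atp_per_glucose = 18, carbon_per_biomass = 40,
                             gam_atp = 60, fpp_capacity = 0.5,
                             include_fermentation_branch = TRUE,
                             glucose_uptake_max = 10, seed = 1L) {
  stopifnot(atp_per_glucose > 0, carbon_per_biomass > 0, gam_atp >= 0,
            fpp_capacity >= 0, glucose_uptake_max > 0)
  structure(list(atp_per_glucose = atp_per_glucose,
                 carbon_per_biomass = carbon_per_biomass,
                 gam_atp = gam_atp, fpp_capacity = fpp_capacity,
                 include_fermentation_branch = include_fermentation_branch,
                 glucose_uptake_max = glucose_uptake_max,
                 seed = as.integer(seed)),
            class = "toy_model_config")
}

#' Build the toy host model
#'
#' Constructs the small aerobic-glucose host network described in
#' [toy_model_config()]. Useful closed forms (for a growth rate mu with
#' maintenance `ngam` and no product drains):
#'
#' * minimal glucose uptake
#'   `q_glc = cb * mu / 6 + (gam * mu + ngam) / a`
#'   with `cb = carbon_per_biomass`, `gam = gam_atp`, `a = atp_per_glucose`;
#' * the matching CO2 evolution is
#'   `q_co2 = 6 * (gam * mu + ngam) / a` (respiration only).
#'
#' The FPP/IPP supply reactions cost glucose carbon (3 glucose per FPP, 1
#' per IPP, venting 3 and 1 CO2 respectively) and ATP (6 and 2), so
#' carotenoid production raises the minimal glucose uptake accordingly.
#'
#' @param config A [toy_model_config()].
#' @return A [metabolic_model()] that passes [validate_model()] with an
#'   empty report; the biomass pseudo-reaction is the objective.
#' @examples
#' m <- build_toy_model()
#' optimize_flux(m)  # max growth at 10 mmol/gDCW/h glucose
#' @export
build_toy_model <- function(config = toy_model_config()) {
  stopifnot(inherits(config, "toy_model_config"))
  a <- config$atp_per_glucose
  cb <- config$carbon_per_biomass
  gam <- config$gam_atp

  mets <- tibble::tribble(
    ~id,       ~name,                  ~compartment, ~formula,
    "glc_e",   "glucose (extracellular)", "e", "C6H12O6",
    "glc_c",   "glucose",                 "c", "C6H12O6",
    "o2_e",    "oxygen (extracellular)",  "e", "O2",
    "o2_c",    "oxygen",                  "c", "O2",
    "co2_e",   "CO2 (extracellular)",     "e", "CO2",
    "co2_c",   "CO2",                     "c", "CO2",
    "etoh_e",  "ethanol (extracellular)", "e", "C2H6O",
    "etoh_c",  "ethanol",                 "c", "C2H6O",
    "cmol_c",  "biomass precursor (1 C)", "c", "CH2O",
    "atp_c",   "ATP equivalent (phosphoryl-bond currency)", "c", "HPO3",
    "fpp_c",   "farnesyl diphosphate",    "c", "C15H28O7P2",
    "ipp_c",   "isopentenyl diphosphate", "c", "C5H12O7P2",
    "ppi_c",   "diphosphate",             "c", "H4O7P2",
    "fad_c",   "FAD",                     "c", "C27H33N9O15P2",
    "fadh2_c", "FADH2",                   "c", "C27H35N9O15P2"
  )
  mets$charge <- NA_integer_

  rx <- list(
    list(id = "EX_glc", name = "glucose exchange", kind = "exchange",
         lb = -config$glucose_uptake_max, ub = default_bound(),
         sto = c(glc_e = -1)),
    list(id = "GLCt", name = "glucose transport", kind = "internal",
         lb = 0, ub = default_bound(), sto = c(glc_e = -1, glc_c = 1)),
    list(id = "EX_o2", name = "oxygen exchange", kind = "exchange",
         lb = -default_bound(), ub = default_bound(), sto = c(o2_e = -1)),
    list(id = "O2t", name = "oxygen transport", kind = "internal",
         lb = 0, ub = default_bound(), sto = c(o2_e = -1, o2_c = 1)),
    list(id = "EX_co2", name = "CO2 exchange", kind = "exchange",
         lb = 0, ub = default_bound(), sto = c(co2_e = -1)),
    list(id = "CO2t", name = "CO2 export", kind = "internal",
         lb = 0, ub = default_bound(), sto = c(co2_c = -1, co2_e = 1)),
    list(id = "RESP", name = "lumped glycolysis + respiration", kind = "internal",
         lb = 0, ub = default_bound(),
         sto = c(glc_c = -1, o2_c = -6, co2_c = 6, atp_c = a)),
    list(id = "PREC", name = "biomass precursor synthesis", kind = "internal",
         lb = 0, ub = default_bound(), sto = c(glc_c = -1, cmol_c = 6)),
    list(id = "BIOMASS", name = "biomass pseudo-reaction", kind = "biomass",
         lb = 0, ub = default_bound(),
         sto = stats::setNames(c(-cb, -gam), c("cmol_c", "atp_c"))),
    list(id = "ATPM", name = "non-growth ATP maintenance", kind = "sink",
         lb = 0, ub = default_bound(), sto = c(atp_c = -1)),
    list(id = "FPP_SYN", name = "lumped MVA pathway to FPP", kind = "internal",
         lb = 0, ub = config$fpp_capacity,
         sto = c(glc_c = -3, atp_c = -6, fpp_c = 1, co2_c = 3)),
    list(id = "IPP_SYN", name = "lumped MVA pathway to IPP", kind = "internal",
         lb = 0, ub = default_bound(),
         sto = c(glc_c = -1, atp_c = -2, ipp_c = 1, co2_c = 1)),
    list(id = "SK_ppi", name = "diphosphate hydrolysis drain", kind = "sink",
         lb = 0, ub = default_bound(), sto = c(ppi_c = -1)),
    list(id = "FADH2_OX", name = "FADH2 reoxidation", kind = "internal",
         lb = 0, ub = default_bound(),
         sto = c(fadh2_c = -1, o2_c = -0.5, fad_c = 1))
  )
  if (config$include_fermentation_branch) {
    rx <- append(rx, list(
      list(id = "FERM", name = "fermentation to ethanol", kind = "internal",
           lb = 0, ub = default_bound(),
           sto = c(glc_c = -1, etoh_c = 2, co2_c = 2, atp_c = 2)),
      list(id = "ETOHt", name = "ethanol export", kind = "internal",
           lb = 0, ub = default_bound(), sto = c(etoh_c = -1, etoh_e = 1)),
      list(id = "EX_etoh", name = "ethanol exchange", kind = "exchange",
           lb = 0, ub = default_bound(), sto = c(etoh_e = -1))
    ))
  } else {
    mets <- mets[!mets$id %in% c("etoh_e", "etoh_c"), ]
  }

  reactions <- purrr::map_dfr(rx, function(r) {
    tibble::tibble(id = r$id, name = r$name, lower_bound = r$lb,
                   upper_bound = r$ub, kind = r$kind)
  })
  stoich <- purrr::map_dfr(rx, function(r) {
    tibble::tibble(reaction = r$id, metabolite = names(r$sto),
                   coefficient = unname(r$sto))
  })
  desc <- sprintf(paste(
    "Toy aerobic-glucose host model.",
    "Closed forms: min glucose at growth mu with maintenance ngam =",
    "%g*mu/6 + (%g*mu + ngam)/%g; biomass yield on glucose =",
    "mu/q_glc; FPP supply capped at %g mmol/gDCW/h.", collapse = " "),
    cb, gam, a, config$fpp_capacity)
  m <- metabolic_model(mets[, c("id", "name", "compartment", "formula", "charge")],
                       reactions, stoich, objective = "BIOMASS",
                       description = desc)
  attr(m, "config") <- config
  m
}

#' Closed-form minimal glucose uptake of the toy model
#'
#' The analytic counterpart of [predict_min_glucose()] on the toy network:
#' carbon for biomass plus ATP for growth and maintenance, all via
#' respiration (the ATP-optimal route).
#'
#' @param config A [toy_model_config()].
#' @param mu Growth rate, 1/h.
#' @param ngam Maintenance ATP drain, mmol/gDCW/h.
#' @return Glucose uptake in mmol/gDCW/h.
#' @export
toy_min_glucose <- function(config, mu, ngam = 0) {
  config$carbon_per_biomass * mu / 6 +
    (config$gam_atp * mu + ngam) / config$atp_per_glucose
}

#' Simulate shake-flask strain measurements from a known flux state
#'
#' Takes a "true" strain state — growth rate, carotenoid accumulation
#' fluxes and CCD1 cleavage fluxes on the pathway-extended toy model —
#' solves for the implied minimal glucose uptake and CO2 evolution, then
#' converts the true fluxes to measurement units (mg/gDCW via molar masses,
#' mg/L titers via the assumed biomass concentration and culture time) and
#' applies multiplicative log-normal noise with the given coefficient of
#' variation. Measurements are positive and HPLC/OD errors are roughly
#' proportional, which is what the log-normal emulates. The unnoised truth
#' is attached as `attr(x, "truth")`.
#'
#' @param model Pathway-extended toy model (from [extend_model()] on
#'   [build_toy_model()]).
#' @param true_state Named list: `mu` (1/h), `ngam` (mmol ATP/gDCW/h),
#'   `sink_phytoene`, `sink_lycopene`, `sink_bcarotene` (mmol/gDCW/h),
#'   `cleavage_double`, `cleavage_single` (mmol/gDCW/h),
#'   `biomass_conc` (gDCW/L), `culture_time` (h). An optional `q_glc`
#'   (mmol/gDCW/h) pins glucose uptake *above* the minimum the other
#'   fluxes require; the surplus leaves through overflow routes
#'   (fermentation/extra respiration with ATP dissipation), emulating a
#'   strain whose carbon flows through products the measurement set does
#'   not see.
#' @param n_strains Number of replicate synthetic strains to emit.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = exact measurements).
#' @param seed Integer seed for reproducibility.
#' @return Tibble of strain measurements in the same layout
#'   [read_measurements()] expects, with the ground-truth state and fluxes
#'   in `attr(, "truth")`.
#' @export
simulate_measurements <- function(model, true_state, n_strains = 1L,
                                  noise_cv = 0.05, seed = 1L) {
  stopifnot(inherits(model, "metabolic_model"), noise_cv >= 0)
  st <- utils::modifyList(
    list(mu = 0.3, ngam = 1, sink_phytoene = 0, sink_lycopene = 0,
         sink_bcarotene = 0.01, cleavage_double = 0, cleavage_single = 0,
         biomass_conc = 5, culture_time = 72),
    true_state)

  # realize the exact flux state: fix the state's fluxes, minimize glucose
  m <- model
  m <- set_bounds(m, "ATPM", lower = st$ngam, upper = st$ngam)
  m <- fix_flux(m, "BIOMASS", st$mu)
  for (nm in c("phytoene", "lycopene", "bcarotene")) {
    sk <- paste0("SK_", nm)
    m <- set_bounds(m, sk, lower = 0, upper = default_bound())
    m <- fix_flux(m, sk, st[[paste0("sink_", nm)]])
  }
  m <- fix_flux(m, "CCD1_DOUBLE", st$cleavage_double)
  if ("CCD1_SINGLE" %in% m$reactions$id) {
    m <- fix_flux(m, "CCD1_SINGLE", st$cleavage_single)
    if ("SK_c27apo" %in% m$reactions$id) {
      m <- set_bounds(m, "SK_c27apo", lower = 0, upper = default_bound())
      m <- fix_flux(m, "SK_c27apo", st$cleavage_single)
    }
  } else if (st$cleavage_single > 0) {
    stop("true_state requests single cleavage but the model has no CCD1_SINGLE",
         call. = FALSE)
  }
  ionone_flux <- 2 * st$cleavage_double + st$cleavage_single
  m <- set_bounds(m, "EX_bionone", lower = 0, upper = default_bound())
  m <- set_bounds(m, "SK_c14dial", lower = 0, upper = default_bound())
  if (!is.null(st$q_glc)) {
    # pin uptake; let maintenance float upward so surplus ATP can dissipate
    m <- set_bounds(m, "EX_glc", lower = -st$q_glc, upper = -st$q_glc)
    m <- set_bounds(m, "ATPM", lower = st$ngam, upper = default_bound())
  }
  sol <- pfba(m, "EX_glc", "max")   # least-negative = minimal uptake
  if (sol$status != "optimal") {
    stop("true_state is infeasible in the supplied model", call. = FALSE)
  }
  fx <- sol$fluxes
  q_glc <- -fx[["EX_glc"]]
  q_co2 <- fx[["EX_co2"]]

  masses <- stats::setNames(
    vapply(c("phytoene_c", "lycopene_c", "bcarotene_c", "bionone_c"),
           function(id) molar_mass(
             model$metabolites$formula[match(id, model$metabolites$id)]),
           numeric(1)),
    c("phytoene", "lycopene", "bcarotene", "bionone"))

  # exact (unnoised) measurement values
  yields <- vapply(c("phytoene", "lycopene", "bcarotene"), function(nm) {
    st[[paste0("sink_", nm)]] * masses[[nm]] / st$mu   # mg/gDCW
  }, numeric(1))
  total <- sum(yields)
  titer <- ionone_flux * masses[["bionone"]] * st$biomass_conc * st$culture_time

  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  jitter <- function(x, n) {
    if (noise_cv == 0 || x == 0) rep(x, n)
    else x * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  n <- as.integer(n_strains)
  out <- tibble::tibble(
    strain_id = sprintf("sim%02d", seq_len(n)),
    mu = jitter(st$mu, n),
    q_co2 = jitter(q_co2, n),
    biomass_conc = jitter(st$biomass_conc, n),
    total_carotenoids = jitter(total, n),
    frac_beta_carotene = if (total > 0) yields[["bcarotene"]] / total else 0,
    frac_lycopene = if (total > 0) yields[["lycopene"]] / total else 0,
    frac_phytoene = if (total > 0) yields[["phytoene"]] / total else 0,
    ionone_titer = jitter(titer, n),
    culture_time = st$culture_time,
    glucose_uptake_exp = jitter(q_glc, n)
  )
  attr(out, "truth") <- c(st, list(q_glc = unname(q_glc), q_co2 = unname(q_co2),
                                   total_carotenoids = unname(total),
                                   ionone_titer = unname(titer),
                                   ionone_flux = unname(ionone_flux),
                                   fluxes = fx))
  out
}

#' Printed shake-flask values for the engineered strains
#'
#' The packaged table of per-strain values as published: total carotenoid
#' yields for the beta-carotene strains, residual carotenoid yields and
#' beta-ionone titers for the cleavage strains, all after 72 h shake-flask
#' cultivation. Growth rates, CO2 evolution rates and biomass
#' concentrations were not published per strain and are left `NA` — they are
#' *inputs* the interrogation requires, not values to invent.
#'
#' @return Tibble with columns `strain_id`, `parent`, `total_carotenoids`
#'   (mg/gDCW; for the `iono` strains this is the residual carotenoid
#'   content), `ionone_titer` (mg/L or `NA`), `culture_time` (h), plus the
#'   empty measurement columns (`mu`, `q_co2`, `biomass_conc`,
#'   fractions, `glucose_uptake_exp`). The attribute `locus_range` holds
#'   the published min/max total-carotenoid yield across integration loci
#'   (2.6-4.1 mg/gDCW).
#' @export
strain_fixtures <- function() {
  path <- system.file("extdata", "strain_fixtures.csv", package = "ionoflux",
                      mustWork = TRUE)
  out <- read_measurements(path)
  attr(out, "locus_range") <- c(min = 2.6, max = 4.1)
  out
}

#' Fold changes between the packaged strain fixtures
#'
#' Recomputes, from the packaged published values, the comparative fold
#' statements quoted between strains (yield fold increases, titer fold
#' increases, and the percentage spread across integration loci), alongside
#' the rounded published figure each comparison was reported as.
#'
#' @return Tibble with columns `comparison`, `computed`, `reported`.
#' @export
fixture_fold_changes <- function() {
  fx <- strain_fixtures()
  v <- stats::setNames(fx$total_carotenoids, fx$strain_id)
  t <- stats::setNames(fx$ionone_titer, fx$strain_id)
  lr <- attr(fx, "locus_range")
  tibble::tribble(
    ~comparison,                              ~computed,                        ~reported,
    "carotenoids bCar3 / parental bCar2.1",   v[["bCar3"]] / v[["bCar2.1"]],    3,
    "carotenoids bCar5 / bCar1.1",            v[["bCar5"]] / v[["bCar1.1"]],    8,
    "carotenoids bCar5 / bCar4.b",            v[["bCar5"]] / v[["bCar4.b"]],    2,
    "ionone titer iono5.1 / iono2.1",         t[["iono5.1"]] / t[["iono2.1"]],  10,
    "ionone titer iono5.3 / iono2.1",         t[["iono5.3"]] / t[["iono2.1"]],  19,
    "% spread across loci (max vs min)",      (lr[["max"]] - lr[["min"]]) / lr[["min"]] * 100, 60
  )
}
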