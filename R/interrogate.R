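# Model interrogation: the four derived analyses run on the contextualized,
# strain-constrained model — minimal glucose prediction, carbon recovery,
# counterfactual maximum beta-ionone yield with cleavage departure, and the
# C14-dialdehyde : beta-ionone molar ratio.

#' Predict the minimal specific glucose uptake
#'
#' With growth, CO2 evolution and product accumulation pinned to their
#' measured values, the smallest glucose uptake able to support them is
#' found by maximizing the (negative) glucose exchange flux; this amounts
#' to optimizing the biomass yield on glucose. The reported flux vector is
#' the parsimonious (minimum total flux) optimum.
#'
#' @param model Strain-constrained model (from [constrain_strain()]).
#' @param glucose_exchange Glucose exchange reaction id.
#' @return List: `q_glc_pred` (uptake magnitude, mmol/gDCW/h) and
#'   `solution` (a `flux_solution`). Infeasible constraint sets yield
#'   `status = "infeasible"` with `q_glc_pred = NA` — reported as such,
#'   distinct from solver failure.
#' @export
predict_min_glucose <- function(model, glucose_exchange = "EX_glc") {
  if (!glucose_exchange %in% model$reactions$id) {
    stop(sprintf("no reaction '%s' in model", glucose_exchange), call. = FALSE)
  }
  sol <- pfba(model, glucose_exchange, "max")  # least-negative exchange flux
  if (sol$status != "optimal") {
    return(list(q_glc_pred = NA_real_, solution = sol))
  }
  list(q_glc_pred = -sol$objective_value, solution = sol)
}

#' Relative error of a prediction, in percent
#'
#' @param pred Predicted value.
#' @param exp Experimental value (> 0).
#' @return `|pred - exp| / exp * 100`.
#' @export
relative_error <- function(pred, exp) {
  if (any(exp <= 0)) stop("experimental value must be positive", call. = FALSE)
  abs(pred - exp) / exp * 100
}

# carbon content of one unit of biomass flux, from the biomass reaction's
# own composition (net mmol C consumed per gDCW formed)
biomass_carbon_content <- function(model, biomass_reaction = NULL) {
  biomass_reaction <- biomass_reaction %||% model$objective
  rows <- model$stoichiometry[model$stoichiometry$reaction == biomass_reaction, ]
  if (nrow(rows) == 0L) {
    stop(sprintf("biomass reaction '%s' has no stoichiometry", biomass_reaction),
         call. = FALSE)
  }
  formulas <- model$metabolites$formula[match(rows$metabolite, model$metabolites$id)]
  if (anyNA(formulas)) {
    stop("biomass carbon content not derivable: participating metabolites lack formulas; pass biomass_carbon explicitly",
         call. = FALSE)
  }
  cc <- vapply(formulas, carbon_count, integer(1))
  -sum(rows$coefficient * cc)
}

#' Degree of carbon recovery, in percent
#'
#' Fraction of the experimentally consumed glucose carbon accounted for by
#' the measured outputs in the flux solution: biomass carbon (growth rate
#' times the biomass reaction's carbon content), CO2, and the
#' sink/exchange fluxes of the measured products. A closure below ~80%
#' means too much carbon leaves through unmeasured routes for yield
#' conclusions to be meaningful.
#'
#' @param solution A `flux_solution` for the constrained model.
#' @param measurement Measurement row providing `glucose_uptake_exp`
#'   (mmol/gDCW/h); the denominator deliberately uses the experimental
#'   uptake, not the model's own prediction (which would close trivially).
#' @param model The model the solution belongs to.
#' @param measured_reactions Ids of the product sink/exchange reactions
#'   counted as measured; defaults to the carotenoid sinks and the
#'   beta-ionone exchange present in the model.
#' @param biomass_reaction Biomass reaction id (default: model objective).
#' @param co2_exchange CO2 exchange id.
#' @param biomass_carbon Override for the biomass carbon content
#'   (mmol C/gDCW); by default derived from the biomass reaction.
#' @return Carbon recovery in percent.
#' @export
carbon_recovery <- function(solution, measurement, model,
                            measured_reactions = NULL,
                            biomass_reaction = NULL, co2_exchange = "EX_co2",
                            biomass_carbon = NULL) {
  stopifnot(inherits(solution, "flux_solution"))
  if (solution$status != "optimal") {
    stop("carbon recovery needs an optimal flux solution", call. = FALSE)
  }
  m <- if (is.data.frame(measurement)) as.list(measurement) else as.list(measurement)
  q_glc_exp <- m$glucose_uptake_exp
  if (is.null(q_glc_exp) || is.na(q_glc_exp)) {
    stop("measurement lacks glucose_uptake_exp; supply the experimental glucose uptake rate",
         call. = FALSE)
  }
  stopifnot(q_glc_exp > 0)
  biomass_reaction <- biomass_reaction %||% model$objective
  cb <- biomass_carbon %||% biomass_carbon_content(model, biomass_reaction)

  measured_reactions <- measured_reactions %||% intersect(
    c("SK_phytoene", "SK_lycopene", "SK_bcarotene", "SK_c14dial", "SK_c27apo",
      "EX_bionone"), model$reactions$id)
  fx <- solution$fluxes
  prod_carbon <- sum(vapply(measured_reactions, function(r) {
    met <- model$stoichiometry$metabolite[model$stoichiometry$reaction == r][1]
    f <- model$metabolites$formula[match(met, model$metabolites$id)]
    abs(fx[[r]]) * carbon_count(f)
  }, numeric(1)))

  mu <- fx[[biomass_reaction]]
  q_co2 <- fx[[co2_exchange]]
  100 * (mu * cb + q_co2 + prod_carbon) / (6 * q_glc_exp)
}

#' Counterfactual maximum beta-ionone yield and cleavage departure
#'
#' Quantifies how far the strain's observed beta-ionone production falls
#' short of what its own carbon supply would permit, in three LP steps:
#'
#' 1. With beta-ionone production forced to zero and the remaining strain
#'    constraints kept, maximize the beta-carotene accumulation sink —
#'    the theoretical carotene supply `q_car_theoretical`.
#' 2. The carbon gap `divertible_carbon = 40 * (q_car_theoretical -
#'    q_car_exp)` (mmol C/gDCW/h) is what could have fed cleavage on top
#'    of the observed accumulation.
#' 3. Re-fix the carotene sink at its measured value, cap the total carbon
#'    entering the CCD1 cleavage reactions at `divertible_carbon`
#'    (40 C per beta-carotene cleaved, regardless of cleavage mode), and
#'    maximize the beta-ionone exchange; the parsimonious optimum gives
#'    `q_ionone_max`.
#'
#' The departure is the percent shortfall
#' `(1 - q_ionone_exp / q_ionone_max) * 100`, and the C14:ionone molar
#' ratio is the C14-dialdehyde flux over the ionone flux in that optimum
#' (0.5 when only double cleavage exists). Because FBA optima are
#' degenerate, the ratio's attainable range at the fixed optimum is also
#' reported (two auxiliary LPs on the C14 flux).
#'
#' @param model Pathway-extended, growth-contextualized (but not yet
#'   strain-constrained) model.
#' @param measurement One measurement row with carotenoid and ionone data.
#' @param tol_frac Constraint interval half-width (see [constrain_strain()]).
#' @param ionone_mode Titer coupling mode, see [titer_to_specific_rate()].
#' @param use_default_rates Passed to [constrain_strain()].
#' @return List: `q_car_theoretical`, `q_car_exp`, `divertible_carbon`,
#'   `q_ionone_max`, `q_ionone_exp`, `departure_pct`, `c14_ionone_ratio`,
#'   `c14_ionone_ratio_range`, `solution` (step-3 parsimonious optimum),
#'   `note` (diagnostics for degenerate cases).
#' @export
counterfactual_max_ionone <- function(model, measurement, tol_frac = 0.05,
                                      ionone_mode = c("endpoint", "growth_coupled"),
                                      use_default_rates = TRUE) {
  ionone_mode <- match.arg(ionone_mode)
  ctx <- constrain_strain(model, measurement, tol_frac = tol_frac,
                          ionone_mode = ionone_mode,
                          use_default_rates = use_default_rates)
  constrained <- ctx$model
  bc_row <- ctx$constraints[ctx$constraints$reaction == "SK_bcarotene", ]
  q_car_exp <- if (nrow(bc_row) == 1L) mean(c(bc_row$lower, bc_row$upper)) else 0
  io_row <- ctx$constraints[grepl("ionone", ctx$constraints$source), ]
  q_ionone_exp <- if (nrow(io_row) == 1L) mean(c(io_row$lower, io_row$upper)) else 0

  # step 1: no ionone requirement, carotene sink free -> theoretical max
  m1 <- constrained
  m1 <- set_bounds(m1, "EX_bionone", lower = 0, upper = 0)
  m1 <- set_bounds(m1, "SK_bcarotene", lower = 0, upper = default_bound())
  sol1 <- optimize_flux(m1, "SK_bcarotene", "max")
  if (sol1$status != "optimal") {
    return(list(q_car_theoretical = NA_real_, q_car_exp = q_car_exp,
                divertible_carbon = NA_real_, q_ionone_max = NA_real_,
                q_ionone_exp = q_ionone_exp, departure_pct = NA_real_,
                c14_ionone_ratio = NA_real_, c14_ionone_ratio_range = c(NA_real_, NA_real_),
                solution = sol1,
                note = sprintf("theoretical carotene maximization %s", sol1$status)))
  }
  q_car_th <- sol1$objective_value
  carotene_carbon <- 40
  divertible <- carotene_carbon * (q_car_th - q_car_exp)
  note <- NULL
  if (divertible < 0) {
    note <- "measurement exceeds model optimum: observed carotene accumulation above theoretical max"
    divertible <- 0
  }

  # step 3: carotene sink back at measured value, cleavage carbon capped,
  # maximize ionone. The cap is a pseudo-metabolite balance: each cleavage
  # produces 40 cap units, drained by CAP_DRAIN with ub = divertible.
  m3 <- constrained
  m3 <- set_bounds(m3, "SK_bcarotene",
                   lower = min(bc_row$lower %||% 0, q_car_exp),
                   upper = max(bc_row$upper %||% 0, q_car_exp))
  m3 <- set_bounds(m3, "EX_bionone", lower = 0, upper = default_bound())
  cleavage <- intersect(c("CCD1_DOUBLE", "CCD1_SINGLE"), m3$reactions$id)
  cap_sto <- dplyr::bind_rows(
    tibble::tibble(reaction = cleavage, metabolite = "ccd1_cap_c",
                   coefficient = carotene_carbon),
    tibble::tibble(reaction = "CAP_DRAIN", metabolite = "ccd1_cap_c",
                   coefficient = -1))
  m3 <- add_to_model(
    m3,
    metabolites = tibble::tibble(id = "ccd1_cap_c", name = "CCD1 substrate-carbon cap",
                                 compartment = "c", formula = NA_character_,
                                 charge = NA_integer_),
    reactions = tibble::tibble(id = "CAP_DRAIN", name = "cleavage carbon cap drain",
                               lower_bound = 0, upper_bound = divertible,
                               kind = "sink"),
    stoichiometry = cap_sto)
  sol3 <- pfba(m3, "EX_bionone", "max")
  if (sol3$status != "optimal") {
    return(list(q_car_theoretical = q_car_th, q_car_exp = q_car_exp,
                divertible_carbon = divertible, q_ionone_max = NA_real_,
                q_ionone_exp = q_ionone_exp, departure_pct = NA_real_,
                c14_ionone_ratio = NA_real_, c14_ionone_ratio_range = c(NA_real_, NA_real_),
                solution = sol3,
                note = paste(c(note, sprintf("ionone maximization %s", sol3$status)),
                             collapse = "; ")))
  }
  q_ionone_max <- sol3$objective_value
  c14_flux <- if ("SK_c14dial" %in% names(sol3$fluxes)) sol3$fluxes[["SK_c14dial"]] else 0

  if (q_ionone_max > 1e-12) {
    departure <- (1 - q_ionone_exp / q_ionone_max) * 100
    ratio <- c14_flux / q_ionone_max
    # degeneracy breadth of the ratio at the fixed ionone optimum
    m4 <- fix_flux(m3, "EX_bionone", q_ionone_max, tol_frac = 0)
    rng <- vapply(c("min", "max"), function(d) {
      s <- optimize_flux(m4, "SK_c14dial", d)
      if (s$status == "optimal") s$objective_value / q_ionone_max else NA_real_
    }, numeric(1))
  } else {
    departure <- NA_real_
    ratio <- NA_real_
    rng <- c(min = NA_real_, max = NA_real_)
    note <- paste(c(note, "q_ionone_max = 0: departure undefined"), collapse = "; ")
  }

  list(q_car_theoretical = q_car_th, q_car_exp = q_car_exp,
       divertible_carbon = divertible, q_ionone_max = q_ionone_max,
       q_ionone_exp = q_ionone_exp, departure_pct = departure,
       c14_ionone_ratio = ratio, c14_ionone_ratio_range = rng,
       solution = sol3, note = note %||% "")
}

#' Interrogate a set of strains
#'
#' The full per-strain pipeline on a pathway-extended,
#' growth-contextualized model: constrain with the strain's measurements,
#' predict minimal glucose uptake (with relative error against the
#' experimental uptake when available), compute carbon recovery, and run
#' the counterfactual maximum-ionone analysis.
#'
#' @param model Pathway-extended, growth-contextualized model.
#' @param measurements Measurement tibble, one row per strain.
#' @param tol_frac Constraint interval half-width.
#' @param ionone_mode Titer coupling mode.
#' @param use_default_rates Use literature defaults for missing mu/q_co2.
#' @param glucose_exchange Glucose exchange reaction id.
#' @return Tibble, one row per strain: `strain_id`, `q_glc_pred`,
#'   `q_glc_exp`, `rel_error_pct`, `carbon_recovery_pct`,
#'   `q_car_theoretical`, `q_car_exp`, `divertible_carbon`,
#'   `q_ionone_max`, `q_ionone_exp`, `departure_pct`, `c14_ionone_ratio`,
#'   `ratio_min`, `ratio_max`, `parsimonious`, `tolerance`, `note`.
#' @export
interrogate_strains <- function(model, measurements, tol_frac = 0.05,
                                ionone_mode = c("endpoint", "growth_coupled"),
                                use_default_rates = TRUE,
                                glucose_exchange = "EX_glc") {
  ionone_mode <- match.arg(ionone_mode)
  purrr::map_dfr(seq_len(nrow(measurements)), function(i) {
    m <- measurements[i, ]
    ctx <- constrain_strain(model, m, tol_frac = tol_frac,
                            ionone_mode = ionone_mode,
                            use_default_rates = use_default_rates)
    pred <- predict_min_glucose(ctx$model, glucose_exchange)
    q_glc_exp <- if (is.na(m$glucose_uptake_exp %||% NA)) NA_real_ else m$glucose_uptake_exp
    rel_err <- if (!is.na(q_glc_exp) && !is.na(pred$q_glc_pred)) {
      relative_error(pred$q_glc_pred, q_glc_exp)
    } else NA_real_
    recov <- if (!is.na(q_glc_exp) && pred$solution$status == "optimal") {
      carbon_recovery(pred$solution, m, ctx$model)
    } else NA_real_
    cf <- counterfactual_max_ionone(model, m, tol_frac = tol_frac,
                                    ionone_mode = ionone_mode,
                                    use_default_rates = use_default_rates)
    tibble::tibble(
      strain_id = m$strain_id,
      q_glc_pred = pred$q_glc_pred, q_glc_exp = q_glc_exp,
      rel_error_pct = rel_err, carbon_recovery_pct = recov,
      q_car_theoretical = cf$q_car_theoretical, q_car_exp = cf$q_car_exp,
      divertible_carbon = cf$divertible_carbon,
      q_ionone_max = cf$q_ionone_max, q_ionone_exp = cf$q_ionone_exp,
      departure_pct = cf$departure_pct, c14_ionone_ratio = cf$c14_ionone_ratio,
      ratio_min = cf$c14_ionone_ratio_range[[1]],
      ratio_max = cf$c14_ionone_ratio_range[[2]],
      parsimonious = isTRUE(cf$solution$parsimonious),
      tolerance = cf$solution$tolerance %||% NA_real_,
      note = cf$note %||% ""
    )
  })
}
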