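# Contextualization: culture conditions and per-strain shake-flask
# measurements become flux constraints on the (pathway-extended) model.

measurement_columns <- function() {
  c("strain_id", "mu", "q_co2", "biomass_conc", "total_carotenoids",
    "frac_beta_carotene", "frac_lycopene", "frac_phytoene",
    "ionone_titer", "culture_time", "glucose_uptake_exp")
}

#' Read a strain-measurement table
#'
#' Comma-delimited, one row per strain, header with the canonical field
#' names: `strain_id`, `mu` (1/h), `q_co2` (mmol/gDCW/h), `biomass_conc`
#' (gDCW/L), `total_carotenoids` (mg/gDCW), `frac_beta_carotene`,
#' `frac_lycopene`, `frac_phytoene` (fractions of total), `ionone_titer`
#' (mg/L), `culture_time` (h), `glucose_uptake_exp` (mmol/gDCW/h,
#' literature-derived). Missing optional fields are empty.
#'
#' @param path Path to the CSV file.
#' @return Tibble of measurements (extra columns such as `parent` are kept).
#' @export
read_measurements <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("strain_id", "total_carotenoids"), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("measurement table lacks required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in setdiff(measurement_columns(), names(df))) df[[col]] <- NA_real_
  num_cols <- setdiff(measurement_columns(), "strain_id")
  df[num_cols] <- lapply(df[num_cols], as.numeric)
  df
}

#' Write a strain-measurement table
#'
#' @param measurements Measurement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  readr::write_csv(measurements, path, na = "")
  invisible(path)
}

#' Validate strain measurements
#'
#' Reports violations of the measurement invariants: negative values,
#' carotenoid profile fractions summing above 1, and ionone titers without
#' the biomass concentration and culture time needed to convert them to a
#' specific rate.
#'
#' @param measurements Measurement tibble (as from [read_measurements()]).
#' @return Tibble with columns `strain_id`, `rule`, `detail`; zero rows
#'   means valid.
#' @export
validate_measurements <- function(measurements) {
  viol <- list()
  num_cols <- setdiff(intersect(measurement_columns(), names(measurements)),
                      "strain_id")
  for (i in seq_len(nrow(measurements))) {
    row <- measurements[i, ]
    sid <- row$strain_id
    neg <- num_cols[!is.na(row[num_cols]) & row[num_cols] < 0]
    if (length(neg) > 0L) {
      viol <- c(viol, list(tibble::tibble(
        strain_id = sid, rule = "nonnegative",
        detail = sprintf("negative value in %s", paste(neg, collapse = ", ")))))
    }
    fr <- c(row$frac_beta_carotene, row$frac_lycopene, row$frac_phytoene)
    if (!all(is.na(fr)) && sum(fr, na.rm = TRUE) > 1 + 1e-9) {
      viol <- c(viol, list(tibble::tibble(
        strain_id = sid, rule = "profile_fractions",
        detail = sprintf("profile fractions sum to %.6g > 1", sum(fr, na.rm = TRUE)))))
    }
    if (!is.na(row$ionone_titer) && row$ionone_titer > 0 &&
        (is.na(row$biomass_conc) || is.na(row$culture_time))) {
      viol <- c(viol, list(tibble::tibble(
        strain_id = sid, rule = "titer_convertibility",
        detail = "ionone_titer present but biomass_conc/culture_time missing")))
    }
  }
  if (length(viol) == 0L) {
    tibble::tibble(strain_id = character(), rule = character(), detail = character())
  } else dplyr::bind_rows(viol)
}

#' Literature defaults for aerobic glucose growth
#'
#' Typical batch-phase rates for *S. cerevisiae* growing aerobically on
#' excess glucose, used (and flagged as defaults in the constraint
#' provenance) when a measurement row lacks its own growth or gas rates.
#'
#' @return One-row tibble: `mu` (1/h), `q_co2`, `q_glc` (mmol/gDCW/h),
#'   `source`.
#' @export
literature_growth_rates <- function() {
  tibble::tibble(mu = 0.37, q_co2 = 23.0, q_glc = 16.0,
                 source = "literature default: aerobic glucose batch growth")
}

#' Apply the aerobic-glucose growth context
#'
#' Constrains the model for aerobic growth on glucose as sole carbon
#' source: uptake of every carbon-containing exchange metabolite other
#' than glucose is closed, oxygen uptake and CO2 export are opened,
#' fermentation-product exports stay open, and the ATP maintenance
#' reaction gets `ngam` as lower bound.
#'
#' @param model A [metabolic_model()].
#' @param ngam Non-growth-associated maintenance, mmol ATP/gDCW/h.
#' @param glucose_exchange,o2_exchange,co2_exchange,maintenance Reaction
#'   ids of the named exchanges and the ATP-maintenance reaction (toy-model
#'   defaults).
#' @return The contextualized model.
#' @export
apply_growth_context <- function(model, ngam = 1,
                                 glucose_exchange = "EX_glc",
                                 o2_exchange = "EX_o2",
                                 co2_exchange = "EX_co2",
                                 maintenance = "ATPM") {
  stopifnot(ngam >= 0)
  named <- c(glucose_exchange, o2_exchange, co2_exchange, maintenance)
  absent <- setdiff(named, model$reactions$id)
  if (length(absent) > 0L) {
    stop(sprintf("model lacks required reaction(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  carbon_of <- function(met_id) {
    f <- model$metabolites$formula[match(met_id, model$metabolites$id)]
    if (is.na(f) || !nzchar(f)) return(NA_integer_)
    carbon_count(f)
  }
  exch <- model$reactions$id[model$reactions$kind == "exchange"]
  for (r in exch) {
    if (r %in% c(glucose_exchange, o2_exchange, co2_exchange)) next
    met <- model$stoichiometry$metabolite[model$stoichiometry$reaction == r][1]
    cc <- carbon_of(met)
    if (!is.na(cc) && cc > 0) {
      # close uptake, keep export open
      i <- match(r, model$reactions$id)
      model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i], 0)
    }
  }
  model <- set_bounds(model, o2_exchange, lower = -default_bound())
  i <- match(co2_exchange, model$reactions$id)
  model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i], 0)
  model$reactions$upper_bound[i] <- default_bound()
  i <- match(maintenance, model$reactions$id)
  model$reactions$lower_bound[i] <- ngam
  model$reactions$upper_bound[i] <- max(model$reactions$upper_bound[i], ngam)
  model
}

#' Convert a secreted-product titer to a specific production rate
#'
#' Endpoint mode treats the titer as accumulated linearly over the whole
#' culture at the final biomass concentration:
#' `titer / (biomass_conc * culture_time * M)`. Growth-coupled mode assumes
#' production proportional to growth: `mu * titer / (biomass_conc * M)`.
#' The two agree exactly when `mu == 1 / culture_time`.
#'
#' @param titer_mg_l Titer in mg/L.
#' @param biomass_conc Biomass concentration, gDCW/L.
#' @param culture_time Culture duration, h (endpoint mode).
#' @param mu Specific growth rate, 1/h (growth-coupled mode).
#' @param molar_mass Product molar mass, g/mol.
#' @param mode `"endpoint"` (default; fits a secreted product collected
#'   over the run) or `"growth_coupled"`.
#' @return Specific rate, mmol/gDCW/h.
#' @export
titer_to_specific_rate <- function(titer_mg_l, biomass_conc = NULL,
                                   culture_time = NULL, mu = NULL,
                                   molar_mass, mode = c("endpoint", "growth_coupled")) {
  mode <- match.arg(mode)
  stopifnot(titer_mg_l >= 0, molar_mass > 0)
  if (titer_mg_l == 0) return(0)
  if (mode == "endpoint") {
    if (is.null(biomass_conc) || is.null(culture_time) ||
        is.na(biomass_conc) || is.na(culture_time)) {
      stop("endpoint mode needs biomass_conc and culture_time", call. = FALSE)
    }
    stopifnot(biomass_conc > 0, culture_time > 0)
    titer_mg_l / (biomass_conc * culture_time * molar_mass)
  } else {
    if (is.null(mu) || is.null(biomass_conc) || is.na(mu) || is.na(biomass_conc)) {
      stop("growth_coupled mode needs mu and biomass_conc", call. = FALSE)
    }
    stopifnot(biomass_conc > 0, mu >= 0)
    mu * titer_mg_l / (biomass_conc * molar_mass)
  }
}

# molar masses of the measured species, from the model's own formulas
measured_species_masses <- function(model) {
  get_mass <- function(id) {
    f <- model$metabolites$formula[match(id, model$metabolites$id)]
    if (length(f) == 0L || is.na(f)) {
      stop(sprintf("metabolite '%s' missing from model or has no formula", id),
           call. = FALSE)
    }
    molar_mass(f)
  }
  c(bcarotene = get_mass("bcarotene_c"), lycopene = get_mass("lycopene_c"),
    phytoene = get_mass("phytoene_c"), bionone = get_mass("bionone_c"))
}

#' Constrain a model with one strain's measurements
#'
#' Turns a measurement row into interval flux constraints on the
#' pathway-extended, growth-contextualized model: growth is fixed to
#' `mu` (+/- `tol_frac`), CO2 evolution to `q_co2`, each carotenoid
#' accumulation sink to the growth-coupled rate implied by
#' `total_carotenoids * fraction` and the species' molar mass, and the
#' beta-ionone exchange to the titer-derived rate (0 when no titer).
#' Measured values become intervals, not equalities, because strict
#' equalities on noisy measurements routinely make the LP infeasible.
#'
#' @param model Pathway-extended, growth-contextualized model.
#' @param measurement One measurement row (one-row tibble or named list).
#' @param tol_frac Fractional half-width of every constraint interval
#'   (default 0.05).
#' @param ionone_mode Coupling mode for the titer conversion, see
#'   [titer_to_specific_rate()]; carotenoid yields are always
#'   growth-coupled (they are per-gDCW).
#' @param use_default_rates If `TRUE`, missing `mu`/`q_co2` fall back to
#'   [literature_growth_rates()], marked as defaults in the provenance;
#'   if `FALSE`, missing rates are an error.
#' @param growth_reaction,co2_exchange Reaction ids (toy defaults
#'   `"BIOMASS"`, `"EX_co2"`).
#' @return List with `model` (constrained) and `constraints` (tibble:
#'   `reaction`, `lower`, `upper`, `source` naming the measurement field
#'   each bound came from).
#' @export
constrain_strain <- function(model, measurement, tol_frac = 0.05,
                             ionone_mode = c("endpoint", "growth_coupled"),
                             use_default_rates = TRUE,
                             growth_reaction = NULL, co2_exchange = "EX_co2") {
  ionone_mode <- match.arg(ionone_mode)
  stopifnot(tol_frac >= 0)
  m <- if (is.data.frame(measurement)) {
    stopifnot(nrow(measurement) == 1L)
    as.list(measurement)
  } else as.list(measurement)
  growth_reaction <- growth_reaction %||% model$objective

  val <- function(x) if (is.null(m[[x]]) || is.na(m[[x]])) NA_real_ else m[[x]]
  mu <- val("mu"); q_co2 <- val("q_co2")
  defaults <- literature_growth_rates()
  mu_src <- "measurement: mu"; co2_src <- "measurement: q_co2"
  if (is.na(mu)) {
    if (!use_default_rates) stop("measurement lacks mu and defaults are disabled",
                                 call. = FALSE)
    mu <- defaults$mu; mu_src <- "default: literature mu"
  }
  if (is.na(q_co2)) {
    if (!use_default_rates) stop("measurement lacks q_co2 and defaults are disabled",
                                 call. = FALSE)
    q_co2 <- defaults$q_co2; co2_src <- "default: literature q_co2"
  }

  masses <- measured_species_masses(model)
  constraints <- list()
  add <- function(reaction, center, source) {
    ends <- sort(c(center * (1 - tol_frac), center * (1 + tol_frac)))
    tibble::tibble(reaction = reaction, lower = ends[1], upper = ends[2],
                   source = source)
  }
  constraints <- c(constraints, list(add(growth_reaction, mu, mu_src)))
  constraints <- c(constraints, list(add(co2_exchange, q_co2, co2_src)))

  total <- val("total_carotenoids")
  if (!is.na(total) && total > 0) {
    fr <- c(bcarotene = val("frac_beta_carotene"), lycopene = val("frac_lycopene"),
            phytoene = val("frac_phytoene"))
    # unprofiled measurements: attribute the whole yield to beta-carotene,
    # the dominant species in the producer strains
    if (all(is.na(fr))) fr <- c(bcarotene = 1, lycopene = 0, phytoene = 0)
    fr[is.na(fr)] <- 0
    for (nm in names(fr)) {
      rate <- yield_to_specific_rate(total * fr[[nm]], mu, masses[[nm]])
      constraints <- c(constraints, list(add(
        paste0("SK_", nm), rate,
        sprintf("measurement: total_carotenoids * frac_%s", nm))))
    }
  }

  titer <- val("ionone_titer")
  if (!is.na(titer) && titer > 0) {
    rate <- titer_to_specific_rate(
      titer, biomass_conc = val("biomass_conc"), culture_time = val("culture_time"),
      mu = mu, molar_mass = masses[["bionone"]], mode = ionone_mode)
    constraints <- c(constraints, list(add("EX_bionone", rate,
                                           "measurement: ionone_titer")))
  } else {
    constraints <- c(constraints, list(tibble::tibble(
      reaction = "EX_bionone", lower = 0, upper = 0,
      source = "measurement: no ionone titer")))
  }
  constraints <- dplyr::bind_rows(constraints)

  out <- model
  for (i in seq_len(nrow(constraints))) {
    r <- constraints$reaction[i]
    if (!r %in% out$reactions$id) {
      stop(sprintf("constraint target '%s' not in model (pathway-extended?)", r),
           call. = FALSE)
    }
    j <- match(r, out$reactions$id)
    out$reactions$lower_bound[j] <- constraints$lower[i]
    out$reactions$upper_bound[j] <- constraints$upper[i]
  }
  # products of cleavage must be free to leave at steady state
  if ("SK_c14dial" %in% out$reactions$id) {
    out <- set_bounds(out, "SK_c14dial", lower = 0, upper = default_bound())
  }
  if ("SK_c27apo" %in% out$reactions$id) {
    out <- set_bounds(out, "SK_c27apo", lower = 0, upper = default_bound())
  }
  list(model = out, constraints = constraints)
}
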