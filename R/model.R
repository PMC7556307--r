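#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` is the in-memory container for a stoichiometric
#' network: a metabolite table, a reaction table with flux bounds, a long
#' stoichiometry table, and one objective reaction. All fluxes are in
#' mmol/gDCW/h (the biomass pseudo-reaction flux is the specific growth
#' rate in 1/h); this single internal unit system is deliberate, and
#' measured yields/titers are converted exactly once, at the measurement
#' boundary.
#'
#' @param metabolites Tibble/data frame with columns `id`, and optionally
#'   `name`, `compartment`, `formula` (Hill string or `NA`), `charge`.
#' @param reactions Tibble with columns `id`, and optionally `name`,
#'   `lower_bound`, `upper_bound` (default -1000/1000 for reversible),
#'   `kind` (one of `"internal"`, `"exchange"`, `"sink"`, `"biomass"`).
#' @param stoichiometry Long tibble with columns `reaction`, `metabolite`,
#'   `coefficient` (negative = consumed).
#' @param objective Reaction id of the objective (e.g. the biomass
#'   pseudo-reaction).
#' @param description Free-text description of the model.
#' @return An object of class `metabolic_model`.
#' @seealso [validate_model()], [read_model()], [extend_model()]
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            objective, description = "") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)

  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_integer_
  metabolites <- metabolites[, c("id", "name", "compartment", "formula", "charge")]

  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"lower_bound" %in% names(reactions)) reactions$lower_bound <- -default_bound()
  if (!"upper_bound" %in% names(reactions)) reactions$upper_bound <- default_bound()
  if (!"kind" %in% names(reactions)) reactions$kind <- "internal"
  reactions <- reactions[, c("id", "name", "lower_bound", "upper_bound", "kind")]

  stoichiometry <- stoichiometry[, c("reaction", "metabolite", "coefficient")]

  m <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, objective = objective,
         description = description),
    class = "metabolic_model"
  )
  assert_model_structure(m)
  m
}

#' Default bound magnitude for practically unbounded fluxes (mmol/gDCW/h)
#'
#' The community convention for constraint-based models: reactions with no
#' physical limit get bounds of +/- 1000 mmol/gDCW/h.
#' @return The scalar 1000.
#' @export
default_bound <- function() 1000

# Structural integrity checks that must hold for the object to be usable at
# all (as opposed to validate_model(), which reports scientific violations).
assert_model_structure <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites; rxns <- model$reactions; sto <- model$stoichiometry
  if (anyDuplicated(mets$id)) {
    stop(sprintf("duplicate metabolite id(s): %s",
                 paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(rxns$id)) {
    stop(sprintf("duplicate reaction id(s): %s",
                 paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")),
         call. = FALSE)
  }
  undeclared <- setdiff(sto$metabolite, mets$id)
  if (length(undeclared) > 0L) {
    bad <- unique(sto$reaction[sto$metabolite %in% undeclared])
    stop(sprintf("reaction(s) %s reference undeclared metabolite(s): %s",
                 paste(bad, collapse = ", "), paste(undeclared, collapse = ", ")),
         call. = FALSE)
  }
  orphan_rxn <- setdiff(sto$reaction, rxns$id)
  if (length(orphan_rxn) > 0L) {
    stop(sprintf("stoichiometry references undeclared reaction(s): %s",
                 paste(orphan_rxn, collapse = ", ")), call. = FALSE)
  }
  if (!model$objective %in% rxns$id) {
    stop(sprintf("objective reaction '%s' not in model", model$objective), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites, %d reactions\n",
              nrow(x$metabolites), nrow(x$reactions)))
  cat(sprintf("  objective: %s\n", x$objective))
  if (nzchar(x$description)) {
    cat("  ", strsplit(x$description, "\n")[[1]][1], "\n", sep = "")
  }
  invisible(x)
}

#' Dense stoichiometric matrix S of a model
#'
#' Rows are metabolites, columns reactions; `S[i, j]` is the signed molar
#' coefficient of metabolite i in reaction j. Steady-state flux balance is
#' `S %*% v == 0`.
#'
#' @param model A `metabolic_model`.
#' @return Numeric matrix with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  sto <- model$stoichiometry
  S[cbind(match(sto$metabolite, mets), match(sto$reaction, rxns))] <- sto$coefficient
  S
}

#' Set flux bounds on one reaction (pure)
#'
#' Returns a modified copy; the input model is never mutated.
#'
#' @param model A `metabolic_model`.
#' @param reaction Reaction id.
#' @param lower,upper New bounds (either may be `NULL` to keep the current
#'   value); must satisfy `lower <= upper`.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction, lower = NULL, upper = NULL) {
  i <- match(reaction, model$reactions$id)
  if (is.na(i)) stop(sprintf("no reaction '%s' in model", reaction), call. = FALSE)
  lb <- if (is.null(lower)) model$reactions$lower_bound[i] else lower
  ub <- if (is.null(upper)) model$reactions$upper_bound[i] else upper
  if (lb > ub) {
    stop(sprintf("bounds for '%s' invalid: lower %g > upper %g", reaction, lb, ub),
         call. = FALSE)
  }
  model$reactions$lower_bound[i] <- lb
  model$reactions$upper_bound[i] <- ub
  model
}

#' Add metabolites and reactions to a model (pure)
#'
#' Low-level extension primitive used by [extend_model()] and the toy-model
#' builder. Ids must not collide with existing ones.
#'
#' @param model A `metabolic_model`.
#' @param metabolites Tibble of new metabolites (may be `NULL`).
#' @param reactions Tibble of new reactions (may be `NULL`).
#' @param stoichiometry Long tibble of new stoichiometry rows (may be `NULL`).
#' @return The extended model.
#' @export
add_to_model <- function(model, metabolites = NULL, reactions = NULL,
                         stoichiometry = NULL) {
  if (!is.null(metabolites) && nrow(metabolites) > 0L) {
    clash <- intersect(metabolites$id, model$metabolites$id)
    if (length(clash) > 0L) {
      stop(sprintf("metabolite id collision: %s", paste(clash, collapse = ", ")),
           call. = FALSE)
    }
  }
  if (!is.null(reactions) && nrow(reactions) > 0L) {
    clash <- intersect(reactions$id, model$reactions$id)
    if (length(clash) > 0L) {
      stop(sprintf("reaction id collision: %s", paste(clash, collapse = ", ")),
           call. = FALSE)
    }
  }
  metabolic_model(
    metabolites = dplyr::bind_rows(model$metabolites, metabolites),
    reactions = dplyr::bind_rows(model$reactions, reactions),
    stoichiometry = dplyr::bind_rows(model$stoichiometry, stoichiometry),
    objective = model$objective,
    description = model$description
  )
}

#' Validate a metabolic model
#'
#' Reports (never throws) violations of the model invariants: bound
#' ordering, non-empty stoichiometry, boundary reactions touching exactly
#' one metabolite, malformed formulas, and — when all participating
#' metabolites carry formulas — carbon imbalance of internal reactions.
#' The full multi-element balance check lives in
#' [check_elemental_balance()]; carbon is checked here because every
#' downstream interrogation depends on carbon accounting.
#'
#' @param model A `metabolic_model`.
#' @return A tibble with columns `rule`, `id`, `detail`; zero rows means
#'   the model is valid.
#' @export
validate_model <- function(model) {
  rxns <- model$reactions
  sto <- model$stoichiometry
  viol <- list()

  bad_bounds <- rxns[rxns$lower_bound > rxns$upper_bound, ]
  if (nrow(bad_bounds) > 0L) {
    viol <- c(viol, list(tibble::tibble(
      rule = "bounds", id = bad_bounds$id,
      detail = sprintf("lower_bound %g > upper_bound %g",
                       bad_bounds$lower_bound, bad_bounds$upper_bound))))
  }

  n_mets <- table(factor(sto$reaction, levels = rxns$id))
  empty <- rxns$id[n_mets == 0L]
  if (length(empty) > 0L) {
    viol <- c(viol, list(tibble::tibble(
      rule = "empty_stoichiometry", id = empty,
      detail = "reaction has no stoichiometry")))
  }
  boundary <- rxns$id[rxns$kind %in% c("exchange", "sink")]
  multi <- boundary[n_mets[boundary] > 1L]
  if (length(multi) > 0L) {
    viol <- c(viol, list(tibble::tibble(
      rule = "boundary_arity", id = multi,
      detail = sprintf("exchange/sink reaction touches %d metabolites (must be 1)",
                       as.integer(n_mets[multi])))))
  }

  # formula syntax
  f <- model$metabolites$formula
  has_f <- !is.na(f) & nzchar(f)
  parse_ok <- vapply(f[has_f], function(s) {
    !inherits(try(parse_formula(s), silent = TRUE), "try-error")
  }, logical(1))
  if (any(!parse_ok)) {
    bad <- model$metabolites$id[has_f][!parse_ok]
    viol <- c(viol, list(tibble::tibble(
      rule = "formula_syntax", id = bad,
      detail = sprintf("unparseable formula '%s'", f[has_f][!parse_ok]))))
  }

  # carbon balance of internal reactions where every metabolite has a formula
  carbon <- stats::setNames(rep(NA_real_, nrow(model$metabolites)), model$metabolites$id)
  ok_ids <- model$metabolites$id[has_f][parse_ok]
  carbon[ok_ids] <- vapply(model$metabolites$formula[match(ok_ids, model$metabolites$id)],
                           carbon_count, integer(1))
  internal <- rxns$id[rxns$kind == "internal"]
  for (r in internal) {
    rows <- sto[sto$reaction == r, ]
    cc <- carbon[rows$metabolite]
    if (anyNA(cc)) next  # formulas incomplete: carbon check not applicable
    imb <- sum(rows$coefficient * cc)
    if (abs(imb) > 1e-9) {
      viol <- c(viol, list(tibble::tibble(
        rule = "carbon_balance", id = r,
        detail = sprintf("net carbon %+g per unit flux", imb))))
    }
  }

  if (length(viol) == 0L) {
    tibble::tibble(rule = character(), id = character(), detail = character())
  } else {
    dplyr::bind_rows(viol)
  }
}
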