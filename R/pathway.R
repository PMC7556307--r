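# Heterologous carotenogenic / apocarotenogenic pathway.
#
# Chemistry grafted onto the host: CrtE condenses FPP (C15) and IPP (C5) to
# GGPP (C20); the bifunctional CrtYB condenses 2 GGPP to phytoene (C40) and
# later cyclizes lycopene to beta-carotene; CrtI performs four lumped
# desaturations (phytoene -> lycopene, 8 H removed onto 4 FAD); CCD1 cleaves
# beta-carotene oxidatively at the 9,10 and 9',10' double bonds — double
# cleavage gives two C13 beta-ionones plus the C14 dialdehyde, single
# cleavage gives one beta-ionone plus a C27 apocarotenal. Accumulated
# pigments drain through irreversible sinks (intracellular accumulation,
# measured as mg/gDCW retained in biomass); beta-ionone leaves through an
# exchange (secreted into the culture / solvent overlay).

pathway_metabolite_table <- function() {
  tibble::tribble(
    ~id,            ~name,                 ~formula,        ~role,
    "fpp_c",        "farnesyl diphosphate",     "C15H28O7P2", "host",
    "ipp_c",        "isopentenyl diphosphate",  "C5H12O7P2",  "host",
    "ppi_c",        "diphosphate",              "H4O7P2",     "host",
    "o2_c",         "oxygen",                   "O2",         "host",
    "fad_c",        "FAD",                      "C27H33N9O15P2", "host",
    "fadh2_c",      "FADH2",                    "C27H35N9O15P2", "host",
    "ggpp_c",       "geranylgeranyl diphosphate", "C20H36O7P2", "pathway",
    "phytoene_c",   "phytoene",                 "C40H64",     "pathway",
    "lycopene_c",   "lycopene",                 "C40H56",     "pathway",
    "bcarotene_c",  "beta-carotene",            "C40H56",     "pathway",
    "bionone_c",    "beta-ionone",              "C13H20O",    "pathway",
    "c14dial_c",    "C14 dialdehyde (rosafluene dialdehyde)", "C14H16O2", "pathway",
    "c27apo_c",     "C27 apocarotenal",         "C27H36O",    "pathway"
  )
}

#' Build the heterologous carotenoid/apocarotenoid pathway specification
#'
#' Assembles the CrtE / CrtYB / CrtI / CCD1 reaction set with elementally
#' balanced stoichiometry, metabolite formulas, and molar masses. Every
#' non-boundary template reaction balances C, H and O (and P for the
#' prenyl-transfer steps); the construction is verified on the fly and the
#' function refuses to emit an unbalanced spec.
#'
#' All sinks (phytoene, lycopene, beta-carotene accumulation, C14
#' dialdehyde, optional C27 apocarotenal) and the beta-ionone exchange are
#' created closed (bounds 0); contextualization opens them to measured
#' values.
#'
#' @param allow_single_cleavage If `TRUE`, include the single-cleavage CCD1
#'   reaction (beta-carotene + O2 -> beta-ionone + C27 apocarotenal),
#'   modelling unspecific cleavage at only one site.
#' @param allow_c27_sink If `TRUE` (requires `allow_single_cleavage`),
#'   include an accumulation sink for the C27 apocarotenal.
#' @return A `pathway_spec`: list with `metabolites`, `reactions`,
#'   `stoichiometry`, `molar_masses`, `options`.
#' @examples
#' spec <- build_pathway_spec()
#' spec$molar_masses[["bionone_c"]] # ~192.3 g/mol
#' @export
build_pathway_spec <- function(allow_single_cleavage = FALSE,
                               allow_c27_sink = allow_single_cleavage) {
  if (allow_c27_sink && !allow_single_cleavage) {
    stop("allow_c27_sink requires allow_single_cleavage", call. = FALSE)
  }
  mets <- pathway_metabolite_table()
  if (!allow_single_cleavage) mets <- mets[mets$id != "c27apo_c", ]

  rx <- list(
    list(id = "CRTE", name = "GGPP synthase (CrtE)", kind = "internal",
         lb = 0, ub = default_bound(),
         sto = c(fpp_c = -1, ipp_c = -1, ggpp_c = 1, ppi_c = 1)),
    list(id = "CRTYB_SYN", name = "phytoene synthase (CrtYB)", kind = "internal",
         lb = 0, ub = default_bound(),
         sto = c(ggpp_c = -2, phytoene_c = 1, ppi_c = 2)),
    list(id = "CRTI", name = "phytoene desaturase, 4 lumped steps (CrtI)",
         kind = "internal", lb = 0, ub = default_bound(),
         sto = c(phytoene_c = -1, fad_c = -4, lycopene_c = 1, fadh2_c = 4)),
    list(id = "CRTYB_CYC", name = "lycopene cyclase (CrtYB)", kind = "internal",
         lb = 0, ub = default_bound(),
         sto = c(lycopene_c = -1, bcarotene_c = 1)),
    list(id = "CCD1_DOUBLE", name = "CCD1 double cleavage (9,10 and 9',10')",
         kind = "internal", lb = 0, ub = default_bound(),
         sto = c(bcarotene_c = -1, o2_c = -2, bionone_c = 2, c14dial_c = 1)),
    list(id = "SK_phytoene", name = "phytoene accumulation", kind = "sink",
         lb = 0, ub = 0, sto = c(phytoene_c = -1)),
    list(id = "SK_lycopene", name = "lycopene accumulation", kind = "sink",
         lb = 0, ub = 0, sto = c(lycopene_c = -1)),
    list(id = "SK_bcarotene", name = "beta-carotene accumulation", kind = "sink",
         lb = 0, ub = 0, sto = c(bcarotene_c = -1)),
    list(id = "SK_c14dial", name = "C14 dialdehyde accumulation", kind = "sink",
         lb = 0, ub = 0, sto = c(c14dial_c = -1)),
    list(id = "EX_bionone", name = "beta-ionone exchange", kind = "exchange",
         lb = 0, ub = 0, sto = c(bionone_c = -1))
  )
  if (allow_single_cleavage) {
    rx <- append(rx, list(
      list(id = "CCD1_SINGLE", name = "CCD1 single cleavage (9,10 only)",
           kind = "internal", lb = 0, ub = default_bound(),
           sto = c(bcarotene_c = -1, o2_c = -1, bionone_c = 1, c27apo_c = 1))),
      after = 5L)
  }
  if (allow_c27_sink) {
    rx <- append(rx, list(
      list(id = "SK_c27apo", name = "C27 apocarotenal accumulation", kind = "sink",
           lb = 0, ub = 0, sto = c(c27apo_c = -1))))
  }

  reactions <- purrr::map_dfr(rx, function(r) {
    tibble::tibble(id = r$id, name = r$name, lower_bound = r$lb,
                   upper_bound = r$ub, kind = r$kind)
  })
  stoichiometry <- purrr::map_dfr(rx, function(r) {
    tibble::tibble(reaction = r$id, metabolite = names(r$sto),
                   coefficient = unname(r$sto))
  })
  metabolites <- tibble::tibble(
    id = mets$id, name = mets$name, compartment = "c",
    formula = mets$formula, charge = NA_integer_, role = mets$role)

  spec <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry,
         molar_masses = stats::setNames(
           vapply(mets$formula, molar_mass, numeric(1)), mets$id),
         options = list(allow_single_cleavage = allow_single_cleavage,
                        allow_c27_sink = allow_c27_sink)),
    class = "pathway_spec"
  )
  # refuse to emit an unbalanced spec
  formulas <- stats::setNames(metabolites$formula, metabolites$id)
  for (r in reactions$id[reactions$kind == "internal"]) {
    rows <- stoichiometry[stoichiometry$reaction == r, ]
    imb <- element_imbalance(rows$coefficient, formulas[rows$metabolite],
                             elements = c("C", "H", "O", "P"))
    if (length(imb) > 0L) {
      stop(sprintf("internal error: pathway reaction %s unbalanced (%s)", r,
                   paste(sprintf("%s%+g", names(imb), imb), collapse = ", ")),
           call. = FALSE)
    }
  }
  spec
}

#' @export
print.pathway_spec <- function(x, ...) {
  cat(sprintf("<pathway_spec> %d reactions, %d metabolites (single cleavage: %s)\n",
              nrow(x$reactions), nrow(x$metabolites),
              x$options$allow_single_cleavage))
  invisible(x)
}

# net element counts of a reaction; returns named vector of nonzero imbalances
element_imbalance <- function(coefficients, formulas, elements = NULL) {
  if (anyNA(formulas) || any(!nzchar(formulas))) {
    stop("no formula: all participating metabolites need an elemental formula",
         call. = FALSE)
  }
  maps <- lapply(formulas, parse_formula)
  all_el <- unique(unlist(lapply(maps, names)))
  if (!is.null(elements)) all_el <- intersect(all_el, elements)
  net <- vapply(all_el, function(el) {
    sum(coefficients * vapply(maps, function(m) {
      if (el %in% names(m)) m[[el]] else 0
    }, numeric(1)))
  }, numeric(1))
  net[abs(net) > 1e-9]
}

#' Check the elemental balance of a reaction
#'
#' Computes the per-element net imbalance of one reaction from the
#' metabolite formulas. Exchange, sink and biomass pseudo-reactions are by
#' definition unbalanced and are reported as skipped rather than failed.
#'
#' @param model A [metabolic_model()] (or a `pathway_spec`).
#' @param reaction Reaction id.
#' @param elements Optional character vector restricting the elements
#'   checked (e.g. `c("C", "H", "O")`).
#' @return Named numeric vector of nonzero per-element imbalances (empty if
#'   balanced), with attribute `status` one of `"balanced"`, `"imbalanced"`,
#'   `"skipped"`.
#' @export
check_elemental_balance <- function(model, reaction, elements = NULL) {
  i <- match(reaction, model$reactions$id)
  if (is.na(i)) stop(sprintf("no reaction '%s'", reaction), call. = FALSE)
  kind <- model$reactions$kind[i]
  if (kind %in% c("exchange", "sink", "biomass")) {
    out <- stats::setNames(numeric(0), character(0))
    attr(out, "status") <- "skipped"
    return(out)
  }
  rows <- model$stoichiometry[model$stoichiometry$reaction == reaction, ]
  formulas <- model$metabolites$formula[match(rows$metabolite, model$metabolites$id)]
  out <- element_imbalance(rows$coefficient, formulas, elements)
  attr(out, "status") <- if (length(out) == 0L) "balanced" else "imbalanced"
  out
}

#' Elemental balance report for every reaction in a model
#'
#' @param model A [metabolic_model()] whose metabolites all carry formulas.
#' @param elements Optional element restriction passed to
#'   [check_elemental_balance()].
#' @return Tibble with columns `reaction`, `status`, `imbalance` (formatted
#'   string, empty when balanced or skipped).
#' @export
balance_report <- function(model, elements = NULL) {
  purrr::map_dfr(model$reactions$id, function(r) {
    imb <- check_elemental_balance(model, r, elements)
    tibble::tibble(
      reaction = r, status = attr(imb, "status"),
      imbalance = if (length(imb) == 0L) "" else
        paste(sprintf("%s%+g", names(imb), imb), collapse = ", "))
  })
}

#' Graft the heterologous pathway onto a host model
#'
#' Adds the pathway reactions and novel metabolites to the host model. The
#' host must already contain the precursor and cofactor pools the pathway
#' taps (FPP, IPP, diphosphate, O2, FAD, FADH2); pass `host_map` to map the
#' spec's metabolite names onto the host's ids (e.g. for a genome-scale
#' reconstruction with its own naming convention). Gene dosage is never
#' modelled — strain differences enter only through the measured yields
#' used as constraints.
#'
#' @param model Host [metabolic_model()].
#' @param spec A `pathway_spec` from [build_pathway_spec()].
#' @param host_map Named character vector mapping spec metabolite ids to
#'   host metabolite ids; defaults to the identity mapping for the host-role
#'   metabolites.
#' @return The extended model; added sinks/exchange stay closed until
#'   contextualization opens them.
#' @export
extend_model <- function(model, spec, host_map = NULL) {
  stopifnot(inherits(model, "metabolic_model"), inherits(spec, "pathway_spec"))
  host_needed <- spec$metabolites$id[spec$metabolites$role == "host"]
  map <- stats::setNames(host_needed, host_needed)
  if (!is.null(host_map)) map[names(host_map)] <- host_map

  missing_host <- map[!map %in% model$metabolites$id]
  if (length(missing_host) > 0L) {
    stop(sprintf("host model lacks required metabolite(s): %s",
                 paste(sprintf("%s (for %s)", missing_host, names(missing_host)),
                       collapse = ", ")), call. = FALSE)
  }

  new_mets <- spec$metabolites[spec$metabolites$role == "pathway", ]
  clash <- intersect(new_mets$id, model$metabolites$id)
  if (length(clash) > 0L) {
    stop(sprintf("metabolite id collision with host: %s (already extended?)",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }
  sto <- spec$stoichiometry
  remap <- sto$metabolite %in% names(map)
  sto$metabolite[remap] <- unname(map[sto$metabolite[remap]])

  extended <- add_to_model(
    model,
    metabolites = new_mets[, c("id", "name", "compartment", "formula", "charge")],
    reactions = spec$reactions,
    stoichiometry = sto
  )
  extended$description <- paste0(model$description,
                                 " + carotenoid/ionone pathway extension")
  extended
}

#' Serialize a pathway spec as a COBRA-style JSON reaction-set fragment
#'
#' @param spec A `pathway_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_spec <- function(spec, path) {
  sto_by_rxn <- split(spec$stoichiometry, spec$stoichiometry$reaction)
  doc <- list(
    description = "carotenoid/ionone pathway reaction-set fragment",
    options = spec$options,
    metabolites = purrr::pmap(
      spec$metabolites,
      function(id, name, compartment, formula, charge, role) {
        list(id = id, name = name, compartment = compartment,
             formula = formula, notes = list(role = role))
      }),
    reactions = purrr::pmap(
      spec$reactions,
      function(id, name, lower_bound, upper_bound, kind) {
        rows <- sto_by_rxn[[id]]
        list(id = id, name = name,
             metabolites = as.list(stats::setNames(rows$coefficient, rows$metabolite)),
             lower_bound = lower_bound, upper_bound = upper_bound,
             notes = list(kind = kind))
      })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Convert a per-biomass yield to a specific production rate
#'
#' Growth-associated production: a product retained in (or proportional to)
#' biomass at yield Y (mg/gDCW) in a culture growing at rate mu (1/h) is
#' produced at the specific rate `mu * Y / M` (mmol/gDCW/h), with M the
#' molar mass in g/mol (= mg/mmol). This is how measured carotenoid yields
#' become sink-flux constraints.
#'
#' @param yield_mg_per_gdcw Yield in mg/gDCW (>= 0).
#' @param mu_per_h Specific growth rate in 1/h (>= 0).
#' @param molar_mass_g_per_mol Molar mass in g/mol (> 0).
#' @return Specific rate in mmol/gDCW/h.
#' @examples
#' yield_to_specific_rate(32, 0.35, molar_mass("C40H56"))
#' @export
yield_to_specific_rate <- function(yield_mg_per_gdcw, mu_per_h,
                                   molar_mass_g_per_mol) {
  stopifnot(yield_mg_per_gdcw >= 0, mu_per_h >= 0)
  if (molar_mass_g_per_mol <= 0) stop("molar mass must be positive", call. = FALSE)
  mu_per_h * yield_mg_per_gdcw / molar_mass_g_per_mol
}
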