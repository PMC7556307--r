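#' Read a metabolic model from COBRA-style JSON or SBML
#'
#' Supports the COBRA JSON dialect (as used by the BiGG repository, e.g.
#' the iMM904 yeast reconstruction) and flat SBML Level 3 with FBC-style
#' chemical-formula and flux-bound annotations. Chemical formulas and
#' bounds are preserved; unknown annotations are ignored with a message.
#' Models without formulas load fine but fail carbon-dependent operations
#' explicitly rather than guessing.
#'
#' @param path Path to the model file.
#' @param format `"auto"` (default; sniffed from extension/content),
#'   `"json"`, or `"sbml"`.
#' @return A [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json"
      else if (ext %in% c("xml", "sbml")) "sbml"
      else {
        head1 <- readChar(path, 64L)
        if (grepl("^\\s*\\{", head1)) "json" else "sbml"
      }
  }
  model <- switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
  assert_model_structure(model)
  model
}

#' Write a metabolic model to COBRA-style JSON or SBML
#'
#' Inverse of [read_model()]: `read_model(write_model(m, path))` is
#' structurally identical to `m` for both formats, including bounds,
#' formulas, charges and reaction kinds.
#'
#' @param model A [metabolic_model()].
#' @param path Output path.
#' @param format `"auto"` (from extension), `"json"`, or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  stopifnot(inherits(model, "metabolic_model"))
  if (nrow(model$reactions) == 0L) {
    stop("model has no reactions; nothing to write", call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "json"
  }
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

# ---- COBRA-style JSON ------------------------------------------------------

read_model_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  known <- c("id", "name", "description", "metabolites", "reactions",
             "compartments", "version", "notes", "objective")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L) {
    message(sprintf("read_model: ignoring unknown top-level annotation(s): %s",
                    paste(extra, collapse = ", ")))
  }
  mets <- purrr::map_dfr(raw$metabolites, function(m) {
    tibble::tibble(
      id = m$id,
      name = m$name %||% m$id,
      compartment = m$compartment %||% "c",
      formula = (function(f) if (is.null(f) || !nzchar(f)) NA_character_ else f)(m$formula),
      charge = if (is.null(m$charge)) NA_integer_ else as.integer(m$charge)
    )
  })
  if (anyDuplicated(mets$id)) {
    stop(sprintf("duplicate metabolite id(s) in %s: %s", path,
                 paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")),
         call. = FALSE)
  }
  rxns <- purrr::map_dfr(raw$reactions, function(r) {
    tibble::tibble(
      id = r$id,
      name = r$name %||% r$id,
      lower_bound = as.numeric(r$lower_bound %||% -default_bound()),
      upper_bound = as.numeric(r$upper_bound %||% default_bound()),
      kind = r$notes$kind %||% NA_character_,
      objective_coefficient = as.numeric(r$objective_coefficient %||% 0)
    )
  })
  if (anyDuplicated(rxns$id)) {
    stop(sprintf("duplicate reaction id(s) in %s: %s", path,
                 paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")),
         call. = FALSE)
  }
  sto <- purrr::map_dfr(raw$reactions, function(r) {
    coefs <- r$metabolites
    if (is.null(coefs) || length(coefs) == 0L) {
      return(tibble::tibble(reaction = character(), metabolite = character(),
                            coefficient = numeric()))
    }
    tibble::tibble(reaction = r$id, metabolite = names(coefs),
                   coefficient = as.numeric(unlist(coefs)))
  })
  undeclared <- setdiff(sto$metabolite, mets$id)
  if (length(undeclared) > 0L) {
    bad <- unique(sto$reaction[sto$metabolite %in% undeclared])
    stop(sprintf("reaction(s) %s reference undeclared metabolite(s): %s",
                 paste(bad, collapse = ", "), paste(undeclared, collapse = ", ")),
         call. = FALSE)
  }
  rxns$kind <- infer_reaction_kind(rxns, sto)
  objective <- raw$objective %||% {
    cand <- rxns$id[rxns$objective_coefficient != 0]
    if (length(cand) == 0L) {
      stop(sprintf("no objective reaction in %s (no objective_coefficient set)", path),
           call. = FALSE)
    }
    cand[[1]]
  }
  rxns$objective_coefficient <- NULL
  metabolic_model(mets, rxns, sto, objective,
                  description = raw$description %||% raw$name %||% "")
}

write_model_json <- function(model, path) {
  sto_by_rxn <- split(model$stoichiometry, model$stoichiometry$reaction)
  rxn_list <- purrr::pmap(model$reactions, function(id, name, lower_bound,
                                                    upper_bound, kind) {
    rows <- sto_by_rxn[[id]]
    coefs <- if (is.null(rows)) stats::setNames(list(), character()) else
      as.list(stats::setNames(rows$coefficient, rows$metabolite))
    list(id = id, name = name,
         metabolites = coefs,
         lower_bound = lower_bound, upper_bound = upper_bound,
         objective_coefficient = if (id == model$objective) 1 else 0,
         notes = list(kind = kind))
  })
  met_list <- purrr::pmap(model$metabolites, function(id, name, compartment,
                                                      formula, charge) {
    out <- list(id = id, name = name, compartment = compartment)
    if (!is.na(formula)) out$formula <- formula
    if (!is.na(charge)) out$charge <- charge
    out
  })
  doc <- list(id = "model", description = model$description,
              objective = model$objective,
              metabolites = met_list, reactions = rxn_list)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# Kind inference for files that carry no explicit kind note: id prefixes
# follow the prevailing COBRA conventions (EX_ exchange, SK_/DM_ sink),
# biomass recognized by name, remaining single-metabolite boundary
# reactions treated as exchanges.
infer_reaction_kind <- function(rxns, sto) {
  n_mets <- table(factor(sto$reaction, levels = rxns$id))
  purrr::map_chr(seq_len(nrow(rxns)), function(i) {
    k <- rxns$kind[i]
    if (!is.na(k)) return(k)
    id <- rxns$id[i]
    if (grepl("^(R_)?EX_", id)) return("exchange")
    if (grepl("^(R_)?(SK|DM)_", id)) return("sink")
    if (grepl("biomass", id, ignore.case = TRUE) ||
        grepl("biomass", rxns$name[i], ignore.case = TRUE)) return("biomass")
    if (n_mets[[id]] == 1L) return("exchange")
    "internal"
  })
}

# ---- SBML Level 3 (flat, FBC-style annotations) ----------------------------

.sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  find_all <- function(node, what) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  }
  attr_of <- function(nodes, name) xml2::xml_attr(nodes, name)

  sp <- find_all(doc, "species")
  mets <- tibble::tibble(
    id = attr_of(sp, "id"),
    name = dplyr::coalesce(attr_of(sp, "name"), attr_of(sp, "id")),
    compartment = dplyr::coalesce(attr_of(sp, "compartment"), "c"),
    formula = attr_of(sp, "chemicalFormula"),
    charge = suppressWarnings(as.integer(attr_of(sp, "charge")))
  )
  if (nrow(mets) > 0L && anyDuplicated(mets$id)) {
    stop(sprintf("duplicate species id(s) in %s", path), call. = FALSE)
  }

  params <- find_all(doc, "parameter")
  pvals <- stats::setNames(suppressWarnings(as.numeric(attr_of(params, "value"))),
                           attr_of(params, "id"))

  rx_nodes <- find_all(doc, "reaction")
  parse_side <- function(rx, side, sign) {
    refs <- xml2::xml_find_all(
      rx, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']", side))
    if (length(refs) == 0L) {
      return(tibble::tibble(metabolite = character(), coefficient = numeric()))
    }
    tibble::tibble(
      metabolite = xml2::xml_attr(refs, "species"),
      coefficient = sign * dplyr::coalesce(
        suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry"))), 1)
    )
  }
  resolve_bound <- function(attr_val, num_attr, fallback) {
    if (!is.na(num_attr)) return(as.numeric(num_attr))
    if (!is.na(attr_val) && attr_val %in% names(pvals)) return(pvals[[attr_val]])
    fallback
  }
  rxns <- list(); sto <- list()
  for (rx in rx_nodes) {
    id <- xml2::xml_attr(rx, "id")
    reversible <- identical(xml2::xml_attr(rx, "reversible"), "true")
    lb <- resolve_bound(xml2::xml_attr(rx, "lowerFluxBound"),
                        xml2::xml_attr(rx, "lowerBound"),
                        if (reversible) -default_bound() else 0)
    ub <- resolve_bound(xml2::xml_attr(rx, "upperFluxBound"),
                        xml2::xml_attr(rx, "upperBound"),
                        default_bound())
    notes_p <- xml2::xml_find_all(rx, ".//*[local-name()='notes']//*[local-name()='p']")
    kind <- NA_character_
    for (p in xml2::xml_text(notes_p)) {
      mk <- stringr::str_match(p, "^\\s*kind:\\s*(\\w+)\\s*$")[, 2]
      if (!is.na(mk)) kind <- mk
    }
    rxns[[length(rxns) + 1L]] <- tibble::tibble(
      id = id, name = dplyr::coalesce(xml2::xml_attr(rx, "name"), id),
      lower_bound = lb, upper_bound = ub, kind = kind,
      objective_coefficient = 0)
    side <- dplyr::bind_rows(parse_side(rx, "listOfReactants", -1),
                             parse_side(rx, "listOfProducts", +1))
    if (nrow(side) > 0L) {
      side$reaction <- id
      sto[[length(sto) + 1L]] <- side[, c("reaction", "metabolite", "coefficient")]
    }
  }
  rxns <- dplyr::bind_rows(rxns)
  sto <- if (length(sto) > 0L) dplyr::bind_rows(sto) else
    tibble::tibble(reaction = character(), metabolite = character(),
                   coefficient = numeric())
  if (anyDuplicated(rxns$id)) {
    stop(sprintf("duplicate reaction id(s) in %s", path), call. = FALSE)
  }
  undeclared <- setdiff(sto$metabolite, mets$id)
  if (length(undeclared) > 0L) {
    bad <- unique(sto$reaction[sto$metabolite %in% undeclared])
    stop(sprintf("reaction(s) %s reference undeclared species: %s",
                 paste(bad, collapse = ", "), paste(undeclared, collapse = ", ")),
         call. = FALSE)
  }

  obj_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  objective <- if (length(obj_nodes) > 0L) {
    xml2::xml_attr(obj_nodes[[1]], "reaction")
  } else {
    stop(sprintf("no flux objective found in %s", path), call. = FALSE)
  }
  rxns$kind <- infer_reaction_kind(rxns, sto)
  rxns$objective_coefficient <- NULL
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  desc <- xml2::xml_attr(model_node, "name")
  metabolic_model(mets, rxns, sto, objective,
                  description = if (is.na(desc)) "" else desc)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" level="3" version="1" ',
                   'xmlns:fbc="%s" fbc:required="false">'), .sbml_ns, .fbc_ns),
    sprintf('  <model id="model" name="%s" fbc:strict="true">',
            esc(model$description)))

  comps <- unique(model$metabolites$compartment)
  lines <- c(lines, "    <listOfCompartments>",
             sprintf('      <compartment id="%s" constant="true"/>', esc(comps)),
             "    </listOfCompartments>")

  sp_lines <- purrr::pmap_chr(model$metabolites, function(id, name, compartment,
                                                          formula, charge) {
    extra <- ""
    if (!is.na(formula)) extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', formula))
    if (!is.na(charge)) extra <- paste0(extra, sprintf(' fbc:charge="%d"', charge))
    sprintf(paste0('      <species id="%s" name="%s" compartment="%s" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"%s/>'), esc(id), esc(name), esc(compartment), extra)
  })
  lines <- c(lines, "    <listOfSpecies>", sp_lines, "    </listOfSpecies>")

  bounds <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  bid <- function(v) sprintf("bnd_%d", match(v, bounds))
  lines <- c(lines, "    <listOfParameters>",
             sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                     bid(bounds), num(bounds)),
             "    </listOfParameters>")

  sto_by_rxn <- split(model$stoichiometry, model$stoichiometry$reaction)
  rx_lines <- unlist(purrr::pmap(model$reactions, function(id, name, lower_bound,
                                                           upper_bound, kind) {
    rows <- sto_by_rxn[[id]]
    reac <- rows[rows$coefficient < 0, ]
    prod <- rows[rows$coefficient > 0, ]
    side <- function(tag, d) {
      if (is.null(d) || nrow(d) == 0L) return(character())
      c(sprintf("        <%s>", tag),
        sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                esc(d$metabolite), num(abs(d$coefficient))),
        sprintf("        </%s>", tag))
    }
    c(sprintf(paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false" ',
                     'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
              esc(id), esc(name), if (lower_bound < 0) "true" else "false",
              bid(lower_bound), bid(upper_bound)),
      '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf("          <p>kind: %s</p>", kind),
      "        </body></notes>",
      side("listOfReactants", reac),
      side("listOfProducts", prod),
      "      </reaction>")
  }))
  lines <- c(lines, "    <listOfReactions>", rx_lines, "    </listOfReactions>",
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             "        <fbc:listOfFluxObjectives>",
             sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                     esc(model$objective)),
             "        </fbc:listOfFluxObjectives>",
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>",
             "  </model>", "</sbml>")
  writeLines(lines, path)
}
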