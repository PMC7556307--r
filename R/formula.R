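#' Parse an elemental formula string
#'
#' Parses a Hill-style chemical formula such as `"C40H56"` or `"C13H20O"`
#' into a named integer vector of element counts. An element symbol with no
#' trailing digits counts once, so `"H2O"` gives `c(H = 2, O = 1)`.
#' Parentheses and isotope notation are not supported; formulas in
#' constraint-based model files are flat element/count strings.
#'
#' @param text A single formula string, e.g. `"C40H56"`.
#' @return Named integer vector mapping element symbols to counts (>= 1).
#' @examples
#' parse_formula("C40H56")
#' parse_formula("C13H20O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    stop("empty formula string", call. = FALSE)
  }
  tokens <- stringr::str_match_all(text, "([A-Z][a-z]?)([0-9]*)")[[1]]
  tokens <- tokens[nzchar(tokens[, 1]), , drop = FALSE]
  consumed <- sum(nchar(tokens[, 1]))
  if (consumed != nchar(text)) {
    # locate first character not covered by a valid token
    covered <- paste0(tokens[, 1], collapse = "")
    pos <- 1L
    while (pos <= nchar(text) && pos <= nchar(covered) &&
           substr(text, pos, pos) == substr(covered, pos, pos)) {
      pos <- pos + 1L
    }
    stop(sprintf("malformed formula '%s': unexpected character '%s' at position %d",
                 text, substr(text, pos, pos), pos), call. = FALSE)
  }
  counts <- ifelse(nzchar(tokens[, 3]), suppressWarnings(as.integer(tokens[, 3])), 1L)
  if (anyNA(counts) || any(counts < 1L)) {
    stop(sprintf("malformed formula '%s': element counts must be positive integers", text),
         call. = FALSE)
  }
  out <- stats::setNames(counts, tokens[, 2])
  # merge repeated symbols (rare, but legal in some model files)
  if (anyDuplicated(names(out))) {
    out <- vapply(split(out, names(out)), sum, integer(1))
  }
  out
}

#' Render an element-count map back to a formula string
#'
#' Inverse of [parse_formula()]; elements are emitted in Hill order
#' (C first, then H, then the rest alphabetically).
#'
#' @param counts Named integer vector of element counts.
#' @return A single formula string.
#' @export
format_formula <- function(counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  counts <- counts[counts > 0]
  syms <- names(counts)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts == 1, "", counts), collapse = "")
}

#' Carbon-atom count of a metabolite or formula
#'
#' Returns the number of carbon atoms in a formula. Formulas without carbon
#' (e.g. water) return 0; a *missing* formula is an error, never a silent
#' zero, because downstream carbon accounting would be corrupted.
#'
#' @param x A formula string, a named count vector from [parse_formula()],
#'   or a one-row metabolite tibble with a `formula` column.
#' @return Non-negative integer count of carbon atoms.
#' @examples
#' carbon_count("C40H56") # beta-carotene, 40
#' carbon_count("H2O")    # 0
#' @export
carbon_count <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, "formula" %in% names(x))
    x <- x$formula
  }
  if (is.character(x)) {
    if (length(x) != 1L || is.na(x) || !nzchar(x)) {
      stop("no formula: metabolite has no elemental formula assigned", call. = FALSE)
    }
    x <- parse_formula(x)
  }
  stopifnot(is.numeric(x), !is.null(names(x)))
  as.integer(if ("C" %in% names(x)) x[["C"]] else 0L)
}

# Standard atomic weights (IUPAC 2021 abridged values), g/mol.
.atomic_weights <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Ar = 39.95, Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933,
  Ni = 58.693, Cu = 63.546, Zn = 65.38, Se = 78.971, Mo = 95.95, I = 126.90
)

#' Molar mass of an elemental formula
#'
#' Sum of count times standard atomic weight over the elements of the
#' formula; used to convert measured yields (mg/gDCW) and titers (mg/L)
#' into molar specific rates.
#'
#' @param formula A formula string or named count vector.
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass("C13H20O") # beta-ionone, ~192.3
#' @export
molar_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(is.numeric(formula), !is.null(names(formula)))
  if (length(formula) == 0L) stop("empty formula", call. = FALSE)
  unknown <- setdiff(names(formula), names(.atomic_weights))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  sum(formula * .atomic_weights[names(formula)])
}
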