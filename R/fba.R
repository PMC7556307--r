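#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# ---- solver backend --------------------------------------------------------
#
# The backend contract is a function
#   function(objective, S, lb, ub, maximize) ->
#     list(status = "optimal"|"infeasible"|"failed", objective = num, x = num[n])
# solving  max/min objective'v  s.t.  S v = 0,  lb <= v <= ub.
# The default backend is the package's own bounded-variable two-phase
# simplex (R/simplex.R); any LP routine honouring the contract can be
# swapped in via options(ionoflux.solver = <fn>).

#' Default LP backend (bounded-variable two-phase simplex)
#'
#' Solves `max/min c'v` subject to `S v = 0` and box bounds with the
#' package's dense bounded-variable primal simplex (Bland's rule, so
#' termination is guaranteed). All bounds must be finite (use
#' [default_bound()] for practically unbounded fluxes), so the feasible
#' set is a polytope and the LP can never be unbounded.
#'
#' @param objective Numeric objective coefficients, length `ncol(S)`.
#' @param S Dense stoichiometric (equality-constraint) matrix.
#' @param lb,ub Finite lower/upper bounds on the variables.
#' @param maximize Logical.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"failed"`),
#'   `objective`, `x`.
#' @keywords internal
#' @export
solve_lp_simplex <- function(objective, S, lb, ub, maximize = TRUE) {
  n <- length(objective)
  stopifnot(ncol(S) == n, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("LP backend requires finite bounds; clamp unbounded fluxes to default_bound()",
         call. = FALSE)
  }
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  simplex_bounded(objective, S, rep(0, nrow(S)), lb, ub, maximize = maximize)
}

active_solver <- function() {
  getOption("ionoflux.solver", solve_lp_simplex)
}

# Feasibility post-check: a solution violating mass balance or bounds beyond
# tolerance is rejected (status "failed"), never silently patched.
check_solution <- function(S, lb, ub, x, rel_tol = 1e-6, abs_tol = 1e-9) {
  scale <- max(1, max(abs(x)))
  tol <- abs_tol + rel_tol * scale
  resid <- max(abs(S %*% x))
  bound_viol <- max(0, max(lb - x), max(x - ub))
  list(ok = resid <= tol && bound_viol <= tol, residual = resid,
       bound_violation = bound_viol, tolerance = tol)
}

new_flux_solution <- function(status, objective_value, fluxes, tolerance,
                              objective_reaction, direction,
                              parsimonious = FALSE, diagnostics = NULL) {
  structure(
    list(status = status, objective_value = objective_value, fluxes = fluxes,
         tolerance = tolerance, objective_reaction = objective_reaction,
         direction = direction, parsimonious = parsimonious,
         diagnostics = diagnostics),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> %s %s: status %s, objective %s%s\n",
              x$direction, x$objective_reaction, x$status,
              format(x$objective_value, digits = 6),
              if (x$parsimonious) " (parsimonious)" else ""))
  invisible(x)
}

#' Tidy a flux solution into a tibble of reaction fluxes
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return Tibble with columns `reaction`, `flux` (mmol/gDCW/h).
#' @method tidy flux_solution
#' @export
tidy.flux_solution <- function(x, ...) {
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' One-row summary of a flux solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return One-row tibble: `status`, `objective_value`, `objective_reaction`,
#'   `direction`, `parsimonious`, `tolerance`.
#' @method glance flux_solution
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective_value = x$objective_value,
                 objective_reaction = x$objective_reaction,
                 direction = x$direction, parsimonious = x$parsimonious,
                 tolerance = x$tolerance)
}

# ---- FBA operations --------------------------------------------------------

#' Flux balance analysis: optimize one flux
#'
#' Maximizes or minimizes the flux through one reaction subject to
#' steady-state mass balance `S v = 0` and the model's flux bounds — the
#' linear program at the heart of every interrogation procedure. Bounds of
#' magnitude above [default_bound()] are clamped so the polytope is compact.
#'
#' @param model A [metabolic_model()].
#' @param objective Reaction id to optimize; defaults to the model's
#'   objective reaction.
#' @param direction `"max"` or `"min"`.
#' @return A `flux_solution` with `status` (`"optimal"`, `"infeasible"`, or
#'   `"failed"` for solver breakdown, kept distinct from infeasibility),
#'   `objective_value`, and the full flux vector. On `"optimal"` the
#'   solution is verified against mass balance and bounds at relative
#'   tolerance 1e-6 / absolute 1e-9.
#' @examples
#' m <- build_toy_model()
#' sol <- optimize_flux(m)          # max growth
#' glance(sol)
#' @export
optimize_flux <- function(model, objective = NULL, direction = c("max", "min")) {
  direction <- match.arg(direction)
  objective <- objective %||% model$objective
  i <- match(objective, model$reactions$id)
  if (is.na(i)) stop(sprintf("no reaction '%s' in model", objective), call. = FALSE)

  S <- stoichiometric_matrix(model)
  lb <- pmax(model$reactions$lower_bound, -default_bound())
  ub <- pmin(model$reactions$upper_bound, default_bound())
  cvec <- rep(0, nrow(model$reactions))
  cvec[i] <- 1

  res <- active_solver()(cvec, S, lb, ub, maximize = direction == "max")
  if (res$status != "optimal") {
    diag <- if (res$status == "infeasible") {
      tight <- model$reactions[model$reactions$lower_bound > -default_bound() |
                               model$reactions$upper_bound < default_bound(), ]
      sprintf("constraint set infeasible; %d non-default bounds in play", nrow(tight))
    } else "LP solver failure (not proven infeasible)"
    return(new_flux_solution(res$status, NA_real_,
                             stats::setNames(rep(NA_real_, ncol(S)), colnames(S)),
                             NA_real_, objective, direction, diagnostics = diag))
  }
  chk <- check_solution(S, lb, ub, res$x)
  if (!chk$ok) {
    return(new_flux_solution(
      "failed", NA_real_, stats::setNames(res$x, colnames(S)), chk$tolerance,
      objective, direction,
      diagnostics = sprintf("solution rejected: mass-balance residual %.3g, bound violation %.3g exceed tolerance %.3g",
                            chk$residual, chk$bound_violation, chk$tolerance)))
  }
  new_flux_solution("optimal", res$x[i], stats::setNames(res$x, colnames(S)),
                    chk$tolerance, objective, direction)
}

#' Fix a flux to a measured value (pure transformation)
#'
#' Replaces the bounds of `reaction` by the interval
#' `value * (1 - tol_frac)` to `value * (1 + tol_frac)`, oriented so the
#' lower bound stays below the upper bound for negative values (uptake
#' fluxes). This is how measured rates become model constraints.
#'
#' @param model A [metabolic_model()].
#' @param reaction Reaction id.
#' @param value Measured flux (mmol/gDCW/h; 1/h for the biomass reaction).
#' @param tol_frac Fractional half-width of the interval (0 = equality).
#' @return A new model; the input is unmodified. If `value` lies outside
#'   the reaction's current structural bounds a warning flags the likely
#'   infeasibility at constraint time.
#' @export
fix_flux <- function(model, reaction, value, tol_frac = 0) {
  stopifnot(tol_frac >= 0)
  i <- match(reaction, model$reactions$id)
  if (is.na(i)) stop(sprintf("no reaction '%s' in model", reaction), call. = FALSE)
  if (value < model$reactions$lower_bound[i] || value > model$reactions$upper_bound[i]) {
    warning(sprintf(
      "fix_flux: value %g for '%s' lies outside structural bounds [%g, %g]; model will be infeasible",
      value, reaction, model$reactions$lower_bound[i], model$reactions$upper_bound[i]),
      call. = FALSE)
  }
  ends <- sort(c(value * (1 - tol_frac), value * (1 + tol_frac)))
  model$reactions$lower_bound[i] <- ends[1]
  model$reactions$upper_bound[i] <- ends[2]
  model
}

#' Parsimonious tie-break: minimize total flux at a fixed objective
#'
#' FBA optima are typically degenerate. To make flux-derived statistics
#' (carbon-recovery numerators, the C14:ionone ratio) unique and
#' reproducible, this re-solves with the objective flux pinned to its
#' optimal value and minimizes the sum of absolute fluxes (reversible
#' reactions split into nonnegative forward/backward parts) — the pFBA
#' tie-break.
#'
#' @param model A [metabolic_model()].
#' @param reaction Objective reaction id whose value is pinned.
#' @param value The previously computed optimal value of that flux.
#' @return A `flux_solution` with `parsimonious = TRUE`; `objective_value`
#'   is the retained flux through `reaction` (within tolerance of `value`),
#'   and `diagnostics$total_flux` carries the minimized sum of absolute
#'   fluxes.
#' @export
minimize_total_flux <- function(model, reaction, value) {
  i <- match(reaction, model$reactions$id)
  if (is.na(i)) stop(sprintf("no reaction '%s' in model", reaction), call. = FALSE)
  tol_abs <- 1e-9 + 1e-8 * abs(value)
  model <- set_bounds(model, reaction,
                      lower = max(model$reactions$lower_bound[i], value - tol_abs),
                      upper = min(model$reactions$upper_bound[i], value + tol_abs))
  # orient in case the clip inverted the interval (value at a bound)
  ii <- match(reaction, model$reactions$id)
  if (model$reactions$lower_bound[ii] > model$reactions$upper_bound[ii]) {
    model$reactions$lower_bound[ii] <- value - tol_abs
    model$reactions$upper_bound[ii] <- value + tol_abs
  }

  S <- stoichiometric_matrix(model)
  lb <- pmax(model$reactions$lower_bound, -default_bound())
  ub <- pmin(model$reactions$upper_bound, default_bound())
  n <- ncol(S)
  # split v = p - q, p, q >= 0
  lb_p <- pmax(lb, 0); ub_p <- pmax(ub, 0)
  lb_q <- pmax(-ub, 0); ub_q <- pmax(-lb, 0)
  S2 <- cbind(S, -S)
  res <- active_solver()(rep(1, 2 * n), S2, c(lb_p, lb_q), c(ub_p, ub_q),
                         maximize = FALSE)
  if (res$status != "optimal") {
    return(new_flux_solution(res$status, NA_real_,
                             stats::setNames(rep(NA_real_, n), colnames(S)),
                             NA_real_, reaction, "parsimony",
                             diagnostics = "infeasible after pinning objective value"))
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  chk <- check_solution(S, lb, ub, v)
  if (!chk$ok) {
    return(new_flux_solution("failed", NA_real_, stats::setNames(v, colnames(S)),
                             chk$tolerance, reaction, "parsimony",
                             diagnostics = "parsimonious solution rejected by post-check"))
  }
  new_flux_solution("optimal", v[i], stats::setNames(v, colnames(S)),
                    chk$tolerance, reaction, "parsimony", parsimonious = TRUE,
                    diagnostics = list(total_flux = sum(abs(v))))
}

#' Optimize with parsimonious tie-break
#'
#' Convenience wrapper: [optimize_flux()] followed by
#' [minimize_total_flux()] at the optimum.
#'
#' @inheritParams optimize_flux
#' @return A parsimonious `flux_solution` (or the failed/infeasible plain
#'   solution if optimization did not succeed).
#' @export
pfba <- function(model, objective = NULL, direction = c("max", "min")) {
  direction <- match.arg(direction)
  objective <- objective %||% model$objective
  sol <- optimize_flux(model, objective, direction)
  if (sol$status != "optimal") return(sol)
  psol <- minimize_total_flux(model, objective, sol$objective_value)
  if (psol$status != "optimal") return(sol)  # keep the verified plain optimum
  psol$direction <- direction
  psol
}
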