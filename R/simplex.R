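# Bounded-variable two-phase primal simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,  l <= x <= u   (all bounds finite).
#
# Written for the small, dense LPs of constraint-based toy/contextualized
# models (tens to a few hundred variables). Entering and leaving variables
# are chosen by Bland's rule, which guarantees finite termination without
# cycling; the basis system is re-solved from scratch each iteration, which
# is numerically self-correcting at these problem sizes. Phase 1 drives a
# full set of artificial variables to zero (infeasibility when it cannot);
# phase 2 optimizes the true objective with the artificials pinned at zero.

simplex_bounded <- function(cvec, A, b, lb, ub, maximize = TRUE,
                            tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  if (!maximize) cvec <- -cvec

  # artificial columns: one per row, signed so the artificial starts >= 0
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)      # nonbasic start at nearer bound
  r <- b - as.numeric(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  ntot <- n + m
  lb_full <- c(lb, rep(0, m))
  ub_full <- c(ub, abs(r) + 1)                 # loose cap; phase 1 shrinks them
  xfull <- c(x, abs(r))

  basis <- n + seq_len(m)
  # status of nonbasic structural vars: TRUE = at lower bound
  at_lower <- c(abs(lb) <= abs(ub), rep(TRUE, m))

  run_phase <- function(cost, xfull, basis, at_lower, lb_full, ub_full) {
    for (iter in seq_len(max_iter)) {
      B <- Afull[, basis, drop = FALSE]
      Blu <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Blu)) {
        return(list(status = "failed", x = xfull, basis = basis,
                    at_lower = at_lower))
      }
      y <- drop(crossprod(Blu, cost[basis]))   # y = B^-T c_B
      nonbasic <- setdiff(seq_len(ntot), basis)
      entering <- 0L; enter_dir <- 0
      for (j in nonbasic) {                    # Bland: smallest eligible index
        dj <- cost[j] - sum(y * Afull[, j])
        if (at_lower[j] && dj > tol && ub_full[j] > lb_full[j]) {
          entering <- j; enter_dir <- 1; break
        }
        if (!at_lower[j] && dj < -tol && ub_full[j] > lb_full[j]) {
          entering <- j; enter_dir <- -1; break
        }
      }
      if (entering == 0L) {
        return(list(status = "optimal", x = xfull, basis = basis,
                    at_lower = at_lower))
      }
      w <- drop(Blu %*% Afull[, entering])     # basic response to entering
      # ratio test: largest step before a basic variable or the entering
      # variable itself hits a bound; ties broken by smallest variable
      # index (Bland) to preclude cycling
      t_max <- ub_full[entering] - lb_full[entering]
      leave_pos <- 0L; leave_to_lower <- TRUE
      for (k in seq_len(m)) {
        delta <- -enter_dir * w[k]             # rate of change of basic k
        if (delta < -tol) {                    # decreasing toward its lb
          tk <- (xfull[basis[k]] - lb_full[basis[k]]) / (-delta)
          to_lower <- TRUE
        } else if (delta > tol) {              # increasing toward its ub
          tk <- (ub_full[basis[k]] - xfull[basis[k]]) / delta
          to_lower <- FALSE
        } else next
        if (tk < t_max - tol) {
          t_max <- tk; leave_pos <- k; leave_to_lower <- to_lower
        } else if (tk < t_max + tol && leave_pos != 0L &&
                   basis[k] < basis[leave_pos]) {
          leave_pos <- k; leave_to_lower <- to_lower
        }
      }
      t_max <- max(t_max, 0)
      # apply the step
      xfull[entering] <- xfull[entering] + enter_dir * t_max
      xfull[basis] <- xfull[basis] - enter_dir * t_max * w
      if (leave_pos == 0L) {
        at_lower[entering] <- !at_lower[entering]   # bound flip, basis unchanged
      } else {
        leaving <- basis[leave_pos]
        xfull[leaving] <- if (leave_to_lower) lb_full[leaving] else ub_full[leaving]
        at_lower[leaving] <- leave_to_lower
        basis[leave_pos] <- entering
      }
    }
    list(status = "failed", x = xfull, basis = basis, at_lower = at_lower)
  }

  # phase 1: minimize sum of artificials (maximize the negative)
  cost1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(cost1, xfull, basis, at_lower, lb_full, ub_full)
  if (p1$status != "optimal") {
    return(list(status = "failed", objective = NA_real_, x = rep(NA_real_, n)))
  }
  art_sum <- sum(p1$x[n + seq_len(m)])
  scale1 <- max(1, max(abs(b)))
  if (art_sum > 1e-7 * scale1) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }

  # phase 2: pin artificials to zero, optimize the true objective
  ub_full[n + seq_len(m)] <- 0
  x2 <- p1$x
  x2[n + seq_len(m)] <- pmin(x2[n + seq_len(m)], 0)
  cost2 <- c(cvec, rep(0, m))
  p2 <- run_phase(cost2, x2, p1$basis, p1$at_lower, lb_full, ub_full)
  if (p2$status != "optimal") {
    return(list(status = "failed", objective = NA_real_, x = rep(NA_real_, n)))
  }
  xs <- p2$x[seq_len(n)]
  obj <- sum(cvec * xs)
  list(status = "optimal", objective = if (maximize) obj else -obj, x = xs)
}
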