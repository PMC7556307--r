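# Independent LP oracle: brute-force vertex enumeration over the polytope
# {v : S v = 0, lb <= v <= ub}. Every vertex has at least n - rank(S)
# variables at a bound; enumerate all such bound assignments, solve the
# remaining (least-squares) system, keep feasible points, and return the
# best objective. Exponential, usable only for tiny instances — which is
# the point: it shares no code with the simplex it checks.
enumerate_lp_opt <- function(cvec, S, lb, ub, maximize = TRUE, tol = 1e-7) {
  n <- length(cvec)
  r <- qr(S)$rank
  k <- n - r
  best <- NULL
  best_v <- NULL
  consider <- function(v) {
    if (any(is.na(v))) return()
    if (max(abs(S %*% v)) > tol * max(1, max(abs(v)))) return()
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    obj <- sum(cvec * v)
    if (is.null(best) || (maximize && obj > best) || (!maximize && obj < best)) {
      best <<- obj
      best_v <<- v
    }
  }
  if (k == 0L) {
    # unique solution of S v = 0 given full column rank: v = 0
    consider(rep(0, n))
  } else {
    for (fixset in utils::combn(n, k, simplify = FALSE)) {
      free <- setdiff(seq_len(n), fixset)
      Sfree <- S[, free, drop = FALSE]
      qf <- qr(Sfree)
      if (qf$rank < length(free)) next
      for (mask in 0:(2^k - 1)) {
        at_ub <- bitwAnd(mask, 2^(seq_len(k) - 1)) > 0
        vals <- ifelse(at_ub, ub[fixset], lb[fixset])
        rhs <- -S[, fixset, drop = FALSE] %*% vals
        vf <- tryCatch(qr.coef(qf, rhs), error = function(e) NULL)
        if (is.null(vf)) next
        v <- numeric(n)
        v[fixset] <- vals
        v[free] <- vf
        consider(v)
      }
    }
  }
  list(objective = best, v = best_v)
}

# Random small flux network: m metabolites, n reactions, integer
# stoichiometry, v = 0 always feasible (lb <= 0 <= ub).
random_network <- function(seed, n_max = 8L) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  m <- sample(2:max(2, n - 2), 1)
  repeat {
    S <- matrix(sample(c(-2, -1, 0, 0, 1, 2), m * n, replace = TRUE), m, n)
    if (all(colSums(abs(S)) > 0) && all(rowSums(abs(S)) > 0)) break
  }
  ub <- round(stats::runif(n, 1, 10), 1)
  lb <- ifelse(stats::runif(n) < 0.4, -round(stats::runif(n, 1, 10), 1), 0)
  cvec <- round(stats::runif(n, -1, 1), 2)
  list(S = S, lb = lb, ub = ub, cvec = cvec)
}
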