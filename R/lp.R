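# Bounded-variable two-phase primal simplex.
#
# Solves  max/min  obj'x   s.t.  A x = b,  lb <= x <= ub.
#
# No LP solver package is available in the target environment, so the
# engine lives here: a dense simplex with bounded variables, Bland's
# anti-cycling pivot rule, and artificial variables for phase 1 (which
# also absorb rank deficiency of A - a redundant mass-balance row simply
# keeps its artificial basic at zero).  Problem sizes in this package are
# small (tens of reactions), so the basis is refactorized with solve() at
# every iteration for numerical robustness rather than speed.
#
# Returns list(status, objective, x) with status one of "optimal",
# "infeasible", "unbounded".

lp_solve <- function(A, b, lb, ub, obj, maximize = TRUE,
                     tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(lb) == n, length(ub) == n,
            length(obj) == n, all(lb <= ub + 1e-12))
  if (is.null(max_iter)) max_iter <- 500L * (n + m + 10L)
  nv <- n + m

  # start structural variables at a finite bound (0 if doubly infinite)
  x0 <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  resid <- b - drop(A %*% x0)
  sgn <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m, ncol = m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  xf <- c(x0, abs(resid))
  basis <- n + seq_len(m)
  in_basis <- logical(nv); in_basis[basis] <- TRUE
  # for nonbasic variables: TRUE = sitting at lower bound
  at_lower <- c(is.finite(lb), rep(TRUE, m))

  run <- function(cvec, env) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex iteration limit reached (", max_iter, ")")
      basis <- env$basis
      B <- Afull[, basis, drop = FALSE]
      nb <- which(!env$in_basis)
      rhs <- b - Afull[, nb, drop = FALSE] %*% env$xf[nb]
      xb <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xb)) stop("singular basis in simplex (numerical failure)")
      env$xf[basis] <- drop(xb)
      y <- solve(t(B), cvec[basis])
      d <- cvec[nb] - drop(crossprod(Afull[, nb, drop = FALSE], y))
      movable <- env$ubf[nb] - env$lbf[nb] > tol
      free <- !is.finite(env$lbf[nb]) & !is.finite(env$ubf[nb])
      improving <- movable &
        ((free & abs(d) > tol) |
         (!free & env$at_lower[nb] & d > tol) |
         (!free & !env$at_lower[nb] & d < -tol))
      elig <- nb[improving]
      if (!length(elig)) return("optimal")
      q <- min(elig)                              # Bland's rule
      dq <- d[match(q, nb)]
      sigma <- if (free[match(q, nb)]) sign(dq) else
        if (env$at_lower[q]) 1 else -1
      w <- drop(solve(B, Afull[, q]))
      t_best <- env$ubf[q] - env$lbf[q]           # own bound-flip distance
      leave <- 0L; leave_to_lower <- NA
      for (i in seq_len(m)) {
        wi <- sigma * w[i]
        bi <- basis[i]
        if (wi > tol) {
          ti <- max((env$xf[bi] - env$lbf[bi]) / wi, 0)
          to_lower <- TRUE
        } else if (wi < -tol) {
          ti <- max((env$ubf[bi] - env$xf[bi]) / (-wi), 0)
          to_lower <- FALSE
        } else next
        better <- ti < t_best - 1e-12 ||
          (ti <= t_best + 1e-12 && (leave == 0L || bi < basis[leave]))
        if (better && ti <= t_best + 1e-12) {
          t_best <- min(t_best, ti); leave <- i; leave_to_lower <- to_lower
        }
      }
      if (!is.finite(t_best)) return("unbounded")
      env$xf[q] <- env$xf[q] + sigma * t_best
      env$xf[basis] <- env$xf[basis] - sigma * t_best * w
      if (leave == 0L) {
        env$at_lower[q] <- !env$at_lower[q]       # bound flip only
      } else {
        lv <- basis[leave]
        env$xf[lv] <- if (leave_to_lower) env$lbf[lv] else env$ubf[lv]
        env$at_lower[lv] <- leave_to_lower
        env$basis[leave] <- q
        env$in_basis[q] <- TRUE
        env$in_basis[lv] <- FALSE
      }
    }
  }

  env <- environment()

  # phase 1: drive artificial variables to zero
  if (any(xf[n + seq_len(m)] > tol)) {
    st <- run(c(rep(0, n), rep(-1, m)), env)
    if (st != "optimal" || sum(xf[n + seq_len(m)]) > 1e-7)
      return(list(status = "infeasible", objective = NA_real_,
                  x = rep(NA_real_, n)))
  }
  # freeze artificials for phase 2 (basic ones may remain, pinned at zero)
  ubf[n + seq_len(m)] <- 0
  xf[n + seq_len(m)] <- pmax(pmin(xf[n + seq_len(m)], 0), 0)

  cvec <- c(if (maximize) obj else -obj, rep(0, m))
  st <- run(cvec, env)
  if (st == "unbounded")
    return(list(status = "unbounded",
                objective = if (maximize) Inf else -Inf,
                x = rep(NA_real_, n)))
  x <- pmin(pmax(xf[seq_len(n)], lb), ub)         # clamp arithmetic fuzz
  list(status = "optimal", objective = sum(obj * x), x = x)
}
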