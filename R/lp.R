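# Dense bounded-variable simplex.
#
# Solves  max/min c'x  s.t.  A x = b,  lb <= x <= ub  (all bounds finite)
# by the two-phase primal simplex with explicit variable bounds and Bland's
# anti-cycling rule. Problem sizes in this package are tiny (at most a few
# hundred variables), so a dense implementation with a fresh factorization
# per pivot is both simple and fast. Written in-house because no dedicated
# LP package is available in the package's dependency set; the test suite
# verifies it against brute-force vertex enumeration on small networks.
# Redundant equality rows are tolerated: their artificial variables simply
# stay basic at zero.

lp_simplex <- function(obj, A, b, lb, ub, maximize = TRUE,
                       tol = 1e-9, max_iter = NULL) {
  n <- length(obj)
  m <- nrow(A)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stopf("lp_simplex requires finite bounds")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", x = rep(NA_real_, n),
                value = NA_real_))
  cc <- if (maximize) obj else -obj
  if (is.null(max_iter)) max_iter <- 2000L + 200L * (n + m)

  # start every structural variable at its bound nearer zero; artificials
  # absorb the residual and form the phase-1 basis
  x0 <- pmin(pmax(rep(0, n), lb), ub)
  at_ub0 <- abs(x0 - ub) < abs(x0 - lb)
  x0 <- ifelse(at_ub0, ub, lb)
  r <- b - as.numeric(A %*% x0)
  Afull <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, abs(r) + 1)
  xf <- c(x0, abs(r))
  basis <- n + seq_len(m)
  nb_at_ub <- c(at_ub0, rep(FALSE, m))

  run_phase <- function(cost, basis, xf, nb_at_ub) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter)
        return(list(ok = FALSE, reason = "iteration_limit"))
      Binv <- tryCatch(solve(Afull[, basis, drop = FALSE]),
                       error = function(e) NULL)
      if (is.null(Binv))
        return(list(ok = FALSE, reason = "singular_basis"))
      y <- as.numeric(crossprod(Binv, cost[basis]))
      nonbasic <- setdiff(seq_along(cost), basis)
      d <- cost[nonbasic] -
        as.numeric(crossprod(Afull[, nonbasic, drop = FALSE], y))
      movable <- ubf[nonbasic] - lbf[nonbasic] > tol
      elig <- nonbasic[movable &
                         ((d > tol & !nb_at_ub[nonbasic]) |
                          (d < -tol & nb_at_ub[nonbasic]))]
      if (length(elig) == 0)
        return(list(ok = TRUE, basis = basis, xf = xf, nb_at_ub = nb_at_ub))
      j <- min(elig)                       # Bland's rule
      sigma <- if (nb_at_ub[j]) -1 else 1
      w <- as.numeric(Binv %*% Afull[, j])
      t_best <- ubf[j] - lbf[j]            # bound-to-bound flip
      leave <- 0L; leave_to <- NA_character_
      for (k in seq_len(m)) {
        wk <- sigma * w[k]
        tk <- if (wk > tol) (xf[basis[k]] - lbf[basis[k]]) / wk
              else if (wk < -tol) (ubf[basis[k]] - xf[basis[k]]) / (-wk)
              else next
        to <- if (wk > tol) "lb" else "ub"
        if (tk < t_best - tol ||
            (tk < t_best + tol && leave != 0L && basis[k] < basis[leave])) {
          t_best <- tk; leave <- k; leave_to <- to
        } else if (leave == 0L && tk < t_best + tol) {
          t_best <- min(t_best, tk); leave <- k; leave_to <- to
        }
      }
      t_best <- max(t_best, 0)
      xf[j] <- xf[j] + sigma * t_best
      xf[basis] <- xf[basis] - sigma * t_best * w
      if (leave == 0L) {
        nb_at_ub[j] <- !nb_at_ub[j]
      } else {
        out_var <- basis[leave]
        xf[out_var] <- if (leave_to == "lb") lbf[out_var] else ubf[out_var]
        nb_at_ub[out_var] <- leave_to == "ub"
        basis[leave] <- j
      }
    }
  }

  p1 <- run_phase(c(rep(0, n), rep(-1, m)), basis, xf, nb_at_ub)
  if (!p1$ok)
    return(list(status = p1$reason, x = rep(NA_real_, n), value = NA_real_))
  if (sum(p1$xf[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible", x = rep(NA_real_, n),
                value = NA_real_))
  # pin artificials at zero for phase 2 (they may remain basic at zero when
  # equality rows are linearly dependent)
  lbf[n + seq_len(m)] <- 0
  ubf[n + seq_len(m)] <- 0
  p1$xf[n + seq_len(m)] <- 0
  p2 <- run_phase(c(cc, rep(0, m)), p1$basis, p1$xf, p1$nb_at_ub)
  if (!p2$ok)
    return(list(status = p2$reason, x = rep(NA_real_, n), value = NA_real_))
  xs <- pmin(pmax(p2$xf[seq_len(n)], lb), ub)
  list(status = "optimal", x = xs, value = sum(obj * xs))
}
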