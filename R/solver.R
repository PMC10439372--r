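## Projected augmented-Lagrangian solver for the stability-constrained
## static optimization problem. Box bounds are handled natively by
## L-BFGS-B; linear equality constraints (moment equilibrium) and the
## smooth scalar inequality (glenoid stability margin) enter through
## Powell-Hestenes-Rockafellar augmented-Lagrangian terms with multiplier
## updates and penalty escalation. Deterministic: fixed zero starting
## point, fixed tolerances, no randomness.

## minimize fn(x) s.t. Aeq x = beq, g(x) >= 0 (optional), lower <= x <= upper
## fn/gr: objective and gradient; gfun returns list(value, grad).
##
## Internally the variables are rescaled to the unit box and the equality
## rows to unit norm; a feasibility-first phase (deterministic multi-start
## least-squares on the constraint violations) supplies the warm start.
al_solve <- function(fn, gr, x0, lower, upper, Aeq = NULL, beq = NULL,
                     gfun = NULL, tol_eq = 1e-8, tol_in = 1e-8,
                     mu0 = 10, mu_max = 1e12, max_outer = 60L) {
  n <- length(x0)
  has_eq <- !is.null(Aeq)
  has_in <- !is.null(gfun)
  scale <- pmax(upper - lower, 1e-12)

  ## scaled problem: x = lower + scale * s, s in [0, 1]^n
  to_x <- function(s) lower + scale * s
  fn_s <- function(s) fn(to_x(s))
  gr_s <- function(s) gr(to_x(s)) * scale
  if (has_eq) {
    As <- sweep(Aeq, 2, scale, `*`)
    row_sc <- pmax(sqrt(rowSums(As^2)), 1e-12)
    As <- As / row_sc
    bs <- (beq - as.numeric(Aeq %*% lower)) / row_sc
  }
  gfun_s <- if (has_in) function(s) {
    gv <- gfun(to_x(s))
    list(value = gv$value, grad = gv$grad * scale)
  } else NULL
  ## inequality scale: bring margins (N) to O(1)
  g_sc <- if (has_in) max(1, abs(gfun(to_x(rep(0.5, n)))$value)) else 1

  eq_res <- function(s) if (has_eq) max(abs(as.numeric(As %*% s - bs)) * row_sc) else 0

  ## phase 0: feasibility-first warm start
  feas_obj <- function(s) {
    v <- 0
    if (has_eq) { cc <- as.numeric(As %*% s - bs); v <- v + sum(cc * cc) }
    if (has_in) { gv <- gfun_s(s)$value / g_sc; v <- v + max(0, -gv)^2 }
    v
  }
  feas_gr <- function(s) {
    g <- numeric(n)
    if (has_eq) { cc <- as.numeric(As %*% s - bs); g <- g + 2 * as.numeric(crossprod(As, cc)) }
    if (has_in) {
      gv <- gfun_s(s)
      h <- max(0, -gv$value / g_sc)
      if (h > 0) g <- g - 2 * h * gv$grad / g_sc
    }
    g
  }
  s_start <- (x0 - lower) / scale
  starts <- list(s_start, rep(0.25, n), rep(0.05, n))
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, feas_obj, feas_gr, method = "L-BFGS-B",
                      lower = rep(0, n), upper = rep(1, n),
                      control = list(maxit = 500, factr = 1e3))
    if (is.null(best) || o$value < best$value) best <- o
    if (best$value < 1e-16) break
  }
  s <- best$par

  lambda <- if (has_eq) numeric(nrow(Aeq)) else numeric(0)
  nu <- 0
  mu <- mu0
  prev_viol <- Inf
  converged <- FALSE
  iters <- 0L

  lag <- function(s) {
    v <- fn_s(s)
    if (has_eq) {
      cc <- as.numeric(As %*% s - bs)
      v <- v + sum(lambda * cc) + 0.5 * mu * sum(cc * cc)
    }
    if (has_in) {
      gv <- gfun_s(s)$value / g_sc
      t <- max(0, nu - mu * gv)
      v <- v + (t * t - nu * nu) / (2 * mu)
    }
    v
  }
  lag_gr <- function(s) {
    g <- gr_s(s)
    if (has_eq) {
      cc <- as.numeric(As %*% s - bs)
      g <- g + as.numeric(crossprod(As, lambda + mu * cc))
    }
    if (has_in) {
      gv <- gfun_s(s)
      t <- max(0, nu - mu * gv$value / g_sc)
      if (t > 0) g <- g - t * gv$grad / g_sc
    }
    g
  }

  for (k in seq_len(max_outer)) {
    iters <- k
    opt <- stats::optim(s, lag, lag_gr, method = "L-BFGS-B",
                        lower = rep(0, n), upper = rep(1, n),
                        control = list(maxit = 500, factr = 1e3, pgtol = 1e-12))
    s <- opt$par
    cc <- if (has_eq) as.numeric(As %*% s - bs) else 0
    gv <- if (has_in) gfun_s(s)$value / g_sc else Inf
    viol <- max(eq_res(s), max(0, -gv) * g_sc)
    if (viol <= min(tol_eq, tol_in)) {
      converged <- TRUE
      break
    }
    if (has_eq) lambda <- lambda + mu * cc
    if (has_in) nu <- max(0, nu - mu * gv)
    if (viol > 0.5 * prev_viol) mu <- min(mu * 10, mu_max)
    prev_viol <- viol
  }

  x <- to_x(s)
  gv <- if (has_in) gfun(x)$value else Inf
  list(par = x, objective = fn(x),
       eq_residual = if (has_eq) max(abs(as.numeric(Aeq %*% x - beq))) else 0,
       ineq_violation = if (has_in) max(0, -gv) else 0,
       converged = converged, outer_iterations = iters)
}
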