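# Nelder-Mead simplex minimizer with fminsearch-style moves and termination:
# iteration stops when the simplex parameter spread is below `tol_x` AND the
# function-value spread is below `tol_f` (both absolute), or when `max_eval`
# function evaluations are exceeded. The initial simplex perturbs each
# coordinate by 5% of its value with a floor of `init_step` (the classic 5% /
# 0.00025 rule produces a micro-simplex that cannot travel on weak-gradient
# objectives such as NMI; 0.5 mm / 0.5 deg is a sensible characteristic
# scale for rigid head motion).
nelder_mead <- function(fn, x0, tol_x = 1e-4, tol_f = 1e-4,
                        max_eval = 200 * length(x0), init_step = 0.5) {
  n <- length(x0)
  rho <- 1; chi <- 2; gam <- 0.5; sig <- 0.5
  simplex <- matrix(rep(x0, n + 1), nrow = n)
  for (i in seq_len(n)) {
    simplex[i, i + 1] <- x0[i] + max(0.05 * abs(x0[i]), init_step)
  }
  nev <- 0L
  evalf <- function(x) { nev <<- nev + 1L; fn(x) }
  fv <- apply(simplex, 2L, evalf)
  repeat {
    ord <- order(fv)
    fv <- fv[ord]; simplex <- simplex[, ord, drop = FALSE]
    if ((max(abs(fv[-1] - fv[1])) <= tol_f &&
         max(abs(simplex[, -1, drop = FALSE] - simplex[, 1])) <= tol_x) ||
        nev >= max_eval) break
    xbar <- rowMeans(simplex[, 1:n, drop = FALSE])
    xr <- xbar + rho * (xbar - simplex[, n + 1])
    fr <- evalf(xr)
    if (fr < fv[1]) {                       # try expansion
      xe <- xbar + rho * chi * (xbar - simplex[, n + 1])
      fe <- evalf(xe)
      if (fe < fr) { simplex[, n + 1] <- xe; fv[n + 1] <- fe }
      else { simplex[, n + 1] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {                # accept reflection
      simplex[, n + 1] <- xr; fv[n + 1] <- fr
    } else {
      if (fr < fv[n + 1]) {                 # outside contraction
        xc <- xbar + gam * rho * (xbar - simplex[, n + 1])
        fc <- evalf(xc)
        shrink <- fc > fr
        if (!shrink) { simplex[, n + 1] <- xc; fv[n + 1] <- fc }
      } else {                              # inside contraction
        xc <- xbar - gam * (xbar - simplex[, n + 1])
        fc <- evalf(xc)
        shrink <- fc >= fv[n + 1]
        if (!shrink) { simplex[, n + 1] <- xc; fv[n + 1] <- fc }
      }
      if (shrink) {
        for (j in 2:(n + 1)) {
          simplex[, j] <- simplex[, 1] + sig * (simplex[, j] - simplex[, 1])
          fv[j] <- evalf(simplex[, j])
        }
      }
    }
  }
  ord <- order(fv)
  list(par = simplex[, ord[1]], value = fv[ord[1]], evaluations = nev,
       converged = nev < max_eval)
}
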