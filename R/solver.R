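## Augmented-Lagrangian solver for linearly constrained smooth problems.
##
## minimise f(x)  subject to  Aeq x = beq,  Ain x >= bin,  lower <= x <= upper
##
## The diet problem is a diagonal quadratic with linear constraints, so an
## augmented Lagrangian with exact gradients and an L-BFGS-B inner loop
## converges in a handful of outer iterations. Constraint rows are normalised
## to unit Euclidean norm so that tolerances are comparable across nutrients
## measured in different units (kcal, mg, g, kgCO2e).

auglag_solve <- function(x0, fn, gr,
                         Aeq = NULL, beq = NULL,
                         Ain = NULL, bin = NULL,
                         lower = -Inf, upper = Inf,
                         ctol = 1e-9, max_outer = 40L,
                         inner_control = list(maxit = 500L, factr = 1e4)) {
  n <- length(x0)
  has_eq <- !is.null(Aeq) && nrow(Aeq) > 0L
  has_in <- !is.null(Ain) && nrow(Ain) > 0L

  norm_rows <- function(A, b) {
    r <- sqrt(rowSums(A^2))
    r[r == 0] <- 1
    list(A = A / r, b = b / r)
  }
  if (has_eq) {
    sc <- norm_rows(Aeq, beq); Aeq <- sc$A; beq <- sc$b
  }
  if (has_in) {
    sc <- norm_rows(Ain, bin); Ain <- sc$A; bin <- sc$b
  }

  lam <- if (has_eq) numeric(nrow(Aeq)) else numeric(0)
  mu <- if (has_in) numeric(nrow(Ain)) else numeric(0)
  rho <- 10

  lagr <- function(x) {
    val <- fn(x)
    if (has_eq) {
      h <- drop(Aeq %*% x) - beq
      val <- val - sum(lam * h) + 0.5 * rho * sum(h^2)
    }
    if (has_in) {
      g <- drop(Ain %*% x) - bin
      a <- pmax(0, mu - rho * g)
      val <- val + sum(a^2 - mu^2) / (2 * rho)
    }
    val
  }
  lagr_gr <- function(x) {
    gvec <- gr(x)
    if (has_eq) {
      h <- drop(Aeq %*% x) - beq
      gvec <- gvec + drop(crossprod(Aeq, rho * h - lam))
    }
    if (has_in) {
      g <- drop(Ain %*% x) - bin
      a <- pmax(0, mu - rho * g)
      gvec <- gvec - drop(crossprod(Ain, a))
    }
    gvec
  }

  x <- pmin(pmax(x0, lower), upper)
  viol_prev <- Inf
  viol <- Inf
  for (k in seq_len(max_outer)) {
    res <- optim(x, lagr, lagr_gr, method = "L-BFGS-B",
                 lower = lower, upper = upper, control = inner_control)
    x <- res$par
    h <- if (has_eq) drop(Aeq %*% x) - beq else numeric(0)
    g <- if (has_in) drop(Ain %*% x) - bin else numeric(0)
    viol <- max(0, abs(h), pmax(0, -g))
    if (has_eq) lam <- lam - rho * h
    if (has_in) mu <- pmax(0, mu - rho * g)
    if (viol < ctol) break
    if (viol > 0.25 * viol_prev) rho <- min(rho * 10, 1e12)
    viol_prev <- viol
  }
  list(par = x, value = fn(x), violation = viol, converged = viol < ctol)
}
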