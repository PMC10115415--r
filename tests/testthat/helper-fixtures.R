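# Shared fixtures and independent oracles used across the suite.

default_ps <- default_parameter_set()
read_commented_csv <- cyp33switch:::read_commented_csv
default_net <- build_network(default_ps)

# independent two-species equilibrium: solve (P-x)(L-x) = kd * x by bisection
oracle_complex_1to1 <- function(p, l, kd) {
  if (p == 0 || l == 0) return(0)
  f <- function(x) (p - x) * (l - x) - kd * x
  stats::uniroot(f, c(0, min(p, l)), tol = 1e-13)$root
}

# independent brute-force two-species kinetics (fixed-step RK4, no deSolve)
oracle_relax_1to1 <- function(p, l, kd, kon = 10, t_end = 20, dt = 1e-4) {
  koff <- kon * kd
  x <- 0
  deriv <- function(x) kon * (p - x) * (l - x) - koff * x
  for (i in seq_len(round(t_end / dt))) {
    k1 <- deriv(x); k2 <- deriv(x + dt / 2 * k1)
    k3 <- deriv(x + dt / 2 * k2); k4 <- deriv(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# independent per-injection ITC recomputation (bisection equilibria)
oracle_itc_heats <- function(n, kd, dH, V0, cell, syringe, inj) {
  P <- cell; L <- 0; pl_prev <- 0
  out <- numeric(length(inj))
  for (i in seq_along(inj)) {
    d <- 1 - inj[i] / V0
    P <- P * d
    L <- L * d + syringe * inj[i] / V0
    pl <- oracle_complex_1to1(n * P, L, kd)
    out[i] <- V0 * dH * (pl - pl_prev * d) * 1e-3
    pl_prev <- pl
  }
  out
}
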