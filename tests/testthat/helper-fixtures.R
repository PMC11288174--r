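# Shared fixtures: quadrature oracle for the tissue response and random
# model configurations (optionally engineered to hit the degenerate
# closed-form branches).

# Independent oracle: adaptive quadrature of the integral representation
# C_T(t) = K1 k2/(k2+k3) int_0^t e^{(k2+k3)(s-t)} C_P(s) ds
#        + K1 k3/(k2+k3) int_0^t C_P(s) ds
ct_quadrature <- function(K, cp, times) {
  kap <- K$k2 + K$k3
  vapply(times, function(tt) {
    if (tt == 0) return(0)
    i1 <- stats::integrate(function(s) exp(kap * (s - tt)) * eval_polyexp(cp, s),
                           0, tt, rel.tol = 1e-12, subdivisions = 400L)$value
    i2 <- stats::integrate(function(s) eval_polyexp(cp, s), 0, tt,
                           rel.tol = 1e-12, subdivisions = 400L)$value
    K$K1 * K$k2 / kap * i1 + K$K1 * K$k3 / kap * i2
  }, 0)
}

# Random valid (kinetics, input curve) pair; `branch` engineers a degenerate
# exponent: "mu0" puts one mu at exactly 0, "resonant" puts one mu at
# exactly -(k2+k3).
random_config <- function(seed, p = 3, branch = c("none", "mu0", "resonant")) {
  branch <- match.arg(branch)
  set.seed(seed)
  K <- kinetic_params(stats::runif(1, 0.05, 0.4),
                      stats::runif(1, 0.05, 0.4),
                      stats::runif(1, 0.02, 0.3))
  repeat {
    mus <- -stats::runif(p, 0.005, 4)
    if (branch == "mu0") mus[1] <- 0
    if (branch == "resonant") mus[1] <- -(K$k2 + K$k3)
    if (min(abs(outer(mus, mus, "-"))[upper.tri(diag(p))]) > 1e-3) break
  }
  lambdas <- stats::runif(p, 0.2, 3) * sample(c(-1, 1), p, replace = TRUE)
  list(K = K, cp = polyexp(lambdas, mus))
}

# Random kinetic parameter sets with generically distinct rates.
random_regions <- function(seed, n) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kinetic_params(stats::runif(1, 0.05, 0.4),
                   stats::runif(1, 0.05, 0.4),
                   stats::runif(1, 0.02, 0.3))
  })
}
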