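# Independent oracles used across the test files. Everything here is
# written from the model definition directly (explicit loops, numerical
# differentiation, root finding) and never calls into the package's
# vectorised stress path, so agreement is a genuine cross-check.

# Strain energy by explicit term-by-term summation over the polynomial
# orders, given the diagonal of the (unimodular) right Cauchy-Green tensor.
psi_oracle <- function(p, cdiag) {
  a_vec <- c(cos(p$beta1 * pi / 180), sin(p$beta1 * pi / 180), 0)
  g_vec <- c(cos(p$beta2 * pi / 180), sin(p$beta2 * pi / 180), 0)
  I1 <- sum(cdiag)
  I4 <- sum(a_vec^2 * cdiag)
  I6 <- sum(g_vec^2 * cdiag)
  a <- c(p$a1, p$a2, p$a3)
  cc <- c(p$c2, p$c3, p$c4)
  ee <- c(p$e2, p$e3, p$e4)
  psi <- 0
  for (i in 1:3) psi <- psi + a[i] * (I1 - 3)^i
  for (j in 2:4) psi <- psi + cc[j - 1] * (I4 - 1)^j
  for (k in 2:4) psi <- psi + ee[k - 1] * (I6 - 1)^k
  psi
}

# Richardson-extrapolated central difference of f at x.
central_diff <- function(f, x, h = 1e-5 * max(1, abs(x))) {
  d1 <- (f(x + h) - f(x - h)) / (2 * h)
  d2 <- (f(x + h / 2) - f(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

# S-tilde = 2 dPsi/dCbar (diagonal entries), by numerical differentiation
# of the summation oracle.
stilde_oracle <- function(p, cdiag) {
  vapply(1:3, function(i) {
    2 * central_diff(function(ci) {
      cd <- cdiag
      cd[i] <- ci
      psi_oracle(p, cd)
    }, cdiag[i])
  }, numeric(1))
}

# Axial second Piola-Kirchhoff stress via an explicit Lagrange multiplier:
# S(pr) = -pr * C^-1 + Stilde with Stilde from numerical differentiation;
# pr is found by solving the traction-free transverse condition S33 = 0
# with a root finder, then substituted into the axial component.
stress_oracle <- function(p, lambda, axis) {
  cdiag <- rep(1 / lambda, 3)
  cdiag[axis] <- lambda^2
  st <- stilde_oracle(p, cdiag)
  cinv <- 1 / cdiag
  s33 <- function(pr) -pr * cinv[3] + st[3]
  scale <- max(abs(st[3]), 1)
  pr <- stats::uniroot(s33,
    lower = -1e3 * scale, upper = 1e3 * scale,
    tol = 1e-12 * scale
  )$root
  -pr * cinv[axis] + st[axis]
}

# Random finite parameter sets with field-realistic magnitudes (tens of kPa
# to ~1 MPa, either sign on the higher-order terms).
rand_params <- function(seed) {
  withr::with_seed(seed, {
    material_parameters(
      a1 = runif(1, 1e4, 5e5),
      a2 = runif(1, -1e5, 1e5),
      a3 = runif(1, -5e4, 5e4),
      c2 = runif(1, 1e3, 5e5),
      c3 = runif(1, -2e5, 2e5),
      c4 = runif(1, -5e4, 5e4),
      e2 = runif(1, 1e3, 2e5),
      e3 = runif(1, -1e5, 1e5),
      e4 = runif(1, -5e4, 5e4),
      beta1 = runif(1, 0, 180),
      beta2 = runif(1, 0, 180)
    )
  })
}

# Rebuild a material_parameters object from a plain named list.
as_mp <- function(x) {
  do.call(material_parameters, as.list(x)[c(
    "a1", "a2", "a3", "c2", "c3", "c4", "e2", "e3", "e4", "beta1", "beta2"
  )])
}

# Naive double-loop normalized error (model vs experimental point lists).
normalized_error_naive <- function(model, experimental) {
  num <- 0
  den <- 0
  for (l in seq_along(model)) {
    num <- num + (experimental[l] - model[l])^2
    den <- den + experimental[l]^2
  }
  num / den
}

# Relative difference with a floor tied to the overall stress scale, so
# points where the stress crosses zero do not blow up the ratio.
rel_diff <- function(x, ref, scale) {
  abs(x - ref) / pmax(abs(ref), 1e-8 * scale)
}
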