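# Shared fixtures and independent oracles for the test suite.

shape27 <- spheroid_shape(2.7)

# Quadrature oracle for the charge offset: the exterior field of a uniformly
# polarized prolate spheroid is that of a focal-segment dipole density
# mu(z) ~ 1 - z^2/c^2, c^2 = a^2 - R^2.  The axial multipole moments of the
# equivalent line charge -mu'(z) are M1 = Int mu dz and M3 = 3 Int mu z^2 dz,
# and the matching charge pair sits at d^2 = M3 / M1.
charge_offset_oracle <- function(rho, R = 1) {
  a <- rho * R
  cf <- sqrt(a^2 - R^2)
  if (cf == 0) return(0)
  mu <- function(z) 1 - z^2 / cf^2
  m1 <- stats::integrate(mu, -cf, cf, rel.tol = 1e-12)$value
  m3 <- 3 * stats::integrate(function(z) mu(z) * z^2, -cf, cf,
                             rel.tol = 1e-12)$value
  sqrt(m3 / m1)
}

# Plain-R four-term site sum for the reduced pair energy of two particles in
# charge-pair mode (independent of the compiled path).
pair_energy_oracle <- function(x1, x2, shape, gamma) {
  d <- shape$d
  e <- 0
  for (a in c(1, -1)) for (b in c(1, -1)) {
    dd <- (x1 + c(0, 0, a * d)) - (x2 + c(0, 0, b * d))
    e <- e + a * b * 2 * gamma * shape$R / sqrt(sum(dd^2))
  }
  e
}

# Random non-overlapping two-particle configuration in a box
random_pair_state <- function(shape, box, gamma, seed) {
  set.seed(seed)
  repeat {
    x1 <- stats::runif(3) * box
    x2 <- stats::runif(3) * box
    if (contact_function(x1, x2, shape, box) > 1.05)
      return(system_state(rbind(x1, x2), shape, box, gamma = gamma))
  }
}
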