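test_that("charge offset matches the multipole quadrature oracle", {
  for (rho in c(1.5, 2, 2.7, 5)) {
    d_closed <- charge_offset(rho)
    d_quad <- charge_offset_oracle(rho)
    expect_lt(abs(d_closed - d_quad) / d_quad, 1e-6)
  }
  # a uniformly polarized sphere is a pure dipole
  expect_equal(charge_offset(1), 0)
  # frozen values from the oracle
  expect_equal(charge_offset(2.7), 1.9426786, tolerance = 1e-6)
  expect_equal(charge_offset(spheroid_shape(2, R = 0.5)), 0.67082039,
               tolerance = 1e-6)
})

test_that("shape construction validates its invariants", {
  expect_error(spheroid_shape(0.8), "rho")
  expect_error(spheroid_shape(2.7, R = -1), "R")
  sh <- spheroid_shape(3.3, R = 2)
  expect_equal(sh$a, 6.6)
  expect_lt(sh$d, sh$a)  # sites strictly inside the particle
})

test_that("overlap predicate is exact for contact and forced-overlap cases", {
  sh <- shape27
  # side-by-side exact contact
  expect_false(spheroid_overlap(c(0, 0, 0), c(2, 0, 0), sh))
  # tip-to-tip exact contact
  expect_false(spheroid_overlap(c(0, 0, 0), c(0, 0, 2 * sh$rho), sh))
  # axial separation 2R overlaps for any rho > 1 (affine map)
  expect_true(spheroid_overlap(c(0, 0, 0), c(0, 0, 2), sh))
})

test_that("contact function evaluates the affine scaled separation", {
  sh <- shape27
  expect_equal(contact_function(c(0, 0, 0), c(2, 0, 0), sh), 1.0)
  expect_equal(contact_function(c(0, 0, 0), c(0, 0, 4 * sh$rho), sh), 4.0)
  expect_equal(contact_function(c(0, 0, 0), c(1, 0, sh$rho), sh), 0.5)
  # minimum image: displacement across the boundary
  expect_equal(contact_function(c(0.5, 0, 0), c(9.5, 0, 0), sh,
                                box = c(10, 10, 10)),
               contact_function(c(0, 0, 0), c(1, 0, 0), sh))
})

test_that("overlap agrees with the sign of the contact function on random pairs", {
  sh <- shape27
  set.seed(42)
  n <- 10000
  x1 <- matrix(stats::runif(3 * n, -4, 4), ncol = 3)
  f <- contact_function(x1, c(0, 0, 0), sh)
  ov <- spheroid_overlap(x1, c(0, 0, 0), sh)
  expect_identical(ov, f < 1)
})

test_that("discrete-charge potential: antisymmetry, axis value, far field", {
  sh <- shape27
  # z = 0 plane is a node by antisymmetry
  pts0 <- cbind(stats::runif(5, 1.5, 6), stats::runif(5, -3, 3), 0)
  expect_true(all(abs(potential_discrete(pts0, sh)) < 1e-14))
  # on-axis closed form 1/(z^2 - d^2), frozen at z = 2a
  expect_equal(potential_discrete(c(0, 0, 5.4), sh),
               1 / (5.4^2 - sh$d^2), tolerance = 1e-12)
  expect_equal(potential_discrete(c(0, 0, 5.4), sh), 0.0393918,
               tolerance = 1e-5)
  # dipole asymptote R^2 / z^2
  z <- 400
  expect_equal(potential_discrete(c(0, 0, z), sh) * z^2, 1, tolerance = 1e-4)
  # z -> -z with charge flip = global sign flip
  p <- c(1.2, 0.4, 3.0)
  expect_equal(potential_discrete(p, sh),
               -potential_discrete(p * c(1, 1, -1), sh))
})

test_that("discrete potential closely tracks the exact polarized spheroid", {
  sh <- shape27
  # far field along several directions: ratio -> 1 (moments matched)
  for (u in list(c(0, 0, 1), c(1, 0, 1) / sqrt(2), c(1, 1, 2) / sqrt(6))) {
    p <- 60 * u
    expect_equal(potential_discrete(p, sh) / potential_exact(p, sh), 1,
                 tolerance = 1e-3)
  }
  # along the axis (where the representation is matched through the
  # octupole) agreement is sub-percent beyond two long axes and improves
  # monotonically outwards
  z <- c(1.4, 2, 2.5, 3, 4, 5) * sh$a
  rel_axis <- abs(potential_discrete(cbind(0, 0, z), sh) /
                    potential_exact(cbind(0, 0, z), sh) - 1)
  expect_lt(max(rel_axis[z >= 2 * sh$a]), 0.01)
  expect_true(all(diff(rel_axis) < 0))
  # over whole sample shells the two-charge representation is a coarser
  # approximation near the surface; its scale-referenced deviation
  # (relative to the shell maximum) shrinks steadily with distance
  dev_shell <- vapply(c(1.1, 1.5, 2), function(sc) {
    th <- seq(0.1, pi / 2 - 0.05, length.out = 24)
    pts <- cbind(sc * sh$R * sin(th), 0, sc * sh$a * cos(th))
    pd <- potential_discrete(pts, sh)
    pe <- potential_exact(pts, sh)
    max(abs(pd - pe)) / max(abs(pe))
  }, numeric(1))
  expect_lt(dev_shell[1], 0.12)
  expect_true(all(diff(dev_shell) < 0))
})

test_that("exact potential rejects interior points and vanishes on z = 0", {
  sh <- shape27
  expect_error(potential_exact(c(0, 0.3, 1), sh), "inside")
  expect_lt(abs(potential_exact(c(2.5, 0, 0), sh)), 1e-12)
})
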