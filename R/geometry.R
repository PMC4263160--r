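#' Prolate spheroid particle shape
#'
#' Defines the hard-particle geometry shared by every particle in the model:
#' a prolate spheroid with short semi-axis `R` (the unit of length) and long
#' semi-axis `a = rho * R` along the z axis. The field-induced polarization
#' is represented by a pair of opposite point charges at `z = +/- d` on the
#' long axis, with `d` chosen so that the charge pair reproduces the ratio of
#' the two lowest non-vanishing multipole moments (dipole and octupole) of a
#' uniformly polarized spheroid; see [charge_offset()].
#'
#' @param rho aspect ratio (long axis over short axis), `rho >= 1`.
#' @param R short semi-axis; defaults to 1 so all lengths are in units of R.
#' @return An object of class `"elltube_shape"`: a list with fields `rho`,
#'   `R`, `a` (long semi-axis) and `d` (charge offset).
#' @examples
#' sh <- spheroid_shape(rho = 2.7)
#' sh$d  # ~= 1.9427
#' @export
spheroid_shape <- function(rho, R = 1) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho < 1)
    stop("invalid shape: aspect ratio 'rho' must be a single number >= 1")
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("invalid shape: short semi-axis 'R' must be > 0")
  sh <- list(rho = rho, R = R, a = rho * R)
  sh$d <- R * sqrt(3 * (rho^2 - 1) / 5)
  class(sh) <- "elltube_shape"
  sh
}

#' @export
print.elltube_shape <- function(x, ...) {
  cat(sprintf(
    "prolate spheroid: R = %g, rho = %g (a = %g), charge offset d = %.6g\n",
    x$R, x$rho, x$a, x$d))
  invisible(x)
}

#' Charge offset of the two-point-charge polarization
#'
#' Position `d` of the two opposite point charges placed at `z = +/- d` on
#' the long axis so that the pair matches both the dipole and the octupole
#' moment of a uniformly polarized prolate spheroid. The axial multipole
#' moments of the charge pair are `M1 = 2qd` and `M3 = 2qd^3`, so matching
#' requires `d^2 = M3/M1` of the spheroid, which evaluates in closed form to
#' `d^2 = (3/5)(a^2 - R^2)`, i.e. `d = R * sqrt(3 (rho^2 - 1) / 5)`.
#'
#' A sphere (`rho = 1`) is a pure dipole and gives `d = 0`.
#'
#' @param shape a [spheroid_shape()], or a numeric aspect ratio.
#' @param R short semi-axis, used when `shape` is given as a bare aspect
#'   ratio.
#' @return The offset `d` in the same length units as `R`.
#' @export
charge_offset <- function(shape, R = 1) {
  if (is.numeric(shape)) shape <- spheroid_shape(shape, R)
  if (!inherits(shape, "elltube_shape")) stop("'shape' must be a spheroid_shape")
  shape$R * sqrt(3 * (shape$rho^2 - 1) / 5)
}

#' Contact function for parallel prolate spheroids
#'
#' For two identical spheroids with parallel long axes the affine map
#' `z -> z / rho` sends both particles to spheres of radius `R`, making the
#' overlap problem exact. The contact function is the squared scaled
#' separation relative to contact:
#' `F = (dx^2 + dy^2 + (dz/rho)^2) / (2R)^2`,
#' with `F < 1` iff the particles interpenetrate and `F = 1` at exact
#' contact. With a periodic `box` the minimum-image displacement is used.
#'
#' @param x1,x2 particle centres, numeric 3-vectors (or matrices with one row
#'   per particle for `x1` against a single `x2`).
#' @param shape a [spheroid_shape()].
#' @param box optional periodic box edge lengths (3-vector); `NULL` for open
#'   boundaries.
#' @return Dimensionless contact value(s) `F`.
#' @export
contact_function <- function(x1, x2, shape, box = NULL) {
  d <- rbind(x1) - rep(as.numeric(x2), each = NROW(rbind(x1)))
  d <- matrix(d, ncol = 3)
  if (!is.null(box)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  (d[, 1]^2 + d[, 2]^2 + (d[, 3] / shape$rho)^2) / (2 * shape$R)^2
}

#' Overlap predicate for parallel prolate spheroids
#'
#' `TRUE` iff the two spheroids interpenetrate; exact for the parallel case
#' via the affine contact criterion (see [contact_function()]). Touching
#' particles (`F = 1`) do not overlap.
#'
#' @inheritParams contact_function
#' @return Logical overlap flag(s).
#' @export
spheroid_overlap <- function(x1, x2, shape, box = NULL) {
  contact_function(x1, x2, shape, box) < 1
}

#' Dimensionless potential of the discrete-charge representation
#'
#' The normalized exterior potential `Phi* = (4 pi eps_m R^2 / 2qd) Phi` of
#' the two-point-charge representation: with charges `+q` at `(0, 0, d)` and
#' `-q` at `(0, 0, -d)`,
#' `Phi* = (R^2 / 2d) (1/|r - r_plus| - 1/|r - r_minus|)`.
#' On axis this is `R^2 / (z^2 - d^2)`, with the dipole asymptote `R^2/z^2`
#' far away.
#'
#' @param points numeric 3-vector or matrix (one point per row).
#' @param shape a [spheroid_shape()] with `rho > 1` (so `d > 0`).
#' @return `Phi*` at each point.
#' @export
potential_discrete <- function(points, shape) {
  p <- matrix(rbind(points), ncol = 3)
  d <- shape$d
  if (d <= 0) stop("discrete-charge potential undefined for a sphere (d = 0)")
  rp <- sqrt(p[, 1]^2 + p[, 2]^2 + (p[, 3] - d)^2)
  rm <- sqrt(p[, 1]^2 + p[, 2]^2 + (p[, 3] + d)^2)
  if (any(rp < 1e-12 | rm < 1e-12))
    stop("point coincides with a charge site")
  shape$R^2 / (2 * d) * (1 / rp - 1 / rm)
}

#' Exact dimensionless potential of a uniformly polarized prolate spheroid
#'
#' The exterior potential of a uniformly polarized prolate spheroid equals
#' that of a line density of point dipoles on the focal segment,
#' `mu(z) ~ 1 - z^2/c^2` for `|z| <= c`, with `c^2 = a^2 - R^2`. This
#' function evaluates that representation by quadrature, normalized so the
#' total dipole moment matches the discrete charge pair:
#' `Phi* = (R^2 / p) Int mu(z') (z - z') / |r - z' e_z|^3 dz'` with
#' `p = Int mu(z') dz'`. It serves as the independent oracle for the
#' discrete-charge approximation.
#'
#' @param points numeric 3-vector or matrix of points strictly outside the
#'   spheroid surface.
#' @param shape a [spheroid_shape()] with `rho > 1`.
#' @param rel.tol quadrature tolerance passed to [stats::integrate()].
#' @return `Phi*` at each point.
#' @export
potential_exact <- function(points, shape, rel.tol = 1e-10) {
  p <- matrix(rbind(points), ncol = 3)
  a <- shape$a; R <- shape$R
  inside <- (p[, 1]^2 + p[, 2]^2) / R^2 + p[, 3]^2 / a^2 < 1
  if (any(inside)) stop("point(s) inside the spheroid: exterior potential only")
  cfoc <- sqrt(a^2 - R^2)
  if (cfoc <= 0) stop("potential_exact requires rho > 1")
  pnorm_ <- 4 * cfoc / 3  # integral of (1 - z^2/c^2) over [-c, c]
  vapply(seq_len(nrow(p)), function(i) {
    s2 <- p[i, 1]^2 + p[i, 2]^2
    z0 <- p[i, 3]
    f <- function(zp) {
      (1 - zp^2 / cfoc^2) * (z0 - zp) / (s2 + (z0 - zp)^2)^1.5
    }
    val <- stats::integrate(f, -cfoc, cfoc, rel.tol = rel.tol,
                            subdivisions = 400L)$value
    R^2 * val / pnorm_
  }, numeric(1))
}
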