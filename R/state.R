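#' System state of the hard-spheroid charge-pair model
#'
#' Bundles the particle centres, the periodic box, the particle shape, the
#' electrostatic coupling and the interaction mode into the state object that
#' the Monte Carlo engine, the classifier and the I/O layer operate on. All
#' particles share one shape and are aligned with their long axis along z;
#' orientation is not a degree of freedom.
#'
#' @param centres numeric matrix, one particle centre per row (3 columns),
#'   in the same length units as `shape$R`.
#' @param shape a [spheroid_shape()].
#' @param box periodic box edge lengths, numeric 3-vector.
#' @param gamma dimensionless electrostatic coupling parameter, `>= 0`;
#'   `gamma = 0` is the pure hard-particle system.
#' @param mode `"charge_pair"` (the polarization model) or `"point_dipole"`
#'   (ideal-dipole control with the same moment `2qd`).
#' @param check if `TRUE`, verify that no pair of particles overlaps.
#' @return An object of class `"elltube_state"`.
#' @export
system_state <- function(centres, shape, box, gamma = 0,
                         mode = c("charge_pair", "point_dipole"),
                         check = TRUE) {
  mode <- match.arg(mode)
  centres <- as.matrix(centres)
  if (ncol(centres) != 3) stop("'centres' must have 3 columns")
  storage.mode(centres) <- "double"
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("'box' must be 3 positive edge lengths")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0)
    stop("'gamma' must be a single number >= 0")
  if (check && nrow(centres) > 1 &&
      cpp_any_overlap(centres, box, shape$R, shape$rho, 1e-12))
    stop("overlapping particles in 'centres'")
  structure(list(centres = centres, shape = shape, box = box,
                 gamma = gamma, mode = mode),
            class = "elltube_state")
}

#' @export
print.elltube_state <- function(x, ...) {
  cat(sprintf(
    "elltube state: %d spheroids (rho = %g), box %.3g x %.3g x %.3g, phi = %.4g\n",
    nrow(x$centres), x$shape$rho, x$box[1], x$box[2], x$box[3],
    volume_fraction(x)))
  cat(sprintf("  gamma = %g, mode = %s\n", x$gamma, x$mode))
  invisible(x)
}

#' Particle volume fraction of a state
#'
#' `phi = n (4/3) pi rho R^3 / V`.
#'
#' @param state an `elltube_state`.
#' @return The volume fraction.
#' @export
volume_fraction <- function(state) {
  n <- nrow(state$centres)
  vp <- 4 / 3 * pi * state$shape$rho * state$shape$R^3
  n * vp / prod(state$box)
}

#' Cubic box edge for a target volume fraction
#'
#' @param n number of particles.
#' @param shape a [spheroid_shape()].
#' @param phi target volume fraction.
#' @return Edge length of the cubic box holding `n` particles at `phi`.
#' @export
box_for_phi <- function(n, shape, phi) {
  vp <- 4 / 3 * pi * shape$rho * shape$R^3
  rep((n * vp / phi)^(1 / 3), 3)
}

#' Random overlap-free initial configuration
#'
#' Places `n` aligned spheroids uniformly in a periodic box by random
#' sequential insertion, rejecting overlapping trial positions, as used to
#' start the Monte Carlo runs.
#'
#' @param n number of particles.
#' @param shape a [spheroid_shape()].
#' @param phi volume fraction fixing a cubic box (ignored when `box` given).
#' @param seed integer seed for the insertion RNG.
#' @param gamma,mode stored in the returned state (see [system_state()]).
#' @param box optional explicit box edge lengths.
#' @param max_attempts insertion attempts per particle before giving up.
#' @return An `elltube_state` with no overlapping pair.
#' @export
init_random_config <- function(n, shape, phi, seed, gamma = 0,
                               mode = "charge_pair", box = NULL,
                               max_attempts = 100000L) {
  if (is.null(box)) box <- box_for_phi(n, shape, phi)
  centres <- cpp_init_random(as.integer(n), as.numeric(box), shape$R,
                             shape$rho, as.integer(seed),
                             as.integer(max_attempts))
  system_state(centres, shape, box, gamma = gamma, mode = mode, check = FALSE)
}
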