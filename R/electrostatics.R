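#' Reduced pair energy of two polarized spheroids
#'
#' Direct (non-periodic) site-site electrostatic energy between two
#' particles: `U* = Gamma * sum Z_i Z_j / r*_ij`, where the sum runs over
#' the four inter-particle pairs of charged sites and `r* = r / (2R)` is the
#' site separation relative to the minimum centre-to-centre distance of
#' parallel spheroids (side-by-side contact, `2R`). Intra-particle site
#' pairs are a configuration-independent constant and are excluded.
#'
#' In `"point_dipole"` mode the particles instead carry ideal z-dipoles with
#' the same moment `2qd` as the charge pair:
#' `U* = mu*^2 (1 - 3 dz^2/r^2) / r^3` with `mu*^2 = 8 Gamma R d^2`.
#'
#' @param x1,x2 particle centres (numeric 3-vectors).
#' @param shape a [spheroid_shape()].
#' @param gamma coupling parameter.
#' @param mode `"charge_pair"` or `"point_dipole"`.
#' @return Reduced energy in units of kT.
#' @export
pair_energy <- function(x1, x2, shape, gamma = 1,
                        mode = c("charge_pair", "point_dipole")) {
  mode <- match.arg(mode)
  if (sum((as.numeric(x1) - as.numeric(x2))^2) < 1e-24)
    stop("zero separation: singular site distance")
  cpp_direct_energy(rbind(as.numeric(x1), as.numeric(x2)), shape$R, shape$d,
                    gamma, if (mode == "charge_pair") 0L else 1L)
}

#' Ideal-dipole pair energy (control mode)
#'
#' Interaction of two ideal z-dipoles carrying the charge pair's moment
#' `2qd`; the large-separation limit of [pair_energy()] in charge-pair mode.
#' Parallel dipoles abreast repel; head-to-tail they attract.
#'
#' @inheritParams pair_energy
#' @export
dipole_pair_energy <- function(x1, x2, shape, gamma = 1) {
  pair_energy(x1, x2, shape, gamma, mode = "point_dipole")
}

#' Total direct energy of a finite aggregate
#'
#' Sum of [pair_energy()] over all particle pairs with open boundaries; used
#' by the lattice minimizer for finite sheet and tube aggregates.
#'
#' @param centres matrix of particle centres (one per row).
#' @inheritParams pair_energy
#' @export
total_energy_direct <- function(centres, shape, gamma = 1,
                                mode = c("charge_pair", "point_dipole")) {
  mode <- match.arg(mode)
  centres <- as.matrix(centres)
  storage.mode(centres) <- "double"
  cpp_direct_energy(centres, shape$R, shape$d, gamma,
                    if (mode == "charge_pair") 0L else 1L)
}

#' Periodic lattice-sum energy (Ewald method)
#'
#' Reduced electrostatic energy of a periodic configuration computed by
#' Ewald summation with conducting ("tinfoil") boundary conditions.
#' Intra-particle site pairs are excluded within the primary cell,
#' consistently with the direct sums; a particle still interacts with its
#' own periodic images. Cutoffs are tuned automatically from the box and the
#' `accuracy` target; the result is invariant (within the accuracy target)
#' to changes of the splitting parameter `alpha`.
#'
#' @param state an [system_state()].
#' @param accuracy relative accuracy target for the lattice sum.
#' @param alpha optional explicit Ewald splitting parameter (inverse
#'   length); used by the splitting-invariance checks.
#' @return Reduced energy in units of kT.
#' @export
ewald_energy <- function(state, accuracy = 1e-5, alpha = NULL) {
  cpp_ewald_energy(state$centres, state$box, state$shape$R, state$shape$rho,
                   state$shape$d, state$gamma,
                   if (state$mode == "charge_pair") 0L else 1L,
                   accuracy, if (is.null(alpha)) NA_real_ else alpha)
}

#' Incremental energy of a single-particle move
#'
#' Energy difference `dU*` for displacing one particle to a trial position,
#' computed incrementally exactly as inside the Monte Carlo loop (real-space
#' partial sums plus a structure-factor update); agrees with recomputing
#' [ewald_energy()] before and after the move.
#'
#' @param state an [system_state()].
#' @param i particle index (1-based).
#' @param newpos trial position, numeric 3-vector.
#' @param accuracy Ewald accuracy target.
#' @return The reduced energy difference.
#' @export
move_energy_delta <- function(state, i, newpos, accuracy = 1e-5) {
  cpp_ewald_delta(state$centres, state$box, state$shape$R, state$shape$rho,
                  state$shape$d, state$gamma,
                  if (state$mode == "charge_pair") 0L else 1L,
                  as.integer(i), as.numeric(newpos), accuracy)
}

#' Brute-force periodic image sum (test oracle)
#'
#' Direct real-space sum of the site-site Coulomb energy over a cube of
#' `(2 nshell + 1)^3` periodic images. Cubic-shell summation of a cell with
#' a net dipole moment converges to the vacuum-boundary value, which exceeds
#' the tinfoil Ewald energy by the shape term `2 pi Mz^2 / (3V)`; see
#' [dipole_shape_term()]. Intended as an independent oracle on very small
#' systems.
#'
#' @param state an [system_state()] in charge-pair mode.
#' @param nshell number of image shells per direction.
#' @export
image_sum_energy <- function(state, nshell = 8L) {
  stopifnot(state$mode == "charge_pair")
  cpp_image_shell_energy(state$centres, state$box, state$shape$R,
                         state$shape$d, state$gamma, as.integer(nshell))
}

#' Dipole shape (boundary) term of a periodic cell
#'
#' `2 pi Mz^2 / (3V)` with `Mz = N mu*` the net reduced dipole moment of the
#' cell; the difference between the vacuum-boundary (spherical or cubic
#' shell-summed) and tinfoil Ewald energies.
#'
#' @param state an [system_state()].
#' @export
dipole_shape_term <- function(state) {
  mu <- 2 * sqrt(2 * state$gamma * state$shape$R) * state$shape$d
  Mz <- nrow(state$centres) * mu
  2 * pi * Mz^2 / (3 * prod(state$box))
}
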