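#' Metropolis Monte Carlo of aligned polarized spheroids
#'
#' Propagates the state by single-particle translations in a periodic box.
#' One cycle is `N` attempted moves. A trial move displaces a uniformly
#' chosen particle by a vector drawn uniformly from a cube of half-width
#' `displacement` (default: one particle radius `R`). Moves producing a
#' hard-core overlap are rejected outright; otherwise the move is accepted
#' with the Metropolis probability `min(1, exp(-dU*))`, with `dU*` evaluated
#' incrementally from the Ewald sum. The trajectory is deterministic given
#' the seed.
#'
#' @param state an [system_state()].
#' @param cycles number of MC cycles.
#' @param seed integer RNG seed.
#' @param displacement trial-move half-width (length units of `R`).
#' @param snapshot_stride cycles between stored snapshots.
#' @param accuracy Ewald accuracy target.
#' @param zero_temperature accept only downhill moves (energy
#'   minimization); used for short inherent-structure quenches.
#' @return An object of class `"elltube_trajectory"`: snapshots with cycle
#'   index, cached energies, windowed acceptance fractions, move counters,
#'   and the final state.
#' @export
run_mc <- function(state, cycles, seed, displacement = state$shape$R,
                   snapshot_stride = 1000L, accuracy = 1e-5,
                   zero_temperature = FALSE) {
  stopifnot(cycles >= 0, displacement > 0)
  res <- cpp_mc_run(state$centres, state$box, state$shape$R, state$shape$rho,
                    state$shape$d, state$gamma,
                    if (state$mode == "charge_pair") 0L else 1L,
                    as.integer(cycles), displacement, as.integer(seed),
                    as.integer(snapshot_stride), accuracy,
                    isTRUE(zero_temperature))
  final <- system_state(res$final_centres, state$shape, state$box,
                        gamma = state$gamma, mode = state$mode, check = FALSE)
  structure(list(
    snapshots = res$snapshots,
    cycle = res$cycle,
    energy = res$energy,
    acceptance = res$acceptance,
    final_state = final,
    final_energy = res$final_energy,
    final_energy_recomputed = res$final_energy_recomputed,
    attempted = res$attempted,
    accepted = res$accepted,
    overlap_rejected = res$overlap_rejected,
    params = list(cycles = cycles, seed = seed, displacement = displacement,
                  snapshot_stride = snapshot_stride, accuracy = accuracy)),
    class = "elltube_trajectory")
}

#' @export
print.elltube_trajectory <- function(x, ...) {
  n <- nrow(x$final_state$centres)
  cat(sprintf("MC trajectory: %d particles, %d cycles, %d frames\n",
              n, x$params$cycles, length(x$cycle)))
  if (x$attempted > 0)
    cat(sprintf("  acceptance %.3f (overlap rejections %.3f), final U* = %.6g\n",
                x$accepted / x$attempted, x$overlap_rejected / x$attempted,
                x$final_energy))
  invisible(x)
}

#' Final state of a trajectory
#' @param traj an `elltube_trajectory`.
#' @export
final_state <- function(traj) traj$final_state

#' State at a stored snapshot
#' @param traj an `elltube_trajectory`.
#' @param frame frame number (1 = initial state).
#' @export
snapshot_state <- function(traj, frame) {
  st <- traj$final_state
  system_state(traj$snapshots[[frame]], st$shape, st$box,
               gamma = st$gamma, mode = st$mode, check = FALSE)
}
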