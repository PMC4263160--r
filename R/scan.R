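#' Simulate field-directed assembly and classify the outcome
#'
#' Convenience driver reproducing the simulation protocol: a random
#' overlap-free start at the requested volume fraction, a Metropolis run of
#' `cycles` cycles, and a morphology classification of the final
#' configuration.
#'
#' @param n number of particles.
#' @param gamma electrostatic coupling parameter.
#' @param cycles MC cycles.
#' @param seed integer seed (used for both insertion and the Markov chain).
#' @param shape a [spheroid_shape()].
#' @param phi volume fraction.
#' @param mode `"charge_pair"` or `"point_dipole"`.
#' @param delta classifier neighbour tolerance.
#' @param quench_cycles zero-temperature cycles run after production before
#'   classification. The label then describes the inherent structure of the
#'   final configuration rather than one thermal snapshot: a short
#'   downhill-only quench lets transient single-particle defects fall back
#'   into the aggregate wall while leaving the morphology itself untouched.
#'   Set to 0 to classify the thermal final state directly.
#' @param classify_frames number of stored late-trajectory snapshots to
#'   classify (each quenched independently); the reported morphology is
#'   the modal label over these frames, with ties broken towards the
#'   latest frame. A self-assembling finite system keeps rearranging, so
#'   the morphology of the late trajectory is a steadier observable than
#'   the single final configuration; 1 classifies the final state only.
#' @param ... further arguments passed to [run_mc()].
#' @return List with `trajectory` (the production `elltube_trajectory`),
#'   `frame_labels` (labels of each classified late frame) and
#'   `morphology` (an `elltube_morphology`; the latest frame carrying the
#'   modal label).
#' @export
simulate_assembly <- function(n, gamma, cycles, seed,
                              shape = spheroid_shape(2.7), phi = 0.06,
                              mode = "charge_pair", delta = 0.2,
                              quench_cycles = 2000L, classify_frames = 1L,
                              ...) {
  st <- init_random_config(n, shape, phi, seed = seed, gamma = gamma,
                           mode = mode)
  traj <- run_mc(st, cycles = cycles, seed = seed + 1L, ...)
  nf <- length(traj$snapshots)
  frames <- seq.int(max(1L, nf - classify_frames + 1L), nf)
  classify_one <- function(f) {
    cst <- snapshot_state(traj, f)
    if (quench_cycles > 0 && gamma > 0) {
      qt <- run_mc(cst, cycles = quench_cycles, seed = seed + 2L,
                   snapshot_stride = quench_cycles,
                   zero_temperature = TRUE)
      cst <- final_state(qt)
    }
    classify_morphology(cst, delta = delta)
  }
  morphs <- lapply(frames, classify_one)
  labels <- vapply(morphs, `[[`, character(1), "label")
  counts <- table(labels)
  modal <- names(counts)[counts == max(counts)]
  pick <- max(which(labels %in% modal))
  list(trajectory = traj,
       frame_labels = labels,
       morphology = morphs[[pick]])
}

#' Morphology scan over the coupling parameter
#'
#' Runs seed-replicated simulations for each value of `gamma` and tabulates
#' the classifier output, reproducing the coupling-parameter ladder of
#' morphologies (fluid at weak coupling, disordered compact aggregates at
#' intermediate coupling, ordered spanning sheets at strong coupling).
#'
#' @param gammas numeric vector of coupling parameters.
#' @param seeds integer vector of seeds (each combination is run).
#' @param n,cycles,shape,phi,mode,delta,... as in [simulate_assembly()].
#' @param quench_cycles defaults to 0 here: the ladder is a phase
#'   diagnostic and classifies thermal configurations. (Quenching a
#'   weakly coupled fluid would aggregate it artificially — at zero
#'   temperature any fluid of attractive particles condenses.)
#' @param verbose print one progress line per run.
#' @return A data frame with one row per (gamma, seed): the morphology
#'   `label`, `largest_fraction`, `spanning` (collapsed to a string), the
#'   final reduced energy per particle, and the run acceptance fraction.
#' @export
scan_gamma <- function(gammas, seeds, n, cycles,
                       shape = spheroid_shape(2.7), phi = 0.06,
                       mode = "charge_pair", delta = 0.2,
                       quench_cycles = 0L, verbose = FALSE, ...) {
  grid <- expand.grid(gamma = gammas, seed = seeds)
  if (nrow(grid) == 0)
    return(data.frame(gamma = numeric(0), seed = integer(0),
                      label = character(0), largest_fraction = numeric(0),
                      spanning = character(0), energy_per_particle = numeric(0),
                      acceptance = numeric(0)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$gamma[i]; s <- grid$seed[i]
    res <- tryCatch(
      simulate_assembly(n, g, cycles, s, shape = shape, phi = phi,
                        mode = mode, delta = delta,
                        quench_cycles = quench_cycles, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (verbose) message(sprintf("gamma=%g seed=%d: ERROR %s", g, s,
                                   conditionMessage(res)))
      return(data.frame(gamma = g, seed = s, label = NA_character_,
                        largest_fraction = NA_real_, spanning = NA_character_,
                        energy_per_particle = NA_real_,
                        acceptance = NA_real_))
    }
    m <- res$morphology
    tr <- res$trajectory
    if (verbose)
      message(sprintf("gamma=%g seed=%d: %s (largest %.2f)", g, s, m$label,
                      m$largest_fraction))
    data.frame(gamma = g, seed = s, label = m$label,
               largest_fraction = m$largest_fraction,
               spanning = paste(m$spanning, collapse = ""),
               energy_per_particle = tr$final_energy / n,
               acceptance = tr$accepted / max(1, tr$attempted))
  })
  do.call(rbind, rows)
}
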