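test_that("random insertion produces overlap-free states at the study densities", {
  sh <- shape27
  # dilute tube system
  st1 <- init_random_config(36, sh, 0.015, seed = 3)
  f1 <- contact_graph(st1, delta = 0)$edges
  expect_true(nrow(f1) == 0 || all(f1[, 3] >= 1))
  expect_equal(volume_fraction(st1), 0.015, tolerance = 1e-12)
  # full-density system
  st2 <- init_random_config(384, sh, 0.06, seed = 5)
  f2 <- contact_graph(st2, delta = 0)$edges
  expect_true(nrow(f2) == 0 || all(f2[, 3] >= 1))
  # single particle, trivially overlap-free
  st3 <- init_random_config(1, sh, 0.01, seed = 1)
  expect_equal(nrow(st3$centres), 1)
})

test_that("trajectories are reproducible and bookkeeping stays exact", {
  sh <- shape27
  st <- init_random_config(20, sh, 0.05, seed = 2, gamma = 4)
  t1 <- run_mc(st, cycles = 300, seed = 7, snapshot_stride = 100)
  t2 <- run_mc(st, cycles = 300, seed = 7, snapshot_stride = 100)
  expect_identical(t1$final_state$centres, t2$final_state$centres)
  expect_identical(t1$energy, t2$energy)
  # different seed diverges
  t3 <- run_mc(st, cycles = 300, seed = 8, snapshot_stride = 100)
  expect_false(identical(t1$final_state$centres, t3$final_state$centres))
  # cached vs recomputed energy
  expect_lt(abs(t1$final_energy - t1$final_energy_recomputed) /
              max(1, abs(t1$final_energy)), 1e-6)
  # zero cycles: trajectory holds only the initial state
  t0 <- run_mc(st, cycles = 0, seed = 7)
  expect_equal(length(t0$cycle), 1L)
  expect_identical(t0$snapshots[[1]], st$centres)
})

test_that("hard core is inviolable along a trajectory", {
  sh <- shape27
  st <- init_random_config(24, sh, 0.08, seed = 6, gamma = 5)
  tr <- run_mc(st, cycles = 400, seed = 3, snapshot_stride = 50)
  for (f in seq_along(tr$snapshots)) {
    ed <- contact_graph(snapshot_state(tr, f), delta = 0)$edges
    expect_true(nrow(ed) == 0 || all(ed[, 3] >= 1 - 1e-12))
  }
})

test_that("at gamma = 0 every non-overlapping trial is accepted", {
  sh <- shape27
  st <- init_random_config(30, sh, 0.06, seed = 4, gamma = 0)
  tr <- run_mc(st, cycles = 200, seed = 9)
  expect_equal(tr$accepted + tr$overlap_rejected, tr$attempted)
  expect_true(all(tr$energy == 0))
})

test_that("assembly driver reports late-trajectory modal morphology", {
  sh <- shape27
  res <- simulate_assembly(12, 2, cycles = 400, seed = 5, shape = sh,
                           phi = 0.02, snapshot_stride = 100,
                           classify_frames = 3, quench_cycles = 50)
  expect_length(res$frame_labels, 3)
  expect_true(res$morphology$label %in%
                c("fluid", "string", "compact", "sheet", "tube"))
  # the reported label is the modal one
  expect_equal(sum(res$frame_labels == res$morphology$label),
               max(table(res$frame_labels)), ignore_attr = TRUE)
  # single-frame default classifies the (quenched) final state
  res1 <- simulate_assembly(12, 2, cycles = 400, seed = 5, shape = sh,
                            phi = 0.02)
  expect_length(res1$frame_labels, 1)
})

test_that("two-particle sampling matches independent Boltzmann integration", {
  sh <- shape27
  L <- 10; gam <- 2
  box <- c(L, L, L)
  # independent oracle: quadrature of exp(-U) over the displacement octant
  ng <- 30
  gr <- (seq_len(ng) - 0.5) * (L / 2) / ng
  dg <- as.matrix(expand.grid(x = gr, y = gr, z = gr))
  s <- sqrt(dg[, 1]^2 + dg[, 2]^2 + (dg[, 3] / sh$rho)^2) / (2 * sh$R)
  feasible <- s > 1
  u <- rep(Inf, nrow(dg))
  u[feasible] <- cpp_pair_energy_map(dg[feasible, , drop = FALSE], box, sh$R,
                                     sh$rho, sh$d, gam, 0L)
  w <- exp(-(u - min(u[feasible])))
  w[!feasible] <- 0
  breaks <- c(1, 1.3, 1.8, Inf)
  bin <- cut(s, breaks, right = FALSE)
  p_oracle <- tapply(w, bin, sum) / sum(w)
  # Metropolis sampling of the same system
  cen <- rbind(c(2, 5, 5), c(8, 5, 5))
  st <- system_state(cen, sh, box, gamma = gam)
  tr <- run_mc(st, cycles = 60000, seed = 12, snapshot_stride = 10)
  dd <- t(vapply(tr$snapshots[-(1:500)], function(m) {
    dv <- m[2, ] - m[1, ]
    dv - box * round(dv / box)
  }, numeric(3)))
  s_mc <- sqrt(dd[, 1]^2 + dd[, 2]^2 + (dd[, 3] / sh$rho)^2) / (2 * sh$R)
  p_mc <- tapply(rep(1, length(s_mc)), cut(s_mc, breaks, right = FALSE),
                 sum)
  p_mc[is.na(p_mc)] <- 0
  p_mc <- p_mc / sum(p_mc)
  expect_lt(max(abs(p_mc - p_oracle)), 0.05)
})
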