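test_that("pair energy reproduces the four-term site sum", {
  sh <- shape27
  # head-to-tail contact
  e_ht <- pair_energy(c(0, 0, 0), c(0, 0, 5.4), sh, gamma = 1)
  expect_equal(e_ht, pair_energy_oracle(c(0, 0, 0), c(0, 0, 5.4), sh, 1),
               tolerance = 1e-12)
  expect_equal(e_ht, -0.7950954, tolerance = 1e-6)
  # near the staggered dimer minimum
  e_st <- pair_energy(c(0, 0, 0), c(1.0169, 0, 4.65), sh, gamma = 1)
  expect_equal(e_st, pair_energy_oracle(c(0, 0, 0), c(1.0169, 0, 4.65), sh, 1),
               tolerance = 1e-12)
  expect_equal(e_st, -0.964267, tolerance = 1e-5)
  # symmetry and decay
  expect_equal(e_ht, pair_energy(c(0, 0, 5.4), c(0, 0, 0), sh, 1))
  expect_lt(abs(pair_energy(c(0, 0, 0), c(0, 0, 500), sh, 1)), 1e-4)
})

test_that("energies scale exactly linearly in the coupling parameter", {
  sh <- shape27
  x2 <- c(1.3, 0.2, 4.1)
  e1 <- pair_energy(c(0, 0, 0), x2, sh, gamma = 1)
  expect_equal(pair_energy(c(0, 0, 0), x2, sh, gamma = 7.5), 7.5 * e1)
  st <- random_pair_state(sh, c(14, 14, 14), gamma = 1, seed = 5)
  st2 <- st; st2$gamma <- 4
  expect_equal(ewald_energy(st2), 4 * ewald_energy(st), tolerance = 1e-12)
})

test_that("total direct energy is the pairwise sum and is extensive", {
  sh <- shape27
  expect_equal(total_energy_direct(rbind(c(0, 0, 0)), sh, 1), 0)
  two <- rbind(c(0, 0, 0), c(1.0169, 0, 4.65))
  expect_equal(total_energy_direct(two, sh, 1),
               pair_energy(two[1, ], two[2, ], sh, 1))
  # three collinear head-to-tail particles: sum of the three pair energies
  three <- rbind(c(0, 0, 0), c(0, 0, 5.4), c(0, 0, 10.8))
  e_expect <- pair_energy(three[1, ], three[2, ], sh, 1) +
    pair_energy(three[2, ], three[3, ], sh, 1) +
    pair_energy(three[1, ], three[3, ], sh, 1)
  expect_equal(total_energy_direct(three, sh, 1), e_expect, tolerance = 1e-12)
})

test_that("Ewald energy of an isolated pair matches the direct sum", {
  sh <- shape27
  cen <- sweep(rbind(c(0, 0, 0), c(1.0169, 0, 4.65)), 2, c(60, 60, 60), "+")
  st <- system_state(cen, sh, c(120, 120, 120), gamma = 1)
  e_direct <- total_energy_direct(cen, sh, 1)
  # the periodic cell carries a net dipole moment, so the tinfoil Ewald
  # energy differs from the open-boundary sum by the vanishing shape term
  e_ewald <- ewald_energy(st, accuracy = 1e-6) + dipole_shape_term(st)
  expect_lt(abs(e_ewald - e_direct) / abs(e_direct), 1e-4)
})

test_that("Ewald energy is invariant to the splitting parameter", {
  sh <- shape27
  cen <- sweep(rbind(c(0, 0, 0), c(1.0169, 0, 4.65)), 2, c(7, 7, 7), "+")
  st <- system_state(cen, sh, c(15.6, 15.6, 15.6), gamma = 1)
  a0 <- 4.8 / 7.8  # converged splitting at the 1e-9 accuracy target
  e <- vapply(a0 * c(0.7, 1, 1.3), function(a)
    ewald_energy(st, accuracy = 1e-9, alpha = a), numeric(1))
  expect_lt(max(abs(e - e[2])) / abs(e[2]), 1e-6)
})

test_that("Ewald agrees with the brute-force periodic image sum", {
  sh <- shape27
  st <- system_state(rbind(c(1, 1, 1), c(2.0169, 1, 5.65)), sh, c(12, 12, 12),
                     gamma = 1)
  e_img <- image_sum_energy(st, nshell = 12)
  # cubic-shell summation converges to the vacuum-boundary value: tinfoil
  # Ewald plus the dipole shape term 2 pi Mz^2 / 3V
  e_ew <- ewald_energy(st, accuracy = 1e-7) + dipole_shape_term(st)
  expect_lt(abs(e_img - e_ew) / abs(e_img), 1e-4)
})

test_that("incremental move energies match full recomputation", {
  sh <- shape27
  st <- init_random_config(10, sh, 0.05, seed = 4, gamma = 3)
  set.seed(11)
  for (rep in 1:4) {
    i <- sample(10, 1)
    np <- st$centres[i, ] + stats::runif(3, -1, 1)
    np <- np %% st$box
    if (any(contact_function(st$centres[-i, , drop = FALSE], np, sh,
                             st$box) < 1)) next
    d_inc <- move_energy_delta(st, i, np, accuracy = 1e-7)
    cen2 <- st$centres; cen2[i, ] <- np
    st2 <- system_state(cen2, sh, st$box, gamma = 3, check = FALSE)
    d_full <- ewald_energy(st2, accuracy = 1e-7) -
      ewald_energy(st, accuracy = 1e-7)
    expect_lt(abs(d_inc - d_full) / max(abs(d_full), 1e-10), 1e-8)
    # a move and its exact reverse cancel
    d_back <- move_energy_delta(st2, i, st$centres[i, ], accuracy = 1e-7)
    expect_lt(abs(d_inc + d_back), 1e-8 * max(1, abs(d_inc)))
  }
  # null move
  expect_equal(move_energy_delta(st, 1, st$centres[1, ]), 0, tolerance = 1e-12)
})

test_that("periodic energy is invariant under global translation", {
  sh <- shape27
  st <- init_random_config(8, sh, 0.04, seed = 9, gamma = 2)
  e0 <- ewald_energy(st)
  shift <- c(3.7, -1.2, 8.9)
  st2 <- system_state(sweep(sweep(st$centres, 2, shift, "+"), 2, st$box,
                            "%%"),
                      sh, st$box, gamma = 2, check = FALSE)
  expect_lt(abs(ewald_energy(st2) - e0) / abs(e0), 1e-6)
})

test_that("ideal-dipole energies: signs and charge-pair asymptote", {
  sh <- shape27
  # parallel dipoles abreast repel at every separation
  for (r in c(2, 3, 5, 10))
    expect_gt(dipole_pair_energy(c(0, 0, 0), c(r, 0, 0), sh, 1), 0)
  # head-to-tail attraction
  expect_lt(dipole_pair_energy(c(0, 0, 0), c(0, 0, 6), sh, 1), 0)
  # charge-pair energy approaches the ideal dipole at large separation,
  # with the O((d/r)^2) octupole correction dying away
  for (u in list(c(0, 0, 1), c(1, 0, 2) / sqrt(5))) {
    ratio <- vapply(c(50, 200), function(r)
      pair_energy(c(0, 0, 0), r * u, sh, 1) /
        dipole_pair_energy(c(0, 0, 0), r * u, sh, 1), numeric(1))
    expect_equal(ratio[2], 1, tolerance = 5e-3)
    expect_lt(abs(ratio[2] - 1), abs(ratio[1] - 1))
  }
})
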