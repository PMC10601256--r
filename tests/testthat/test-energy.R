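test_that("pair_energy: LJ zero crossing, minimum, Coulomb constant", {
  p <- default_params()
  a <- list(charge = 0, sigma = 3.2, epsilon = 0.5)
  b <- list(charge = 0, sigma = 3.2, epsilon = 0.5)
  # r = sigma_ij: LJ term crosses zero
  e <- pair_energy(a, b, r = 3.2, p)
  expect_equal(e$e_lj, 0, tolerance = 1e-12)
  expect_equal(e$e_cb, 0)
  # r = 2^(1/6) sigma: LJ minimum of -epsilon for identical atoms
  e <- pair_energy(a, b, r = 2^(1 / 6) * 3.2, p)
  expect_equal(e$e_lj, -0.5, tolerance = 1e-12)
  # unit charges, no LJ, r = 10 A: the Coulomb constant over 10
  qa <- list(charge = 1, sigma = 1, epsilon = 0)
  e <- pair_energy(qa, qa, r = 10, p)
  expect_equal(e$e_cb, 138.935458, tolerance = 1e-12)
  expect_equal(e$e_lj, 0)
  # beyond cutoff: exactly zero
  e <- pair_energy(qa, qa, r = 10.01, p)
  expect_equal(e$e_cb, 0)
  expect_equal(e$e_lj, 0)
  expect_error(pair_energy(qa, qa, r = 0, p), "singularity")
  # symmetry and charge linearity
  x <- list(charge = 0.3, sigma = 3.0, epsilon = 0.2)
  y <- list(charge = -0.7, sigma = 4.0, epsilon = 0.8)
  expect_equal(pair_energy(x, y, 5, p), pair_energy(y, x, 5, p))
  x2 <- x; x2$charge <- 2 * x$charge
  expect_equal(pair_energy(x2, y, 5, p)$e_cb,
               2 * pair_energy(x, y, 5, p)$e_cb)
})

test_that("interaction energy series equals the brute-force oracle", {
  tt <- tiny_traj(L = 4L, n_frames = 3L, noise = 0.3, seed = 55L,
                  occ = occupancy_map(1:4, c(1, 0.5, 0, 1), 2L))
  traj <- tt$trajectory
  p <- default_params()
  series <- interaction_energy_series(traj, p)
  rna <- select_atoms(traj$topology, selection = "rna")
  dna <- select_atoms(traj$topology, selection = "duplex")
  for (t in 1:3) {
    oracle <- brute_energy(frame_coords(traj, t), traj$topology$atoms,
                           rna, dna)
    expect_equal(series$e_lj[t], oracle[["e_lj"]], tolerance = 1e-9)
    expect_equal(series$e_cb[t], oracle[["e_cb"]], tolerance = 1e-9)
    expect_equal(series$e_total[t], sum(oracle), tolerance = 1e-9)
  }
  # clipping to all levels is the identity
  clipped <- interaction_energy_series(traj, p, clip_levels = 1:4)
  expect_equal(clipped, series, tolerance = 1e-12)
})

test_that("level hb/cross/stack energies equal residue-pair brute force", {
  tt <- tiny_traj(L = 4L, n_frames = 2L, noise = 0.25, seed = 9L)
  traj <- tt$trajectory
  topo <- traj$topology
  p <- default_params()
  for (t in 1:2) {
    fr <- frame_coords(traj, t)
    # hb at interior levels 2, 3: (A,B) + (B,C) + (A,C) at level i
    for (i in 2:3) {
      oracle <- sum(
        brute_energy(fr, topo$atoms, res_atoms(topo, "A", i),
                     res_atoms(topo, "B", i)),
        brute_energy(fr, topo$atoms, res_atoms(topo, "B", i),
                     res_atoms(topo, "C", i)),
        brute_energy(fr, topo$atoms, res_atoms(topo, "A", i),
                     res_atoms(topo, "C", i))
      )
      expect_equal(level_hbond_energy(traj, t, i, p), oracle,
                   tolerance = 1e-9)
      # cross: B_i vs A/C at i-1 and i+1
      oracle_cross <- sum(
        brute_energy(fr, topo$atoms, res_atoms(topo, "B", i),
                     c(res_atoms(topo, "A", i - 1),
                       res_atoms(topo, "A", i + 1),
                       res_atoms(topo, "C", i - 1),
                       res_atoms(topo, "C", i + 1)))
      )
      expect_equal(level_cross_energy(traj, t, i, p), oracle_cross,
                   tolerance = 1e-9)
    }
    # stack at the single fully interior step (2, 3)
    oracle_stack <- sum(vapply(c("A", "B", "C"), function(ch) {
      sum(brute_energy(fr, topo$atoms, res_atoms(topo, ch, 2),
                       res_atoms(topo, ch, 3)))
    }, numeric(1)))
    expect_equal(level_stack_energy(traj, t, 2, p), oracle_stack,
                 tolerance = 1e-9)
  }
})

test_that("terminal-residue contributions are excluded everywhere", {
  tt <- tiny_traj(L = 6L, n_frames = 1L, noise = 0)
  expect_error(level_hbond_energy(tt$trajectory, 1, 1), "terminal")
  expect_error(level_hbond_energy(tt$trajectory, 1, 6), "terminal")
  expect_error(level_cross_energy(tt$trajectory, 1, 6), "terminal")
  expect_error(level_stack_energy(tt$trajectory, 1, 5), "step-index")
  expect_error(level_stack_energy(tt$trajectory, 1, 1), "step-index")
  prof <- level_profile(tt$trajectory, tail = 1e6)
  expect_equal(prof$level, 2:5)
  expect_true(all(!is.na(prof$e_stack[prof$level <= 4])))
  expect_true(is.na(prof$e_stack[prof$level == 5]))
})

test_that("profile decomposition is internally consistent and conserved", {
  tt <- tiny_traj(L = 4L, n_frames = 3L, noise = 0.2, seed = 23L)
  traj <- tt$trajectory
  p <- default_params()
  prof <- level_profile(traj, p, tail = 1e6)
  # e_total is the sum of its parts
  stack0 <- ifelse(is.na(prof$e_stack), 0, prof$e_stack)
  expect_equal(prof$e_total, prof$e_hb + prof$e_cross + stack0,
               tolerance = 1e-9)
  # conservation: profile terms equal frame-averaged per-level calls
  for (i in 2:3) {
    hb <- mean(vapply(1:3, function(t) level_hbond_energy(traj, t, i, p),
                      numeric(1)))
    expect_equal(prof$e_hb[prof$level == i], hb, tolerance = 1e-9)
  }
  st <- mean(vapply(1:3, function(t) level_stack_energy(traj, t, 2, p),
                    numeric(1)))
  expect_equal(prof$e_stack[prof$level == 2], st, tolerance = 1e-9)
  # constant trajectory: profile equals the single-frame values
  tt0 <- tiny_traj(L = 4L, n_frames = 3L, noise = 0)
  prof0 <- level_profile(tt0$trajectory, p, tail = 1e6)
  expect_equal(prof0$e_hb[1], level_hbond_energy(tt0$trajectory, 1, 2, p),
               tolerance = 1e-9)
})

test_that("Coulomb terms scale linearly in one chain's charges", {
  tt <- tiny_traj(L = 4L, n_frames = 1L, noise = 0.1, seed = 3L)
  traj <- tt$trajectory
  # pure-Coulomb comparison: zero out epsilon
  traj$topology$atoms$epsilon <- 0
  p <- default_params()
  e1 <- level_hbond_energy(traj, 1, 2, p, pairs = "rna")   # A-involving
  bc1 <- level_hbond_energy(traj, 1, 2, p) - e1            # B-C term
  traj2 <- traj
  iA <- which(traj2$topology$atoms$chain == "A")
  traj2$topology$atoms$charge[iA] <- 2 * traj2$topology$atoms$charge[iA]
  e2 <- level_hbond_energy(traj2, 1, 2, p, pairs = "rna")
  bc2 <- level_hbond_energy(traj2, 1, 2, p) - e2
  expect_equal(e2, 2 * e1, tolerance = 1e-9)
  expect_equal(bc2, bc1, tolerance = 1e-9)
})

test_that("isolated levels beyond the cutoff contribute zero", {
  # rise large enough that consecutive levels exceed the 10 A cutoff
  b <- build_ideal_triplex(tiny_alignment(4L), rise = 40)
  syn <- synthesize_trajectory(b, n_frames = 1L, noise_sigma = 0,
                               occupancies = NULL, seed = 1L)
  expect_equal(level_cross_energy(syn$trajectory, 1, 2), 0)
  expect_equal(level_stack_energy(syn$trajectory, 1, 2), 0)
})
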