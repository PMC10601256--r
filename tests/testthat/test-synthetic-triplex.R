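test_that("ideal build places bonds at matched levels only", {
  L <- 8L
  b <- build_ideal_triplex(tiny_alignment(L, mismatch = c(3L, 7L)))
  topo <- b$topology
  expect_equal(topo$n_levels, L)
  expect_equal(nrow(topo$atoms), L * 3L * 5L)
  dist_AB <- function(i) {
    iD <- res_atoms(topo, "A", i)[topo$atoms$name[res_atoms(topo, "A", i)] == "D"]
    iB <- res_atoms(topo, "B", i)[topo$atoms$name[res_atoms(topo, "B", i)] == "B"]
    sqrt(sum((b$reference[iD, ] - b$reference[iB, ])^2))
  }
  for (i in setdiff(seq_len(L), c(3L, 7L))) {
    expect_equal(dist_AB(i), 2.9, tolerance = 1e-12)
  }
  expect_gte(dist_AB(3L), 5)
  expect_gte(dist_AB(7L), 5)
  # Watson-Crick B-C bonding geometry at every level
  for (i in seq_len(L)) {
    iD <- res_atoms(topo, "B", i)[topo$atoms$name[res_atoms(topo, "B", i)] == "D"]
    iB <- res_atoms(topo, "C", i)[topo$atoms$name[res_atoms(topo, "C", i)] == "B"]
    expect_equal(sqrt(sum((b$reference[iD, ] - b$reference[iB, ])^2)), 2.9,
                 tolerance = 1e-12)
  }
  expect_error(build_ideal_triplex(tiny_alignment(3L)), ">= 4")
})

test_that("helical symmetry: consecutive same-chain P-P distances equal", {
  b <- build_ideal_triplex(tiny_alignment(10L), rise = 3.4, twist = 30)
  for (ch in c("A", "B", "C")) {
    iP <- which(b$topology$atoms$chain == ch & b$topology$atoms$name == "P")
    iP <- iP[order(b$topology$atoms$level[iP])]
    d <- sqrt(rowSums((b$reference[iP[-1], ] -
                         b$reference[iP[-length(iP)], ])^2))
    expect_equal(max(d) - min(d), 0, tolerance = 1e-9)
    # closed form: chord of the helix at the P radius plus the rise
    r <- sqrt(sum(b$reference[iP[1], 1:2]^2))
    expect_equal(d[1], sqrt((2 * r * sin(pi * 15 / 180))^2 + 3.4^2),
                 tolerance = 1e-9)
  }
})

test_that("protonated cytosine template applies to interior RNA C only", {
  a <- triplex_alignment(
    sequence_record("r", "CUCUC", "rna"),
    sequence_record("p", "GAGAG", "dna"), 1, 1, 5)
  b <- build_ideal_triplex(a)
  at <- b$topology$atoms
  rn <- at$resname[at$chain == "A"][match(1:5, at$level[at$chain == "A"])]
  expect_equal(rn, c("C", "U", "C+", "U", "C"))
  # the override shifts the donor-group charge by +1 e in total
  hd <- at$charge[at$chain == "A" & at$level == 3 & at$name == "HD"]
  expect_equal(hd, 1.0)
})

test_that("occupancy-1 zero-noise trajectory has the bond every frame", {
  tt <- tiny_traj(L = 6L, mismatch = 4L, n_frames = 4L, noise = 0)
  cs <- count_series(tt$trajectory, tail = 1e6)
  expect_equal(cs$count, rep(5, 4))   # L_match = 5 matched levels
  hb <- detect_hbonds(tt$trajectory, 1)
  expect_equal(sort(hb$rna_level), setdiff(1:6, 4L))
  expect_true(all(hb$register == "in"))
})

test_that("empty occupancies give zero bonds", {
  tt <- tiny_traj(L = 5L, n_frames = 3L, noise = 0.1,
                  occ = occupancy_map(integer(0), numeric(0), integer(0)))
  expect_equal(count_series(tt$trajectory, tail = 1e6)$count, rep(0, 3))
})

test_that("planted occupancy is recovered within binomial error", {
  tt <- tiny_traj(L = 6L, n_frames = 400L, noise = 0.2,
                  occ = occupancy_map(3L, 0.8), seed = 99L)
  om <- occurrence_map(tt$trajectory, all_frames = TRUE)
  f <- om$fraction[om$rna_res == 3 & om$dna_chain == "B" & om$dna_res == 3]
  se <- sqrt(0.8 * 0.2 / 400)
  expect_lt(abs(f - 0.8), 3 * se)
  # detection matches the generator's own Bernoulli draws exactly
  expect_equal(f, mean(tt$truth$bond_draws[, 3]))
})

test_that("same seed reproduces the trajectory bit-identically", {
  t1 <- tiny_traj(L = 5L, n_frames = 10L, noise = 0.3, seed = 12L)
  t2 <- tiny_traj(L = 5L, n_frames = 10L, noise = 0.3, seed = 12L)
  expect_identical(t1$trajectory$coords, t2$trajectory$coords)
  expect_identical(t1$truth$bond_draws, t2$truth$bond_draws)
  t3 <- tiny_traj(L = 5L, n_frames = 10L, noise = 0.3, seed = 13L)
  expect_false(identical(t1$trajectory$coords, t3$trajectory$coords))
})

test_that("occupancy validation rejects out-of-range values", {
  expect_error(occupancy_map(1L, 1.2), "outside")
  expect_error(occupancy_map(1L, -0.1), "outside")
  b <- build_ideal_triplex(tiny_alignment(4L))
  expect_error(
    synthesize_trajectory(b, 2, occupancies = occupancy_map(9L, 0.5)),
    "level outside"
  )
})

test_that("fraying separates terminal levels after the fray frame", {
  nf <- 200L
  tt <- tiny_traj(L = 8L, n_frames = nf, noise = 0.1, seed = 4L,
                  fray = list(after_frame = nf / 2L, levels = 2L,
                              max_shift = 12))
  topo <- tt$trajectory$topology
  iD <- res_atoms(topo, "A", 1L)[topo$atoms$name[res_atoms(topo, "A", 1L)] == "D"]
  iB <- res_atoms(topo, "B", 1L)[topo$atoms$name[res_atoms(topo, "B", 1L)] == "B"]
  d_last_quarter <- vapply((3 * nf / 4):nf, function(t) {
    fr <- frame_coords(tt$trajectory, t)
    sqrt(sum((fr[iD, ] - fr[iB, ])^2))
  }, numeric(1))
  expect_true(all(d_last_quarter > 5))
  # interior levels stay bonded
  hb_end <- detect_hbonds(tt$trajectory, nf)
  expect_true(all(3:6 %in% hb_end$rna_level))
  expect_false(any(c(1, 2, 7, 8) %in%
                     hb_end$rna_level[hb_end$register == "in"]))
})

test_that("truth sidecar round-trips through JSON", {
  tt <- tiny_traj(L = 5L, n_frames = 6L, noise = 0.2,
                  occ = occupancy_map(c(2L, 3L), c(0.5, 1), c(1L, 2L)))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(tt$truth, path)
  tr <- read_truth_json(path)
  expect_equal(tr$occupancies, tt$truth$occupancies)
  expect_equal(tr$expected_bonds_per_frame,
               tt$truth$expected_bonds_per_frame)
  expect_equal(tr$seed, tt$truth$seed)
})
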