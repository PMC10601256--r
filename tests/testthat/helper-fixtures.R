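# fixtures are built in code: no data files

# small alignment with chosen mismatch positions (1-based, window-local);
# canonical positions are U.A, mismatches are C over dT
tiny_alignment <- function(L = 6L, mismatch = integer(0)) {
  pur <- rep("A", L); rna <- rep("U", L)
  pur[mismatch] <- "T"; rna[mismatch] <- "C"
  triplex_alignment(
    sequence_record("tiny_rna", paste(rna, collapse = ""), "rna"),
    sequence_record("tiny_pur", paste(pur, collapse = ""), "dna"),
    rna_start = 1L, purine_start = 1L, window_len = L
  )
}

# small build + synthesized trajectory in one call
tiny_traj <- function(L = 6L, mismatch = integer(0), n_frames = 5L,
                      noise = 0, occ = NULL, seed = 42L, fray = NULL,
                      dt = 0.3) {
  b <- build_ideal_triplex(tiny_alignment(L, mismatch))
  if (is.null(occ)) {
    matched <- strsplit(b$topology$pairing, "")[[1]] == "|"
    occ <- occupancy_map(which(matched), 1)
  }
  syn <- synthesize_trajectory(b, n_frames = n_frames, dt = dt,
                               noise_sigma = noise, occupancies = occ,
                               seed = seed, fray = fray)
  list(build = b, trajectory = syn$trajectory, truth = syn$truth)
}

# independent brute-force oracle: LJ + Coulomb over explicit atom index
# sets, plain double loop, no shared code with the package internals
brute_energy <- function(fr, atoms, idx_i, idx_j, coulomb = 1389.35458,
                         cutoff = 10) {
  e_lj <- 0; e_cb <- 0
  for (i in idx_i) {
    for (j in idx_j) {
      r <- sqrt(sum((fr[i, ] - fr[j, ])^2))
      if (r <= cutoff) {
        sij <- (atoms$sigma[i] + atoms$sigma[j]) / 2
        eij <- sqrt(atoms$epsilon[i] * atoms$epsilon[j])
        e_lj <- e_lj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
        e_cb <- e_cb + coulomb * atoms$charge[i] * atoms$charge[j] / r
      }
    }
  }
  c(e_lj = e_lj, e_cb = e_cb)
}

res_atoms <- function(topology, chain, level) {
  which(topology$atoms$chain == chain & topology$atoms$level == level)
}

# independent mismatch counter for the scan oracle
count_mm <- function(rna_bases, pur_bases) {
  sum(!((rna_bases == "U" & pur_bases == "A") |
          (rna_bases == "C" & pur_bases == "G")))
}

random_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
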