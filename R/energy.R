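# Pairwise short-range LJ + Coulomb energies with a hard cutoff, and the
# per-base-pair-level decomposition into hydrogen-bond, cross and stacking
# terms. Units: Angstrom, kJ/mol, elementary charges; Coulomb constant
# f = 1389.35458 kJ mol^-1 A e^-2. No periodic boundaries (vacuum toys);
# long-range electrostatics are out of scope.

#' Lennard-Jones + Coulomb energy of one atom pair
#'
#' Lorentz-Berthelot combining (`sigma_ij = (sigma_i + sigma_j)/2`,
#' `eps_ij = sqrt(eps_i eps_j)`); pairs beyond `params$cutoff` contribute
#' exactly zero to both terms.
#'
#' @param atom_i,atom_j lists or single data.frame rows with fields
#'   `charge` (e), `sigma` (A), `epsilon` (kJ/mol).
#' @param r interatomic distance, Angstrom (> 0; may be a vector).
#' @param params `ff_params`.
#' @return list with numeric `e_lj` and `e_cb` (kJ/mol), same length as
#'   `r`.
#' @export
pair_energy <- function(atom_i, atom_j, r, params = default_params()) {
  if (any(r <= 0)) stop("pair_energy: r must be > 0 (singularity)")
  sij <- (atom_i$sigma + atom_j$sigma) / 2
  e4 <- 4 * sqrt(atom_i$epsilon * atom_j$epsilon)
  qq <- params$coulomb * atom_i$charge * atom_j$charge
  inside <- r <= params$cutoff
  sr6 <- ifelse(inside, (sij / r)^6, 0)
  list(
    e_lj = ifelse(inside, e4 * (sr6^2 - sr6), 0),
    e_cb = ifelse(inside, qq / r, 0)
  )
}

# precompute a pair table for repeated per-frame evaluation
.pair_table <- function(topology, idx_i, idx_j, params, group = NULL) {
  at <- topology$atoms
  g <- expand.grid(i = idx_i, j = idx_j)
  data.frame(
    i = g$i, j = g$j,
    qq = params$coulomb * at$charge[g$i] * at$charge[g$j],
    sij = (at$sigma[g$i] + at$sigma[g$j]) / 2,
    e4 = 4 * sqrt(at$epsilon[g$i] * at$epsilon[g$j]),
    group = if (is.null(group)) "" else group,
    stringsAsFactors = FALSE
  )
}

# evaluate one frame over a pair table; returns matrix with columns
# e_lj, e_cb summed per group (groups in the order of unique(tab$group))
.frame_energy <- function(fr, tab, cutoff) {
  d <- fr[tab$i, , drop = FALSE] - fr[tab$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) stop("energy: coincident atoms (r = 0)")
  inside <- r <= cutoff
  sr6 <- numeric(length(r))
  sr6[inside] <- (tab$sij[inside] / r[inside])^6
  e_lj <- tab$e4 * (sr6^2 - sr6)
  e_cb <- numeric(length(r))
  e_cb[inside] <- tab$qq[inside] / r[inside]
  grp <- factor(tab$group, levels = unique(tab$group))
  cbind(
    e_lj = as.numeric(tapply(e_lj, grp, sum)),
    e_cb = as.numeric(tapply(e_cb, grp, sum))
  )
}

#' Total RNA-DNA interaction-energy time series
#'
#' Per frame, sums LJ and Coulomb energies over all (RNA atom, DNA atom)
#' pairs within the cutoff, phosphate and sugar backbone included. With
#' `clip_levels` (the extended-model comparison case) only atoms of
#' residues at those register levels contribute on both sides.
#'
#' @param trajectory `triplex_trajectory`.
#' @param params `ff_params`.
#' @param clip_levels optional integer levels to restrict to.
#' @return data.frame: time (ns), e_lj, e_cb, e_total (kJ/mol).
#' @export
interaction_energy_series <- function(trajectory, params = default_params(),
                                      clip_levels = NULL) {
  stopifnot(inherits(trajectory, "triplex_trajectory"))
  topo <- trajectory$topology
  rna <- select_atoms(topo, selection = "rna", levels = clip_levels)
  dna <- select_atoms(topo, selection = "duplex", levels = clip_levels)
  tab <- .pair_table(topo, rna, dna, params)
  vals <- t(vapply(seq_len(n_frames(trajectory)), function(t) {
    e <- .frame_energy(trajectory$coords[, , t], tab, params$cutoff)
    c(e[1, "e_lj"], e[1, "e_cb"])
  }, numeric(2)))
  data.frame(time = trajectory$times, e_lj = vals[, 1], e_cb = vals[, 2],
             e_total = vals[, 1] + vals[, 2])
}

# residue atom indices for (chain, level)
.res_idx <- function(topology, chain, level) {
  which(topology$atoms$chain == chain & topology$atoms$level == level)
}

.check_interior <- function(topology, i, what) {
  L <- topology$n_levels
  if (i <= 1L || i >= L) {
    stop(what, ": level ", i, " involves a terminal residue (excluded)")
  }
}

#' Hydrogen-bond energy at one base-pair level
#'
#' Sum of LJ + Coulomb energies over all atom pairs between the three
#' inter-chain residue pairs at level i: (A_i, B_i), (B_i, C_i),
#' (A_i, C_i). `pairs = "rna"` restricts to the RNA-involving pairs for
#' sensitivity analysis. Terminal levels are excluded by construction.
#'
#' @param trajectory `triplex_trajectory`.
#' @param frame frame index.
#' @param i interior register level.
#' @param params `ff_params`.
#' @param pairs `"all"` (default) or `"rna"`.
#' @return energy in kJ/mol.
#' @export
level_hbond_energy <- function(trajectory, frame, i,
                               params = default_params(),
                               pairs = c("all", "rna")) {
  stopifnot(inherits(trajectory, "triplex_trajectory"))
  pairs <- match.arg(pairs)
  topo <- trajectory$topology
  .check_interior(topo, i, "level_hbond_energy")
  combos <- list(c("A", "B"), c("B", "C"), c("A", "C"))
  if (pairs == "rna") combos <- combos[c(1, 3)]
  tabs <- lapply(combos, function(p) {
    .pair_table(topo, .res_idx(topo, p[1], i), .res_idx(topo, p[2], i),
                params)
  })
  tab <- do.call(rbind, tabs)
  e <- .frame_energy(frame_coords(trajectory, frame), tab, params$cutoff)
  sum(e)
}

#' Cross energy at one base-pair level
#'
#' Sum of LJ + Coulomb energies of the central purine residue B_i with the
#' diagonal neighbors A_(i-1), A_(i+1), C_(i-1), C_(i+1).
#'
#' @inheritParams level_hbond_energy
#' @return energy in kJ/mol.
#' @export
level_cross_energy <- function(trajectory, frame, i,
                               params = default_params()) {
  stopifnot(inherits(trajectory, "triplex_trajectory"))
  topo <- trajectory$topology
  .check_interior(topo, i, "level_cross_energy")
  bi <- .res_idx(topo, "B", i)
  nb <- c(.res_idx(topo, "A", i - 1L), .res_idx(topo, "A", i + 1L),
          .res_idx(topo, "C", i - 1L), .res_idx(topo, "C", i + 1L))
  tab <- .pair_table(topo, bi, nb, params)
  sum(.frame_energy(frame_coords(trajectory, frame), tab, params$cutoff))
}

#' Stacking energy at one base-pair step
#'
#' Sum over the three chains of the LJ + Coulomb energy between residues
#' at levels i and i+1 (a base-pair-step quantity). Both i and i+1 must be
#' interior levels.
#'
#' @inheritParams level_hbond_energy
#' @return energy in kJ/mol.
#' @export
level_stack_energy <- function(trajectory, frame, i,
                               params = default_params()) {
  stopifnot(inherits(trajectory, "triplex_trajectory"))
  topo <- trajectory$topology
  L <- topo$n_levels
  if (i <= 1L || i + 1L >= L) {
    stop("level_stack_energy: step (", i, ", ", i + 1L,
         ") involves a terminal residue (step-index error)")
  }
  tabs <- lapply(c("A", "B", "C"), function(ch) {
    .pair_table(topo, .res_idx(topo, ch, i), .res_idx(topo, ch, i + 1L),
                params)
  })
  tab <- do.call(rbind, tabs)
  sum(.frame_energy(frame_coords(trajectory, frame), tab, params$cutoff))
}

#' Frame-averaged per-level energy decomposition profile
#'
#' For each interior level i (2..L-1) reports the converged-window
#' averages of the hydrogen-bond, cross and stacking terms and their sum.
#' Any contribution involving a terminal residue is dropped uniformly, so
#' the stacking term is undefined (NA) at level L-1, whose step would
#' reach the terminal level; the total there sums the remaining terms.
#'
#' @param trajectory `triplex_trajectory`.
#' @param params `ff_params`.
#' @param tail converged-window length (ns).
#' @param all_frames average over all frames instead of the window.
#' @return data.frame: level, e_hb, e_cross, e_stack, e_total (kJ/mol).
#' @export
level_profile <- function(trajectory, params = default_params(),
                          tail = 400, all_frames = FALSE) {
  stopifnot(inherits(trajectory, "triplex_trajectory"))
  topo <- trajectory$topology
  L <- topo$n_levels
  if (L < 3L) stop("level_profile: need >= 3 levels")
  win <- if (all_frames) {
    seq_len(n_frames(trajectory))
  } else {
    suppressWarnings(converged_window(trajectory, tail))
  }
  interior <- 2:(L - 1L)
  steps <- interior[interior + 1L < L]   # steps fully interior
  # one big grouped pair table evaluated per frame
  tabs <- list()
  for (i in interior) {
    for (p in list(c("A", "B"), c("B", "C"), c("A", "C"))) {
      tabs[[length(tabs) + 1L]] <- .pair_table(
        topo, .res_idx(topo, p[1], i), .res_idx(topo, p[2], i), params,
        group = paste0("hb:", i))
    }
    nb <- c(.res_idx(topo, "A", i - 1L), .res_idx(topo, "A", i + 1L),
            .res_idx(topo, "C", i - 1L), .res_idx(topo, "C", i + 1L))
    tabs[[length(tabs) + 1L]] <- .pair_table(
      topo, .res_idx(topo, "B", i), nb, params, group = paste0("cross:", i))
  }
  for (i in steps) {
    for (ch in c("A", "B", "C")) {
      tabs[[length(tabs) + 1L]] <- .pair_table(
        topo, .res_idx(topo, ch, i), .res_idx(topo, ch, i + 1L), params,
        group = paste0("stack:", i))
    }
  }
  tab <- do.call(rbind, tabs)
  groups <- unique(tab$group)
  acc <- matrix(0, nrow = length(groups), ncol = 2,
                dimnames = list(groups, c("e_lj", "e_cb")))
  for (t in win) {
    acc <- acc + .frame_energy(trajectory$coords[, , t], tab,
                               params$cutoff)
  }
  acc <- acc / length(win)
  tot <- acc[, 1] + acc[, 2]
  gv <- function(kind, i) {
    k <- paste0(kind, ":", i)
    if (k %in% groups) tot[[k]] else NA_real_
  }
  out <- data.frame(
    level = interior,
    e_hb = vapply(interior, function(i) gv("hb", i), numeric(1)),
    e_cross = vapply(interior, function(i) gv("cross", i), numeric(1)),
    e_stack = vapply(interior, function(i) gv("stack", i), numeric(1))
  )
  out$e_total <- out$e_hb + out$e_cross +
    ifelse(is.na(out$e_stack), 0, out$e_stack)
  attr(out, "n_frames_used") <- length(win)
  out
}

#' Write an interaction-energy series or level profile as TSV
#' @param x data.frame from [interaction_energy_series()] or
#'   [level_profile()].
#' @param path TSV path.
#' @export
write_energy_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
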