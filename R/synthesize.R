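#' Planted hydrogen-bond occupancies for a synthetic trajectory
#'
#' Occupancies are keyed by in-register pairs, i.e. by register level: the
#' pair (RNA residue at level i, purine residue at level i). `n_bonds = 2`
#' plants a second simultaneous bond for the pair (the purine Watson-Crick
#' donor to the RNA acceptor), producing "H bond units" of 2 when the
#' occupancy is 1.
#'
#' @param level integer register levels.
#' @param occupancy per-level bond probability in `[0, 1]`.
#' @param n_bonds 1 or 2 simultaneous planted bonds per level.
#' @return data.frame with columns level, occupancy, n_bonds.
#' @export
occupancy_map <- function(level, occupancy, n_bonds = 1L) {
  df <- data.frame(level = as.integer(level),
                   occupancy = as.numeric(occupancy),
                   n_bonds = as.integer(n_bonds))
  if (any(df$occupancy < 0 | df$occupancy > 1)) {
    stop("occupancy_map: occupancy outside [0, 1]")
  }
  if (any(!df$n_bonds %in% c(1L, 2L))) {
    stop("occupancy_map: n_bonds must be 1 or 2")
  }
  if (anyDuplicated(df$level)) stop("occupancy_map: duplicate levels")
  df
}

#' Synthesize a seeded triplex trajectory with planted hydrogen bonds
#'
#' Frame coordinates are the ideal reference plus isotropic iid Gaussian
#' noise, except that each in-register donor/hydrogen/acceptor triple is
#' posed deterministically every frame: at bonding geometry
#' (donor..acceptor 2.9 A, hydrogen on the bond axis) with the planted
#' probability, otherwise displaced to >= 5 A. Levels without an occupancy
#' entry are never bonded. With `fray` set, the RNA and pyrimidine strands
#' of the terminal `fray$levels` levels drift apart linearly after frame
#' `fray$after_frame` (emulating artefactual strand separation of a
#' too-short model). The whole trajectory is reproducible from `seed`.
#'
#' @param build a `triplex_build` from [build_ideal_triplex()].
#' @param n_frames number of frames (>= 1).
#' @param dt frame spacing in ns; frame times are `(0:(n-1)) * dt`.
#' @param noise_sigma Gaussian coordinate noise, Angstrom.
#' @param occupancies an [occupancy_map()] (may be empty/NULL: no bonds).
#' @param seed integer RNG seed.
#' @param fray `NULL` or `list(after_frame=, levels=, max_shift=)`;
#'   `max_shift` (Angstrom, default 12) is reached at the final frame.
#' @return list with `trajectory` (class `triplex_trajectory`: topology,
#'   `coords` array n_atoms x 3 x n_frames, `times` ns) and `truth`
#'   (class `planted_truth`).
#' @export
synthesize_trajectory <- function(build, n_frames, dt = 0.3,
                                  noise_sigma = 0.2, occupancies = NULL,
                                  seed = 1L, fray = NULL) {
  stopifnot(inherits(build, "triplex_build"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("synthesize_trajectory: n_frames must be >= 1")
  if (noise_sigma < 0) stop("synthesize_trajectory: negative noise_sigma")
  topo <- build$topology
  L <- topo$n_levels
  if (is.null(occupancies)) {
    occupancies <- occupancy_map(integer(0), numeric(0), integer(0))
  }
  if (any(occupancies$occupancy < 0 | occupancies$occupancy > 1)) {
    stop("synthesize_trajectory: occupancy outside [0, 1]")
  }
  if (any(!occupancies$level %in% seq_len(L))) {
    stop("synthesize_trajectory: occupancy level outside topology")
  }
  if (!is.null(fray)) {
    fray$after_frame <- as.integer(fray$after_frame)
    fray$levels <- as.integer(fray$levels)
    if (is.null(fray$max_shift)) fray$max_shift <- 12
    if (fray$after_frame < 1L || fray$after_frame > n_frames) {
      stop("synthesize_trajectory: fray$after_frame outside 1..n_frames")
    }
  }

  occ <- numeric(L); nb <- rep(1L, L)
  occ[occupancies$level] <- occupancies$occupancy
  nb[occupancies$level] <- occupancies$n_bonds

  # per-level atom indices and radial directions
  iBB <- vapply(seq_len(L), function(i) .atom_idx(topo, "B", i, "B"), 1L)
  iDA <- vapply(seq_len(L), function(i) .atom_idx(topo, "A", i, "D"), 1L)
  iHA <- vapply(seq_len(L), function(i) .atom_idx(topo, "A", i, "HD"), 1L)
  iDB <- vapply(seq_len(L), function(i) .atom_idx(topo, "B", i, "D"), 1L)
  iHB <- vapply(seq_len(L), function(i) .atom_idx(topo, "B", i, "HD"), 1L)
  iBA <- vapply(seq_len(L), function(i) .atom_idx(topo, "A", i, "B"), 1L)
  U <- do.call(rbind, lapply(seq_len(L), function(i) .level_u(i, build$twist)))
  ref <- build$reference
  n_atoms <- nrow(ref)
  idxA <- which(topo$atoms$chain == "A")
  idxC <- which(topo$atoms$chain == "C")

  set.seed(as.integer(seed))
  coords <- array(NA_real_, dim = c(n_atoms, 3, n_frames))
  bond_draws <- matrix(FALSE, nrow = n_frames, ncol = L)
  for (t in seq_len(n_frames)) {
    fr <- ref + matrix(stats::rnorm(n_atoms * 3, 0, noise_sigma),
                       ncol = 3)
    bonded <- stats::runif(L) < occ
    bond_draws[t, ] <- bonded
    for (i in seq_len(L)) {
      u <- U[i, ]
      bpos <- ref[iBB[i], ]
      d <- if (bonded[i]) .hbond_pose_dist else .unbond_pose_dist
      fr[iBB[i], ] <- bpos
      fr[iDA[i], ] <- bpos + d * u
      fr[iHA[i], ] <- bpos + (d - 1.0) * u
      if (nb[i] == 2L) {
        # second bond: purine WC donor swings up to the RNA acceptor,
        # approaching axially (+z) so no other atom is within clash range
        fr[iBA[i], ] <- ref[iBA[i], ]
        if (bonded[i]) {
          zax <- c(0, 0, 1)
          fr[iDB[i], ] <- ref[iBA[i], ] + .hbond_pose_dist * zax
          fr[iHB[i], ] <- ref[iBA[i], ] + (.hbond_pose_dist - 1.0) * zax
        } else {
          fr[iDB[i], ] <- ref[iDB[i], ]
          fr[iHB[i], ] <- ref[iHB[i], ]
        }
      }
    }
    if (!is.null(fray) && t > fray$after_frame) {
      shift <- fray$max_shift * (t - fray$after_frame) /
        (n_frames - fray$after_frame)
      lv <- unique(c(seq_len(fray$levels), L - seq_len(fray$levels) + 1L))
      for (i in lv) {
        u <- U[i, ]
        sa <- idxA[topo$atoms$level[idxA] == i]
        sc <- idxC[topo$atoms$level[idxC] == i]
        fr[sa, ] <- fr[sa, ] + rep(shift * u, each = length(sa))
        fr[sc, ] <- fr[sc, ] - rep(shift * u, each = length(sc))
      }
    }
    coords[, , t] <- fr
  }
  times <- (seq_len(n_frames) - 1) * dt
  trajectory <- structure(
    list(topology = topo, coords = coords, times = times),
    class = "triplex_trajectory"
  )
  truth <- structure(
    list(
      occupancies = occupancies, noise_sigma = noise_sigma,
      seed = as.integer(seed), dt = dt, n_frames = n_frames,
      fray = fray, times = times,
      expected_bonds_per_frame = sum(occ * nb),
      bond_draws = bond_draws
    ),
    class = "planted_truth"
  )
  list(trajectory = trajectory, truth = truth)
}

#' @export
print.triplex_trajectory <- function(x, ...) {
  cat(sprintf(
    "<triplex_trajectory> %d frames (%.1f..%.1f ns), %d atoms, %d levels\n",
    length(x$times), min(x$times), max(x$times), dim(x$coords)[1],
    x$topology$n_levels))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory `triplex_trajectory`.
#' @export
n_frames <- function(trajectory) length(trajectory$times)

#' Coordinates of one frame
#' @param trajectory `triplex_trajectory`.
#' @param frame frame index (1-based).
#' @return n_atoms x 3 matrix, Angstrom.
#' @export
frame_coords <- function(trajectory, frame) {
  stopifnot(frame >= 1L, frame <= n_frames(trajectory))
  trajectory$coords[, , frame]
}

#' Write/read the planted-truth sidecar as JSON
#' @param truth `planted_truth`.
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$bond_draws <- NULL  # bulky; recomputable from the seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$occupancies <- as.data.frame(x$occupancies)
  structure(x, class = "planted_truth")
}
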