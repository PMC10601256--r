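# Multi-model PDB is the trajectory interchange format: human readable,
# fine at desk scale, one MODEL per frame with chains A/B/C in Angstrom.
# Frame times travel in a JSON sidecar ("<pdb>.times.json") or via `dt`.

#' Write a trajectory as multi-model PDB (plus times sidecar)
#'
#' @param trajectory `triplex_trajectory`.
#' @param path output PDB path. A sidecar `<path>.times.json` holding the
#'   frame times (ns) is written alongside unless `sidecar = FALSE`.
#' @param sidecar write the times sidecar (default TRUE).
#' @export
write_trajectory_pdb <- function(trajectory, path, sidecar = TRUE) {
  stopifnot(inherits(trajectory, "triplex_trajectory"))
  at <- trajectory$topology$atoms
  nf <- n_frames(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(nf)) {
    fr <- trajectory$coords[, , t]
    writeLines(sprintf("MODEL     %4d", t), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), at$name, at$resname, at$chain, at$level,
      fr[, 1], fr[, 2], fr[, 3], at$element
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (sidecar) {
    jsonlite::write_json(list(times = trajectory$times),
                         paste0(path, ".times.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a multi-model PDB trajectory against a topology
#'
#' Atom names, residue names, chains and register levels of every MODEL
#' are validated against the topology; the first offending atom is named
#' in the error. A truncated final MODEL (missing ENDMDL) is an error, not
#' a silent drop. Frame times come from the sidecar written by
#' [write_trajectory_pdb()], from `times`, or from `dt`; having none is an
#' error because converged-window selection needs times.
#'
#' @param path PDB file.
#' @param topology `triplex_topology` the file must conform to.
#' @param dt frame spacing (ns), used if no sidecar/`times`.
#' @param times explicit frame times (ns); takes precedence over the
#'   sidecar and `dt`.
#' @return `triplex_trajectory`.
#' @export
read_trajectory_pdb <- function(path, topology, dt = NULL, times = NULL) {
  stopifnot(inherits(topology, "triplex_topology"))
  if (!file.exists(path)) stop("read_trajectory_pdb: no such file: ", path)
  lines <- readLines(path)
  at <- topology$atoms
  n_atoms <- nrow(at)
  rec <- substr(lines, 1, 6)
  i_model <- which(startsWith(rec, "MODEL"))
  i_end <- which(startsWith(rec, "ENDMDL"))
  i_atom <- which(rec == "ATOM  " | rec == "HETATM")
  if (length(i_model) == 0L) stop("read_trajectory_pdb: no MODEL records")
  if (length(i_end) > length(i_model) ||
      any(i_end[seq_along(i_end)] < i_model[seq_along(i_end)])) {
    stop("read_trajectory_pdb: ENDMDL without matching MODEL")
  }
  if (length(i_end) < length(i_model)) {
    stop("read_trajectory_pdb: truncated final MODEL (missing ENDMDL)")
  }
  if (length(i_atom) && (min(i_atom) < min(i_model))) {
    stop("read_trajectory_pdb: ATOM record outside MODEL/ENDMDL block")
  }
  # assign each atom line to its enclosing model
  model_of <- findInterval(i_atom, i_model)
  frames <- split(lines[i_atom], model_of)
  if (length(frames) != length(i_model)) {
    stop("read_trajectory_pdb: MODEL without atoms")
  }
  if (length(frames) == 0L) stop("read_trajectory_pdb: no frames in ", path)
  coords <- array(NA_real_, dim = c(n_atoms, 3, length(frames)))
  for (t in seq_along(frames)) {
    fl <- frames[[t]]
    if (length(fl) != n_atoms) {
      stop(sprintf(
        "read_trajectory_pdb: MODEL %d has %d atoms, topology has %d",
        t, length(fl), n_atoms))
    }
    name <- trimws(substr(fl, 13, 16))
    resname <- trimws(substr(fl, 18, 20))
    chain <- substr(fl, 22, 22)
    level <- as.integer(substr(fl, 23, 26))
    bad <- which(name != at$name | resname != at$resname |
                   chain != at$chain | level != at$level)
    if (length(bad)) {
      b <- bad[1]
      stop(sprintf(
        paste0("read_trajectory_pdb: MODEL %d atom %d is %s %s%d %s, ",
               "topology expects %s %s%d %s"),
        t, b, name[b], chain[b], level[b], resname[b],
        at$name[b], at$chain[b], at$level[b], at$resname[b]))
    }
    coords[, 1, t] <- as.numeric(substr(fl, 31, 38))
    coords[, 2, t] <- as.numeric(substr(fl, 39, 46))
    coords[, 3, t] <- as.numeric(substr(fl, 47, 54))
  }
  if (is.null(times)) {
    sidecar <- paste0(path, ".times.json")
    if (file.exists(sidecar)) {
      times <- jsonlite::read_json(sidecar, simplifyVector = TRUE)$times
    } else if (!is.null(dt)) {
      times <- (seq_along(frames) - 1) * dt
    } else {
      stop("read_trajectory_pdb: no times sidecar and no dt given")
    }
  }
  if (length(times) != length(frames)) {
    stop("read_trajectory_pdb: times length != frame count")
  }
  if (any(diff(times) <= 0)) {
    stop("read_trajectory_pdb: frame times must be strictly increasing")
  }
  structure(
    list(topology = topology, coords = coords, times = as.numeric(times)),
    class = "triplex_trajectory"
  )
}
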