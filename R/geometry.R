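#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `frame` onto `reference` and returns the post-fit RMSD. Uses the SVD
#' form of the Kabsch algorithm with the determinant sign correction, so
#' the rotation is always proper (det = +1). Unweighted (the toy atoms
#' carry no masses).
#'
#' @param reference,frame n x 3 coordinate matrices (same atom order).
#' @return list with `rotation` (3 x 3), `translation` (length-3; the fit
#'   is `frame %*% rotation + translation`), `rmsd` (Angstrom).
#' @export
superpose <- function(reference, frame) {
  reference <- as.matrix(reference); frame <- as.matrix(frame)
  if (!all(dim(reference) == dim(frame)) || ncol(reference) != 3L) {
    stop("superpose: coordinate matrices must be equal n x 3")
  }
  n <- nrow(reference)
  if (n < 3L) stop("superpose: need >= 3 atoms")
  cr <- colMeans(reference); cf <- colMeans(frame)
  A <- sweep(reference, 2, cr); B <- sweep(frame, 2, cf)
  sv <- svd(crossprod(B, A))   # t(B) %*% A
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
    stop("superpose: degenerate (collinear or coincident) selection")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fit <- B %*% R
  rmsd <- sqrt(mean(rowSums((fit - A)^2)))
  list(rotation = R, translation = as.numeric(cr - cf %*% R), rmsd = rmsd)
}

# raw (no-fit) RMSD between two coordinate sets
.rmsd_raw <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series versus the first frame
#'
#' @param trajectory `triplex_trajectory`.
#' @param selection `"rna"`, `"duplex"` or `"all"`.
#' @param fit superpose each frame on the reference over the same
#'   selection before measuring (default TRUE); `fit = FALSE` gives the
#'   raw displacement RMSD.
#' @return data.frame with columns time (ns), rmsd (Angstrom), selection.
#' @export
rmsd_series <- function(trajectory, selection = c("rna", "duplex", "all"),
                        fit = TRUE) {
  stopifnot(inherits(trajectory, "triplex_trajectory"))
  selection <- match.arg(selection)
  idx <- select_atoms(trajectory$topology, selection = selection)
  ref <- trajectory$coords[idx, , 1]
  vals <- vapply(seq_len(n_frames(trajectory)), function(t) {
    fr <- trajectory$coords[idx, , t]
    if (fit) superpose(ref, fr)$rmsd else .rmsd_raw(ref, fr)
  }, numeric(1))
  data.frame(time = trajectory$times, rmsd = vals, selection = selection,
             stringsAsFactors = FALSE)
}

#' Frames of the converged tail of a trajectory
#'
#' Convergence is operator-specified, not auto-detected: the analysis
#' window is the trailing `tail` ns of the trajectory (frames with
#' `time > t_end - tail`). If `tail` covers the whole span, all frames are
#' returned with a warning.
#'
#' @param trajectory `triplex_trajectory`.
#' @param tail window length in ns (default 400).
#' @return integer vector of frame indices.
#' @export
converged_window <- function(trajectory, tail = 400) {
  stopifnot(inherits(trajectory, "triplex_trajectory"))
  if (tail <= 0) stop("converged_window: tail must be > 0")
  times <- trajectory$times
  if (length(times) == 0L) stop("converged_window: empty trajectory")
  span <- times[length(times)] - times[1]
  if (tail >= span && length(times) > 1L) {
    warning("converged_window: tail covers the whole trajectory")
    return(seq_along(times))
  }
  which(times > times[length(times)] - tail)
}
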