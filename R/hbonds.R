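# Geometric hydrogen-bond detection between the RNA third strand and the
# DNA duplex. Criteria follow the common gmx-hbond convention:
# donor..acceptor distance <= 3.5 A and hydrogen-donor-acceptor angle
# <= 30 degrees; both are tunable. Only RNA<->DNA bonds are reported.

# enumerate candidate donor/hydrogen/acceptor combinations across the
# RNA/DNA divide, with residue-pair bookkeeping
.hbond_pairs <- function(topology) {
  at <- topology$atoms
  don <- which(at$is_donor)
  acc <- which(at$is_acceptor)
  # the (single) hydrogen of each donor
  hyd_of <- integer(nrow(at))
  hyd <- which(at$is_hydrogen)
  if (length(hyd) == 0L || any(is.na(at$donor_parent[hyd]))) {
    stop(".hbond_pairs: hydrogen without donor parent in topology")
  }
  hyd_of[at$donor_parent[hyd]] <- hyd
  don_rna <- don[at$chain[don] == "A"]
  don_dna <- don[at$chain[don] != "A"]
  acc_rna <- acc[at$chain[acc] == "A"]
  acc_dna <- acc[at$chain[acc] != "A"]
  g1 <- expand.grid(donor = don_rna, acceptor = acc_dna)
  g2 <- expand.grid(donor = don_dna, acceptor = acc_rna)
  g <- rbind(g1, g2)
  g$hydrogen <- hyd_of[g$donor]
  rna_side <- ifelse(at$chain[g$donor] == "A", g$donor, g$acceptor)
  dna_side <- ifelse(at$chain[g$donor] == "A", g$acceptor, g$donor)
  g$rna_level <- at$level[rna_side]
  g$dna_chain <- at$chain[dna_side]
  g$dna_level <- at$level[dna_side]
  g$register <- ifelse(g$dna_chain == "B" & g$dna_level == g$rna_level,
                       "in", "out")
  g
}

.detect_frame <- function(fr, pairs, d_max, a_max) {
  d <- fr[pairs$donor, , drop = FALSE]
  a <- fr[pairs$acceptor, , drop = FALSE]
  h <- fr[pairs$hydrogen, , drop = FALSE]
  da <- a - d
  dist <- sqrt(rowSums(da^2))
  ok <- dist <= d_max
  if (!any(ok)) return(integer(0))
  dh <- h[ok, , drop = FALSE] - d[ok, , drop = FALSE]
  cosang <- rowSums(dh * da[ok, , drop = FALSE]) /
    (sqrt(rowSums(dh^2)) * dist[ok])
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  hit <- which(ok)[ang <= a_max]
  attr(hit, "distance") <- dist[hit]
  attr(hit, "angle") <- ang[match(hit, which(ok))]
  hit
}

#' Detect RNA-DNA hydrogen bonds in one frame
#'
#' A bond is reported iff the donor-acceptor distance is at most `d_max`
#' and the hydrogen-donor-acceptor angle at most `a_max`; only bonds with
#' the donor on one of RNA/DNA and the acceptor on the other are
#' considered. `register` is `"in"` iff the DNA partner is the purine
#' strand (chain B) residue at the same register level as the RNA residue.
#'
#' @param trajectory `triplex_trajectory`.
#' @param frame frame index.
#' @param d_max donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param a_max hydrogen-donor-acceptor angle cutoff, degrees (default 30).
#' @return data.frame: frame, donor, hydrogen, acceptor (atom indices),
#'   rna_level, dna_chain, dna_level, distance, angle, register.
#' @export
detect_hbonds <- function(trajectory, frame, d_max = 3.5, a_max = 30) {
  stopifnot(inherits(trajectory, "triplex_trajectory"))
  pairs <- .hbond_pairs(trajectory$topology)
  fr <- frame_coords(trajectory, frame)
  hit <- .detect_frame(fr, pairs, d_max, a_max)
  out <- pairs[hit, c("donor", "hydrogen", "acceptor", "rna_level",
                      "dna_chain", "dna_level", "register")]
  out <- cbind(frame = rep(as.integer(frame), length(hit)), out)
  out$distance <- attr(hit, "distance")
  out$angle <- attr(hit, "angle")
  rownames(out) <- NULL
  out
}

#' Classify hydrogen bonds as in-register or out-of-register
#'
#' In-register means the DNA partner is the purine-strand (chain B)
#' residue at the same register level as the RNA residue; bonds to the
#' pyrimidine strand or to shifted levels are out-of-register.
#'
#' @param hbonds data.frame with columns rna_level, dna_chain, dna_level
#'   (as produced by [detect_hbonds()]).
#' @param topology `triplex_topology` (used to check levels exist).
#' @return character vector `"in"`/`"out"`.
#' @export
classify_register <- function(hbonds, topology = NULL) {
  need <- c("rna_level", "dna_chain", "dna_level")
  if (!all(need %in% names(hbonds))) {
    stop("classify_register: hbonds must have rna_level/dna_chain/dna_level")
  }
  if (!is.null(topology)) {
    lv <- c(hbonds$rna_level, hbonds$dna_level)
    if (any(is.na(lv)) || any(!lv %in% seq_len(topology$n_levels))) {
      stop("classify_register: residue without a register level")
    }
  }
  ifelse(hbonds$dna_chain == "B" & hbonds$dna_level == hbonds$rna_level,
         "in", "out")
}

#' Per-frame RNA-DNA hydrogen-bond counts
#'
#' @inheritParams detect_hbonds
#' @param tail converged-window length (ns) used for the reported mean.
#' @param levels optional register levels to restrict both partners to
#'   (the clipped extended-model comparison).
#' @return data.frame with columns frame, time, count; attribute
#'   `mean_converged` holds the mean count over the converged window.
#' @export
count_series <- function(trajectory, d_max = 3.5, a_max = 30, tail = 400,
                         levels = NULL) {
  stopifnot(inherits(trajectory, "triplex_trajectory"))
  pairs <- .hbond_pairs(trajectory$topology)
  if (!is.null(levels)) {
    pairs <- pairs[pairs$rna_level %in% levels &
                     pairs$dna_level %in% levels, ]
  }
  counts <- vapply(seq_len(n_frames(trajectory)), function(t) {
    length(.detect_frame(trajectory$coords[, , t], pairs, d_max, a_max))
  }, numeric(1))
  out <- data.frame(frame = seq_len(n_frames(trajectory)),
                    time = trajectory$times, count = counts)
  win <- suppressWarnings(converged_window(trajectory, tail))
  attr(out, "mean_converged") <- mean(counts[win])
  out
}

#' Centered running average with truncated edge windows
#'
#' Window must be odd so the window is centered; edge values average over
#' the shrunken window that fits, preserving series length. Window 1 is
#' the identity.
#'
#' @param series numeric vector.
#' @param window odd integer >= 1 (default 5).
#' @return numeric vector of the same length.
#' @export
running_average <- function(series, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("running_average: window must be odd and >= 1")
  }
  n <- length(series)
  if (window == 1L || n == 0L) return(series)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    mean(series[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Per-residue-pair hydrogen-bond occurrence map
#'
#' For every (RNA residue, DNA residue) pair seen bonded, reports the
#' fraction of analyzed frames with at least one bond and the mean number
#' of simultaneous bonds per frame ("H bond units"; can exceed 1). By
#' default statistics use the converged window. In-register pairs are
#' always marked for display; out-of-register pairs below `min_freq` are
#' flagged `shown = FALSE` but retained in the table.
#'
#' @inheritParams count_series
#' @param min_freq display threshold for out-of-register pairs (default
#'   0.01, i.e. 1 percent of frames).
#' @param all_frames use all frames instead of the converged window.
#' @return data.frame: rna_res, dna_chain, dna_res, level_offset,
#'   fraction, units, register, shown. Attribute `n_frames_used`.
#' @export
occurrence_map <- function(trajectory, d_max = 3.5, a_max = 30,
                           min_freq = 0.01, tail = 400,
                           all_frames = FALSE) {
  stopifnot(inherits(trajectory, "triplex_trajectory"))
  topo <- trajectory$topology
  pairs <- .hbond_pairs(topo)
  win <- if (all_frames) {
    seq_len(n_frames(trajectory))
  } else {
    suppressWarnings(converged_window(trajectory, tail))
  }
  key <- paste(pairs$rna_level, pairs$dna_chain, pairs$dna_level)
  # accumulate per residue-pair: total bonds and frames-with->=1-bond
  tot <- list(); present <- list()
  for (t in win) {
    hit <- .detect_frame(trajectory$coords[, , t], pairs, d_max, a_max)
    if (length(hit) == 0L) next
    kt <- table(key[hit])
    for (k in names(kt)) {
      tot[[k]] <- (if (is.null(tot[[k]])) 0 else tot[[k]]) + kt[[k]]
      present[[k]] <- (if (is.null(present[[k]])) 0L else present[[k]]) + 1L
    }
  }
  # all in-register pairs are reported even if never bonded
  in_keys <- paste(seq_len(topo$n_levels), "B", seq_len(topo$n_levels))
  keys <- union(in_keys, names(tot))
  parts <- strsplit(keys, " ")
  out <- data.frame(
    rna_res = vapply(parts, function(p) as.integer(p[1]), 1L),
    dna_chain = vapply(parts, function(p) p[2], ""),
    dna_res = vapply(parts, function(p) as.integer(p[3]), 1L),
    stringsAsFactors = FALSE
  )
  out$level_offset <- out$dna_res - out$rna_res
  nf <- length(win)
  out$fraction <- vapply(keys, function(k) {
    if (is.null(present[[k]])) 0 else present[[k]] / nf
  }, numeric(1))
  out$units <- vapply(keys, function(k) {
    if (is.null(tot[[k]])) 0 else tot[[k]] / nf
  }, numeric(1))
  out$register <- classify_register(
    data.frame(rna_level = out$rna_res, dna_chain = out$dna_chain,
               dna_level = out$dna_res), topo)
  out$shown <- out$register == "in" | out$fraction >= min_freq
  out <- out[order(out$register, out$rna_res, out$dna_chain, out$dna_res), ]
  rownames(out) <- NULL
  attr(out, "n_frames_used") <- nf
  out
}

#' Write per-frame hydrogen-bond counts (raw and smoothed) as TSV
#' @param counts output of [count_series()].
#' @param path TSV path.
#' @param window smoothing window (odd; default 5).
#' @export
write_count_series_tsv <- function(counts, path, window = 5L) {
  counts$smoothed <- running_average(counts$count, window)
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
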