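# Idealized three-strand triplex geometry.
#
# Residues of the three chains sit on a common helical axis (z), one
# register level per 'rise' Angstrom, rotated by 'twist' degrees per level.
# Within a level all atoms lie along the level's radial direction u_i at
# fixed signed offsets (Angstrom): positive offsets are the RNA side,
# negative the pyrimidine-DNA side, with the purine strand (chain B) in
# the middle. Offsets are chosen so that
#   * Hoogsteen donor..acceptor (A:D -> B:B) distance is exactly 2.9 at
#     matched levels and 5.4 (>= 5) at mismatch levels,
#   * Watson-Crick donor..acceptor (B:D -> C:B) distance is exactly 2.9,
#   * hydrogens lie on the donor->acceptor line (ideal 0 degree angle),
#   * all inter-level donor/acceptor distances exceed the 3.5 A hydrogen
#     bond cutoff by a wide margin.
.chain_offsets <- list(
  A = c(P = 14.0, S = 12.6, B = 10.4, D = 9.4, HD = 8.4),
  B = c(P = 2.0,  S = 0.0,  B = 6.5,  D = -6.5, HD = -7.5),
  C = c(P = -15.0, S = -13.4, B = -9.4, D = -11.4, HD = -12.4)
)
.mismatch_shift <- 2.5  # extra outward shift of the RNA donor group
.hbond_pose_dist <- 2.9
.unbond_pose_dist <- 5.4

.wc_complement <- c(A = "T", C = "G", G = "C", T = "A")

# radial unit vector of level i
.level_u <- function(i, twist) {
  th <- (i - 1) * twist * pi / 180
  cbind(cos(th), sin(th), 0)
}

#' Build an idealized parallel triplex from an alignment
#'
#' Constructs a three-chain topology (A = RNA third strand, B = DNA purine
#' strand, C = DNA pyrimidine strand) over the alignment's register levels
#' and a deterministic reference structure: canonical helical geometry with
#' Hoogsteen (A-B) and Watson-Crick (B-C) donor/acceptor triples posed at
#' bonding geometry (donor..acceptor 2.9 A) at matched levels and displaced
#' to >= 5 A at mismatch levels. Interior RNA cytosines use the protonated
#' template `C+`.
#'
#' @param alignment a [triplex_alignment()] of length >= 4.
#' @param rise helical rise per level, Angstrom (default 3.4).
#' @param twist helical twist per level, degrees (default 30).
#' @param params `ff_params` supplying atom charges/LJ parameters.
#' @return object of class `triplex_build`: list with `topology`
#'   (`triplex_topology`), `reference` (n_atoms x 3 coordinate matrix,
#'   Angstrom), `rise`, `twist`, `alignment`.
#' @export
build_ideal_triplex <- function(alignment, rise = 3.4, twist = 30,
                                params = default_params()) {
  stopifnot(inherits(alignment, "triplex_alignment"))
  L <- length(alignment)
  if (L < 4L) stop("build_ideal_triplex: alignment length must be >= 4")
  rna <- strsplit(alignment$rna_window, "")[[1]]
  pur <- strsplit(alignment$purine_window, "")[[1]]
  pyr <- unname(.wc_complement[pur])
  matched <- strsplit(alignment$pairing, "")[[1]] == "|"

  tmpl <- residue_template()
  rows <- list(); coords <- list()
  for (ch in c("A", "B", "C")) {
    off <- .chain_offsets[[ch]]
    for (i in seq_len(L)) {
      base <- switch(ch, A = rna[i], B = pur[i], C = pyr[i])
      resname <- if (ch == "A") {
        if (base == "C" && i > 1L && i < L) "C+" else base
      } else {
        paste0("D", base)
      }
      charges <- tmpl$charge
      names(charges) <- tmpl$name
      ov <- params$residue_overrides[[resname]]
      if (!is.null(ov$charge)) charges[names(ov$charge)] <- ov$charge
      o <- off[tmpl$name]
      # mismatch levels: push the RNA Hoogsteen donor group out of
      # bonding range
      if (ch == "A" && !matched[i]) {
        o[c("D", "HD")] <- o[c("D", "HD")] + .mismatch_shift
      }
      u <- .level_u(i, twist)
      xyz <- outer(o, u[1, ]) # n x 3
      xyz[, 3] <- xyz[, 3] + (i - 1) * rise
      rows[[length(rows) + 1L]] <- data.frame(
        name = tmpl$name, element = tmpl$element, chain = ch,
        resname = resname, level = i, terminal = i == 1L | i == L,
        charge = unname(charges[tmpl$name]), sigma = tmpl$sigma,
        epsilon = tmpl$epsilon, is_backbone = tmpl$is_backbone,
        is_acceptor = tmpl$is_acceptor, is_donor = tmpl$is_donor,
        is_hydrogen = tmpl$is_hydrogen, stringsAsFactors = FALSE
      )
      coords[[length(coords) + 1L]] <- xyz
    }
  }
  atoms <- do.call(rbind, rows)
  reference <- do.call(rbind, coords)
  rownames(reference) <- NULL
  # hydrogens are covalently bound to the donor of the same residue
  atoms$donor_parent <- NA_integer_
  hyd <- which(atoms$is_hydrogen)
  for (h in hyd) {
    atoms$donor_parent[h] <- which(
      atoms$chain == atoms$chain[h] & atoms$level == atoms$level[h] &
        atoms$is_donor
    )
  }
  topology <- structure(
    list(n_levels = L, chain_roles = .chain_roles,
         pairing = alignment$pairing, atoms = atoms),
    class = "triplex_topology"
  )
  validate_topology(topology)
  structure(
    list(topology = topology, reference = reference, rise = rise,
         twist = twist, alignment = alignment),
    class = "triplex_build"
  )
}

#' @export
print.triplex_build <- function(x, ...) {
  cat(sprintf("<triplex_build> %d levels (%d matched), rise %.2f A, twist %.1f deg\n",
              x$topology$n_levels,
              sum(strsplit(x$topology$pairing, "")[[1]] == "|"),
              x$rise, x$twist))
  invisible(x)
}

# atom row index helper: single atom (chain, level, name)
.atom_idx <- function(topology, chain, level, name) {
  which(topology$atoms$chain == chain & topology$atoms$level == level &
          topology$atoms$name == name)
}
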