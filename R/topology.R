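#' Minimal five-atom residue template
#'
#' Each residue carries exactly five pseudo-atoms, sufficient for every
#' implemented observable (hydrogen-bond geometry, backbone-inclusive
#' energies, stacking/cross/level decompositions):
#' \describe{
#'   \item{P}{phosphate, backbone}
#'   \item{S}{sugar, backbone}
#'   \item{B}{base acceptor (hydrogen-bond acceptor)}
#'   \item{D}{base donor heavy atom}
#'   \item{HD}{hydrogen covalently bound to D}
#' }
#' Charges sum to -1 e per residue (the phosphate); the protonated cytosine
#' template `C+` carries one extra elementary charge on its donor group.
#'
#' @return data.frame with columns name, element, charge, sigma, epsilon
#'   and logical role columns is_backbone, is_acceptor, is_donor,
#'   is_hydrogen.
#' @export
residue_template <- function() {
  data.frame(
    name = c("P", "S", "B", "D", "HD"),
    element = c("P", "C", "N", "N", "H"),
    charge = c(-1.0, 0.2, -0.4, -0.3, 0.5),
    sigma = c(4.0, 3.6, 3.2, 3.2, 1.0),       # Angstrom
    epsilon = c(0.8, 0.6, 0.4, 0.4, 0.1),     # kJ/mol
    is_backbone = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    is_acceptor = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    is_donor = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    is_hydrogen = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Default toy force-field parameter set
#'
#' These are NOT a real nucleic-acid force field: they are a minimal,
#' readable parameter set for exercising the decomposition math. The
#' Coulomb constant and the 10 Angstrom short-range cutoff follow the
#' GROMACS conventions (f = 1389.35458 kJ mol^-1 A e^-2, i.e.
#' 138.935458 kJ mol^-1 nm e^-2). Residue-level charge overrides hold the
#' protonated-cytosine entry.
#'
#' @param cutoff short-range cutoff in Angstrom.
#' @return list of class `ff_params` with `coulomb`, `cutoff`,
#'   `atom_types` (from [residue_template()]) and `residue_overrides`.
#' @export
default_params <- function(cutoff = 10) {
  if (cutoff <= 0) stop("default_params: cutoff must be > 0")
  structure(
    list(
      coulomb = 1389.35458,
      cutoff = cutoff,
      atom_types = residue_template()[, c("name", "charge", "sigma",
                                          "epsilon")],
      # protonated cytosine: +1 e spread over the Hoogsteen donor group
      residue_overrides = list(
        `C+` = list(charge = c(D = 0.2, HD = 1.0))
      )
    ),
    class = "ff_params"
  )
}

#' Write/read force-field parameters as JSON
#' @param params `ff_params` object.
#' @param path JSON file path.
#' @export
write_params_json <- function(params, path) {
  x <- unclass(params)
  # keep override names: serialize named charge vectors as objects
  x$residue_overrides <- lapply(x$residue_overrides, function(o) {
    list(charge = as.list(o$charge))
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$coulomb) || is.null(p$cutoff) || p$cutoff <= 0) {
    stop("read_params_json: malformed parameter file ", path)
  }
  ro <- p$residue_overrides
  if (!is.null(ro)) {
    ro <- lapply(ro, function(o) list(charge = unlist(o$charge)))
  }
  structure(list(coulomb = p$coulomb, cutoff = p$cutoff,
                 atom_types = p$atom_types, residue_overrides = ro),
            class = "ff_params")
}

# chain roles are fixed: A = RNA third strand, B = central DNA purine
# strand (the only chain with cross terms to both others), C = DNA
# pyrimidine strand.
.chain_roles <- c(A = "rna_third_strand", B = "dna_purine",
                  C = "dna_pyrimidine")

#' Select atoms from a topology
#'
#' Selectors compose by intersection. `selection` accepts the shorthand
#' labels `"rna"` (the chain with role rna_third_strand), `"duplex"` (the
#' union of the two DNA chains) and `"all"`.
#'
#' @param topology a `triplex_topology`.
#' @param chain chain id(s) in `A,B,C`, or `NULL`.
#' @param role any of `donor,hydrogen,acceptor,backbone`, or `NULL`.
#' @param levels integer register levels, or `NULL`.
#' @param selection `"rna"`, `"duplex"` or `"all"`, or `NULL`.
#' @return sorted integer vector of atom indices (row indices into
#'   `topology$atoms`).
#' @export
select_atoms <- function(topology, chain = NULL, role = NULL, levels = NULL,
                         selection = NULL) {
  stopifnot(inherits(topology, "triplex_topology"))
  at <- topology$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(selection)) {
    if (!selection %in% c("rna", "duplex", "all")) {
      stop("select_atoms: unknown selection '", selection,
           "' (available: rna, duplex, all)")
    }
    keep <- keep & switch(selection,
      rna = at$chain == "A",
      duplex = at$chain %in% c("B", "C"),
      all = TRUE
    )
  }
  if (!is.null(chain)) {
    bad <- setdiff(chain, c("A", "B", "C"))
    if (length(bad)) {
      stop("select_atoms: unknown chain '", bad[1], "' (available: A, B, C)")
    }
    keep <- keep & at$chain %in% chain
  }
  if (!is.null(role)) {
    bad <- setdiff(role, c("donor", "hydrogen", "acceptor", "backbone"))
    if (length(bad)) {
      stop("select_atoms: unknown role '", bad[1],
           "' (available: donor, hydrogen, acceptor, backbone)")
    }
    rk <- rep(FALSE, nrow(at))
    if ("donor" %in% role) rk <- rk | at$is_donor
    if ("hydrogen" %in% role) rk <- rk | at$is_hydrogen
    if ("acceptor" %in% role) rk <- rk | at$is_acceptor
    if ("backbone" %in% role) rk <- rk | at$is_backbone
    keep <- keep & rk
  }
  if (!is.null(levels)) {
    bad <- setdiff(levels, seq_len(topology$n_levels))
    if (length(bad)) {
      stop("select_atoms: unknown level ", bad[1], " (available: 1..",
           topology$n_levels, ")")
    }
    keep <- keep & at$level %in% levels
  }
  which(keep)
}

#' @export
print.triplex_topology <- function(x, ...) {
  cat(sprintf(
    "<triplex_topology> %d levels, 3 chains (A=%s, B=%s, C=%s), %d atoms\n",
    x$n_levels, .chain_roles[["A"]], .chain_roles[["B"]], .chain_roles[["C"]],
    nrow(x$atoms)))
  invisible(x)
}

#' Write/read a topology as JSON
#' @param topology `triplex_topology`.
#' @param path JSON path.
#' @export
write_topology_json <- function(topology, path) {
  stopifnot(inherits(topology, "triplex_topology"))
  jsonlite::write_json(
    list(
      n_levels = topology$n_levels,
      chain_roles = as.list(topology$chain_roles),
      pairing = topology$pairing,
      atoms = topology$atoms
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  at <- as.data.frame(x$atoms, stringsAsFactors = FALSE)
  need <- c("name", "element", "chain", "resname", "level", "terminal",
            "charge", "sigma", "epsilon", "is_backbone", "is_acceptor",
            "is_donor", "is_hydrogen", "donor_parent")
  miss <- setdiff(need, names(at))
  if (length(miss)) {
    stop("read_topology_json: missing atom fields: ",
         paste(miss, collapse = ", "))
  }
  structure(
    list(n_levels = x$n_levels, chain_roles = unlist(x$chain_roles),
         pairing = x$pairing, atoms = at),
    class = "triplex_topology"
  )
}

# validate structural invariants of a topology (used after JSON read and
# by the builder)
validate_topology <- function(topology) {
  at <- topology$atoms
  if (!all(sort(unique(at$chain)) == c("A", "B", "C"))) {
    stop("topology: expected exactly chains A, B, C")
  }
  for (ch in c("A", "B", "C")) {
    lv <- sort(unique(at$level[at$chain == ch]))
    if (!identical(lv, seq_len(topology$n_levels))) {
      stop("topology: chain ", ch, " does not cover levels 1..",
           topology$n_levels)
    }
  }
  hyd <- which(at$is_hydrogen)
  if (any(is.na(at$donor_parent[hyd]))) {
    stop("topology: hydrogen without a covalent donor parent")
  }
  if (!all(at$is_donor[at$donor_parent[hyd]])) {
    stop("topology: hydrogen parent is not a donor atom")
  }
  if (any(!is.finite(at$charge)) || any(at$sigma <= 0) ||
      any(at$epsilon < 0)) {
    stop("topology: invalid charge/LJ parameters")
  }
  invisible(topology)
}
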