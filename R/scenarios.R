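# Scenario presets: the package's self-contained test universe. Four
# named presets emulate the qualitative behaviour of the four simulated
# triplex systems (a stable and a less-stable binding-mode alternative,
# and a short model whose too-narrow boundaries fray versus its extended
# fix). Sequences are SYNTHETIC STAND-INS: they are not the published
# binding sites, but are constructed to satisfy every printed
# sequence-level fact (15-nt parallel pyr/d-pur windows whose pairing is
# interrupted by exactly one C-dT and one G-dG mismatch, adjacent and
# immediately followed by a U.A-T pair; an extended variant containing
# the short window as a unique contiguous subsequence).

#' Synthetic stand-in triplex alignments
#'
#' Returns the four stand-in alignments used by the scenario presets:
#' `stable_A` and `unstable_A` (two slightly different 15-nt binding-mode
#' alternatives on one promoter-like purine tract) and `short` /
#' `extended` (a 15-nt window and its 21-nt extension with canonical
#' flanks). All are parallel, with exactly one C-dT and one G-dG
#' mismatch; the extension's clip region equals the short alignment.
#'
#' @return named list of [triplex_alignment()] objects.
#' @export
example_alignments <- function() {
  mk <- function(rna_seq, pur_seq, rid, pid) {
    triplex_alignment(
      sequence_record(rid, rna_seq, "rna"),
      sequence_record(pid, pur_seq, "dna"),
      rna_start = 1L, purine_start = 1L, window_len = nchar(rna_seq)
    )
  }
  list(
    stable_A = mk("UCCUUCCGUCUCCUU", "AGGAAGTGAGAGGAA",
                  "synthetic_dbd_A1", "synthetic_promoterA_site1"),
    unstable_A = mk("CCUUCCGUCUCCUUC", "GGAAGTGAGAGGAAG",
                    "synthetic_dbd_A2", "synthetic_promoterA_site2"),
    short = mk("CUUCCUCGUCCUUCU", "GAAGGATGAGGAAGA",
               "synthetic_dbd_N", "synthetic_promoterN_site"),
    extended = mk("UCUCUUCCUCGUCCUUCUCCU", "AGAGAAGGATGAGGAAGAGGA",
                  "synthetic_dbd_Next", "synthetic_promoterN_site_ext")
  )
}

#' Scenario presets for the synthetic trajectory universe
#'
#' Occupancies are chosen so the analysis readouts qualitatively mirror
#' the stable-versus-unstable orderings without copying MD-derived
#' magnitudes: `stable_A` plants 27 expected bonds per frame (13 matched
#' levels x 2 bonds x 0.96 + 2 mismatch levels x 2 x 0.51),
#' `unstable_A` 20, `short_frayed` 15 with terminal fraying after half
#' the run, and `extended_stable` the stable occupancies on a 21-level
#' extension whose clipped region equals `short_frayed`'s alignment.
#' All presets run 2000 frames at dt 0.3 ns (600 ns span) with 0.2 A
#' coordinate noise.
#'
#' @return named list of preset definitions.
#' @export
scenario_presets <- function() {
  aln <- example_alignments()
  occ_for <- function(alignment, occ_match, occ_mismatch, n_bonds = 2L) {
    matched <- strsplit(alignment$pairing, "")[[1]] == "|"
    occupancy_map(
      level = seq_along(matched),
      occupancy = ifelse(matched, occ_match, occ_mismatch),
      n_bonds = n_bonds
    )
  }
  list(
    stable_A = list(
      alignment = aln$stable_A,
      occupancies = occ_for(aln$stable_A, 0.96, 0.51),
      n_frames = 2000L, dt = 0.3, noise_sigma = 0.2, fray = NULL
    ),
    unstable_A = list(
      alignment = aln$unstable_A,
      occupancies = occ_for(aln$unstable_A, 0.75, 0.125),
      n_frames = 2000L, dt = 0.3, noise_sigma = 0.2, fray = NULL
    ),
    short_frayed = list(
      alignment = aln$short,
      occupancies = occ_for(aln$short, 0.55, 0.175),
      n_frames = 2000L, dt = 0.3, noise_sigma = 0.2,
      fray = list(after_frame = 1000L, levels = 2L, max_shift = 12)
    ),
    extended_stable = list(
      alignment = aln$extended,
      occupancies = occ_for(aln$extended, 0.96, 0.51),
      n_frames = 2000L, dt = 0.3, noise_sigma = 0.2, fray = NULL,
      clip_to = aln$short
    )
  )
}

#' Write a triplex alignment as JSON
#' @param alignment `triplex_alignment`.
#' @param path JSON path.
#' @export
write_alignment_json <- function(alignment, path) {
  stopifnot(inherits(alignment, "triplex_alignment"))
  jsonlite::write_json(unclass(alignment), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_alignment_json
#' @export
read_alignment_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- triplex_alignment(
    sequence_record(x$rna_id, x$rna_window, "rna"),
    sequence_record(x$purine_id, x$purine_window, "dna"),
    rna_start = 1L, purine_start = 1L, window_len = nchar(x$rna_window)
  )
  a$rna_start <- x$rna_start; a$rna_end <- x$rna_end
  a$purine_start <- x$purine_start; a$purine_end <- x$purine_end
  if (a$pairing != x$pairing) {
    stop("read_alignment_json: stored pairing inconsistent with sequences")
  }
  a
}

#' Generate a scenario: topology, trajectory, truth and parameter files
#'
#' One command produces every input the analysis modules need, fully
#' reproducible from the seed: `alignment.json`, `topology.json`,
#' `params.json`, `traj.pdb` (+ `.times.json` sidecar) and `truth.json`
#' in `out_dir`.
#'
#' @param preset preset name (see [scenario_presets()]).
#' @param out_dir output directory (created if needed); `NULL` skips
#'   file output and just returns the objects.
#' @param seed integer RNG seed.
#' @return (invisibly) list with `alignment`, `build`, `trajectory`,
#'   `truth`, `params`, `preset`, and `clip_levels` (extended preset
#'   only).
#' @export
make_scenario <- function(preset, out_dir = NULL, seed = 7L) {
  presets <- scenario_presets()
  if (!preset %in% names(presets)) {
    stop("make_scenario: unknown preset '", preset, "' (available: ",
         paste(names(presets), collapse = ", "), ")")
  }
  p <- presets[[preset]]
  params <- default_params()
  build <- build_ideal_triplex(p$alignment, params = params)
  syn <- synthesize_trajectory(
    build, n_frames = p$n_frames, dt = p$dt, noise_sigma = p$noise_sigma,
    occupancies = p$occupancies, seed = seed, fray = p$fray
  )
  clip_levels <- NULL
  if (!is.null(p$clip_to)) {
    clipped <- clip_alignment(p$alignment, p$clip_to)
    clip_levels <- seq.int(clipped$clip_offset,
                           clipped$clip_offset + length(clipped) - 1L)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_alignment_json(p$alignment, file.path(out_dir, "alignment.json"))
    write_topology_json(build$topology, file.path(out_dir, "topology.json"))
    write_params_json(params, file.path(out_dir, "params.json"))
    write_trajectory_pdb(syn$trajectory, file.path(out_dir, "traj.pdb"))
    write_truth_json(syn$truth, file.path(out_dir, "truth.json"))
  }
  invisible(list(
    alignment = p$alignment, build = build, trajectory = syn$trajectory,
    truth = syn$truth, params = params, preset = preset,
    clip_levels = clip_levels
  ))
}
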