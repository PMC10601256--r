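---
title: "Models and methods: parallel triplex prediction and trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: parallel triplex prediction and trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplexlens)
```

## The problem

A lncRNA can bind promoter DNA as a third strand in the major groove of
the Watson–Crick duplex, forming a triple helix. In the parallel
(pyrimidine) motif the third strand runs 5'→3' parallel to the duplex
purine strand and reads it through Hoogsteen hydrogen bonds; the
canonical triplets are U·A–T and C⁺·G–C, where C⁺ is N3-protonated
cytosine. `triplexlens` provides (1) a strict canonical-code scanner for
candidate triplex target sites, and (2) a trajectory-analysis stack —
hydrogen-bond networks, RMSD, and a per-base-pair-level LJ+Coulomb
energy decomposition — validated against a synthetic triplex trajectory
generator whose planted ground truth is machine-checkable.

## The canonical-code scanner

`canonical_triplet_match()` accepts exactly two pairings: RNA U opposite
purine-strand A, and RNA C opposite purine-strand G. This is a design
choice: the modeled systems are parallel pyrimidine-motif triplexes, so
G·T and the antiparallel purine-motif triplets are excluded rather than
scored. Whether the upstream statistical predictor that motivates such
scans admits non-canonical triplets or gaps is not documented; the
scanner here is deliberately strict-canonical with an explicit mismatch
budget (`max_mismatch`), which makes its output enumerable and testable
against a brute-force oracle.

Conventions, fixed throughout the sequence interfaces:

* coordinates are 1-based and inclusive on both ends (a DBD annotated at
  nt 1896–1925 has length 30); conversion to 0-based half-open happens
  only at the BED boundary;
* RNA containing T (or DNA containing U) is a validation error, never a
  silent transliteration — `dna_as_rna()` converts explicitly;
* among equal-mismatch windows the order is lexicographic in
  (purine offset, RNA offset); no biological ranking is implied;
* a duplex supplied as two strands is scanned on the strand with more
  purines, overridable with `force` (strand selection is otherwise
  undocumented in the field's site tables).

`clip_alignment()` restricts an extended model to the span of its short
core and refuses ambiguous or absent matches: extended models exist to
tame terminal fraying, and comparisons between short and extended
variants are only meaningful on the shared span.

### Stand-in sequences

The package's example sites (`example_alignments()`) are **synthetic
stand-ins**, not published promoter sequences. They are constructed to
satisfy the documented sequence-level facts: 15-nt parallel windows of
RNA-pyrimidine/DNA-purine pairs interrupted by exactly one C·dT and one
G·dG mismatch, adjacent and immediately followed by a canonical U·A–T
pair, plus a 21-nt extended variant whose canonical flanks contain the
short window at a unique offset. Every property claimed for them is
asserted in the test suite; nothing depends on their exact letters
beyond those properties.

## The synthetic trajectory generator

`build_ideal_triplex()` places three chains (A = RNA third strand,
B = DNA purine strand — the central chain, the only one with cross
terms to both neighbors — and C = DNA pyrimidine strand) on a common
helical axis: rise 3.4 Å and twist 30° per register level, the textbook
B-form-like values. Each residue is a minimal 5-atom template —
P (phosphate), S (sugar), both backbone; B (base acceptor); D (base
donor heavy atom); HD (its hydrogen) — which is sufficient for every
implemented observable while keeping fixtures human-readable. Atoms sit
at fixed signed radial offsets chosen so that:

* Hoogsteen donor–acceptor distances (A:D → B:B) are exactly 2.9 Å at
  matched levels and 5.4 Å (≥ 5 Å) at mismatch levels, with hydrogens on
  the bond axis (ideal 0° angle);
* Watson–Crick B:D → C:B distances are exactly 2.9 Å at every level;
* every inter-level donor–acceptor distance exceeds the 3.5 Å detection
  cutoff by a wide margin, so no bond can be detected that was not
  planted.

Interior RNA cytosines use the protonated template `C+`, carrying one
extra elementary charge on the donor group — mirroring the convention of
parameterizing protonated cytosine for all non-terminal cytosines.

`synthesize_trajectory()` emits frames as reference + iid isotropic
Gaussian noise (default σ = 0.2 Å), **except** that each in-register
donor/hydrogen/acceptor triple is posed deterministically every frame:
at bonding geometry with the planted per-level probability, otherwise
displaced to ≥ 5 Å. Posing the triple exactly (noise-free) is a
deliberate choice: it makes detected occupancy equal the generator's own
Bernoulli draws, so planted-truth recovery is exactly binomial and the
acceptance tolerance (3 binomial standard errors) is a statement about
sampling, not about detector slack. A second simultaneous bond per pair
(`n_bonds = 2`) is realized by swinging the purine Watson–Crick donor up
to the RNA acceptor along the helix axis, the one approach direction
with no atom within clash range; this lets occurrence maps exceed 1
"H bond unit" as real triplex pairs do. Optional fraying displaces the
RNA and pyrimidine strands of the terminal levels outward, linearly in
frame number after `after_frame` (default full displacement 12 Å),
emulating the artefactual strand separation of a too-narrow binding-site
model.

What the generator does **not** emulate: solvation, ions, correlated
thermal motion, base-specific donor/acceptor multiplicity, backbone
torsional dynamics, energy conservation. A green test therefore
establishes that the *analysis* is correct against planted truth — it
says nothing about force-field realism, and the toy parameter set
(`default_params()`) is likewise a readable fixture (e.g. phosphate
charge −1.0 e, σ between 1.0 and 4.0 Å), not a nucleic-acid force field.

## Trajectory analyses

**Hydrogen bonds.** Detection is geometric — donor–acceptor ≤ 3.5 Å and
H-D-A angle ≤ 30°, the common gmx-hbond convention, adopted because the
analyses this package mirrors were run with GROMACS tooling without
stating criteria; both cutoffs are arguments. Only RNA↔DNA bonds are
counted. *In-register* is interpreted as: the DNA partner is the
purine-strand residue at the same register level as the RNA residue;
bonds to the pyrimidine strand or to level i±1 are out-of-register. The
alternative reading (admitting pyrimidine-strand bonds as in-register)
cannot be excluded from the available descriptions; the purine-strand
reading matches occurrence-lane labels that name single purine-strand
residues, and is flagged here as an interpretation. Out-of-register
pairs below 1% frequency are suppressed from rendered output but kept in
the raw table. Per-frame counts are smoothed with a centered window-5
running average; edges use truncated (shrinking) windows rather than NA
padding so the series keeps its length for plotting.

**RMSD.** `superpose()` is the SVD form of the Kabsch algorithm with the
determinant correction (rotations are always proper). The reference is
frame 1 — the generator's start structure, matching the common MD
convention when the reference is unstated — and weighting is uniform
(the toy atoms have no masses). `converged_window()` is operator-
specified (trailing `tail` ns, default 400): convergence is asserted,
not auto-detected, because the analysis it mirrors asserts it.

**Energies.** Pair energies are Lennard-Jones with Lorentz–Berthelot
combining plus Coulomb `f·q_i·q_j/r`, `f = 1389.35458 kJ·mol⁻¹·Å·e⁻²`,
both zero beyond the 10 Å cutoff. There are no periodic boundaries and
no long-range electrostatics: the synthetic systems are vacuum toys and
only the short-range cutoff sums are defined. The per-level
decomposition at level i is

* hydrogen-bond term: all atom pairs between (A_i,B_i), (B_i,C_i),
  (A_i,C_i) — all three inter-chain pairs, since the defining
  description is generic in the chains; a `pairs = "rna"` mode restricts
  to RNA-involving pairs for sensitivity analysis;
* cross term: B_i against A_{i±1} and C_{i±1};
* stacking term: X_i against X_{i+1} within each chain X (a base-pair
  step quantity).

Any contribution involving a terminal residue is dropped, uniformly
across the three terms, to keep the number of contributing terms
comparable between levels. Consequently the profile covers levels
2..L−1, and the stacking entry at level L−1 (whose step would touch the
terminal level) is `NA`; the total at that level sums the remaining
terms. The decomposition is asserted numerically against a brute-force
all-pairs double loop at 1e−9 relative tolerance.

## Scenario presets

Four presets span the qualitative behaviours of interest. Occupancies
are calibrated once to the stated per-frame bond expectations — 27
(stable_A), 20 (unstable_A), 15 before fraying (short_frayed), and the
stable occupancies on the 21-level extension (extended_stable) — using
2 planted bonds per level: e.g. 13 matched levels × 2 × 0.96 + 2
mismatch levels × 2 × 0.51 = 27.0. All presets run 2000 frames at
dt = 0.3 ns (a 600 ns span analyzed over the last 400 ns) with 0.2 Å
noise; `short_frayed` frays 2 terminal levels per end after frame 1000.
These magnitudes are preset definitions, fixed before any measurement;
the tests verify that the analysis recovers them and their orderings
(more bonds ⇒ more negative RNA–DNA interaction energy; intact
in-register lanes in the clipped extended model versus degraded terminal
lanes in the frayed short model).

## Numerical choices and degenerate inputs

* Superposition refuses selections whose centered coordinates are rank-
  deficient (collinear/coincident atoms) at a relative singular-value
  threshold of 1e−8.
* `pair_energy()` treats r = 0 as a singularity error; the cutoff test
  is `r ≤ r_c` (closed boundary).
* A trajectory must carry strictly increasing frame times, from a JSON
  sidecar, an explicit vector, or `--dt`; having none is an error
  because windowed averages are time-based.
* A truncated final PDB MODEL is an error, never a silent drop; atom
  records are validated against the topology and the first offender is
  named.
* `running_average()` requires an odd window so the window is centered.
* ΔΔCt uses amplification efficiency 2.0 (exposed as a parameter but
  not corrected per assay); the ChIP/CLIP material-fraction correction
  subtracts `log2(f_IP/f_input)` cycles from the input Ct — the standard
  percent-input form, adopted because the exact printed formula is not
  available; results carry it explicitly in code, and identities
  (control → 1, one cycle → 2, shift invariance) pin its behaviour.

## Known limitations

* The scanner does not score thermodynamic stability, pH-dependent C⁺
  stability, or genome-wide statistical enrichment of target sites.
* The generator's noise is uncorrelated and isotropic; RMSD series lack
  the slow relaxations of real trajectories, so convergence-window
  logic is exercised only mechanically.
* Energies are comparable *within* this package's toy parameter set
  only; absolute magnitudes are meaningless relative to any real force
  field.
* Multi-model PDB is the only trajectory format; compressed MD formats
  (XTC/DCD) and mmCIF are out of scope.
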