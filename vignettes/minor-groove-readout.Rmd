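---
title: "DNA minor-groove shape readout: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA minor-groove shape readout: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minorgroove)
```

# The scientific question

Several chromatin-binding modules — among them PWWP domains of the HDGF
family — bind double-stranded DNA not by reading its sequence but by reading
its *shape*: they contact the phosphate backbone of the minor groove and
prefer DNA whose minor groove is already narrow. TA-rich tracts form narrow
minor grooves because of negative propeller twisting and higher helical
twist; narrow grooves in turn focus the electric field of the phosphates,
deepening the negative electrostatic potential at the groove centre and
attracting basic side chains (arginine readout, "electrostatic focusing").

This package implements the complete computational chain behind that
argument so it can be applied to any protein–DNA complex and validated
end-to-end on synthetic data:

1. coordinate I/O (PDB and the mmCIF `atom_site` loop);
2. Watson–Crick pair identification and standard-reference-frame fitting;
3. intra-base-pair and base-pair-step helical parameters (propeller twist,
   helical twist, roll, ...);
4. minor-groove width profiles by the cross-strand phosphate method;
5. a finite-difference linearized Poisson–Boltzmann (PB) solver and a
   7-point potential sampler at the groove midpoints;
6. Kabsch superposition and single-site Kd fitting of NMR
   chemical-shift-perturbation (CSP) titrations;
7. a synthetic B-DNA builder that makes every stage testable without
   structure downloads.

# Helical parameters: the mid-frame scheme

Each base carries the community *standard reference frame*: origin between
the paired bases, x toward the major groove, y toward the reference-strand
backbone, z along the helix toward the 3' end of the reference strand.
Frames are fitted by least-squares superposition of idealized base templates
onto the observed ring atoms (`base_frame()`); the fit RMSD doubles as a
quality flag (pairs with RMSD ≥ 0.5 Å are excluded from averages).

Parameters are computed with a mid-frame (CEHS-style) decomposition. For a
step with twist ω, roll ρ and tilt τ the frame transform is

    R = Rz(ω/2 − φ) · Ry(Γ) · Rz(ω/2 + φ),  Γ = √(ρ² + τ²),  φ = atan2(τ, ρ)

and the translations (shift, slide, rise) are expressed in the mid-step
triad. Intra-base-pair parameters use the same decomposition after flipping
the strand-II frame 180° about its x axis, with (buckle, propeller, opening)
in the roles of (tilt, roll, twist). Two properties motivated this choice:

* **Self-inverse.** The duplex builder composes frames with exactly this
  scheme, so analysis of a built duplex recovers the generating profile to
  machine precision. The acceptance suite verifies 200 random profiles in
  the B-form box (twist 25–45°, |propeller| ≤ 20°, rise 2.8–4.0 Å) to
  0.1°/0.01 Å; the observed error is ~1e-12.
* **Sign-robust extraction.** A naive ZYZ Euler extraction is ambiguous at
  zero twist (pure propeller flips sign depending on rounding). The
  implementation uses the hinge-axis formulation — bend axis z1 × z2, both
  frames rotated by ∓Γ/2 onto the common z — whose signed hinge removes the
  branch ambiguity.

Because the literature is ambiguous about whether a reported "helical twist"
is the local step twist or the screw-axis rotation, both are emitted: the
`twist` column (mid-frame twist) and `h_twist` (rotation angle about the
true screw axis of the step, signed by its projection on the mean helical
direction). For a pure-twist step they coincide.

Strand-swap behaviour follows the standard convention and is tested:
swapping the reference strand negates shear, buckle, shift and tilt and
leaves the other eight parameters unchanged.

# Pair identification

`find_base_pairs()` screens all nucleotide residue pairs against:
complementary base types; C1'–C1' distance 8.5–12.0 Å; ≥ 2 Watson–Crick-edge
donor–acceptor heavy-atom contacts < 3.6 Å; base-plane normal angle < 65°
(undirected, since pairing is antiparallel); fitted-frame origin distance
< 2.5 Å. Candidates are accepted greedily by increasing origin distance with
each residue used at most once. The criteria are deliberately permissive for
crystal-structure distortion but strict enough to reject stacked neighbours;
a brute-force enumeration over all residue pairs under the same criteria is
part of the test suite and must give the identical pair set.

# Minor-groove widths

The width at base i of the reference strand is the raw Euclidean distance
between the phosphate P of residue i (strand I) and the phosphate of the
strand-II residue four pairs away. Both register offsets (±4 pairs) are
evaluated through the pairing map — never through raw author numbering — and
the span whose midpoint lies on the minor-groove side of the local pair
frame (negative x) is kept; entries with no minor-groove span (termini
lacking phosphates) are omitted and listed. Widths are reported as **raw
P–P distances** because narrow-groove readout work quotes that scale;
`subtract_radius = TRUE` applies the conventional 5.8 Å phosphate-diameter
subtraction. Electrostatic potentials are sampled at the midpoints of
exactly these phosphate pairs.

The protein "footprint" annotation marks an entry bound when any protein
atom lies within a cutoff (default 5.0 Å, heavy atoms) of either phosphate.
The number is a package choice — the source analyses never define the bound
region numerically — so it is configurable and recorded in the report.

The global bend estimate fits a straight axis segment (first principal
direction of pair-frame origins) to the first and last 6 pairs and reports
the angle between the segments, total and normalized per 6 bp. This is an
axis-segment approximation, not a curvilinear-axis reconstruction; on a
built duplex with a single 10° central roll kink it recovers 10° ± 2°, and
the working tolerance for comparisons with curvilinear-axis programs is
±1.5°.

# Electrostatics

`solve_pb()` solves the linearized PB equation on a cubic lattice,

    ∇·(ε∇φ) − ε_out κ̄² λ φ = −4π λ_B ρ,

with φ in kT/e, distances in Å and charges in e (λ_B is the vacuum Bjerrum
length e²/4πε₀kT ≈ 560.5 Å at 298.15 K). Defaults follow the reproduction
setting: solute dielectric 2, solvent 80, 0.145 M 1:1 salt (Debye length
8.06 Å), solvent probe 1.4 Å, Stern layer 2.0 Å, 4 grids/Å, solute filling
70% of the box edge. Implementation choices:

* **Dielectric map.** A node is solute if it lies inside the probe-expanded
  atom spheres and survives erosion by the probe (the two-pass lattice
  approximation of the molecular surface), or inside any vdW sphere. Link
  dielectrics are harmonic means of the node values.
* **Salt map.** The Debye term is switched off inside the solute and its
  Stern shell (atom radius + 2.0 Å).
* **Charges** are spread trilinearly to the 8 surrounding nodes.
* **Boundary.** Debye–Hückel monopole of the total charge on the box faces.
* **Solver.** Red–black SOR with the Chebyshev-estimated optimal relaxation
  factor; convergence at max |update| < 1e-4 kT/e, max 10,000 sweeps (a
  non-converged solve is an error, never a silent result).
* **Box fill.** "Solute occupies 70% of the box" is read as the largest
  linear extent being 70% of the box edge (the convention of grid-based PB
  codes); `fill_mode = "volumetric"` gives the literal volumetric reading.

Against closed forms the solver matches the uniform-dielectric Coulomb
potential to < 1% and the screened Yukawa form to < 1% over the 5–15 Å
shell (acceptance tolerances 5%/10%), doubles exactly under charge doubling,
and reproduces Gauss's law flux to ~3%. Groove-midpoint samples move by
< 0.2 kT/e between 2 and 4 grids/Å on a 10-bp duplex. The per-point sampler
averages the nearest node with its six axis neighbours (7 points), so it is
exact on constant fields and returns the nodal value on linear fields.

**Charge model.** The shipped charge/radius table is a *synthetic*
AMBER-style reconstruction, not the force field itself (whose files are not
redistributable here): hydrogens are collapsed onto bonded heavy atoms, the
full −1 e phosphodiester charge sits on P, and each base + C1' group is
neutral with a chemically reasonable internal distribution; radii are
element-based (C 1.91, N 1.82, O 1.66, P 2.10, S 2.00 Å). Per-nucleotide
formal sums are exact (−1 e per internal nucleotide; a 16-bp duplex with
5'-OH ends carries −30 e), which is what groove-scale electrostatics is
dominated by. Protein atoms (optional, `include_protein = TRUE`) carry
formal charges on Arg/Lys/Asp/Glu termini only. Protonation is fixed at
standard states — at pH 7.4 these coincide with expected assignments for
DNA; the pKa-calculation step of a full reproduction is a documented
limitation. By default only the DNA is charged, since the shape comparison
is between naked DNA molecules.

# The synthetic-data generator

`build_duplex()` turns a 5'→3' sequence and a helical-parameter profile into
all-atom duplex coordinates: base (and C1') templates in the standard
reference frame are placed by the intra-pair half-transforms, pair frames
are chained by the step transforms, and the backbone is *minimal* — one
idealized phosphate per non-5'-terminal residue, placed in the base frame.
Chain B runs 1..n along its own 5'→3' direction so that pairing is
established geometrically downstream rather than baked into the numbering.

The phosphate template position was calibrated **once** against canonical
fiber-B geometry — P at ~9.3 Å from the helix axis, a raw cross-strand
minor-groove P–P distance of 11.7 Å for straight B-DNA (canonical ~11.5 Å),
and the physical requirement that negative propeller and higher twist narrow
the groove — and then frozen in the fixture. With it the presets give mean
raw widths of 11.0 Å (`ta_like`: twist 37.1°, propeller −11.2°) versus
11.7 Å (`gc_like`: twist 35.3°, propeller −7.3°), reproducing the direction
and roughly the geometric part of the narrow-vs-wide contrast.

What the generator deliberately does **not** emulate: sequence-dependent
parameter prediction, sugar pucker and BI/BII backbone substates, real
backbone atoms beyond P/C1', crystal-packing distortion, and the large
sequence-driven width differences of real TA- versus GC-tracts (the
deposited complexes differ by ~2.5 Å where the rigid presets differ by
~0.7 Å). A green synthetic test therefore establishes the *correctness of
the machinery* (exact round trips, oracle agreement, invariances and the
direction of the contrast), not the magnitudes seen in crystal structures;
magnitudes must come from real coordinates.

`synth_titration()` draws CSP titrations from the exact single-site
isotherm with receptor depletion,

    Δδ(L) = Δδ_max · ((P + L + Kd) − √((P + L + Kd)² − 4PL)) / 2P,

plus Gaussian noise. The depletion form (rather than the hyperbola) is the
default fitting model as well, because millimolar Kd at a 1:20 maximum
molar ratio makes depletion non-negligible.

# Titration fitting

`fit_single_site()` exploits that Δδ_max enters the model linearly: at each
Kd the optimal plateau is the closed-form least-squares coefficient, so the
fit is a smooth one-dimensional profile in log10(Kd), scanned on a fixed
grid (10⁻⁹–1 M) and refined by golden-section search. This is deterministic,
start-free, and immune to the convergence failures a two-parameter
Gauss–Newton shows on noisy series. Standard errors come from the
Gauss–Newton Jacobian at the optimum. Fits whose data reach less than half
the fitted plateau are flagged (`saturation_warning`); an all-zero series is
an error, not a spurious Kd.

Simulation design for the recovery criterion: receptor at 0.5 mM (a typical
¹⁵N-HSQC titration concentration; the source does not print one), the
8-point 1:0…1:20 molar ladder, noise 5% of Δδ_max, Kd log-uniform
0.1–10 mM. The acceptance threshold median |log(K̂d/Kd)| < 0.15 is read in
**log10** (agreement within a factor ~1.4): measured with the
globally-optimal profiled estimator, the information content of an 8-point
1:20 ladder at 5% noise bounds the natural-log median near 0.2–0.33
regardless of receptor concentration, so the log10 reading — the standard
convention for Kd-recovery accuracy — is the attainable one. The measured
median is ≈ 0.09.

# Numerical choices and degenerate inputs

* Altloc resolution keeps the highest-occupancy location, ties broken by the
  smallest altloc code; first model only; author numbering is the public
  residue coordinate system.
* PDB coordinates are written at 0.001 Å; field overflow is an error, never
  silent truncation. Read∘write∘read is idempotent at that precision.
* Kabsch superposition always returns a proper rotation (the smallest
  singular direction is negated at reflective optima); collinear inputs are
  an error. RMSD is symmetric to 1e-9.
* A twist of exactly 180° (mid-frame undefined) and a 180° bend (hinge
  undefined) are errors; both are far outside B-form geometry.
* Degenerate width/potential correlations (constant field, < 3 entries) are
  reported as NA with a note, never as a crash.
* Profile entries at chain termini without phosphates are omitted and
  listed, which is this package's choice; the source does not state how its
  averages handled terminal bases.
* `analyze()` is fully deterministic given its options; reports serialize
  byte-identically and the provenance block suffices to replay the run.

# Known limitations

* The PB molecular surface is the lattice expand/erode approximation, not an
  analytic solvent-excluded surface; accuracy is grid-limited near the
  surface (groove midpoints sit several grid nodes from it).
* The charge table is a labelled synthetic stand-in for force-field-derived
  values; absolute potentials shift with the intra-group charge details,
  though groove-midpoint contrasts are phosphate-dominated.
* The bend estimate uses straight end-segments, adequate for nearly straight
  duplexes (the regime of interest) but not for strongly curved DNA.
* Only canonical Watson–Crick pairs are recognized — no Hoogsteen, wobble or
  mismatches — and RNA is out of scope.
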