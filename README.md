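# minorgroove

Analysis of DNA **minor-groove shape readout** — how minor-groove-binding
proteins (e.g. PWWP domains of the HDGF family) select DNA by groove
geometry and electrostatics rather than by sequence.

For structural biologists and computational biophysicists, the package turns
a protein–DNA complex (PDB/mmCIF) into one coherent report:

* **Base-pair geometry.** Watson–Crick pairs are found geometrically,
  standard base reference frames are fitted by least squares, and the twelve
  helical parameters are computed by the self-inverse mid-frame (CEHS-style)
  decomposition — intra-pair shear, stretch, stagger, buckle, **propeller
  twist** ω_p, opening, and step shift, slide, rise, tilt, roll, **helical
  twist** Ω (plus the screw-axis variant).
* **Minor-groove widths** by the cross-strand phosphate method: the width at
  base *i* is the raw distance ‖P(i, strand I) − P(i±4 pairs, strand II)‖,
  with the minor-groove-side register chosen via the pair frames.
* **Electrostatics.** A finite-difference linearized Poisson–Boltzmann
  solver, ∇·(ε∇φ) − ε_out κ̄² λ φ = −4π λ_B ρ (ε_in 2, ε_out 80, 0.145 M
  salt, 1.4 Å probe, 4 grids/Å, 70% box fill), samples φ in kT/e at the
  groove midpoints with a 7-point average and correlates groove narrowing
  with potential minima (electrostatic focusing).
* **Superposition and titrations.** Kabsch rigid-body superposition/RMSD,
  and single-site K_d fitting of NMR chemical-shift-perturbation series
  Δδ = √(Δδ_H² + (Δδ_N/5)²) with the exact receptor-depletion isotherm.
* **Synthetic B-DNA builder.** All-atom duplexes from helical-parameter
  profiles; `ta_like` (twist 37.1°, propeller −11.2°) gives narrow grooves,
  `gc_like` (35.3°, −7.3°) wide ones, so the whole pipeline is testable
  offline. The builder and analyzer are exact inverses.

## Worked example

```r
library(minorgroove)

ta <- analyze(build_duplex("TATATATATATATATA", preset_profile("ta_like", 16)),
              pb = TRUE, pb_opts = pb_params(scale = 2))
gc <- analyze(build_duplex("GCGCGCGCGC", preset_profile("gc_like", 10)),
              pb = TRUE, pb_opts = pb_params(scale = 2))
ta
#> <analysis_report 'synthetic-duplex-16bp'>
#>   base pairs: 16   mean propeller: -11.2 deg   mean twist: 37.1 deg
#>   minor-groove width (Å): all 10.97  bound NA  free 10.97
#>   bend: 0.00 deg per 6 bp (0.00 deg total)
#>   mean groove potential: -5.14 kT/e   width-potential r: 0.346
compare_reports(ta, gc)[c(1, 2, 6, 10), ]
#>                 quantity value_a value_b difference
#> 1         mean_propeller  -11.20   -7.30     -3.900
#> 2             mean_twist   37.10   35.30      1.800
#> 6             mean_width   10.97   11.75     -0.774
#> 10 mean_groove_potential   -5.14   -5.13     -0.006
```

Reading the output: the analyzer recovers the generating profile exactly
(propeller −11.2°/−7.3°, twist 37.1°/35.3°); the TA-like duplex has the
narrower raw minor groove (10.97 vs 11.75 Å — real TA/GC crystal structures
differ more, since rigid presets carry only the propeller/twist part of the
contrast); groove-midpoint potentials are negative (~−5.1 kT/e) as phosphate
electrostatics demands.

Fitting a simulated titration (K_d 1.3 mM, 0.5 mM receptor, the 1:0…1:20
molar ladder, 5% noise):

```r
ser <- synth_titration(kd = 1.3e-3, ddmax = 0.6, receptor_conc = 5e-4,
                       ligand_concs = 5e-4 * c(0, 0.5, 1.5, 4, 6, 10, 15, 20),
                       noise_sd = 0.03, seed = 42)
fit_single_site(ser)
#> <binding_fit (depletion): Kd = 0.001279 M, ddmax = 0.6157 ppm, rss = 0.00371>
```

## Command line

```sh
exec/groove-readout synth --seq TATATATATATATATA --preset ta_like -o ta.pdb
exec/groove-readout analyze ta.pdb --pb --scale 2 --out report.json
exec/groove-readout superpose a.pdb b.pdb --mode ca_only
exec/groove-readout fit-titration titr.tsv --receptor-conc 5e-4
```

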