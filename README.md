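# groovedyn

Geometry and dynamics of the MHC class II peptide-binding groove, in R.

Some drugs linked to HLA-associated hypersensitivity (nevirapine is the
motivating case) are thought to bind **inside** the peptide-binding groove
of a class II molecule such as HLA-DRB1\*01:01 — around the P4 pocket —
and reshape it: the distance between the α- and β-chain helices changes,
and the bound peptide shifts. `groovedyn` provides the quantitative stack
for characterizing such effects from conformational ensembles (multi-model
PDB), for structural immunologists and computational chemists analyzing
trajectory output or published summary data.

## What it computes

The central observable is the **inter-helical distance** of the groove:

d = (1/N_α) · Σ_{i ∈ α-helix} min_{j ∈ β-helix} ‖x_i − x_j‖

— the mean, over α-helix Cα atoms, of the distance to the nearest β-helix
Cα. Per-frame evaluation gives a time series summarized by mean, sample
SD and OLS slope (Å/ns); a negative slope is a closing motion. Around it:

* multi-model PDB I/O and Cα/heavy-atom selections (`read_trajectory`,
  `select_calpha`, `atom_select`);
* Kabsch superposition, RMSD series, mean-structure RMSF profiles, and
  medoid representative frames (`superpose`, `rmsd_series`,
  `rmsf_profile`, `representative_frame`);
* voxel occupancy maps and 50% occupancy volumes with OpenDX export
  (`occupancy_grid`, `occupancy_isovolume`, `write_opendx`);
* drug-induced peptide displacement maps, B-factor-encoded for viewers
  (`peptide_displacement`, `encode_bfactor`);
* peptide register scanning along the groove axis with clash/contact
  scoring and P1–P9 pocket assignment (`enumerate_registers`,
  `rank_registers`, `assign_pockets`);
* molecular-mass arithmetic and μg/mL → μM conversion (`molar_mass`,
  `mass_conc_to_molar`, `protonated_mz`);
* exact two-tailed **Dunnett** many-to-one statistics for competitive
  binding assays, including a fixed-reference mode for published
  percent-of-control tables (`dunnett_test`, `dunnett_maxt_p`);
* a synthetic groove-trajectory generator with analytic ground truth
  (`groove_sim_spec`, `simulate_trajectory`, `ligand_occupancy_truth`).

See `vignettes/groove-dynamics.Rmd` for the models, assumptions and
design choices.

## A worked example

Simulate a groove under drug-bound study conditions (trajectory mean
13.1 Å, closing drift −0.14 Å/ns, separation SD 0.4 Å, 1250 frames of
0.004 ns) and recover the summary through the full pipeline:

```r
library(groovedyn)

spec <- groove_sim_spec(d0 = d0_for_mean(13.1, -0.14), slope = -0.14,
                        sigma_d = 0.4, n_frames = 1250, seed = 42)
traj <- simulate_trajectory(spec)
g    <- groove_of(traj$topology)
summarize_series(groove_distance_series(traj, g))
#> inter_helical_distance: mean 13.09 +/- 0.4461, slope -0.1363 per ns (n = 1250)
```

The recovered mean (13.09 Å) sits within one standard error
(0.4/√1250 ≈ 0.011 Å) of the generator truth, and the OLS slope recovers
the imposed closing drift.

Analyze a published percent-of-control competitive-assay table
(quadruplicates; the control is the constant 100, so the fixed-reference
mode pools variance across the dose groups):

```r
tab <- data.frame(group = c("1000", "200", "40", "8"),
                  mean = c(263.9, 99.7, 106.2, 101.9),
                  sd   = c(15.5, 11.3, 6.5, 8.1), n = 4)
dunnett_test(tab, fixed_reference = 100)
#> Two-tailed Dunnett test: k = 4 comparisons, pooled df = 12 (fixed reference = 100)
#>   group estimate        t   p_unadj     p_adj
#> 1  1000    163.9 30.05569 1.152e-12 4.562e-12
#> 2   200     -0.3 -0.05501 9.570e-01 1.000e+00
#> 3    40      6.2  1.13695 2.778e-01 6.989e-01
#> 4     8      1.9  0.34842 7.336e-01 9.937e-01
```

Only the 1000 μM dose departs from control (adjusted p ≈ 4.6 × 10⁻¹²,
far below 10⁻⁴); the estimate column is the % difference from control.
Pocket assignment for the hemagglutinin 306–318 peptide with P1 at
position 3 gives the canonical core:

```r
assign_pockets("PRYVKQNTLKLAT", p1_index = 3)[1:5, ]
#>   pocket position resname
#> 1     P1        3     TYR
#> 2     P2        4     VAL
#> 3     P3        5     LYS
#> 4     P4        6     GLN
#> 5     P5        7     ASN
```

And the small-molecule arithmetic for nevirapine (C15H14N4O):
`mass_conc_to_molar(100, "C15H14N4O")` → 375.51 μM,
`protonated_mz("C15H14N4O")` → 267.1.

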