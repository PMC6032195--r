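---
title: "Quantifying drug-induced changes in the MHC class II binding groove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug-induced changes in the MHC class II binding groove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovedyn)
```

## The scientific problem

Several small-molecule drugs associated with HLA-linked hypersensitivity
reactions — nevirapine among them — are thought to act by binding inside
the peptide-binding groove of a class II MHC molecule such as
HLA-DRB1\*01:01 and subtly reshaping it. The groove is a cleft between one
helix of the α chain and one helix of the β chain; a peptide of roughly 13
residues lies extended between them, its side chains anchored in the P1–P9
pockets. A drug sitting in or near the P4 pocket can change how far apart
the two helices sit, how the bound peptide is positioned, and therefore
what a T-cell receptor sees.

`groovedyn` implements the quantitative machinery used to characterize
such effects from conformational ensembles (trajectory frames sharing one
topology, stored as multi-model PDB):

* **groove geometry** — the inter-helical distance metric, its time
  series, and mean/SD/drift-slope summaries;
* **fluctuation analysis** — per-residue RMSF, RMSD-vs-time curves, and
  medoid representative structures;
* **occupancy volumes** — where a ligand or peptide spends at least a
  stated fraction (typically 50%) of frames;
* **peptide displacement maps** — how far each peptide Cα moves between a
  drug-bound and a drug-free structure, after superposing the receptors;
* **register scanning** — sliding the peptide along the groove axis,
  scoring poses by clashes and per-chain contacts, and mapping a register
  onto the P1–P9 pockets;
* **assay statistics** — percent-of-control normalization and a two-tailed
  Dunnett many-to-one test for competitive binding assays;
* **a synthetic groove generator** providing ground truth for all of the
  above.

## The inter-helical distance metric

For a groove definition `g` naming the α- and β-chain helices, each frame
is scored as

$$ d = \frac{1}{N_\alpha}\sum_{i \in \alpha\text{-helix}}
       \min_{j \in \beta\text{-helix}} \lVert x_i - x_j \rVert , $$

the mean over α-helix Cα atoms of the distance to the nearest β-helix Cα.
The metric is deliberately **directional** (α → β): that is how groove
opening/closing is defined in the structural literature this package
follows, and the asymmetric form is sensitive to which helix frays. A
symmetrized variant (the mean of both directions) is available via
`symmetrize = TRUE` but is never the default.

A trajectory yields a `metric_series`, summarized by `summarize_series()`
as the arithmetic mean, the sample SD (n−1 denominator), and the ordinary
least-squares slope of value on time (Å/ns). No detrending or smoothing is
applied before the OLS fit: the slope is meant to summarize the raw curve,
drift included. A negative slope is a closing motion of the groove.

The helix spans are configuration, not constants. The shipped preset
`groove_preset("drb1-default")` uses the standard HLA-DR architecture
(α 46–78, β 54–91, Cα only), but published figures rarely enumerate their
exact spans, so every range is user-overridable.

## Superposition, RMSF and the representative frame

All fitting is least-squares rigid superposition (Kabsch, with the
reflection case corrected by flipping the smallest singular vector). RMSF
uses the **mean structure** as reference, found by iterating
superpose → average → superpose until the mean shifts by less than
10⁻⁶ Å; this removes the arbitrariness of a reference frame. (A
`reference = "frame"` mode is provided since some published profiles fit to
a fixed frame; the two differ little for equilibrated ensembles.)

The "representative structure" of a run is operationalized as the
**medoid**: the frame of the trailing window (default 1000 frames) that
minimizes its mean pairwise superposed RMSD to every other frame in the
window, with ties going to the earliest frame. The medoid is always an
actual frame — unlike the mean structure, it can be deposited and
inspected.

## Occupancy volumes

`occupancy_grid()` bins selected atom *centers* (not van-der-Waals
spheres) into a regular lattice; a voxel's value is the fraction of frames
in which at least one selected atom lies inside it, and
`occupancy_isovolume(g, 0.5)` extracts the 50% occupancy volume with an
*inclusive* (≥) threshold, tested explicitly at the boundary. Defaults:
1.0 Å spacing, 2.0 Å bounding-box padding. Because an occupancy envelope
is only meaningful in the receptor frame, `align_on` superposes every
frame onto the first frame's framework selection before binning; the
synthetic generator emits frames already in the receptor frame, so its
tests exercise both paths. Grids export to OpenDX for standard viewers.

## Displacement maps and register scanning

`peptide_displacement()` superposes the drug-bound structure onto the
drug-free one using **all HLA α+β Cα atoms** as the framework — never the
peptide itself — and reports per-residue peptide Cα distances. The
framework choice favors a stable fit over a helix-only one; a test asserts
that moving only the peptide changes the map while moving everything
rigidly does not. For display, `encode_bfactor()` writes the values,
clamped to 0–10 Å, into the B-factor column; raw values are always kept.

`enumerate_registers()` slides the peptide along the groove's principal
axis in steps of 3.4 Å — the extended-peptide rise per residue, so one
offset is approximately one register shift — and counts heavy-atom pairs
below 2.5 Å (clashes) and below 4.5 Å (contacts, split by chain). The
ranking is purely geometric: fewest clashes, then most total contacts,
then the best balance of contacts across both helices, then smallest
|offset|. Energetic re-scoring by simulation, the final arbiter in
published register selections, is deliberately out of scope, as is any
sequence-motif scoring. Pose labels are relative offsets only; published
"frame 2 / frame 3" nomenclatures have no stated origin, so a user-side
label map is the only faithful representation.

## Assay statistics

Competitive-assay readouts arrive as replicate fluorescence counts or as
published summaries (mean, SD, n per dose group), expressed as % of a
vehicle (DMSO) control. `dunnett_test()` computes pooled-variance
many-to-one t statistics and adjusts them with the exact two-sided
Dunnett distribution: the comparisons have the product correlation
structure corr(Tᵢ,Tⱼ) = bᵢbⱼ with bᵢ = √(nᵢ/(nᵢ+n₀)) — the n-weighted
generalization of the classical ½ — and the family-wise tail probability
is evaluated by nested quadrature over the shared normal variate and the
pooled-SD scale factor (`dunnett_maxt_p()`), written so the far tail
retains full relative precision. A seeded Monte Carlo estimator
(`dunnett_maxt_mc()`) cross-checks the quadrature, and the test suite also
checks it against an independent general-purpose implementation
(multcomp) and calibrates the family-wise type-I error on 10⁴ null
simulations.

Published percent-of-control tables often omit the control's own SD. The
**fixed-reference mode** (`fixed_reference = 100`) treats the control as
the constant 100 with variance pooled across the treatment groups
(bᵢ = 0); this is the documented route for re-analyzing such tables, with
the caveat that it ignores control sampling noise and is therefore
slightly anti-conservative in principle. For the quadruplicate tables this
package targets, the headline conclusion (adjusted p far below 10⁻⁴ at the
top dose, nothing at lower doses) is insensitive to the mode and to
whether n = 4 or n = 8 is assumed.

## The synthetic generator

`groove_sim_spec()` / `simulate_trajectory()` emulate exactly the
statistical structure the analysis stack consumes:

* two ideal Cα helix traces (2.3 Å radius, 1.5 Å rise, 100°/residue) laid
  antiparallel, chain A numbered from 46 and chain B from 54 so the
  `drb1-default` preset applies unchanged; a 13-residue chain C carries
  the influenza hemagglutinin 306–318 sequence (PRYVKQNTLKLAT);
* a per-frame separation d(t) = d₀ + slope·t + ε, ε ~ N(0, σ_d),
  realized by rigid β-helix displacement. Because the metric responds to
  a rigid shift almost but not exactly linearly (nearest-neighbour
  pairings drift with the helical wobble), the generator inverts the
  shift→metric map with a monotone spline, so the realized metric equals
  the drawn separation essentially exactly — a noiseless run is exactly
  linear and `build_groove()` measures exactly d₀;
* optional isotropic per-residue jitter (for RMSF recovery) and an
  optional three-center ligand pseudo-molecule (resname NVP) near the
  mid-groove — a P4-pocket analog — present per frame with a stated
  probability (for occupancy tests, with `ligand_occupancy_truth()` as
  the closed-form oracle).

Defaults are chosen once to mirror the study conditions the package
targets: 1250 frames at dt = 0.004 ns (a 5-ns window), separation SD
0.4 Å, and drift slopes of order −0.1 Å/ns. `residue_jitter` defaults to
0 so that σ_d alone controls the separation statistics; jitter is an
independent knob used when fluctuation recovery is the question. The
trajectory time step dt is not stored in PDB and is always a caller
parameter.

Two limitations are intentional. The noise is **independent across
frames**: published trajectory SDs are emulated marginally, not
dynamically, so autocorrelation-sensitive quantities (e.g. effective
sample sizes) are not represented. And the models are Cα-only (plus
ligand pseudo-atoms): every metric in scope reads Cα or heavy-atom
centers, so side-chain realism would add nothing the tests could detect.
Consequently, passing tests demonstrate that the estimators recover known
geometric/statistical ground truth at realistic noise levels — not that
any force-field-level behavior is reproduced.

## Numerical choices

* Superposition requires ≥ 3 non-collinear points; collinearity is
  detected on the singular spectrum and rejected.
* Medoid ties break to the lowest frame index; register-ranking ties break
  to the smaller |offset| then the smaller offset, making the order total.
* PDB altloc records resolve to the highest-occupancy conformer (ties
  toward altloc A); insertion codes are rejected outright with the line
  number — the toy and synthetic data this package handles never carry
  them, and silently renumbering would corrupt author numbering.
* Occupancy thresholds are inclusive (≥), tested at the boundary.
* The atomic-mass table (IUPAC 2021 conventional weights and
  principal-isotope masses, 6 decimals) is pinned in code for bit-stable
  results; the proton mass used for [M+H]⁺ is 1.00728 Da.
* Dunnett quadrature uses `integrate()` with relative tolerance 10⁻⁹
  (outer) / 10⁻¹⁰ (inner) and log1p/expm1 complements, keeping tiny
  adjusted p-values (≈10⁻¹²) accurate in relative terms.

## Problem sizes used in the tests

The shipped suite runs entirely on generated data: recovery tests use
1250-frame trajectories (the 5-ns convention above), RMSF calibration
2000 frames, medoid brute-force checks windows of ≤ 100 frames, the
Dunnett Monte Carlo cross-check 10⁶ draws, and the family-wise error
calibration 10⁴ simulated null tables. These sizes keep every statistical
tolerance (e.g. 5% on RMSF recovery, ±0.01 on the family-wise error, and
±0.1 Å on trajectory means) a multiple of the corresponding standard
error under a fixed seed.

## A worked example

```{r, eval = FALSE}
library(groovedyn)

## drug-bound study conditions: mean 13.1 A, closing drift -0.14 A/ns
spec <- groove_sim_spec(d0 = d0_for_mean(13.1, -0.14), slope = -0.14,
                        sigma_d = 0.4, n_frames = 1250, seed = 42)
traj <- simulate_trajectory(spec)
g <- groove_of(traj$topology)

summarize_series(groove_distance_series(traj, g))
#> inter_helical_distance: mean 13.09 +/- 0.4461, slope -0.1363 per ns (n = 1250)

## published percent-of-control summaries, fixed-reference Dunnett
tab <- data.frame(group = c("1000", "200", "40", "8"),
                  mean = c(263.9, 99.7, 106.2, 101.9),
                  sd = c(15.5, 11.3, 6.5, 8.1), n = 4)
dunnett_test(tab, fixed_reference = 100)
```

## Known limitations

Beyond the generator caveats above: the package does not perform docking,
force-field simulation or homology modeling; the inter-helical metric's
helix spans must be supplied (or taken from the preset) because published
figures mark them only graphically; and mmCIF and compressed trajectory
formats (DCD/XTC) are out of scope — multi-model PDB is the interchange
format.
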