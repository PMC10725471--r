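---
title: "Methods: quantifying small-molecule modulation of the inactive BAX dimer"
author: "baxdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying small-molecule modulation of the inactive BAX dimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baxdm)
```

## The problem

Pro-apoptotic BAX normally waits in the cytosol as an inactive monomer,
but it can also form an autoinhibited homodimer in which one protomer's
N-terminal trigger site (helices α1/α6 and the α1–α2 loop) is occluded by
the other protomer's C-terminal surface (mainly helix α9). Cells carrying
this cytosolic dimer are harder to push into apoptosis: the trigger site
is hidden, so BH3 activators and BH3-mimetic drugs engage BAX less
efficiently. A small molecule that binds the dimer interface and releases
the autoinhibited conformation is therefore a route to re-sensitizing
such cells.

`baxdm` implements the computational layer of that program: building a
pharmacophore hypothesis from the dimer-interface residues and screening
conformer libraries against it; localizing a hit's binding site by NMR
chemical-shift perturbation; quantifying its allosteric effect on
conformational ensembles; and fitting the downstream biophysical and
cellular assays. Every stage has a seeded synthetic generator so the
whole pipeline is exercised end-to-end without external data.

## Pharmacophore model and library screen

The model is a set of typed feature points placed on the dimer-interface
residues: hydrophobic points at the sidechain heavy-atom centroids of
Q28, L45, L47 and T172, an aromatic point at the F176 ring centroid, a
positive point at the R109 guanidinium (NH1/NH2/CZ centroid), a negative
point at the D48 carboxylate (OD1/OD2/CG centroid), a donor at the A46
backbone amide nitrogen and an acceptor at the Y164 hydroxyl oxygen.
These placements are conventional pharmacophore choices (the source
residues, not atoms, are what define the hypothesis), and every one is
overridable through the feature specification.

A conformer matches when an injective, type-compatible correspondence of
at least `min_matched` features exists whose rigid (Kabsch) superposition
leaves every paired distance within the tolerance, and whose matched
types satisfy the composition rule — by default 4–5 points built from
three hydrophobic groups, one aromatic group and (for 5-point matches)
one hydrogen-bonding or charged group. Two points were genuinely open and
are configuration, not conviction:

* whether a 4-point match may omit the aromatic feature — the default
  requires it (`required_aromatic = 1` at any size);
* whether the polar/charged role is mandatory at 4 points — the default
  requires it only from 5 points up (`required_polar_4 = 0`,
  `required_polar_5 = 1`).

Candidate correspondences are enumerated depth-first with pairwise
distance-consistency pruning at `2 * tolerance`. The bound is sound: a
rigid alignment that puts both members of two pairs within `tolerance` of
their model features can change neither pairwise distance by more than
`2 * tolerance`, so no mapping accepted by exhaustive search is ever
pruned — the test suite verifies exact agreement with a brute-force
enumeration (combinations × permutations, quaternion superposition) on
thousands of random instances. Ranking uses
`fit_score = n_matched − rmsd / tolerance`, a package-defined statistic
chosen to be monotone in both match size and geometric quality; it is
deliberately *not* comparable to proprietary screening scores. Ties break
on lower RMSD, then on the lexicographically smallest mapping, so screens
are deterministic.

Default tolerance is 2.0 Å, a typical pharmacophore matching radius.
Aromatic ligand features do not satisfy hydrophobic model features unless
`aromatic_as_hydrophobic = TRUE`; strict typing is the testable default.

## Chemical-shift perturbation analysis

For each backbone amide observed in both the free and bound HSQC peak
lists,

$$\mathrm{CSP} = \frac{1}{2}\sqrt{(\Delta\delta_\mathrm{H})^2 +
(\Delta\delta_\mathrm{N}/5)^2} \quad \text{(ppm)}.$$

The printed form of this expression places the factor 1/2 outside the
radical, and that literal reading is the default; the common alternative
convention (the scale inside the radical) is one parameter change away
because both the nitrogen weight and the overall scale are explicit
arguments. Residues present in only one list (prolines, overlapped or
missing peaks) are classed `absent`, carry no CSP and are excluded from
the statistics. Significance uses the mean plus 0.5 or 1 sample standard
deviations (n − 1 denominator; the estimator choice is ours, stated
because at small n it matters) of the measured CSPs: above `m + s` is
`highly_significant`, above `m + 0.5 s` is `significant`. Classifications
are scale-equivariant, and the thresholds travel with the result as an
attribute. Per-region summaries take a user-supplied region table;
`bax_helix_regions()` ships approximate α1–α9 boundaries as a documented
example only — real analyses should derive the table from the reference
structure's own helix annotations.

## Ensemble metrics

`kabsch_superpose()` is the geometry core (SVD with reflection
correction; collinear sets are flagged and handled translation-only).
RMSD series superpose each frame onto a reference frame on the selection.
RMSF superposes every frame onto the unfitted mean structure in a single
pass, recomputes the mean, and reports per-residue fluctuation on the
Cα trace. The superposition selection is separate from the reporting
selection and defaults to **all atoms**: fitting on a small reporting
selection lets one genuinely mobile residue drag the frame of reference
(its leverage on the six rigid degrees of freedom reaches several percent
on a 60-atom trace), biasing its own RMSF low. With an all-atom fit the
planted-amplitude recovery error stays under ~2.5% at 2000 frames, which
is what the recovery tests assert (within 5% of the closed form
$\sigma\sqrt{3}$).

ΔRMSF is the elementwise relative change `(bound − apo) / apo`, with the
apo denominator conventionally the average over apo replicates. Replicate
aggregation throughout is the mean of per-ensemble means, never frame
pooling.

The canonical-site opening is quantified as the sum of two triangles over
four residues — by default the Cα atoms of K189, V91, T85 and M79,
decomposed as K189–V91–T85 plus K189–M79–T85 — each area by Heron's
formula with the radicand clamped at zero for near-degenerate triangles.
Cα is the conventional residue proxy; the vertices are configurable
selections because the atoms behind the printed areas are not stated
anywhere authoritative. Percent change is `100 (Ā_bound − Ā_apo)/Ā_apo`.

## Assay models

* **One-site binding** (`fit_one_site`): `B_max [L]/(K_D + [L]) + b`,
  nonlinear least squares (Levenberg–Marquardt via `minpack.lm`).
  Deterministic data-driven starts (K_D at the half-max concentration,
  amplitude and baseline from the response range); K_D box-constrained to
  `[1e-3, 1e7]` nM and flagged at a bound. Requires ≥ 5 points spanning
  ≥ 2 decades.
* **Competitive 4PL** (`fit_competitive_4pl`): `bottom + (top −
  bottom)/(1 + (x/IC50)^h)` with both plateaus fixed to measured anchors
  (saturated complex and free probe), leaving IC50 and the Hill slope
  free. Data that never leave a plateau are flagged unidentifiable.
* **Thermal shift** (`fit_melt`): signal is first normalized so the 25 °C
  anchor maps to 100% and the 74 °C anchor to 0%, then a two-state
  Boltzmann `b + A/(1 + exp((T − T_m)/k))` is fitted. The amplitude and
  baseline are free rather than pinned at 100/0 — anchor normalization
  rescales the *measured* anchor signals, not the sigmoid's asymptotes
  (a melt with T_m 62 °C and k 2 °C still retains ~0.25% signal at
  74 °C), so the normalized curve is an affine image of the sigmoid.
  Because the inflection temperature is invariant under affine maps of
  the response, the free-span fit recovers T_m exactly on noiseless data,
  which the pinned-asymptote form cannot. `delta_tm()` reports
  `T_m(control) − T_m(treated)`, so destabilization is positive.
* **Bliss synergy** (`bliss_synergy`): expected effect `f_A + f_B −
  f_A f_B` from the single-agent marginals; per-cell score `observed −
  expected`; summary is the mean over cells with both doses nonzero.
  Scores are formula-exact — no surface smoothing or weighting is
  applied, and the output is labelled accordingly.
* **SEC quantification** (`sec_quantify`): label-keyed windows, monomer
  `(C6/2 + C7 + C8 + C9)/total`, dimer `(C3 + C4 + C5 + C6/2)/total`,
  optional oligomer `(C2 + C1 + B1 + B2)/total`, each ×100; the boundary
  fraction C6 is split half-and-half. The label→volume map is
  configuration (`sec_fraction_map()` lays 0.5-ml fractions so a dimer
  peak at 14–14.5 ml sits mid-window C3–C5 and a monomer peak at
  15.5–16 ml starts window C7). MW calibration is a log-linear fit
  through the standards with an extrapolation flag.
* **Depolarization** (`depolarization_percent`): trapezoid AUCs
  normalized between the solvent control (0%) and the uncoupler control
  (100%); out-of-range values are flagged, never clipped, and the
  statistic is invariant to a common affine gain/offset of all traces.

## Synthetic data: what it emulates, and what it does not

Each generator is a pure function of its arguments including the seed
(a single RNG stream per call, restored afterwards), and returns a
`truth` element the tests consume. Noise models follow the dominant error
source per assay: multiplicative Gaussian for plate/fluorescence signals,
additive Gaussian in ppm for chemical shifts, isotropic Gaussian in Å for
coordinates.

Study-condition defaults are fixed once: isotherms use 12 log-spaced
points bracketing K_D 30-fold each side with 3% CV noise; melt pairs use
the 8-temperature gradient (50, 52.1, 55.4, 59.4, 64.9, 69.2, 72.1,
74 °C) plus the 25 °C anchor, control T_m 62 °C, slope 2 °C, 2% CV
noise; peak lists draw amide shifts uniformly in 6.5–9.5 ppm (¹H) and
105–130 ppm (¹⁵N) with noise SDs of 0.005/0.025 ppm and planted offsets
at five times those SDs.

The planted area change scales the four vertex residues about their
common centroid by `sqrt(1 + p/100)` in every frame: uniform scaling
multiplies every vertex pairwise distance by that factor and hence the
two-triangle area by exactly `1 + p/100`, so the target percent change is
exact in expectation rather than depending on a drift schedule.

The 60-residue helical-hairpin toy fold is built by a deterministic
function rather than shipped as a coordinate file; its residue numbering
covers 20–190 sparsely so all named interface, trigger-site and
canonical-site residues exist with full heavy-atom sidechains. Its
geometry is schematic: selections resolve, distances and areas are
well-conditioned, but it is a synthetic scaffold with no physical
meaning. Decoy conformers keep the active's feature types but scale its
geometry by a factor computed from the model's own distance range so
that no pairwise distance can be matched within `2 × tolerance` — decoy
rejection is guaranteed by construction, not by chance.

Consequences for interpretation: passing recovery tests shows the
estimators are unbiased and correctly implemented *under these noise
models*. Real spectra have peak overlap and assignment errors; real
trajectories have correlated, anisotropic motions; real plates have
edge and drift effects. None of those are emulated, so the synthetic
recoveries bound implementation error, not experimental error.

## Numerical choices

* Matching tie-breaks (score, then RMSD, then lexicographic mapping)
  make screens reproducible to the byte for fixed inputs.
* Heron radicands are clamped at zero; degenerate (collinear)
  superposition targets fall back to translation with a flag.
* Curve-fit failures never throw: they return `converged = FALSE` with
  named flags (`no_dynamic_range`, `ic50_unidentifiable`, `kd_at_bound`,
  `fit_failed`), so screens over many fits keep running.
* The "lowest-energy NMR model" is taken as model 1 of a multi-model
  file unless overridden by index — the conventional ordering — since
  the energetic ordering of deposited models is not otherwise available.

## Problem sizes

The shipped tests run the matcher–oracle comparison on 1000 random
instances (≤ 7 features a side), the Heron/cross-product comparison on
10⁴ random triangles, Kabsch/quaternion on 10³ point-set pairs, K_D and
ΔT_m recovery on 100 seeded replicates each, CSP recall on 100 seeded
peak-list pairs, and RMSF recovery on 12 seeded ensembles of 2000 frames
over the full-atom toy fold. These sizes were chosen so the full suite
completes in a few minutes on one core while keeping Monte-Carlo error
well below every asserted tolerance.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
report <- run_pipeline(default_pipeline_config(seed = 1))
report$summary
#>              quantity      value rounded
#> 1 area_percent_change   9.093535     9.0
#> 2          delta_tm_C   4.275101     4.3
#> 3        kd_nM_fitted 572.030818   572.0
```

Every number in the report names its producing stage and output file;
re-running with the same config and seed reproduces the numerics
identically.

## Known limitations

* The screen operates on supplied, rigid, typed conformers: no conformer
  generation from chemical structures, no flexible alignment, no
  excluded-volume features, no property (ADMET) filtering.
* Ensembles are analyzed, never generated physically — there is no force
  field, thermostat or solvent anywhere in the package.
* CSP analysis starts from assigned peak lists; peak picking and
  resonance assignment are upstream of this package.
* Bliss scores are exact independence residuals; smoothed heatmaps from
  dedicated combination-analysis software will differ near the dose-grid
  edges.
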