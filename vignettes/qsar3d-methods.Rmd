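---
title: "Methods and design notes for qsar3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for qsar3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the scientific model the package implements, the
choices made where conventions diverge, and what the synthetic-data tests do
and do not establish about behaviour on real data.

## The modelling problem

Lattice-based 3D-QSAR assumes that, for a congeneric series of ligands
binding one site in one conformation and alignment, binding affinity is
approximately linear in the molecular interaction fields sampled on a
regular grid surrounding the aligned series. The response is pIC50
(−log10 of IC50 in molar); the descriptors are, per molecule, one value per
lattice point per field kind. The model chain is:

1. **Alignment.** Each molecule is rigidly superposed onto a template (by
   convention the most potent compound) using only a shared substructure
   anchor — for phosphate-bearing series, a phosphorus bonded to three or
   more oxygens (`"P(O)(O)O"`). Only anchor atoms enter the least-squares
   fit, matching database-alignment semantics; the resulting transform moves
   the whole molecule. The fit is the Kabsch solution (SVD of the
   cross-covariance with a determinant correction, so reflections are never
   produced). When the anchor is symmetric the pattern matcher enumerates
   every automorphic embedding; the minimum-RMSD one is kept, with ties
   broken by the lexicographically smallest atom-index tuple so the result
   is deterministic.

2. **Fields.** CoMFA-style fields use an sp3-carbon probe of charge +1:
   steric energies are Lennard-Jones 6-12 sums with the probe/atom
   well-depth combined as a geometric mean and the contact distance as the
   sum of van der Waals radii (a Tripos-force-field-style element table is
   embedded; unknown elements are an error, never a default); electrostatic
   energies are Coulombic, 332.0636 q_probe Σ q_i / (ε(r) r) kcal/mol with
   the distance-dependent dielectric ε(r) = r by default (switchable to
   constant ε = 1). Both are truncated to ±30 kcal/mol. At lattice points
   where a molecule's steric field is at the truncation ceiling (probe
   inside the molecule) its electrostatic value is not meaningful; it is
   replaced by the column mean of the unclamped training molecules, the
   standard convention, and the replacement is recorded.

   CoMSIA fields are Gaussian similarity indices
   A_{F,k}^q(j) = −Σ_i ω_{probe,k} ω_{ik} exp(−α r_{iq}²), with α = 0.3, a
   probe of radius 1 Å whose five properties are all +1, and atom properties
   ω: r_vdW³ (steric), partial charge (electrostatic), an atom
   hydrophobicity contribution, and 0/1 donor/acceptor flags. No truncation
   is applied; for an all-positive property the leading minus sign makes
   every value ≤ 0.

3. **Descriptor matrix.** Blocks are concatenated column-wise; lattice
   points are ordered x-fastest, then y, then z, so column indices are
   stable and documented. Near-constant columns (training standard deviation
   below `min_sigma`) are dropped before modelling; dropped columns render
   as zeros when coefficients are mapped back to the grid, keeping exported
   volumes rectangular.

4. **PLS.** Partial least squares is fitted by the NIPALS recursion
   (univariate response). With as many components as the matrix rank the
   fit coincides with least squares on the column space, which the tests
   verify against independent implementations. Leave-one-out
   cross-validation refits *everything* per fold, including the scaling
   weights, which is the stricter reading of the protocol; q² = 1 − PRESS /
   Σ(y − ȳ)² uses the full training mean. The component count is the
   smallest whose q² is within 0.005 of the profile maximum — additional
   components that do not demonstrably improve cross-validated performance
   are not retained, mirroring the usual overfitting audit.

5. **Validation.** Internal: r²ncv (squared Pearson correlation of fitted
   vs observed), SEE = √(SS_res/(n − pcs − 1)), F = (r²/pcs)/((1 − r²)/(n −
   pcs − 1)); bootstrap means r²bs/SEEbs over resamples refitted at fixed
   component count; y-randomization q² distributions at fixed component
   count. External, on the held-out test set: r²pred = 1 − PRESS/SD with SD
   taken about the *training* mean; r²test; through-origin slopes k
   (observed regressed on predicted) and k′ (the transpose); r²₀ from the
   observed-on-predicted through-origin residuals (the alternate r′²₀ is
   also reported); the gap ratio (r²test − r²₀)/r²test; and the modified
   statistic r²m = r²test (1 − √(r²test − r²₀)). Acceptability requires
   r²pred > 0.5, r²test > 0.6, gap ratio < 0.1, and at least one slope in
   [0.85, 1.15].

6. **Contours.** StDev*Coeff values (training column SD × PLS coefficient)
   are contoured at percentile levels: the favoured level is the stated
   percentile of the *positive* values, the disfavoured level the stated
   percentile of the *negative* values (80/20 for steric and electrostatic
   maps, 85/15 for hydrogen-bond maps, configurable). An alternative
   contribution-mass mode is available. Volumes export as OpenDX scalar
   fields (body in the format's canonical z-fastest order).

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `spacing` | 2.0 | Å | conventional lattice resolution for CoMFA/CoMSIA |
| `margin` | 4.0 | Å | automatic-box convention; box snapped outward to whole steps |
| `truncation` | 30 | kcal/mol | standard CoMFA energy ceiling |
| `alpha` | 0.3 | Å⁻² | standard CoMSIA attenuation factor |
| `min_sigma` | 0.01 | field units | drops numerically dead far-field columns; note CoMFA (kcal/mol) and CoMSIA (similarity) units differ, so set per method when filtering aggressively |
| `scaling` | `"block"` | — | CoMFA-standard scaling equalises block variance so multi-field models are not dominated by the widest-ranging field; `none`/`autoscale` available |
| `max_pcs` | 10 | — | upper bound for the component search; the profile also truncates automatically at the achievable rank |
| `bootstrap_n`, `yrand_n` | 100, 50 | runs | conventional robustness-run counts |

## The synthetic pseudo-receptor

Real 3D-QSAR studies of this kind build their structures interactively in a
modelling suite, so the package ships a generator that emulates the *shape*
of such a dataset: a congeneric series (default 105 molecules, split
77/28) sharing a rigid phosphate-anchored scaffold; per-molecule variable
substituents drawn as pseudo-atoms at up to six sites (occupancy 0.5,
position jitter SD 0.3 Å so the signal stays recoverable at 2 Å lattice
spacing); explicit per-atom charges and properties carried in SDF data
fields so no charge-assignment chemistry is needed; and every molecule
emitted at a random rigid pose so alignment is actually exercised.

Activities are planted by a *pseudo-receptor*: weighted interaction centers
(default: two steric, two electrostatic, one acceptor, one hydrophobic,
with both signs represented) whose CoMSIA field values, evaluated at the
center positions, combine linearly into the noiseless activity. The signal
is mapped onto the conventional 4.87–8.00 pIC50 range (the effective
rescaled weights are recorded as ground truth) and Gaussian noise (default
SD 0.1 pIC50 units) is added. Centers are snapped onto lattice points, which
makes the planted activity an *exact* linear function of descriptor columns
— at zero noise the pipeline is fully identifiable, and the tests verify
that training residuals vanish with sufficient components.

What passing these tests shows: the implementation chain is self-consistent
and recovers known structure through alignment, field computation, scaling,
PLS, validation and contouring. What it does not show: performance on real
chemistry. The generator has no conformational flexibility, no realistic
valence or geometry for substituents, element-level (not fragment-level)
hydrophobicity, and a planted relationship that is linear by construction —
real field–activity relationships need not be. Statistics obtained on
synthetic data characterise the software, not any assay.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear mapped atoms (collinearity
  detected via the second singular value, threshold 1e-8); reflections are
  excluded by the determinant correction.
* Grid snapping guarantees ≥ 2 planes per axis even for a degenerate
  (single-point) bounding box.
* NIPALS declares rank deficiency when a weight or score norm falls below
  1e-12 and asks for fewer components; `select_components()` truncates its
  profile there rather than failing a whole sweep.
* A constant fitted or predicted vector reports r² = 0 with a warning
  rather than NaN.
* When r²₀ exceeds r²test (possible with aggressive through-origin fits)
  the difference inside the square root of r²m is clamped at 0, with a
  warning.
* The modified-r² uses the square-root form r²test (1 − √(r²test − r²₀)),
  the form that reproduces its defining reference values (0.828 and 0.579
  from the inputs (0.909, 0.901) and (0.741, 0.693)).
* The through-origin slope k is reported with the observed-on-predicted
  orientation and k′ with the transpose; since both are always reported and
  the acceptability criterion is a disjunction, the orientation convention
  cannot silently change a verdict.
* Bootstrap resamples with zero response variance (or too few unique rows
  for the requested components) are redrawn and counted.
* All randomised routines (splitting, generation, bootstrap, scrambling)
  take explicit integer seeds, run under a temporarily swapped RNG state so
  callers' streams are undisturbed, and are bit-reproducible; a pipeline
  rerun with the same seed writes byte-identical reports.

## Problem sizes used by the test suite

Unit tests run on deliberately small instances (tens of molecules, hundreds
of lattice columns). The study-scale recovery checks use the full
conventional geometry — 105 compounds, 77/28 split, noise SD 0.1, ten
generator seeds — and require median leave-one-out q² and median external
r²pred above 0.5 with ≥ 90% StDev*Coeff sign agreement at high-weight
centers; the y-randomization null uses 50 scrambles at study scale plus 200
small null datasets. These sizes were chosen to exercise the pipeline at
realistic dimensions while keeping the whole suite comfortably runnable on
a laptop.

## Known limitations

* Gasteiger (PEOE) charges via OpenBabel are a stand-in for the
  Gasteiger–Hückel hybrid used by classic modelling suites; file-supplied
  charges always take precedence, and the validation statistics are
  charge-scheme-agnostic.
* The Lennard-Jones element table is a compact Tripos-style approximation
  covering H, C, N, O, S, P and halogens; exotic elements error out.
* The anchor-pattern language covers element-labelled connectivity with
  branches and wildcards — sufficient for rigid alignment anchors, far from
  full SMARTS.
* Alignment is rigid-body only: no conformer generation, no flexible
  fitting, no docking-based poses.
* V3000 SDF records are rejected; only V2000 is supported.
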