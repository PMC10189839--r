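---
title: "Dynamics scoring and meta-classification of switch-regulated GTPase variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics scoring and meta-classification of switch-regulated GTPase variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SwitchScore)
```

## The problem

Small GTPases such as KRAS are conformationally regulated by two mobile
loops, Switch 1 and Switch 2, whose positions differ between the
GDP-bound (inactive) and GTP-bound (active) states and gate binding to
GAPs, GEFs and downstream effectors. Point mutations perturb switch
dynamics in mutation-specific ways that a static structure cannot
resolve. Given conformational ensembles per variant and nucleotide
state — molecular-dynamics replicates, or synthetic ensembles —
SwitchScore quantifies each variant's dynamics relative to the wild
type (WT) on a battery of biophysically interpretable metrics,
standardizes every metric in WT-sigma units, and aggregates the
standardized scores into binary meta-classes, k-means group signatures
and 2D embeddings. A melting-curve module links the computed scores to
measured thermostabilities.

## The scoring model

All per-ensemble metrics are computed on C-alpha atoms after
superposing every frame onto a common reference with a least-squares
(Kabsch) fit that ignores the two mobile switch loops — fitting on the
stable core so that switch motion is measured, not removed. The
components are:

* **RMSF** per residue, `sqrt(mean_t ||r_i(t) - <r_i>||^2)` per
  replicate, aggregated across replicates by the arithmetic mean
  (median available). Flexibility-profile deviation is summarized as
  `SSR = sum_i (RMSF_i - RMSF_ref,i)^2` against a reference profile,
  with `|SSR_mut - SSR_wt| < 0.5` (Angstrom^2) calling a variant's
  profile WT-similar.
* **RMSD distributions** against reference conformations (e.g. GAP- or
  GEF-bound poses), over frames sampled at an even stride.
* **PC landscapes**: PCA of flattened C-alpha Cartesian coordinates
  over the pooled frames; the observed free-energy surface over a 2D
  PC subspace is `F = -kT log(rho / rho_max)`, so the most occupied bin
  has `F = 0`. A kernel-density estimate along PC1 detects the
  characteristic two-well structure of the inactive state; the well
  boundary is the density minimum between the two wells, and each
  variant's occupancy ratio `n_II / (n_I + n_II)` measures how much it
  samples the extended-Switch-1 well.
* **PC standard scores**: `z_k = (mean_mut,k - mean_WT,k) / SD_WT,k`
  for the top 3 PCs — the number of WT standard deviations separating
  the variant's mean projection from the WT mean.
* **Distance monitors**: ten literature-derived residue pairs (shipped
  as `krasMonitors()`) whose distances track switch opening,
  inter-switch coordination and nucleotide/Mg coordination. Each
  monitor uses the centroid of side-chain heavy atoms as the residue's
  representative point (C-alpha for glycine and C-alpha-only models);
  scores are `(median_mut - median_WT) / SD_WT` with the SD taken from
  the pooled WT per-frame distribution.
* **Interaction energy**: per-frame protein–ligand nonbonded energy,
  direct-sum Coulomb (`332.0716 q_i q_j / r`) plus Lennard-Jones with
  CHARMM combining rules, both terms switched smoothly to zero between
  10 and 12 Angstrom. This is a pair-interaction energy in the spirit
  of an MD engine's pair-interaction reports, not a lattice (Ewald)
  sum; it is intended for relative, WT-standardized comparisons.

## Classification and aggregation

Every metric is classified against the WT reference statistics at a
configurable threshold (default 1 sigma): three-way low / wt-like /
high with boundaries inclusive to the extreme categories (`z >= 1` is
high, `z <= -1` low); the nucleotide interaction energy in two
dimensions (GDP and GTP) as Stable / Neutral / Unstable, yielding a
9-member label set; and RMSD against each binding-competent reference
as Closed / Deviated per state, combined into labels such as
`"GTP Closed GDP Deviated"`. `buildMetaclassMatrix()` emits one binary
column per (metric, state, non-wt-like category) plus the energy and
RMSD combination columns; the column count is emergent from the
configuration — deliberately not hard-coded, since the source analyses
report both 108 and 90 such classifications in different places, an
inconsistency this package surfaces rather than resolves.

Variants are grouped per nucleotide state by k-means (default k = 6,
50 restarts, seeded) on the WT-z-standardized score matrix, and each
group is described by its signature: meta-classes ranked by
within-group occupancy, ties broken by global occupancy and then name
so the ranking is fully deterministic. The retained meta-class set is
the union of every group's top 10. `embed2D()` places every
(variant, state) row in 2D; the default backend is PCA (deterministic,
always available, exact for rank-2 score matrices), with UMAP
dispatched to an installed backend when present.

## Thermostability

`fitTm()` calls the melting temperature of a 350/330 nm fluorescence
ratio curve as the peak of the first derivative, using a
Savitzky-Golay derivative filter (window 11 points, order 3 — robust
on the 0.5 degC grids produced by a 0.5 degC/min ramp) and refining
the peak below the grid spacing with a local quadratic fit (half-width
6 points). Curves whose derivative peak does not rise above 5x the
median absolute derivative raise a no-transition error rather than
returning a spurious Tm; secondary peaks within 50% of the main peak
are flagged. Derived statistics per variant are
`dTm_state = Tm_mut - Tm_WT`, the within-protein spread
`ddTm = Tm_GDP - Tm_PNP`, and the activation stability change
`ddTm* = dTm_PNP - dTm_GDP`, which satisfies
`ddTm* = ddTm(WT) - ddTm(mutant)` exactly. Negative `ddTm*` means the
variant is destabilized more in the GTP-analog state — the activating
direction.

## The synthetic-ensemble generator

`generateEnsemble()` builds frames as base coordinates plus zero-mean
Gaussian excitations of orthonormal displacement modes, an optional
two-state collective coordinate, and per-residue isotropic noise.
Design choices, fixed once:

* **Base geometry**: residues on a helix-like curve with 3.8 Angstrom
  C-alpha spacing (`idealChainCoords()`), giving realistic
  inter-residue distances without an input structure.
* **Two-well dynamics**: a two-state Markov chain over frames with
  exactly controllable stationary occupancy and a mean state-II dwell
  of 10 frames by default — short enough that a few thousand frames
  mix well (the SD of the occupied fraction is
  `sqrt(p(1-p)(2d(1-p)-1)/n)`), long enough to be visibly metastable.
  Well centers default to 0 and 4 Angstrom along the planted
  direction, a clear separation against the default 0.2–0.4 Angstrom
  residue noise.
* **Seeding**: one integer seed, with a derived stream per replicate,
  so replicates are individually reproducible.

Every generator returns its planted ground truth (occupancy, state
sequence, per-residue RMSF, mode directions) so downstream estimates
are testable against known values. What the generator does *not*
emulate: force-field physics, solvent, side-chain packing, anharmonic
well shapes, or the slow drift of real trajectories. Tests passing on
synthetic ensembles therefore validate the estimators and the
pipeline plumbing — recovery of planted occupancies, shifts, and group
structure — not the biological realism of any particular MD protocol.

## Numerical choices and degenerate inputs

* PCA is fit per nucleotide state by default (the two states'
  landscapes differ qualitatively); a pooled fit across states is
  available. Component signs are fixed so each component's
  largest-magnitude loading is positive, making scores reproducible
  across runs.
* Free-energy surfaces use 50x50 bins over the data extent padded 5%,
  kT at 300 K; empty bins are undefined (`NA`), never zero.
* Well detection uses a Gaussian KDE with Silverman bandwidth. Local
  maxima below 5% of the global mode are treated as estimate wiggles;
  a second well must be separated from the global mode by a valley
  dipping at least 10% below the lower peak, otherwise the landscape
  is declared unimodal and the occupancy ratio is undefined (callers
  receive an explicit flag). WT-degenerate spreads (zero SD across
  replicates) leave the occupancy metric unclassified rather than
  dividing by zero.
* Superposition requires at least 3 fitting atoms after exclusions;
  ensemble/reference mapping is gap-aware by residue number, so
  missing residues in crystal references are tolerated.
* SSR's reference profile is the across-variant mean profile per state
  by default, with a WT-profile reference available — both readings of
  the deviation-from-average idea are supported because the choice is
  genuinely underdetermined; the threshold (default 0.5 Angstrom^2) is
  configurable and assumed to be in squared Angstrom.
* Classification boundaries are inclusive toward the extreme
  categories, and classification is invariant under affine rescaling
  of a metric together with its WT statistics.

## Worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig(
  seed = 11, outdir = tempfile(), k = 2, nRestarts = 10,
  synthetic = list(nResidues = 80, nReplicates = 3,
                   nFramesPerReplicate = 150,
                   variants = c("WT", "V1", "V2", "V3", "V4"),
                   plantedGroups = 2))
res <- runPipeline(cfg)
res$table                      # ScoreTable: 10 rows, both states
res$wells$GDP$boundary         # two-well boundary along GDP PC1
res$groups$GDP$assignments     # k-means groups per variant
head(res$signatures$GDP$signatures[["1"]])
```

The default synthetic landscape plants two groups: a WT-like group
(well-II occupancy 0.15 in the GDP state, baseline switch-mode
amplitudes, nucleotide interaction energy -260/-250 kcal/mol) and a
deviated group (occupancy 0.8, 1.8x amplitudes, energies shifted
+15 kcal/mol); three replicates of 150 frames per variant and state
mirror a small multi-replicate study design at test-friendly scale.

## Problem sizes used by the test-suite property checks

Recovery properties are exercised at sizes chosen to make the
statistical tolerances meaningful on a laptop: two-well occupancy over
the grid 0.1–0.9 at 6000 frames and 20 seeds (mean absolute error
under 0.05); PC mean shifts of 0–3 WT SD at 10^4 frames (recovered
within 0.15); the isotropic-noise RMSF limit `s * sqrt(3)` at 10^4
frames and 100 residues (within 2% — the Kabsch fit absorbs six rigid
degrees of freedom, so short chains would bias the comparison);
the Gaussian-cloud free-energy check at 2x10^5 points (radial shells
within 0.1 kT of `r^2/2sigma^2 * kT` out to 2 sigma); Tm recovery on
100 noisy curves (95%+ within 0.5 degC).

## Limitations

Interaction energies are direct-sum approximations, suitable for
WT-relative classification, not for absolute energetics. Occupancy
ratios require a detectable two-well density; heavily imbalanced wells
(beyond roughly 20:1 at a few thousand frames) fall below the
detection floor by design. Kinetic models (MSMs, tICA), enhanced
sampling reweighting, and thermodynamic two-state fits of melting
curves (dH, dG) are out of scope.
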