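# SwitchScore

Dynamics scoring and meta-classification of conformational ensembles
across a mutational landscape of a switch-regulated GTPase.

## The problem

Small GTPases such as KRAS switch between a GDP-bound inactive state
and a GTP-bound active state, gated by two mobile loops (Switch 1 and
Switch 2) whose conformations control binding to GAPs, GEFs and
effectors. Different point mutations perturb switch dynamics in
different ways, but most of the mutational landscape has never been
characterized structurally. Given per-variant, per-nucleotide-state
conformational ensembles (MD replicates, or synthetic ensembles with
planted ground truth), SwitchScore computes a battery of
biophysically interpretable dynamics metrics, standardizes each one in
wild-type sigma units, and aggregates the standardized scores into
variant classifications, group signatures and embeddings.

## What it computes

For each variant x nucleotide state, after a Kabsch superposition that
ignores the mobile switches:

* per-residue mobility **RMSF**, and the profile deviation
  **SSR** = Σᵢ (RMSFᵢ − RMSFᵢ,ref)²;
* **RMSD distributions** against reference conformations
  (GAP-/GEF-bound poses);
* a **PC free-energy landscape** F = −kT·ln(ρ/ρ_max) over the leading
  principal components of Cα coordinates, two-well detection along
  PC1, and each variant's **well-occupancy ratio** n_II/(n_I+n_II);
* **PC standard scores** z_k = (mean_mut,k − mean_WT,k)/SD_WT,k for
  the top 3 PCs;
* ten literature-derived **distance monitors**
  (Q61–D92, E62–H95, A11–Q61, G12–Q61, I36–A59, Y32–Y40, Y32–A59,
  G12–T35, Q61–T35, S17–T35), scored as
  (median_mut − median_WT)/SD_WT;
* protein–ligand **nonbonded interaction energy** (direct-sum Coulomb
  + Lennard-Jones, CHARMM switching between 10 and 12 Å).

Scores are classified against the WT at 1σ (three-way low / wt-like /
high; a 9-group Stable/Neutral/Unstable scheme for the GDP/GTP energy
pair; Closed/Deviated RMSD combinations), assembled into a binary
meta-class matrix, grouped by seeded k-means per state, summarized as
ranked group signatures, and embedded in 2D. A thermostability module
calls melting temperatures from 350/330 nm ratio curves via the
derivative-peak rule and derives ΔTm, ΔΔTm = Tm_GDP − Tm_PNP and the
activation stability change ΔΔTm* = ΔTm_PNP − ΔTm_GDP.

## Worked example

A synthetic landscape with two planted variant groups (WT-like and
deviated), run end to end:

```r
library(SwitchScore)
cfg <- pipelineConfig(
  seed = 11, outdir = tempfile(), k = 2, nRestarts = 10,
  synthetic = list(nResidues = 80, nReplicates = 3,
                   nFramesPerReplicate = 150,
                   variants = c("WT", "V1", "V2", "V3", "V4"),
                   plantedGroups = 2))
res <- runPipeline(cfg)
res$table
#> ScoreTable: 10 rows (5 variants x states GDP/GTP), 11 metrics
res$wells$GDP$boundary
#> [1] 0.4161729
res$groups$GDP$assignments
#> WT V1 V2 V3 V4
#>  1  1  2  1  2
sc <- scoreData(res$table)
round(sc[sc$nucleotide == "GDP",
         c("pc1_score", "pc1_fraction", "ssr", "eint")], 3)
#>   pc1_score pc1_fraction   ssr     eint
#> 1     0.000        0.158 0.036 -260.372
#> 2    -0.095        0.118 0.061 -259.876
#> 3     1.734        0.811 0.106 -246.395
#> 4    -0.119        0.116 0.063 -260.108
#> 5     1.800        0.847 0.095 -244.745
```

The planted structure is recovered: V2 and V4 (the deviated group,
planted well-II occupancy 0.8 and interaction energy shifted
+15 kcal/mol) separate cleanly from WT/V1/V3 in PC1 score
(≈ +1.8 σ), occupancy ratio (≈ 0.82 vs ≈ 0.13) and mean energy
(≈ −245 vs ≈ −260 kcal/mol), and k-means on the GDP-state scores
splits the variants accordingly. The GDP landscape is two-welled
(boundary at PC1 ≈ 0.42) while the GTP landscape is unimodal, so the
occupancy metric exists only for GDP — mirroring the
inactive-state-specific duality of Switch 1.

Melting-curve analysis:

```r
cv <- generateMeltingCurve(62.8, steepness = 0.5, noiseSd = 0.002)
fitTm(cv)
#> [1] 62.82172
#> attr(,"secondaryPeaks")
#> numeric(0)
```

## Command line

A thin wrapper over the package functions ships in
`inst/scripts/switchscore.R` with subcommands `run`, `synth`, `score`,
`classify`, `tm` and `report`; all interchange is via the documented
CSV/JSON/YAML formats.
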