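# mstfc

Minimum-spanning-tree analysis of resting-state functional connectivity for
studies of predisposing delirium risk factors.

Older patients who carry predisposing risk factors for delirium — higher age,
cognitive impairment, depression, functional impairment, alcohol misuse, a
history of TIA or stroke, poor physical status — may already show altered
organisation of their resting-state brain networks before any acute insult.
`mstfc` implements the full analysis chain used to test that idea on
region-of-interest BOLD fMRI data, and a seeded synthetic-cohort generator so
that every stage can be exercised and validated without access to scanner
data. It is written for imaging researchers who have per-subject ROI
time-series tables (e.g. Power-264 parcellation extractions) plus rigid-body
motion parameters, and want a tested, reproducible route from those tables to
group-level statistics.

## The analysis

For each subject with region-by-volume signal matrix and motion parameters:

1. **Temporal denoising** — delete the first 15 volumes; compute framewise
   displacement FD(t) = Σ|Δd| + r·Σ|Δθ| (r = 50 mm); exclude subjects whose
   mean relative displacement exceeds 0.2 mm; regress out the 36-parameter
   nuisance design (6 motion + WM + CSF + global signals, their temporal
   derivatives, and the squares of all 18); zero-phase band-pass 0.01–0.08 Hz;
   censor volumes with FD > 0.2 mm; exclude subjects with < 240 s of retained
   data.
2. **Connectivity** — Pearson correlation between all pairs of the 264 region
   time series over retained volumes, giving the 264 × 264 matrix R.
3. **MST backbone** — on the strictly positive correlations, Kruskal's
   algorithm adds edges in descending weight order, skipping any edge that
   would close a loop, until all regions are connected: formally a
   *maximum*-weight spanning tree (called MST per the field's convention).
   Three metrics summarise it:
   - global strength = mean of the n−1 edge weights,
   - diameter = edges between the two most remote nodes (efficiency),
   - leaf fraction = share of degree-1 nodes (integration).
4. **Regional connectivity** — mean PCC series (Power regions 77, 78, 82)
   correlated with mean DLPFC-left (167, 176) and DLPFC-right (168, 175)
   series.
5. **Group statistics** — each outcome y is regressed on each risk factor x
   with adjustment for center, age (when not the determinant), gender and IQ;
   coefficients are reported as standardized β = b·SD(x)/SD(y);
   Benjamini–Hochberg FDR is applied within each determinant's family of
   outcomes; extreme-quintile contrasts, summary-statistic Welch/pooled
   t-tests and 2×2 chi-square tests cover the cohort-description analyses.

The synthetic cohort plants a controllable standardized effect γ of a
covariate on connectivity: each subject's off-diagonal correlations are
scaled by 1 + c·x with unit-variance modulator x = γ·z + √(1−γ²)·η, so the
downstream standardized β̂ of the covariate on global MST strength recovers γ.

## Worked example

```r
library(mstfc)

cfg <- simulationConfig(nSubjects = 24, nRegions = 40, nModules = 8,
                        plantedGamma = 0.18, seed = 42)
res <- runPipeline(cfg)
res$flow
#>      stage count remaining
#> 1 eligible    24        24
#> 2 analyzed    24        24

head(res$outcomes[, c("id", "age", "strength", "diameter", "leaf_fraction")], 4)
#>     id      age  strength diameter leaf_fraction
#>  S0001 74.86690 0.5697537       17         0.300
#>  S0002 67.80292 0.6148175       16         0.325
#>  S0003 75.11995 0.4831277       17         0.400
#>  S0004 67.76373 0.5850892       16         0.400
```

All 24 simulated subjects pass the motion and duration gates, and each ends
with its MST summary: strengths around 0.5–0.6 (mean backbone correlation
after denoising), diameters of 16–17 edges on the 40-node tree, leaf
fractions of 0.30–0.40. For contrast, a raw (still confounded) subject shows
what the 36-parameter regression removes — the shared low-frequency nuisance
signal inflates every correlation:

```r
ts <- genSubjectTimeseries(genBaseCorrelation(cfg), 0, cfg, seed = 1)$series
kruskalMST(pearsonMatrix(ts))
#> SpanningTree: 40 nodes, 39 edges
#>   strength 0.8283 | diameter 11 | leaf fraction 0.525

rep <- plantedEffectStudy(7, nSubjects = 100, gamma = 0.18,
                          nRegions = 40, nVolumes = 200)
sprintf("beta = %.3f, p = %.4f", rep$beta, rep$p)
#> [1] "beta = 0.197, p = 0.0531"
```

The planted-effect replicate recovers a standardized β̂ of 0.197 for a
planted γ = 0.18 at n = 100 (at the study's n = 222, the estimate averages
0.18 across replicates; see the methods vignette).

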