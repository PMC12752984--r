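# terravalue

Grid-based farmland quality grading and economic valuation from natural
attributes, for land-resource analysts who need a reproducible,
market-independent baseline value for farmland.

Most farmland valuation leans on market transactions or capitalised
income, which are volatile and undervalue the natural productivity that
underpins them. `terravalue` implements the alternative chain that
prices land from its biophysical endowment:

1. **Fuzzy indicator scoring** — 16 natural-attribute indicators
   (terrain, soil physics and chemistry, location, ecology) map to
   membership degrees F_i ∈ [0, 1] via fitted decreasing / peak
   (Y = 1/(1 + a(u − c)²)) and linear (Y = au + b) functions, or expert
   lookup scales for qualitative classes.
2. **AHP weighting** — weights C_i from the principal eigenvector of a
   reciprocal pairwise judgment matrix, gated by Saaty's consistency
   ratio CR < 0.1.
3. **Comprehensive quality index** — IFI = Σ C_i F_i per evaluation
   unit (connected components of the land-use × soil × administrative
   overlay), graded I–V by exact Jenks natural breaks.
4. **Thornthwaite Memorial potential** — L = 0.05T³ + 25T + 300,
   V = 1.05R / √(1 + (1.05R/L)²), NPP_T = 3000(1 − e^(−0.0009695(V−20))),
   converted at 1 g/m² = 0.01 t/hm²; corrected as MPP = IFI × NPP_T and
   averaged into grade-standard yields MPP_j.
5. **Valuation** — V_j = MPP_j (p − c) per hectare and
   V_total = Σ V_j S_j over grade areas, with shares, regional
   breakdowns and a single-year discount PV = V₁/(1 + r).

A seeded synthetic-landscape generator (autocorrelated fields,
categorical patch maps, Euclidean-distance buffer rings, overlay
evaluation units) makes the whole pipeline runnable and testable with no
external data, and the published Hefei (Anhui, China) case-study
constants — indicator weights, membership parameters, grade thresholds,
per-region grade areas, unit and total values — ship as embedded
reference fixtures with an internal-consistency ledger
(`consistencyCheck()`).

Rasters travel as plain-text Esri ASCII grids (`readAsciiGrid()` /
`writeAsciiGrid()`), tables as CSV, configuration as YAML.

## Worked example

```r
library(terravalue)

res <- runPipeline(pipelineConfig(), seed = 1)

res$landscape$units
#> UnitMap: 50 evaluation units over 2475 farmland cells, total 222.75 hm2 (mean 4.46 hm2)

round(res$yields, 2)   # grade-standard yields, t/hm2
#>    I   II  III   IV    V
#> 9.68 8.58 8.26 7.81 7.41

res$report
#> ValuationReport
#>  grade area_hm2 unit_value_yuan_hm2 total_yuan value_share_pct
#>      I     2.25             8515.75   19160.44            1.23
#>     II    21.60             7551.58  163114.09           10.46
#>    III    73.17             7266.78  531710.40           34.08
#>     IV    73.71             6875.02  506758.09           32.48
#>      V    52.02             6523.30  339342.00           21.75
#> Grand total: 1560085.02 yuan
```

On this 3 km × 3 km synthetic tile the overlay yields 50 evaluation
units averaging 4.46 hm². Grade-standard yields fall monotonically from
9.68 t/hm² (grade I) to 7.41 t/hm² (grade V): better-scoring units keep
more of the climate-limited potential. At the default rice margin of
880 yuan/t that prices grade-I land at 8 515.75 yuan/hm², and the tile's
single-year theoretical output at about 1.56 million yuan, dominated by
the extensive middle grades rather than the small top grade.

Individual stages are exported and composable, e.g.:

```r
evaluateMembership(refMembershipSpecs()[["I2"]], 10)  # slope of 10 degrees
#> [1] 0.3891051
classifyGrades(0.6477, refGradeScheme())              # threshold belongs to grade I
jenksBreaks(c(1, 2, 3, 100, 101, 102), k = 2)         # exact natural breaks
```

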