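---
title: "Grading and valuing farmland from natural attributes"
author: "terravalue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading and valuing farmland from natural attributes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terravalue)
```

## The model

`terravalue` prices farmland from its natural attributes alone. The chain
has five links, each a small, testable operation:

1. **Indicator scoring.** Sixteen gridded indicators — terrain position,
   slope, plough-layer texture, bulk density, gravel volume, available
   water, fragmentation, pH, organic matter, cation exchange capacity,
   organic carbon, total nitrogen, distance to water, distance to
   settlements, water conservation and soil retention — are mapped to
   fuzzy membership degrees $F_i \in [0,1]$. Numeric indicators use one
   of three fitted families: decreasing and peak types
   $Y = 1/\bigl(1 + a(u-c)^2\bigr)$, and linear $Y = au + b$
   (`evaluateMembership()`, parameters in `refMembershipSpecs()`).
   Qualitative indicators use expert lookup scales
   (`refConceptualScales()`), e.g. impact plains score 1.0 and small
   undulating mountains 0.4.

2. **Weighting.** Indicator weights $C_i$ come from the analytic
   hierarchy process: the principal right eigenvector of a positive
   reciprocal pairwise judgment matrix, with Saaty's consistency ratio
   $CR = \frac{(\lambda_{max}-n)/(n-1)}{RI(n)}$ gating acceptance at
   $CR < 0.1$ (`weightsFromMatrix()`, `consistencyRatio()`). The
   published Hefei weight vector ships verbatim as `refWeights()`; its
   printed sum is 0.9999 and is deliberately not renormalised by
   default.

3. **Quality index and grading.** Scores are averaged over evaluation
   units — 4-connected components of identical (land-use, soil,
   administrative) overlay triples — and combined per unit as
   $IFI = \sum_i C_i F_i$. Units are cut into five grades I–V by exact
   Jenks natural breaks (`jenksBreaks()`), minimising the within-class
   sum of squared deviations.

4. **Production potential.** The Thornthwaite Memorial model turns
   annual mean temperature $T$ (°C) and precipitation $R$ (mm) into
   climatic potential:
   $L = 0.05T^3 + 25T + 300$ (mm),
   $V = 1.05R / \sqrt{1 + (1.05R/L)^2}$ (mm),
   $NPP_T = 3000\bigl(1 - e^{-0.0009695 (V-20)}\bigr)$ (g/m²),
   converted at 1 g/m² = 0.01 t/hm². The quality index attenuates it,
   $MPP = IFI \times NPP_T$, and area-weighted grade means give the
   grade-standard yields $MPP_j$ (`gradeStandardYield()`).

5. **Valuation.** $V_j = MPP_j (p - c)$ with market price $p$ and
   production cost $c$ (yuan/t), and
   $V_{total} = \sum_j V_j S_j$ over grade areas $S_j$ (hm²)
   (`unitValue()`, `totalValue()`). A single-year discount
   $PV = V_1/(1+r)$ is available (`presentValue()`).

The core assumption is that quality acts as a multiplicative attenuation
on climate-limited productivity: soil and site conditions scale down
what light, heat and water would otherwise permit. This is linear by
design — interpretable and standard in regional assessments — and is
the main structural simplification of the model.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| membership `a, b, c` | per indicator | `refMembershipSpecs()` | fitted coefficients of the published functions, verbatim |
| indicator weights | — | `refWeights()` | published AHP weights (sum 0.9999 as printed) |
| grade count `k` | — | 5 | five-grade convention of the quality-grading standard |
| grade thresholds | index units | Jenks on the data, or `refGradeScheme()` | the published canonical thresholds accompany the published areas |
| price `p`, cost `c` | yuan/t | 2640, 1760 | season-averaged rice price and cost for the study year |
| discount rate `r` | — | none | single-year sensitivity only, 3–5 % typical |
| cell size | m | 30 | the common resolution of the source rasters |
| sliver threshold | hm² | 0.36 | four 30 m cells; overlay slivers below this merge into their largest neighbour (no threshold is published; this is the package's choice) |

Three printed quirks in the membership table are reproduced as printed
rather than "fixed", and only flagged in the documentation: the pH row
is labelled peak-type but has $c = 0$, making it monotone decreasing
over its domain [5.4, 7.2]; the effective-water linear function
($a = 0.0015$, $b = 0$) cannot exceed ≈ 0.055 over its printed bounds,
which looks like a units inconsistency upstream; and the total-nitrogen
linear fit exceeds 1 below its upper bound, so its output is clamped.
Clamping is the package's general out-of-range rule: inputs clamp to
the fitted domain $[u_{lo}, u_{hi}]$, outputs to $[0, 1]$.

## The synthetic landscape

No rasters are redistributable, so `generateLandscape()` builds a
self-consistent study area from a single seed:

* continuous indicators are Gaussian-smoothed white noise
  (`generateField()`), affinely rescaled so each layer's min/max equal
  the fitted membership domain exactly;
* qualitative indicators are nearest-seed (Voronoi) patch maps whose
  legends match the scoring scales (`generateCategorical()`);
* the two locational indicators are derived the way a GIS workflow
  would: exact Euclidean distance to the nearest water or settlement
  cell (`distanceTransform()`), cut into five 500 m buffer rings
  (`ringClassify()`), innermost ring scoring best;
* evaluation units come from the overlay of land-use, soil and
  administrative patch maps (`buildEvaluationUnits()`), with slivers
  under 0.36 hm² merged into their largest adjacent unit.

Climate defaults (T in 15–17 °C, R in 900–1100 mm) are plausible for a
subtropical monsoon setting; they are configuration, not reference
values. The default grid is 100 × 100 cells at 30 m (a 3 km × 3 km
tile, typically a few dozen evaluation units); the real study area —
20,439 units averaging 5.1 hm² — is three orders of magnitude larger,
and nothing in the code depends on the tile size. Tests run tiles
between 1 × 1 and 60 × 60.

What the generator does **not** emulate: real covariance between
indicators (slope and gravel volume are independent fields here, while
in real terrain they correlate), anisotropy and drainage structure,
registration error between layers, and measurement noise. Passing
tests therefore demonstrate that the computational chain is correct
and internally consistent — not that the model is validated against
observed yields.

## Numerical choices

* **Jenks breaks** use the exact $O(kn^2)$ Fisher dynamic programme on
  the sorted distinct values with frequency weights, never the
  iterative Jenks–Caspall heuristic, so results are deterministic and
  provably optimal; tests verify equality with exhaustive enumeration
  on over 200 random instances. Breaks are computed on unit-level
  indices (the unit, not the cell, is the analysis atom).
* **Grade intervals** are half-open on the lower bound, $[lo, hi)$,
  with the top interval closed at its maximum, so a value exactly on a
  published threshold (e.g. 0.6477) belongs to the better grade. A
  top class containing a single distinct value degenerates to a point
  interval; the scheme class allows this for the top grade only.
* **Two published threshold sets** exist; `refGradeScheme("canonical")`
  is the set consistent with the published grade areas and is the one
  used in checks, `"alternate"` preserves the other printing.
* **Thornthwaite NPP** is floored at 0 for $V < 20$ mm, where the
  printed formula goes negative. The unit conversion is 0.01
  (1 g/m² = 0.01 t/hm²); the alternative "divide by 10,000" phrasing
  that circulates is dimensionally inconsistent with the published
  potential range and is not used.
* **Grade-standard yields** are area-weighted means by default
  (matching a zonal-statistics workflow); an unweighted flag exists.
* **AHP** uses power iteration to relative tolerance 1e-10; the
  random-index table covers $n \le 15$. The published unit-value table
  is *not* reproduced by $MPP_j (p-c)$ with its own printed inputs
  (10.28 × 880 = 9046.4 ≠ 3291.13, an effective margin of ≈ 320
  yuan/t would be implied); the package computes the formula
  literally, also offers totals-division (`deriveUnitValues()`), and
  restricts reference-table checks to aggregation identities that do
  hold (`consistencyCheck()`).
* **Determinism**: every generator takes an explicit seed, restores
  the caller's RNG state, and derives independent sub-seeds per layer,
  so bundles are bit-identical across runs and platforms.

## Limitations

The valuation is a single-year, single-crop theoretical output: no
capitalisation horizon, no management effects, no market dynamics. The
climate model is empirical and annual; it ignores seasonality and CO₂.
The quality–productivity coupling is linear by assumption. Grade
results depend on the classification method (natural breaks versus
equal intervals), which is why the scheme is explicit, inspectable and
swappable throughout.
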