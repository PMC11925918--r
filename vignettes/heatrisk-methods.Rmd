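---
title: "Methods: composite heat health risk assessment and CA-Markov prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite heat health risk assessment and CA-Markov prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatrisk)
```

## The model

`heatrisk` implements a risk-triangle assessment of heat-related health risk
on gridded (1-km) indicators, followed by a spatially explicit forecast of
the resulting risk-class maps. The composite index at every cell is

$$\mathrm{HHR} = H \times S \times E,$$

the product of a thermal **hazard** surface (nighttime land surface
temperature), a weighted **social vulnerability** score (GDP, disposable
income, physicians, hospital beds, older adults, female population,
unemployment) and a weighted **exposure** score (population density,
agricultural and construction practitioners, NDVI, water resources). The
multiplicative form encodes the assumption that risk requires the joint
presence of a stressor, a susceptible population and actual exposure: any
factor near zero suppresses the cell's risk regardless of the others.

Every indicator is first min-max normalized onto $[0.01,\,1.01]$:

$$X_p = \frac{X - \min X}{\max X - \min X} + 0.01,
\qquad
X_n = \frac{\max X - X}{\max X - \min X} + 0.01,$$

with the reversed form $X_n$ for indicators whose larger raw values *reduce*
risk (GDP, income, physicians, beds, NDVI, water resources). The $+0.01$
offset keeps all factors strictly positive so the product never collapses to
an uninformative zero plateau. Min and max are taken over unmasked cells
only; a constant layer is an error (the formula divides by zero), not a
silent pass-through. The product surface is itself min-max rescaled to
$[0, 1]$, per assessment year — each year's map spans the full scale, which
is also what the five-level grading below assumes.

## Indicator weights from PCA

Within the vulnerability and exposure batteries the indicators are combined
linearly, with weights derived from a principal component analysis of the
indicator correlation matrix (cells are observations; the hazard layer, a
battery of one, is excluded). With eigenvalues $X_j$, loadings $a_{ij}$ and
variance-contribution rates $PC_j = 100\,X_j/p$, each retained component's
loadings are turned into score coefficients and averaged:

$$b_{ij} = \frac{|a_{ij}|}{\sqrt{X_j}}, \qquad
W_i = \frac{\sum_j b_{ij}\,PC_j}{\sum_j PC_j},$$

after which the $W_i$ are renormalized to sum to 1 within each category.
Components are retained by the eigenvalue-greater-than-1 rule by default.
Two diagnostics gate the PCA: the Kaiser–Meyer–Olkin measure (adequate
above about 0.7; a battery of independent indicators scores near 0.5) and
Bartlett's sphericity test ($\chi^2 = -((n-1)-(2p+5)/6)\ln\det R$ on
$p(p-1)/2$ degrees of freedom).

Design choices worth stating explicitly:

* **Absolute loadings.** $|a_{ij}|$ is used because the direction of each
  indicator's risk contribution is already carried by its normalization
  direction; the weights are magnitudes of importance and must be
  nonnegative. The alternative coefficient form $|a_{ij}|/X_j$ is available
  via `b_formula = "a_over_x"`.
* **Per-category renormalization.** The vulnerability weights sum to 1 and
  the exposure weights sum to 1 separately, so $S$ and $E$ stay on the
  $[0.01, 1.01]$ scale of their inputs and neither battery's size inflates
  its influence.
* **Pooled fit.** The PCA is fit once on the pooled unmasked cells of all
  assessment years (thinned to a 50,000-cell cap on a regular grid), giving
  a single weight vector for the whole study period. No rotation is
  applied: with weights built from absolute loadings scaled by component
  contributions, an orthogonal rotation would only redistribute variance
  among components while the package's retention rule and weight formula
  are defined for the unrotated solution; the unrotated solution is also
  the one that is reproducible without a rotation-target convention.

## Five-level classification

The $[0,1]$ risk surface is classified into *lowest / low / medium / high /
highest* with Jenks natural breaks — the partition of the sorted values into
five contiguous classes minimizing the total within-class sum of squared
deviations. The optimizer is an exact dynamic programme (O($kn^2$), in
compiled code), not the common iterative heuristic, and is verified in the
test suite against exhaustive enumeration on small inputs.

The breaks are computed once on the **baseline year** and then frozen: later
years and predictions are graded against the same thresholds, so class
changes over time reflect changes in the surface, not changes in the ruler.
Bins are half-open, $[t_{k-1}, t_k)$, with each boundary value belonging to
the upper class; the returned thresholds are the minima of classes 2–5. A
fixed conventional standard (0.2 / 0.4 / 0.5 / 0.58) can replace the Jenks
breaks (`breaks: {mode: table}`) for replication against published maps.

From the class maps the package derives three accountings: per-level area
shares; cross-date transition matrices (cell-by-cell cross-tabulation, whose
marginals reproduce both dates' shares exactly); and, within the high +
highest cells, **dominant-factor subzones** — each cell attributed to the
component ($H$, $S$ or $E$) with the largest value after min-max rescaling
over that domain. "Leading component" has no unique definition; the argmax
of domain-rescaled components is the package's, with ties resolved in the
fixed order hazard > social vulnerability > exposure, so results are
deterministic.

## CA-Markov prediction

Future class maps are simulated with a cellular-automaton/Markov hybrid.
From two dated maps the row-stochastic transition matrix $P$ is estimated by
cross-tabulation ($S^{t+1} = S^t P$ projects aggregate class areas; a class
absent at the first date receives an identity row). The spatial allocation
then runs `iterations` annual cycles (default 10):

1. **Demand.** The cumulative class demand after cycle $m$ of $M$ is
   $S^0[(1 - m/M)\,I + (m/M)\,P]$ — a linear interpolation between the
   identity and the full one-period matrix. Fractional matrix powers
   $P^{1/M}$ do not exist (or are complex) for many empirical $P$, so the
   interpolation is used instead; its last cycle enforces the exact
   one-period Markov demand, which is the quantity the validation checks.
   Real-valued demands are rounded largest-remainder so they sum exactly to
   the unmasked cell count.
2. **Suitability.** For each class, a cell's suitability is the fraction of
   valid cells in its 5 × 5 Moore window (centre included, windows truncated
   at edges, nodata excluded) currently holding that class. Per cell the
   suitabilities partition to 1.
3. **Allocation.** Every cell–class pair is scored
   $\text{suitability}_k(\text{cell}) \times P[\text{current class},\,k]$
   and pairs are assigned greedily in descending score until every class
   demand is filled. This is a deliberate simplification of multi-objective
   land allocation; it preserves the two properties the validation relies
   on (exact demand, spatial coherence) at a fraction of the complexity.
   Ties are broken by a seeded uniform jitter of amplitude $10^{-9}$, so
   runs are deterministic under a fixed seed. Masked cells never change
   class and carry no demand.

Prediction assumes a stationary transition regime: the matrix estimated
between the two calibration dates is applied unchanged one period forward.

## Validation

Agreement between a predicted and an observed class map is scored with
Cohen's kappa, $\kappa = (p_o - p_e)/(1 - p_e)$, computed over cells
unmasked in both maps. Significance uses the large-sample normal deviate of
$\kappa$ under the independence null (Fleiss variance); the package reports
$z$ and the two-sided $p$. The robustness protocol re-runs the hindcast at
several iteration counts (8/10/12 by default in the tests) and tabulates
kappa per setting — a stable model moves by well under 0.05 across these.

## The synthetic world

No real rasters ship with the package; a seeded generator produces the
inputs the pipeline was designed for, at desk scale (default 128 × 128
cells ≙ ~128 km, three years: 2010/2015/2019):

* an elliptical study boundary (cells outside are nodata end to end);
* an urbanization intensity field: Gaussian bumps at `n_urban_cores = 3`
  cores (radius 10 cells, the first at the centre) plus 8% smooth texture,
  rescaled to $[0,1]$;
* a landform map with 25% mountain and 8% water drawn from thresholded
  smooth fields — the low-risk fringe real study areas have;
* 13 indicators as latent-factor fields: each is
  `loading_urb · z(urbanization) + loading_grp · group_field + noise`,
  with three shared secondary fields (socio-economic, demographic,
  environmental) so the correlation matrix has a multi-component structure
  worth a PCA, and i.i.d. Gaussian noise (`noise_sd = 0.15` against a
  unit-variance common factor — strong but not degenerate common structure,
  giving KMO ≈ 0.9);
* a drift: the urbanization loading of LST and population density grows by
  `trend_per_year = 2%` per elapsed year. A uniform additive trend would be
  removed by the min-max normalization, so drift is expressed as gradient
  amplification, which changes the cell ordering and moves cells between
  *adjacent* risk classes — the transition pattern the accounting and the
  CA-Markov stages are built for.

One deliberate stylization: each indicator's urbanization-loading **sign
equals its risk direction** (so GDP, an indicator whose larger values reduce
risk, *decreases* toward the urban cores). In real geography GDP rises with
urbanization; here the signs are tied so that a direction is recoverable
from data as the sign of the correlation with urbanization, which keeps the
direction conventions testable end to end. The generator makes no attempt
to imitate any real region's geography or climatology — a green test
establishes that the pipeline's logic is correct on a world with the stated
structure, not that the package reproduces any particular empirical map.

Smooth fields are white noise convolved with an isotropic Gaussian kernel
(`smoothing_scale = 6` cells), standardized; everything is a pure function
of the scenario seed, and the RNG state of the session is restored after
every seeded call.

For the prediction stages the generator can also evolve a categorical map
under a known transition matrix (`gen_markov_series`), optionally letting
each cell adopt its 5 × 5 modal class with probability `spatial_mixing` —
injecting the spatial autocorrelation a CA expects while keeping the
aggregate dynamics close to $P$. With `spatial_mixing = 0` the empirical
transition frequencies converge to $P$, which is how the estimator is
validated.

## Numerical conventions and degenerate inputs

* Grids are north-up, row-major; cell (1,1) is the NW corner and cell
  centres sit at `origin + ((j-0.5), -(i-0.5)) · cell_size`. Alignment uses
  the intersection extent; nearest-neighbour resampling never invents
  values. Nodata propagates as the union of masks: the product index is
  undefined wherever any factor is missing.
* All inputs must declare the same `crs_tag`; the package never reprojects.
* Admin-table rasterization fills each unit uniformly (the only
  distribution derivable from a per-unit total alone); zone id 0 is masked
  and a zone missing from the table is an error naming the id.
* GeoTIFF I/O is a minimal built-in single-band codec (uncompressed
  float32, nodata-tagged), round-trip-tested against an independent TIFF
  reader; ESRI ASCII grids carry the crs tag in a `.prj` sidecar.
* Constant surfaces are errors wherever a min-max rescale is required
  (normalization, HHR); in the dominance step a component that is constant
  over the high+highest domain rescales to 0 and simply never dominates.
* Two maps that are both constant and identical have $p_e = 1$; kappa is
  undefined there and the package says so rather than returning 1.

## Limitations

* The greedy allocation can differ from IDRISI-style multi-objective
  allocation in the placement of marginal cells; class totals are identical
  by construction, so validation kappas are comparable but not bit-equal to
  other CA-Markov implementations.
* Weights from the default synthetic world are nearly uniform within each
  category (the common factor dominates every indicator); rank recovery of
  ground-truth loadings is therefore tested on a dedicated one-factor
  design, not on the default scenario.
* Transition stationarity is an assumption, not a finding: the hindcast
  kappa measures one period of it.
* The pipeline is desk-scale by design; the exact Jenks programme is
  quadratic in the cell count and is the stage that would need sampling on
  multi-million-cell rasters (`stack_observations` already caps the PCA
  sample for the same reason).
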