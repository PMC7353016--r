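---
title: "Geostatistical mapping of serum selenium status: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistical mapping of serum selenium status: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selmapr)
```

## The problem

National micronutrient surveys measure serum biomarkers — here selenium (Se),
in µg/L — on individuals sampled in geographic clusters (enumeration areas,
EAs). Policy questions are spatial: *where* is the population likely to be
deficient? selmapr implements a model-based geostatistical pipeline for this
setting: survey-weighted summaries and deficiency prevalence; aggregation of
individuals to EA means; empirical variography of the EA means on
great-circle distances; an exponential variogram model fitted by weighted
least squares and screened by kriging cross-validation; ordinary kriging
prediction and variance surfaces on a national grid; and maps of the
probability that serum Se falls below a deficiency threshold, expressed with
the IPCC's calibrated likelihood phrases.

Because individual-level serum datasets of this kind are restricted, the
package ships a synthetic-survey generator that emulates the relevant
structure (a spatially correlated EA-mean field, within-EA individual
variation, survey demographic composition, missingness and outliers), so
every stage is exercised end-to-end by tests without access to any real
records.

## Data model and exclusions

A survey record carries a person and EA identifier, region, demographic
group (YC = young children, SAC = school-age children, WRA = women of
reproductive age, MEN = adult men), sex, residence, a survey weight,
WGS84 latitude/longitude, and serum Se in µg/L. Records are excluded in a
fixed precedence — missing GPS coordinates, then missing demographic data,
then flagged marginal outliers — so each record is counted under exactly one
reason and the exclusion log reconciles exactly. The precedence itself is a
convention (sources typically report only counts); fixing it makes logs
deterministic.

Deficiency thresholds default to 84.9 µg/L (optimal glutathione peroxidase 3
activity; the midpoint of the 1.00–1.15 µmol/L optimal range converted with
the molar mass of Se, 78.97 g/mol, and rounded to 0.1), 64.8 µg/L (optimal
iodothyronine deiodinase activity) and the conventional 70 µg/L cut-off.
Prevalence uses the strict inequality (serum Se < threshold).

Survey-weighted quantiles use a cumulative-weight inverse CDF: the `p`
quantile is the smallest sorted value whose cumulative weight share reaches
`p`, interpolating midway between adjacent values when `p` falls exactly on
a cumulative boundary. This choice (among the many weighted-quantile
definitions in circulation) reproduces the ordinary sample median under
equal weights, which makes weighted and unweighted summaries directly
comparable; both modes are exposed via `summarize_se(weighted = )` because
survey reports are not always explicit about which was used.

## Variography on the sphere

Spatial analysis operates on EA means (serum values and coordinates averaged
per EA; coordinates as raw degrees — EAs are tiny relative to the spatial
scales of interest, so planar averaging error is negligible). Before
variography the EA means are screened with Tukey's fences on type-7
quartiles: values beyond the outer fences (3 × IQR) are "probable" outliers,
removed for variogram estimation but **reinstated for kriging and
cross-validation**, since an extreme-but-plausible observation should still
inform local prediction even though it would distort variance estimation.

Lags are great-circle distances on a sphere of radius 6378.137 km (the
conventional equatorial radius; configurable), with arrival bearings folded
to [0°, 180°) so a lag and its reverse share a direction class. On the
sphere not every planar variogram family remains valid; the exponential
model

$$\gamma(h) = c_0 + c_1\,(1 - e^{-h/a}), \qquad \gamma(0)=0$$

is, and is the single family the package fits: nugget $c_0$ (spatially
uncorrelated variance including measurement error), partial sill $c_1$
(spatially correlated variance), distance parameter $a$ (effective range
≈ $3a$).

Three empirical estimators are provided per lag bin with pair differences
$d$: Matheron's method of moments $\sum d^2 / 2N$; Cressie–Hawkins'
fourth-power-of-root-moments estimator
$\bar{(|d|^{1/2})}^4 / (2(0.457 + 0.494/N))$; and Dowd's median-based
$2.198\,\mathrm{med}(|d|)^2/2$. The robust pair are there because spatial
outliers inflate squared differences; the suite verifies that Dowd's
estimate is essentially unmoved by an injected spike that inflates
Matheron's by orders of magnitude, and that all three agree on iid Gaussian
differences at large pair counts.

### Numerical choices in binning and fitting

* **Lag bins.** Default: 25 equal-width bins from 0 to one third of the
  maximum inter-point distance, with bins under 30 pairs dropped. The
  cutoff matters more than the bin count. In simulation calibration at the
  package's reference model (345 EAs in the Ethiopia box, 400 replicates),
  extending bins to half the maximum distance biased the mean fitted nugget
  by about +36% and the distance parameter by +15%: the longest-lag bins
  contain the most pairs, so they dominate a pair-count-weighted fit, while
  being the least stable between realizations. With the third-of-maximum
  cutoff the same experiment recovers all three parameters essentially
  unbiased (within ~4%). A third of the maximum distance is also the common
  default in variography software. Both cutoff and bin count are arguments.
* **WLS weights.** Bin pair counts $n_k$ by default; Cressie's
  $n_k/\gamma(h_k;\theta)^2$ is available (`weights = "cressie"`).
* **Optimization.** Bounded quasi-Newton (`nlminb`) from three perturbed
  starts, lowest objective wins; non-negativity enforced on $c_0, c_1$.
* **Identifiability bound on `a`.** The distance parameter is bounded above
  by one third of the largest lag (so the effective range $3a$ cannot
  exceed the span of the empirical variogram). Without this bound, a few
  percent of simulated realizations — those whose empirical variogram keeps
  creeping upward at long lags — drive $a$ (and $c_1$ with it) to
  arbitrarily large values where the model is exactly linear in $h$ and the
  parameters are unidentified. Fits that peg at the bound indicate that the
  data do not resolve a sill. The bound is an argument (`a_max`).
* **Degenerate inputs.** A flat empirical variogram collapses cleanly to a
  pure-nugget fit ($c_1 \to 0$); fewer than four usable bins is an error.

### Directional variograms

Four bearing classes of 45° (centred on 0°, 45°, 90°, 135°) by default —
the standard screen for anisotropy. The package reports class-wise
variograms and leaves the isotropy judgement to the analyst, matching how
such checks are reported in practice.

## Ordinary kriging and its validation

Ordinary kriging solves the bordered semivariance system; the implementation
uses a single dense factorization per data configuration, reused across all
prediction targets (global neighbourhood — at a few hundred EAs this is
cheap and avoids search-neighbourhood artifacts). Duplicate locations are
collapsed to their mean with a warning (they make the system singular at
zero nugget). The suite checks the classical identities: weights sum to one
to 1e-10; exact interpolation with zero nugget (prediction = datum, variance
= 0); shift invariance; agreement with an independently assembled dense
solve.

Model validity is screened by leave-one-out cross-validation. Each site is
predicted from the rest; the squared error standardized by the kriging
variance (SSPE) is $\chi^2_1$ under a valid model with Gaussian errors, so
the median SSPE has expected value `qchisq(0.5, 1)` ≈ 0.455. The 95%
validity interval for the median SSPE is obtained by Monte-Carlo: fields
simulated under the candidate model *at the actual data locations*, each
cross-validated, and the 2.5/97.5 percentiles of the median taken. (The
kriging weights depend only on geometry, so they are computed once and
reused across simulated fields; 1000 simulations cost about a second at
n = 345.) The interval is data-configuration-specific, not a universal
constant.

Model selection is efficiency-first: the fit to Matheron estimates is
cross-validated first and accepted if its median SSPE falls in the interval;
only on failure are the robust-estimator fits cross-validated, the candidate
with median SSPE closest to 0.455 winning. If nothing passes, selection
fails explicitly with the full audit trail — no silent fallback.

## Probability maps and calibrated phrases

The prediction at a grid node is treated as Gaussian with the kriging mean
and variance (the plug-in form — a modelling assumption, stated rather than
derived; conditional simulation would be the alternative). The probability
of deficiency is then $\Phi((t - \hat z)/\sigma)$, degenerate limits handled
explicitly at $\sigma = 0$. Probabilities map to seven IPCC-style phrases
from "exceptionally unlikely" (< 1%) to "virtually certain" (≥ 99%); the
published IPCC ranges overlap, so the package uses non-overlapping
left-closed bins (a boundary probability belongs to the upper bin) to make
classification exhaustive and unique. Grids are lattices with spacing
converted from km at the domain's central latitude, optionally masked by a
boundary polygon (a deliberately coarse synthetic Ethiopia outline ships
with the package; real administrative boundaries do not).

The default grid spacing is 10 km: a survey of ~350 clusters with an
effective range of ~400 km carries no information at finer resolution, and
sub-km national grids would be computationally absurd.

## The synthetic world

`sim_config()` defaults state the reference condition the generator
emulates: 346 EAs placed uniformly in a lon 33–48°E / lat 3–15°N box; EA
means drawn from a Gaussian field with exponential covariance
$c_1 e^{-h/a}$ ($c_0 = 2.51$, $c_1 = 26.23$ (µg/L)², $a = 132.8$ km — the
reference cross-validated model) around a mean of 103.6 µg/L; 3376
individuals split YC 584 / SAC 1034 / MEN 419 / WRA 1339 and allocated
round-robin so realized group totals are exact; GPS and demographic
missingness at rates reproducing, in expectation, 101 and 5 records of
3376; and one injected WRA outlier. Design notes:

* The nugget is realized as iid Gaussian noise added to the correlated
  field (measurement-error interpretation).
* Individuals are EA mean + iid noise with a within-EA standard deviation
  of 20 µg/L. No empirical estimate of this quantity is available, so it is
  a stated parameter: 20 µg/L is a realistic serum-biomarker spread, chosen
  once and not revisited.
* Serum values below 1 µg/L are re-drawn (serum Se is positive); at the
  default mean/sill this truncation is essentially never triggered, so the
  field remains effectively Gaussian.
* Covariance factorization adds a jitter of 1e-8 of the sill; dense
  factorization limits simulation to a few thousand locations.
* EA placement is uniform, not proportional-to-size, and no household
  clustering is emulated: the spatial model operates on EA means, so these
  survey-design details are out of the generator's scope. Consequently a
  green simulation suite establishes that the *machinery* is correct under
  the stated model — not that any real survey satisfies the model's
  stationarity and Gaussianity assumptions.

A deterministic companion, `enms_count_fixture()`, reproduces exactly the
itemized exclusion structure of the reference survey (3376 records, 101
GPS-missing with its per-group breakdown, 5 demographic-missing, one
outlier, 3269 retained with the published composition), for tests of the
exclusion and summary stages.

## What the tests establish

The non-acceptance suite covers each stage against independent oracles:
closed-form spherical trigonometry for distances and bearings; brute-force
pair enumeration for the Matheron estimator; hand-evaluated robust-estimator
cases; an independently assembled kriging system; closed-form two-point
cross-validation; scale equivariance of SSPE; Monte-Carlo convergence of
simulated-field covariances to $c_1 e^{-h/a}$. The acceptance suite then
runs the calibration experiments: WLS refits across repeated simulated
fields recover the generating parameters on average (nugget within 25%,
partial sill and distance parameter within 20%), and the LOO median SSPE
under the true model falls inside its Monte-Carlo validity interval in at
least 90% of replicate experiments. `scripts/acceptance.R` recomputes the
recovery experiment from scratch at 200 replicates.

## Known limitations

* One variogram family (exponential) — by design, as the sphere-valid
  choice; no Matérn/spherical alternatives, no ML/REML fitting.
* Plain ordinary kriging only: no covariates, no trans-Gaussian or
  indicator variants.
* The plug-in Gaussian probability map understates uncertainty relative to
  conditional simulation when the prediction distribution matters jointly
  across nodes.
* Dense linear algebra throughout: comfortable to ~3000 locations, not
  beyond.
* Survey weights enter summaries only; the spatial model treats EA means as
  unweighted, mirroring the reference analysis.
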