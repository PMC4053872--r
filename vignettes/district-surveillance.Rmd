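---
title: "Spatio-temporal surveillance of district hospitalization rates"
author: "citysurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal surveillance of district hospitalization rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citysurv)
```

## The problem

Health administrations of fast-growing cities routinely hold only coarse
surveillance data: annual hospital admission counts and populations per
administrative district, district centroids, and hospital counts. citysurv
implements a complete analysis chain for exactly this data shape, oriented at
chronic-disease hospitalization (the motivating case is ischemic heart
disease in a ten-district city observed over a decade):

1. **Rate standardization and ranking** — crude admission rates per 1,000
   residents, indirectly standardized ratios, and discrete rank maps.
2. **Point-pattern summaries** — mean centers and standard deviational
   ellipses of annual case clouds, to describe drift and dispersion.
3. **Space-time cluster detection** — a retrospective scan statistic with
   cylindrical windows and a discrete Poisson likelihood.
4. **Grey forecasting** — GM(1,1) models per district with
   posterior-deviation validation, and a per-hospital burden projection.

A seeded synthetic-data generator reproduces the statistical structure this
chain assumes, so every stage can be exercised and tested end to end without
access to confidential records.

## Rates and ranks

For district $i$ in a given year, with admissions $Q_i$ and population
$N_i$, the crude rate is $IR_i = 1000\,Q_i/N_i$. The city-wide general rate
$G = \sum_j Q_j / \sum_j N_j$ defines expected counts $E_i = G\,N_i$ and the
standardized ratio $SR_i = Q_i/E_i$. Two algebraic identities follow
directly and are enforced by the tests: $\sum_i E_i = \sum_i Q_i$ within
round-off for every year, and the pooled SR of the whole city is exactly 1.
$G$ is computed per year, because SR maps are annual.

Average rates are classified into four ranks at z-score cut points
$\{-0.29, 0.61, 1.5\}$ (population-convention standard deviation; any
consistent convention only rescales the cuts, which are arguments).
`classify_ir_rank(on = "value")` applies the cuts to raw values instead,
which is how published fixed-interval legends are reproduced. SRs are
classified into five ranks at the fixed breakpoints
$\{0.580, 0.890, 1.270, 1.840, 2.500\}$; these are k-means-derived bounds
kept as constants for reproducibility, while `kmeans_1d()` regenerates
data-driven boundaries (Lloyd's iteration from deterministic quantile-based
centers, boundaries at midpoints between adjacent cluster extremes) when a
user prefers them. All intervals are half-open (left-open, right-closed) on
the continuous line, so no value is unassignable; values above the top SR
bound are capped at rank 5 with a warning. Rank transitions between two
years are labelled `higher` / `lower` / `invariant`.

## Mean centers and standard deviational ellipses

For a planar point cloud, the mean center is the (weighted) average
coordinate. The standard deviational ellipse summarizes dispersion and
orientation: with centered coordinates $\tilde x, \tilde y$ and second
moments $S_{xx}, S_{yy}, S_{xy}$, the major-axis direction is
$\theta = \tfrac12\,\mathrm{atan2}(2S_{xy},\,S_{xx}-S_{yy})$ and the axis
lengths are the root-mean-square deviations along the rotated axes,
$\sqrt{\lambda_{\pm}/m}$ with $\lambda_\pm$ the second-moment eigenvalues.
This is the classical Ebdon/CrimeStat formulation — the familiar
$\tan\theta = \big[(S_{xx}-S_{yy}) + \sqrt{(S_{xx}-S_{yy})^2 +
4S_{xy}^2}\big]\,/\,2S_{xy}$ arctangent form is the same ellipse expressed
as an azimuth from north ($\tan(90^\circ - \theta)$), and the test suite
cross-checks the two routes against each other.

Conventions, each chosen to keep the statistic testable:

* $\theta$ is reported counterclockwise from the positive x-axis in
  $[0^\circ, 180^\circ)$ — the mathematical convention, under which rotation
  equivariance is a one-line property test. `theta_to_geographic()` converts
  to the GIS clockwise-from-north convention.
* the RMS denominator is $m$ (the point count), not $m-2$;
* no $\sqrt2$ axis inflation is applied (some GIS products inflate the axes
  so the ellipse covers ~63% of points); `scale = sqrt(2)` restores it;
* a perfectly isotropic cloud has no defined orientation: $\theta = 0$ by
  convention with `degenerate = TRUE`.

Overlap between two annual ellipses — the qualitative measure of
year-to-year spatial correlation — is computed as a seeded Monte-Carlo
estimate of intersection over union on the joint bounding box. An exact
conic-intersection area is possible but unnecessary: overlap is interpreted
qualitatively, and the Monte-Carlo error at the default $10^5$ samples
(about $\pm 0.005$) is far below interpretive resolution.

## The space-time scan

Candidate clusters are cylinders: a circular base centered on a district
centroid whose radius sweeps the sorted inter-centroid distances (including
zero), crossed with every contiguous year interval. A base is retained while
its share of the study-average population is at most 50% (configurable), and
intervals are capped at 50% of the study length — both standard defaults for
retrospective scans. Membership is centroid-in-circle with inclusive
boundary; the average population decides the cap because populations vary by
year.

Expected counts use the whole-study general rate applied to district-year
populations, making expectations purely population-proportional across
space-time. For a window with observed $O$ and expected $E$ out of $C$ total
cases, the discrete-Poisson log likelihood ratio is

$$LLR = O \ln\frac{O}{E} + (C-O)\ln\frac{C-O}{C-E}$$

for high-rate windows ($O > E$; otherwise 0, with $0\ln 0 \equiv 0$), and
the relative risk is the inside rate over the outside rate. Inference is by
Monte Carlo conditional on $C$: replicates redistribute the $C$ cases
multinomially with probabilities proportional to the expected counts, and
$p = (1 + \#\{\text{replicate max } LLR \ge LLR\})/(1 + R)$ with $R = 999$
replicates by default. The most likely cluster maximizes the LLR (ties:
smaller member set, then lexicographic ids); secondary clusters are
significant windows sharing no district with a better-ranked cluster.

Because the window family is cylindrical *by definition*, arbitrary district
subsets (two far-apart districts without the one between them) are not
candidate clusters; the brute-force oracle in the test suite therefore
enumerates all subsets independently and compares the scan against the
subset maximum over ball-representable member sets, which it must match
exactly.

## GM(1,1) grey forecasting

Given a positive series $x_0,\dots,x_n$ ($n \ge 3$), the accumulated series
$y_t = \sum_{j\le t} x_j$ and its consecutive means
$z_t = (y_t + y_{t-1})/2$ define the grey difference equation
$x_t + \alpha z_t = \mu$, solved by least squares. The fitted accumulated
trajectory is $\hat y_t = (x_0 - \mu/\alpha)e^{-\alpha t} + \mu/\alpha$;
fitted and forecast values are its first differences. Numerical choices:

* $|\alpha| < 10^{-10}$ switches to the linear limit
  $\hat y_t = x_0 + \mu t$, so constant series are fitted and forecast
  exactly instead of dividing by zero;
* for a geometric series $x_t = a q^t$ the difference equation is satisfied
  with zero residual at $\alpha = -2(q-1)/(q+1)$, $\mu = 2a/(q+1)$ — a
  closed form the tests pin to $10^{-10}$. The *reconstructed* values are
  not the geometric series itself (the reconstruction ratio is
  $e^{-\alpha}$, not $q$): an inherent, documented property of the grey
  model, not an implementation artifact.

Validation follows the posterior-deviation scheme: residuals
$\delta_t = x_t - \hat x_t$ over $t = 0..n$ (with $\delta_0 = 0$ by
construction), $S_1$ the population standard deviation of the series, $S_2$
that of the residuals, $c = S_2/S_1$, and $p$ the fraction of residuals
within $0.6745\,S_1$ of the mean residual. Grades: *excellent* if
$p > 0.95 \wedge c < 0.35$, else *good* if $p > 0.80 \wedge c < 0.50$, else
*marginal* if $p > 0.70 \wedge c < 0.65$, else *unreliable*. The grading is
monotone in both arguments (a property test). Rate forecasts are reported to
2 decimals and admission forecasts to whole counts, mirroring the usual
presentation. The burden projection divides forecast admissions by the
district's hospital count.

## What the synthetic generator emulates — and what it does not

The generator produces the study design the chain assumes: ~10 districts
observed over 10 years; first-year populations spanning $10^5$–$10^6$
persons growing at 4%/year; admission counts Poisson around
$N_{it} \times r_i \times g^{t-t_0}$ with first-year rates $r_i$ spanning
0.3–1.5 per 1,000 person-years and a common growth factor $g = 1.08$ (so
rates roughly double over a decade, ending around 0.6–3 per 1,000); an
optional embedded cluster (district subset × contiguous years × rate
multiplier, redrawn Poisson); case points drawn isotropic-normally
(default dispersion 1,500 m) around district centroids that drift north at
150 m/year. The Poisson/log-linear form is the minimal model consistent
with the scan's discrete-Poisson assumption; the within-district isotropic
normal is an explicit assumption, since nothing constrains the
within-district distribution of real addresses. Geometry is a jittered
two-row grid spanning an elongated ~45 × 20 km city, in projected meters —
no polygons, road networks, age/sex structure, or migration covariates.
Each stochastic operation draws from its own stream derived from the master
seed by stable sub-seeding, so adding an operation never perturbs another's
draws.

Two consequences matter for interpreting green tests. First, the *default*
configuration contains genuine space-time structure (a spatial rate gradient
and a secular trend), which the scan — whose expectations are purely
population-proportional — correctly reports as clustering; calibration
experiments therefore use a homogeneous configuration (constant 1/1,000
rate, no trend), which is the scan's null, not a weakened test. Second,
passing on synthetic panels demonstrates correctness of the arithmetic and
the statistical calibration of the machinery, not that any particular real
city exhibits these effects.

## Problem sizes and runtime envelope

The suites run at the scale the method targets: 10 × 10 panels for
end-to-end runs (≈1,400 windows per scan), 999 Monte-Carlo replicates for
power/recovery experiments over 50 seeds, 199 replicates for the 200-seed
null-calibration experiment (p-values are uniform for any replicate count),
$10^5$ samples for ellipse-overlap estimates, and brute-force oracle
comparisons on every panel size up to 4 districts × 3 years. These sizes
give sub-second individual scans and tight Monte-Carlo error while keeping
the whole suite in the minutes range.

## Known limitations

* The scan supports circular bases only; elongated true clusters may be
  reported as a union of cylinders or with extra members.
* Monte-Carlo p-values have resolution $1/(R+1)$; claims below 0.001 need
  more replicates.
* GM(1,1) fits an exponential trend: series with turning points will
  validate poorly (by design, the degree grade says so), and long-horizon
  extrapolation of a fitted growth rate compounds quickly.
* Indirect standardization uses total population only; age/sex structure is
  out of scope.
* Ellipse overlap is estimated, not exact; seeds make it reproducible.
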