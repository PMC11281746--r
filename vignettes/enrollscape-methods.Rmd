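---
title: "Models and methods behind enrollscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind enrollscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`enrollscape` analyses the *enrollment potential* of a disease-management
program — the proportion of diabetics not enrolled — on lattices of small
areas. This vignette is the package's own account of its models, the
choices behind them, and what the synthetic validation does and does not
demonstrate.

## The analysis lattice

All models consume three structures built by the `spatial_structure`
functions: an `area_set` (polygons, centroids in planar km, per-area
counts), its contiguity graph, and the intrinsic CAR (ICAR) structure
matrix `Q = D - W` (the graph Laplacian).

Contiguity is defined as a shared boundary segment of *positive length*.
Two polygons touching only at a corner are not neighbours: an "edge or
border" has length, a point does not. This is the rook-style reading of
edge contiguity; on the square lattices the generator produces it coincides
with what most disease-mapping work uses. Areas with no neighbours are kept
in the lattice but can carry no structured effect — in BYM-type models they
receive only the unstructured term, the standard treatment for islands.

All geometry is planar, in km. The package never performs geodesic
computations; `centroid_distances` warns when every coordinate looks like
longitude/latitude, because feeding unprojected degrees to a km-based scan
radius is a silent unit error.

## Deprivation index

`compute_deprivation` builds a multi-domain index from five indicators:
unemployment rate (+), employed-at-residence share (−), purchasing power
(−), high-school degree share (−), no-formal-education share (+). Each
indicator is oriented so that larger = more deprived, converted to a
mid-rank percentile `(rank − 0.5)/n` (average ranks for ties), averaged
within its domain (employment: 2 indicators; income: 1; education: 2), and
the three domain scores — weighted equally — are averaged and linearly
rescaled across areas to `[1, 100]`.

Rank-percentile aggregation was chosen because only the indicator set, the
equal domain weights and the 1–100 range are fixed by the index family this
follows; ranks make the result invariant to affine transforms of any
indicator and robust to heavy-tailed indicators like purchasing power. Ties
take mid-ranks so the index is deterministic and permutation-invariant. If
every area is identical the rescaling is undefined; all areas then get the
midpoint 50.5 with a warning. The construction is isolated behind this one
function so a factor-analytic variant could be swapped in without touching
anything downstream. Note the equal weighting is at the *domain* level:
with 2+1+2 indicators per domain, the single income indicator carries more
weight than any single employment indicator.

## BYM disease mapping

Counts of unenrolled diabetics per area follow

$$O_i \sim \text{Poisson}(E_i\,\theta_i), \qquad
  \log\theta_i = \beta_0 + u_i + v_i,$$

with expected counts `E_i` from internal standardization (global rate times
the area's diabetics, so `ΣE = ΣO` exactly), `u` an ICAR field with
precision `τ_u` and a sum-to-zero constraint per connected component, and
`v_i ~ N(0, 1/τ_v)`. Both precisions carry Gamma(1, 5e-4) priors — the
conventional diffuse disease-mapping default, config-overridable; the
intercept has a Normal(0, 10²) prior.

Inference is Metropolis-within-Gibbs, with three design elements worth
recording:

* **Colored single-site updates.** The lattice is properly colored
  (greedy), and all areas of one color are updated simultaneously; since no
  two neighbours move together, the joint update is a valid product of
  single-site kernels and fully vectorises.
* **Self-adapting proposals.** Every site update is an independence MH step
  whose proposal is the Gaussian approximation at the mode of the
  (log-concave) full conditional, found by a few Newton iterations. No step
  sizes need tuning, and acceptance stays high regardless of how tight the
  conditional is.
* **Interweaving for the precisions.** After the conjugate Gamma draw, each
  precision takes one more MH step in the *non-centered* parameterisation
  (field rescaled by `√τ`), where the prior and Jacobian terms cancel and
  only the likelihood constrains `τ`. This removes the funnel that
  otherwise freezes `τ_v` when the unstructured field is near zero.

`u` is recentered to per-component zero mean each sweep, with the removed
mean absorbed into `β₀` (for a connected graph this leaves the likelihood
untouched). Convergence is monitored by split-Rhat on `β₀` and the log
precisions across chains; a fit exceeding the threshold (default 1.1) is
returned with `converged = FALSE` and a warning — flagged, never silent.
Defaults are 4 chains × 5,000 draws after 2,000 burn-in; the validation
suite uses 2 × 2,000/1,000, which on the 15×15 recovery problem already
yields Rhat < 1.01 and a truth correlation near 0.97.

### Continuous surface

The smoothed rates are interpolated from the area centroids to a regular
grid with Gaussian-process regression under a Matérn covariance with
smoothness fixed at 1 — the member of the Matérn family that the common
SPDE formulation (α = 2) corresponds to in the plane. Range and sill are
fitted by profile maximum likelihood; the nugget defaults to 1e-8 times the
data variance, so the surface interpolates the centroid values and reverts
to the fitted constant mean far from data. This is a deliberate, documented
replacement of finite-element SPDE machinery by direct GP regression: the
deliverable — a continuous, boundary-free rate surface from
point-referenced smoothed rates — is the same, without a mesh generator.
Grid default: bounding box / 200 per axis.

## Spatial scan statistic

`detect_clusters` implements the purely spatial Poisson scan for high-rate
clusters. Circular windows grow around every centroid by adding the
next-nearest centroid (ties broken by area order) up to `max_radius_km`
(default 30 km; a population-share cap is deliberately not imposed — the
radius cap replaces it, and windows swallowing the entire region carry no
information and are excluded). The window statistic is

$$\text{LLR} = O_{in}\log\frac{O_{in}}{E_{in}}
 + (O_{tot}-O_{in})\log\frac{O_{tot}-O_{in}}{E_{tot}-E_{in}}$$

when the inside rate exceeds the outside rate, else 0, with `0·log 0 = 0`.
Significance is Monte-Carlo, conditional on the observed total: each of
`n_sim` replications (default 9,999) redistributes the cases multinomially
with probabilities `E/ΣE` and records the maximum window LLR, giving
`p = (1 + #{null ≥ observed})/(1 + n_sim)`. Secondary clusters are reported
in LLR order under the strictest standard overlap rule — no shared member
areas with any better-ranked cluster — each judged against the same null
maximum distribution. The implementation is validated by exhaustive
enumeration over every (center, radius) pair on maps of up to 12 areas, by
its type-I error against the nominal 5% level, and by power against an
injected relative-risk-3 cluster.

## Global regression and DIC

`fit_global` fits the individual-level logistic model
`logit P(unenrolled) = x'β + s_area` with `s` absent, exchangeable,
ICAR-structured, or both (BYM), Normal(0, 10²) priors on `β`, and
Gamma(1, 5e-4) priors on effect precisions. Continuous covariates enter
*unstandardized* here; standardization is reserved for the SVC model, where
comparability of local coefficients across covariates is the point.
Reference categories are female, German/host-country citizenship, not
unemployed. Multicollinearity is screened with `compute_vif`
(`VIF = 1/(1−R²)` from the auxiliary regression; > 5 flags a covariate,
perfect collinearity reports `Inf`).

Inference is a Gaussian (Laplace) approximation: the posterior mode of
`(β, s)` by Newton iterations, effect precisions by EM (MAP under the
Gamma prior, with the E-step taken under the Gaussian approximation), and
posterior draws from the approximation at convergence. Two structural facts
make this fast and exact enough:

* ICAR fields are parameterised in the eigenbasis of `Q` restricted to its
  positive spectrum, which enforces the per-component sum-to-zero
  constraints exactly and turns the singular prior into a proper diagonal
  one. The same basis drives the generator's field sampler, so prior and
  simulation agree by construction.
* Because every individual belongs to exactly one area, all field blocks of
  the Hessian reduce to per-area aggregations; cost per Newton step is
  linear in the number of individuals.

The asymptotic-Gaussian character of this scheme is the same bet that
integrated nested Laplace approximations make, and it is validated the same
way any backend must be here: credible-interval coverage at the nominal
rate in replicate simulations, agreement with the ML fit for the non-spatial
model, and correct DIC ordering under structured confounding. Possible
separation (a fixed effect beyond ±10 on the logit scale) is flagged with a
warning, not an error.

Model comparison uses the classical DIC with `pD = D̄ − D(posterior mean)`
(not the half-variance variant), matching the usual report of the
Laplace-approximation school. Deviance draws are computed from the
posterior sample, so `DIC = D̄ + pD` holds identically on every fit object.

## Spatially varying coefficients

`fit_svc` extends the global model to
`logit P = Σ_k (β_k + δ_{k,j(i)}) x_{ik}` with one ICAR deviation field
`δ_k` (own precision, sum-to-zero) per varying covariate on a *coarsened*
graph built by contracting fine areas into administrative units
(`coarsen_graph`; contraction provably preserves connectivity). The
intercept varies spatially too by default — the local baseline is as
heterogeneous as any slope, and the flag `intercept_varies` exposes the
choice. Continuous covariates age, deprivation and commuter share are
z-scored (population sd, invertible via the stored scalers) so local
coefficients are comparable; binary covariates, household size and
physician density stay on their natural scales.

Per unit, the *total* coefficient `β_k + δ_{k,j}` is summarised and the
exceedance probability computed on the log scale — the fraction of
posterior draws above 0 (direction "greater", i.e. P(OR > 1)) or below 0
("less", the conventional direction for covariates with an established
protective effect such as household size). Working with total rather than
deviation-only coefficients is a deliberate choice: a map reader asks
"does this covariate raise risk *here*", not "is this place above the
global average effect". Probabilities are banded `[0, 0.6)`, `[0.6, 0.8]`,
`(0.8, 1]` for mapping; closing both boundaries into the middle band is a
package convention, stated here because prose band descriptions rarely
define their edges.

Two properties of this design matter for interpretation. First, fitting the
SVC on the same graph as a global structured model buys almost nothing in
DIC terms — the extra fields' fit gain roughly cancels their pD. The local
model's DIC penalty appears when it is used as intended: on a *coarser*
graph than the global model's, trading fine-scale resolution of the
baseline for tractable per-covariate fields. The validation suite encodes
exactly that asymmetry (global fit on the fine lattice, SVC on 2×2-block
units) and reproduces the expected ordering — the SVC explains *where*
effects differ at a goodness-of-fit price. Second, exceedance probabilities
inherit Monte-Carlo error of order `1/√draws`; with the default 200 draws
the bands are stable, but per-unit probabilities should not be read to
three decimals.

## The synthetic generator

`simulate_study` is first-class, tested code, not a fixture. It generates:

* a square lattice (default 10×10, 2 km cells) with Poisson(300)
  insurants per area, truncated at 1 — the micro-area scale of a few
  hundred households;
* spatially correlated area covariates: the five deprivation indicators
  share one latent ICAR field (so deprivation is smooth in space), while
  household size, commuting, physician density and the foreign-citizenship
  propensity ride on independent fields with indicator-specific noise;
* individuals with age ~ Normal(55, 20) truncated to [18, 100], balanced
  sex, unemployment with a logit linear in area deprivation, citizenship
  from the area propensity, and a diabetic flag with a logit linear in age
  (slope 0.055/year) whose intercept is *calibrated* so the expected
  diabetic share hits the target (default 17.3%) — so diabetics average
  about 70 years, the age structure such programs face;
* the enrollment outcome: for each diabetic,
  `P(not enrolled) = logistic(intercept + β·x_individual + γ·x_area + u + v
  + Σ δ_k x_k)`, with default coefficients equal to the published global
  regression odds ratios (male 0.938, age/year 0.997, foreign 1.058,
  unemployed 1.100, deprivation 1.000, household size 0.801, commuter %
  0.996, physician density 0.998), structured/unstructured area effects of
  sd 0.3/0.1 on the logit scale (moderate spatial confounding, enough for
  structured priors to win the DIC comparison), and an intercept calibrated to a 36.8% marginal
  unenrollment rate unless set explicitly.

Every simulated study carries its full ground truth (config, calibrated
intercepts, field draws), which is what the recovery tests compare
against.

What the generator does *not* emulate: realistic polygon shapes (all
methods downstream depend only on adjacency, centroids and counts — square
cells make exact combinatorial oracles possible), real geography or
address geocoding, household structure, insurance-switching dynamics, and
any systematic difference between the insured population and the general
population. Passing recovery tests therefore demonstrates correctness of
the estimators under the stated model, not robustness to the
misspecifications real insurance data would add.

## Problem sizes and numerical choices

The validation suite runs at deliberately desk-scale sizes chosen so each
check is statistically informative: scan oracle maps of ≤ 12 areas (where
exhaustive enumeration is exact), 200 type-I replicates at 100 areas with
999 Monte-Carlo replications, 100 coverage replicates of n = 50,000
individuals, 100 DIC-comparison replicates at 4,000 individuals, BYM
recovery on a 15×15 lattice, and SVC recovery with 100 coarse units and
50,000 individuals. Tolerances follow from the randomness involved:
binomial bands for rates, correlation thresholds (0.7 BYM, 0.5 SVC) that
sit far below observed performance (≈ 0.96 for both) but above what a
broken estimator could reach.

Other numerical conventions: `percent_change` rounds half-up to one
decimal (so 0.938 → −6.2, never −6.1999…); eigen-decompositions of ICAR
structures are exact dense decompositions (fine up to a few hundred
nodes, the regime all coarse graphs and desk-scale lattices live in);
duplicate centroids make the GP covariance singular and are rejected by id;
degenerate inputs (all-zero scan counts, identical deprivation rows,
zero-variance standardization) produce warnings or errors, never silent
numbers.

## Known limitations

* The Laplace/EM backend conditions on hyperparameters at their MAP;
  hyperparameter uncertainty is not propagated into the credible intervals.
  At the sample sizes the models are meant for (tens of thousands of
  individuals), that underestimation is negligible, but at very small n a
  full MCMC treatment would be more honest.
* The BYM sampler's per-component recentering absorbs the mean into the
  intercept only for connected graphs; on multi-component lattices the
  component means are constrained to zero without per-component
  intercepts.
* DIC is reported because it is the established comparison statistic in
  this literature; its known optimism for random-effects models applies
  here as everywhere.
* The scan statistic implements circular windows and high-rate detection
  only; elliptic windows, low-rate scans and covariate adjustment are out
  of scope.
* 2SFCA-style physician-density computation is not implemented; physician
  density is a supplied covariate.
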