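# enrollscape

Small-area Bayesian mapping and modelling of disease-management-program
(DMP) unenrollment.

Chronic-disease management programs only help the patients who are enrolled
in them. When enrollment is voluntary, the diabetics who stay outside tend
to be exactly the groups with the highest risk of secondary disease, and the
share of unenrolled diabetics — the *enrollment potential* — varies strongly
across space. `enrollscape` implements the full spatial-epidemiological
workflow for quantifying and explaining those disparities on fine-grained
area lattices (micro-areas of a few hundred households), for
health-services researchers and insurance analysts:

* **Disease mapping.** The Besag–York–Mollié (BYM) model
  `O_i ~ Poisson(E_i θ_i)`, `log θ_i = β₀ + u_i + v_i`, with an intrinsic
  CAR (Besag) field `u` on the contiguity graph and an exchangeable `v`,
  smooths unstable small-area rates toward their neighbourhood and the
  global mean (`fit_bym`). Expected counts `E_i` come from internal
  standardization (`expected_counts`). A Matérn (smoothness-1)
  Gaussian-process interpolator turns the smoothed rates into a continuous,
  boundary-free surface (`interpolate_surface`).
* **Cluster detection.** Kulldorff's purely spatial Poisson scan statistic
  over circular windows with Monte-Carlo inference conditional on the total
  count (`detect_clusters`), for prioritising intervention areas.
* **Global regression.** Individual-level Bayesian logistic regression of
  unenrollment on personal (sex, age, unemployment, citizenship) and area
  covariates (deprivation, household size, commuter share, physician
  density) with `none`/`iid`/`besag`/`bym` area effects, VIF screening,
  and DIC model comparison (`fit_global`, `compute_vif`, `compute_dic`,
  `odds_ratio_table`, `percent_change`).
* **Local regression.** A Bayesian spatially varying coefficient (SVC)
  model on a coarsened administrative graph, with per-unit exceedance
  probabilities P(OR > 1) (or < 1) banded for choropleth mapping
  (`fit_svc`, `coarsen_graph`, `exceedance`, `band_probability`).
* **Deprivation index.** A rank-percentile multi-domain area deprivation
  index (employment, income, education weighted equally) on a 1–100 scale
  (`compute_deprivation`).
* **Synthetic regions.** Because individual insurance records cannot be
  shared, `simulate_study` generates square-lattice study regions with a
  known ground truth — ≈300 insurants per area, ≈17.3% diabetic, ≈36.8%
  unenrolled, covariate odds ratios matching the published global
  regression estimates — so every model can be exercised and validated by
  parameter recovery.
* **Pipeline.** `run_pipeline` chains simulate → deprivation → map → scan →
  global-fit → svc with seeded determinism, manifest-based caching and
  GeoJSON/CSV/JSON artifacts; `inst/cli/enrollscape` is a thin command-line
  wrapper.

## Worked example

```r
library(enrollscape)

sim <- simulate_study(sim_config(10, 10, mean_insurants_per_area = 300,
                                 seed = 42))
sim
#> Synthetic study region: 100 areas, 30068 insurants
#>   diabetics: 5240 (17.4%); unenrolled among diabetics: 36.2%
#>   spatial sds (logit): structured 0.30, unstructured 0.10

E <- expected_counts(sim$areas$n_diabetics, sim$areas$n_unenrolled)
fit <- fit_bym(sim$areas$n_unenrolled, E, sim$graph,
               chains = 2, iter = 2000, burnin = 1000, seed = 1)
fit
#> BYM disease-mapping fit: 100 areas, 2 chains x 2000 draws
#>   beta0 -0.008  tau_u 176.7  tau_v 1838.7  DIC 595.2 (pD 16.2)
#>   max split-Rhat 1.007 (converged)
```

The diabetic share (17.4%) and unenrollment rate (36.2%) sit at the
generator's calibration targets; `beta0 ≈ 0` says the average relative risk
is at the null, and the precisions measure how much spatial (`tau_u`) and
unstructured (`tau_v`) variation the counts support. Scanning for clusters
and fitting the global model:

```r
D <- centroid_distances(sim$areas)
detect_clusters(sim$areas$n_unenrolled, E, D, max_radius_km = 30,
                n_sim = 999, seed = 1, area_ids = sim$areas$area_id)
#> Spatial scan: 10 non-overlapping cluster(s), 999 Monte-Carlo replications
#>  rank center_area_id radius_km n_areas observed expected relative_risk   llr p_value
#>     1           r5c1        10      45      969    860.8         1.126 12.39   0.001
#>     2           r1c8         0       1       39     25.3         1.540  3.21   0.878
#>     ...

design <- regression_design(sim)
fit_global(unenrolled ~ male + age + foreign + unemployed + deprivation +
             household_size + commuter_pct + physician_density,
           design, sim$graph, effect = "bym", seed = 1)
#> Bayesian logistic regression (area effect: bym), n = 5240
#>   DIC 6792.6 (pD 46.0)
#>               term    or ci_2.5 ci_97.5
#>        (Intercept) 2.459  1.388   4.855
#>               male 0.951  0.852   1.038
#>                age 0.997  0.993   1.000
#>     household_size 0.691  0.493   0.867
#>     ...
```

The primary scan cluster (45 areas, relative risk 1.13, p = 0.001) flags
where the structured field the generator planted raises unenrollment. The
odds ratios recover the generating coefficients (male 0.938, age/year
0.997, household size 0.801) within their credible intervals at this sample
size; `percent_change(0.801)` renders the household-size OR as `-19.9`
("19.9% lower risk per additional household member").

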