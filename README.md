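# fertimap

Small-area analysis of urban fertility inequalities: deprivation-index
construction, stratified fertility rates, Bayesian spatial smoothing, and
ecological regression of fertility on deprivation across time periods.

## The problem

Tract-level fertility rates — live births per 1000 women aged 15–49 over a
period — are noisy exactly where they are most interesting: small, often
deprived census tracts. `fertimap` implements the standard
disease-mapping answer for fertility:

- **Deprivation index** (`compute_index`): the first principal component
  of five standardized census indicators (manual work, unemployment,
  temporary work, low education, low education among the young), oriented
  so higher = more deprived, rescaled to mean 0 / sd 1, with septile
  grouping and the 5th/95th percentile contrast.
- **Stratified crude rates** (`crude_rate`, `rates_table`): per tract ×
  period × age group (15–19, 20–24, 25–34, 35–49, 15–49) × nationality
  group ("Spanish" = Spanish plus high-income-country nationals, GNI per
  capita ≥ $12,056; "LIC" otherwise).
- **BYM smoothing** (`fit_bym`, `smoothed_rates`): the Besag–York–Mollié
  model `O_i ~ Poisson(N_i exp(α + u_i + v_i))` with an intrinsic CAR
  (ICAR) spatial field `u` on the tract adjacency graph and iid
  heterogeneous effects `v`, fitted by Metropolis-within-Gibbs MCMC
  (Rcpp), with split-R̂ convergence monitoring.
- **Ecological regression** (`fit_ecoregression`, `relative_risk`,
  `run_stratified_analysis`): the three-period joint model
  `O_ip ~ Poisson(N_ip exp(α_p + (β₁+δ_p)x_i + u_ip + v_ip))`, δ₁ ≡ 0,
  reported as relative risks `RR_p = exp((β₁+δ_p)(q95−q5))` comparing the
  95th to the 5th percentile of deprivation, with period-change flags from
  the posteriors of δ₂ and δ₃−δ₂.
- **Synthetic city** (`simulate_city`): lattices of tracts with spatially
  correlated indicators, known ground-truth effects, and Poisson counts —
  the validation substrate for everything above.
- **I/O**: GAL spatial-weights files (`read_gal`/`write_gal`), counts and
  indicator CSVs, GeoJSON choropleths (`write_choropleth`), and a full
  orchestrated run (`run_pipeline`) with a reproducibility manifest.

## Worked example

```r
library(fertimap)

# a 10x10 synthetic city with known truth: RR(95th vs 5th) = 1.0, 1.5, 2.0
city <- simulate_city(n_rows = 10, n_cols = 10, seed = 2, stratified = FALSE,
                      rr_95_5 = c(1.0, 1.5, 2.0))
idx <- city$index
print(idx)
#> deprivation_index: 100 tracts; PC1 explains 99.3% of indicator variance
#>   q5 = -1.462  q95 = 1.717

fit <- fit_ecoregression(city$counts, idx, city$graph,
                         mcmc_control(n_chains = 2, n_retained = 3000,
                                      burn_in = 2000, thin = 2, seed = 9))
relative_risk(fit)
#>  period                  rr
#>      P1 1.177 (0.974-1.431)
#>      P2 1.613 (1.332-1.983)
#>      P3 2.233 (1.835-2.738)
#>   change P1->P2 significant: TRUE  | P2->P3 significant: TRUE
```

Each `rr` line is the posterior median relative risk of fertility in a
highly deprived versus a highly affluent tract for that period, with its
95% credible interval; all three intervals cover the simulation truth, and
the flags correctly detect that the gradient steepened between periods.
Smoothing one period's rates shows the shrinkage the BYM model buys on
100 small tracts:

```r
cc <- subset(city$counts, period == "P1")
cc <- cc[match(city$graph$tract_id, cc$tract_id), ]
sm <- smoothed_rates(fit_bym(bym_model(cc$births, cc$women, city$graph),
                             mcmc_control(2, 3000, 3000, 2, seed = 10)))
#> crude rate sd: 12.99, smoothed sd: 6.10   (rates per 1000 women)
```

## Analysis workflow

`analysis/` contains the numbered drivers of the full study on a
simulated city, each a thin narrative over the package functions:

1. `01_simulate_city.R` — generate the stratified city with ground truth
2. `02_deprivation_index.R` — index, septiles, choropleth
3. `03_crude_rates.R` — wide crude-rate table
4. `04_smooth_rates.R` — BYM smoothing per nationality × period
5. `05_eco_regression.R` — relative risks per stratum, compared to truth

Run them in order from the repository root (`Rscript analysis/01_...`);
outputs land under `results/`.

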