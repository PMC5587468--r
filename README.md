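# soilresp

Analysis of soil respiration (soil CO2 efflux) measured with closed dynamic
chambers in seasonal tropical forests — from raw chamber concentration
traces to annual carbon budgets.

Soil respiration returns a large share of a tropical forest's carbon uptake
to the atmosphere, but integrating it is hard: chamber networks sample
irregularly, traces need quality control, the flux responds nonlinearly to
soil moisture, rewetting of dry soil triggers transient pulses (the Birch
effect), and collar-to-collar variation is large even at 20 m spacing.
`soilresp` is for ecosystem scientists who run such chamber networks (or
want to test estimators against a realistic simulator) and implements the
full chain:

* **Flux computation** — linear and exponential regression of chamber CO2
  vs time with deadbands, the ideal-gas conversion
  `F = P·V/(R·T·A) · dC/dt`, and a screening cascade (plausible range
  0–16 µmol m⁻² s⁻¹, R² ≥ 0.97 automated / 0.90 manual, RMSE ≤ 0.2,
  between-campaign jump rule).
* **Moisture response** — robust (Tukey bisquare) fit of
  `F = a + b·swc + c·swc²` and its optimum `swc* = −b/(2c)`.
* **Rewetting pulses** — detection of dry-season pulses after rain on dry
  soil and OLS of relative flux rise on relative moisture rise.
* **Variability** — temporal/spatial coefficients of variation, anomaly
  autocorrelation `acf(τ)` with the per-campaign spatial mean removed,
  semivariogram `γ(r)` of collar temporal means, diurnal composites and
  phase lags.
* **Gap-filling and budgets** — an ensemble of feed-forward neural networks
  (10 sigmoid hidden units, 70/15/15 split, validation early stopping)
  combined with inverse-test-MSE weights,
  `f_ij = Σ_k (f_ijk/MSE_ik) / Σ_k (1/MSE_ik)`, then August–July annual
  integration (`gC = µmol m⁻² s⁻¹ × 12·10⁻⁶ × 3600 × 24 × days`).
* **Spatial ANOVA** — sequential decomposition of moisture-detrended
  residuals on topography, log basal area, gap fraction, temperature and
  their pairwise interactions.
* **Synthetic chamber network** — a calibrated generator (4 automated + 32
  manual collars, BCI-like seasonality, rain-driven soil moisture, pulses,
  dry-season diurnal cycles, lognormal site effects) with a ground-truth
  sidecar, so every stage is testable without field data.

## Worked example

Three simulated years, 12 manual collars sampled weekly, full chain:

```r
library(soilresp)

cfg    <- sim_config(seed = 1, n_manual = 12L)
env    <- generate_env(cfg)
sites  <- make_collar_sites(cfg)
latent <- generate_latent_flux(env, sites, cfg)
ed     <- env_daily(env)

## moisture response of the daily spatial-mean efflux
daily <- as.numeric(tapply(rowMeans(latent$flux), env$day_index, mean))
fit_moisture_quadratic(ed$swc, daily)
#> <moisture_response> flux = -1.417 + 27.210 swc -30.390 swc^2  (robust, n = 1156)
#>   optimum swc* = 0.4477 | R2 = 0.511 | RMSE = 0.700

## raw traces -> fluxes -> QC
traces <- synthesize_traces(latent, cfg, system = "manual")
est    <- apply_jump_filter(qc_filter(fit_fluxes(traces), "manual"))
sum(est$kept)
#> kept 1975 of 1980 flux estimates

## ensemble gap-filling (20 members/location) and annual budgets
kept   <- est[est$kept, ]
filled <- do.call(rbind, lapply(sites$site_id[sites$system == "manual"],
  function(sid) {
    ep <- ensemble_fill(feature_table(ed, kept[kept$site_id == sid, ]),
                        K = 20, seed = 1)
    data.frame(site_id = sid, day_index = ep$day_index, flux = ep$f)
  }))
integrate_annual(filled)
#> <carbon_budget> annual integrals (gC m-2 yr-1, Aug-Jul):
#>   2013: 1594 (+/- 120 SE, n = 12)
#>   2014: 1592 (+/- 120 SE, n = 12)
#>   2015: 1602 (+/- 122 SE, n = 12)
#>   seasonal daily means: dry 3.56, wet 4.77 gC m-2 d-1
```

The efflux optimum sits at ~0.45 cm³/cm³ of volumetric soil water, and the
recovered annual totals agree with the generator's calibrated budgets
(1,591/1,602/1,646 gC m⁻² yr⁻¹) to within a few percent — the gap-filling
chain neither inflates nor loses carbon.

`run_pipeline(cfg, "out/")` executes the same chain plus pulse detection,
variability statistics, diurnal composites and the spatial ANOVA, writing
every artifact (CSV/JSON) and a manifest with the resolved configuration.
A thin command-line wrapper lives at `inst/scripts/soilresp.R`.

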