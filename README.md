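# erythrosim

Individualized modeling of red blood cell production in hemodialysis
patients under erythropoiesis-stimulating agent (ESA) therapy.

Renal anemia is managed with ESAs, but the hemoglobin (Hgb) response is
delayed by weeks and varies enormously between patients, so dosing by
rule-of-thumb produces the familiar hemoglobin cycling. `erythrosim`
implements a mechanistic alternative: a five-class age-structured
population model of erythropoiesis whose patient-specific parameters are
identified from routine per-treatment Hgb measurements, and which then
forecasts Hgb under any dosing regimen.

Each erythroid class (BFU-E, CFU-E, erythroblasts, marrow reticulocytes,
circulating erythrocytes) obeys a transport equation along cell maturity
μ,

    ∂u/∂t + v(E) ∂u/∂μ = (β − α(E, μ)) u,     v(E) u(t, 0) = f(t),

chained by boundary fluxes from the stem-cell influx S₀ down to
circulating red cells, which are removed at the lifespan T_RBC.
Erythropoietin E (constant endogenous release plus first-order-eliminated
ESA boluses) prevents CFU-E apoptosis, accelerates reticulocyte release,
and — when it drops below a threshold — triggers neocytolysis of the
youngest circulating cells. Five parameters are estimated per patient by
multi-start Nelder–Mead least squares on post-dialysis Hgb: the red cell
lifespan T_RBC, endogenous EPO level E_endo, ESA half-life t_half, and
the two marrow response slopes s_α and s_v. Hemoglobin is observed
through Nadler blood volumes with the standard pre/post-dialysis volume
conversion. Fits and frozen-parameter forecasts are scored with the mean
absolute percentage error (MAPE) and parameter distributions compared by
the Kantorovich (Wasserstein-1) distance.

Because per-treatment clinical records cannot be redistributed, the
package ships a synthetic cohort generator (thrice-weekly schedules,
feedback ESA titration, Crit-Line-like measurement noise and missingness)
so the entire pipeline is reproducible and testable end to end.

## A worked example

```r
library(erythrosim)

pat <- synthesize_records(sample_patient(62), noise_cv = 0.03)
pat$profile
#> Patient profile: female, 163 cm, 53.9 kg (post-dialytic)
#>   total blood volume 3.50 l, ESA V_d 2.97 l

fit <- estimate_patient(pat$records, pat$profile,
                        estimation_config(dmu = 0.5, dmu_ery = 2))
fit
#> Parameter estimate: cost 3.814 (g/dl)^2, adaptation MAPE 1.83%, 4427 cost evaluations
#> Patient parameters:
#>   RBC lifespan        86.7 days
#>   endogenous EPO      6.07 U/l
#>   ESA half-life       18.51 h
#>   apoptosis slope     0.0006237 l/U
#>   velocity slope      0.04285
#>   stem-cell influx S0 8.773e+09 cells/day

pred <- predict_patient(pat$records, pat$profile, fit$params_hat,
                        dmu = 0.5, dmu_ery = 2)
windowed_prediction_error(pred)
#>   window_start_day window_end_day mape_median n_patients
#> 1                0             30    2.441094          1
#> 2               30             60    3.638444          1
#> 3               60             90    2.709975          1
#> 4               90            120    1.355839          1
```

The fit reads: over the 150-day adaptation window the individualized
model tracks the measured post-dialysis Hgb to ~1.8% (about the
measurement noise floor), and with parameters frozen it forecasts the
following 120 days of pre-dialysis Hgb within a few percent per 30-day
window. This virtual patient's true generating parameters were
T_RBC = 82.9 d, E_endo = 9.4 U/l, t_half = 6.2 h: the lifespan is
recovered within 5%, while half-life and slopes land on the weakly
identified directions of the cost surface — at realistic noise several
parameter combinations produce nearly identical Hgb trajectories, which
is visible here and discussed in the methods vignette.

`run_pipeline(out_dir, n_patients = 5, seed = 1)` runs
generate → fit → predict → evaluate for a whole cohort and writes
`records.csv`, `fits.json`, `evaluation.csv` and a run log.

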