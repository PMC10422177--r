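# mhdid

Quasi-experimental estimation of how mobile health and fitness app adoption
changes hospital visits, with hospital visits measured from hourly
geolocation epochs ("digital phenotyping"). The package is aimed at
health-economics and medical-informatics researchers who want a tested,
reusable implementation of the full pipeline — synthetic cohorts with known
ground truth, outcome construction from epoch streams, event-study
difference-in-differences (DD), triple-difference (DDD) and moderation
estimation — rather than a one-off analysis script.

## The design in brief

Every user in the sample adopts the same health and fitness app, but in
different months of an April–September window inside a January–December
calendar. Adopters in other months act as counterfactuals. With
`Visit_it` the monthly hours user *i* spends in hospital (only stays of at
least *k* = 2 consecutive hourly epochs count; *k* = 3, 4 and a day-count
are sensitivity variants), the dynamic DD is

    log(1 + Visit_it) = Σ_{r≠0} β_r · 1[R_it = r] + γ_i + δ_t + ε_it

with user fixed effects γ_i, month fixed effects δ_t, event time `R_it`
(months since adoption, adoption month omitted), and SEs clustered by user.
Because adoption does not imply use, the DDD adds a third difference between
adopters who used the app and adopters who installed it but never did:

    log(1 + Visit_it) = Σ β_r·1[R=r] + Σ β^u_r·1[R=r]·Used_i + θ_i + μ_{t,used} + ε_it

The `β^u_r` are immune to any adoption-timed shock that hits both subgroups
alike. Fixed effects are absorbed by a from-scratch alternating-projection
engine with CR1 cluster-robust inference, validated against explicit
dummy-variable OLS to 1e-8.

## Worked example

Simulate a cohort with injected dynamic effects (−0.058, −0.131, −0.184 at
one, two, three months after adoption, applied only to the used subgroup),
build the panel and fit the DDD:

```r
library(mhdid)

cfg    <- recovery_config(n_users = 3000, p_used = 0.3, seed = 42)
sim    <- simulate_cohort(cfg, streams = FALSE)
window <- cohort_window()
panel  <- add_ddd_terms(event_time_dummies(sim$truth, window))
fit    <- fe_fit(build_ddd(window), panel)
fit
#> Fixed-effects fit: log_outcome ~ ev_pre + ... + used_x_ev_post
#> FE: user_id + month:used_flag | cluster: user_id
#> n = 36,000 | clusters = 3,000 | R2 = 0.652 | sweeps = 2
#>
#>            term  estimate std_error   ci_low  ci_high   p_value
#>   ...
#>    used_x_ev_p1 -0.070565   0.02239 -0.11445 -0.02668 1.626e-03
#>    used_x_ev_p2 -0.146909   0.02535 -0.19659 -0.09723 6.806e-09
#>    used_x_ev_p3 -0.191089   0.02848 -0.24692 -0.13526 1.962e-11
```

The `used_x_ev_p1..3` rows are the dynamic treatment effects: estimated
reductions of about 7%, 15% and 19% in hospital-visit duration one, two and
three months after adoption, each within one standard error of the injected
truth, while the lead terms (`used_x_ev_m2`, `used_x_ev_m1`) are near zero.
A pre-trend check on the corresponding DD fit:

```r
pretrend_report(fe_fit(build_dd(window), panel), window)
#> Pre-trend assessment (joint Wald on lead terms)
#>   term   estimate std_error   ci_low ci_high p_value
#>  ev_m2  0.0002218   0.01191 -0.02313 0.02357  0.9851
#>  ev_m1 -0.0051318   0.01061 -0.02594 0.01567  0.6288
#> Wald = 0.349 on 2 df, p = 0.8401
#> Verdict: no pre-trend detected
```

The full sensitivity battery (visit rules 2/3/4, hours and days, main and
shortened adoption windows, DD + DDD + moderation) runs end to end with

```r
res <- run_all(run_config(sim = sim_config(n_users = 500), seed = 1))
```

which writes tidy coefficient CSVs, an event-study export for plotting, a
JSON-lines stage log and a reproducibility manifest. A thin command-line
wrapper lives at `inst/cli/mhdid.R`
(`Rscript inst/cli/mhdid.R run-all --users 500 --seed 1 --out out/`).

## Package layout

| Area | Contents |
| --- | --- |
| `R/synth.R` | `sim_config()`, `generate_users()`, `generate_outcomes()`, `generate_epoch_streams()`, `simulate_cohort()` |
| `R/visits.R` | `find_runs()`, `monthly_visits()`, `visit_rule()`, `exclude_multi_category()` |
| `R/panel.R` | `build_panel()`, `event_time_dummies()`, `add_ddd_terms()`, `cohort_window()` |
| `R/fe_engine.R` | `model_spec()`, `fe_demean()`, `fe_fit()`, `coef_table()` |
| `R/specs.R` | `build_dd()`, `build_ddd()`, `build_moderation()`, `moderation_panel()`, `pretrend_report()`, YAML (de)serialization |
| `R/pipeline.R` | `run_config()`, `run_all()`, `eventstudy_export()` |
| `R/validation.R` | `study_*()` / `check_*()` Monte-Carlo validation studies |
| `vignettes/mhdid-methods.Rmd` | model, assumptions, generator design, numerical choices |

See the methods vignette for the statistical background, the reasoning
behind the defaults, and known limitations.
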