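---
title: "Methods: event-study DD and triple-difference estimation of app-adoption effects on hospital visits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-study DD and triple-difference estimation of app-adoption effects on hospital visits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mobile health and fitness apps promise population-level health benefits, but
the link between adopting such an app and subsequent health-care use is
confounded: health-conscious people both adopt apps and visit hospitals
differently. `mhdid` implements a quasi-experimental pipeline for this
question built on three ingredients:

1. **A digital-phenotype outcome.** Hourly geolocation epochs carry an
   at-hospital flag; the monthly outcome is the number of hours a user spends
   in hospital, counting only stays of at least *k* consecutive epochs
   (default *k* = 2, i.e. "more than an hour"; *k* = 3, 4 and a day-count
   measure are sensitivity variants). Physicians and ride-hailing drivers are
   excluded — they frequent hospitals for reasons unrelated to their own
   health.
2. **Staggered adoption as the experiment.** Every user in the sample adopts
   the same app, but in different months of a six-month window (April to
   September on a January-December calendar). Adopters in other months serve
   as counterfactuals; the three months before and after the window allow
   leads and lags to be traced.
3. **A used / never-used third difference.** Many adopters install the app
   and never open it. Contrasting adopters who used the app with adopters
   who merely installed it removes adoption-timed confounds common to both
   subgroups, at the price of assuming those confounds do not differ between
   subgroups.

## Models

With `log(1 + Visit_it)` as the outcome, the dynamic difference-in-differences
(event-study) specification is

$$\log(1+\mathrm{Visit}_{it}) = \sum_{r \ne 0} \beta_r \, \mathbf{1}[R_{it} = r]
  + \gamma_i + \delta_t + \varepsilon_{it},$$

where $R_{it}$ is event time (months since the user's adoption month),
$\gamma_i$ are user fixed effects and $\delta_t$ calendar-month fixed
effects. The adoption month $r = 0$ is the omitted reference. The
triple-difference (DDD) specification interacts every event-time indicator
with the used flag $U_i$ and replaces $\delta_t$ with month-by-subgroup
effects:

$$\log(1+\mathrm{Visit}_{it}) = \sum_{r \ne 0} \beta_r \, \mathbf{1}[R_{it}=r]
  + \sum_{r \ne 0} \beta^{u}_r \, \mathbf{1}[R_{it}=r]\,U_i
  + \theta_{i} + \mu_{t,u} + \varepsilon_{it}.$$

Because users are nested in subgroups, user-by-subgroup fixed effects
coincide with user fixed effects. The coefficients of interest are the
$\beta^u_r$: any shock that is timed with adoption but hits both subgroups
alike loads on the base indicators and leaves them untouched
(`study_ddd_immunity()` demonstrates this to machine precision).

Moderation models regress the outcome **three months ahead** on a
post-adoption indicator, a moderator (consumption level, city tier, or the
mean-centred installed-app count as a digital-literacy proxy), and their
interaction. Reference categories are low consumption and tier 4. The main
effects of time-invariant moderators are not identified under user fixed
effects, so the default `controls_mode = "observables"` keeps the moderators
as controls with month fixed effects only; a `"user_fe"` variant drops the
main effects and keeps the interactions. Both modes exist because reported
layouts of this kind of table are ambiguous about which was used; neither is
asserted as the only correct reading.

## Event-time coding choices

* **Reference period** is the adoption month ($r=0$): reported coefficient
  tables for this design show $r \in \{-2,-1,1,2,3\}$ and no adoption-month
  row.
* **End caps.** With a 12-month calendar and a 6-month adoption window,
  event times span $-8..8$. Event times beyond the reported range are binned
  into `ev_pre` ($r \le -3$) and `ev_post` ($r \ge 4$) rather than dropped.
  Binning keeps all observations while leaving the reported coefficients
  comparable; a trimmed variant (`include_caps = FALSE` plus filtering) is
  available. Binning also breaks the exact collinearity between a fully
  saturated event-time set and the two fixed-effect dimensions that arises
  when every user is eventually treated.
* **Every row activates exactly one indicator** among the reported terms,
  the caps and the implicit reference — a tested invariant.

## The fixed-effects engine

Fixed effects are absorbed by **alternating projections** (repeatedly
subtracting cell means per dimension) rather than by dummy expansion, so the
engine scales to hundreds of thousands of users. Convergence is declared
when the largest absolute subtracted cell mean falls below `demean_tol`
(default `1e-8`; `max_sweeps = 100`). A single dimension converges in one
sweep; a balanced two-way user-month panel converges in one pass of each
dimension, reproducing the closed form
$y - \bar y_i - \bar y_t + \bar y$. Singleton-only dimensions (which would
absorb everything) and regressors constant within cells raise errors, as do
rank-deficient designs, with the offending columns named.

Inference is cluster-robust at the user level:
$\widehat V = c \,(X'X)^{-1}\left(\sum_g X_g'e_g e_g' X_g\right)(X'X)^{-1}$
with the CR1 factor $c = \frac{G}{G-1}\cdot\frac{N-1}{N-K}$ and normal
critical values (with $10^3$–$10^5$ clusters the $t$/normal distinction is
immaterial). Two conventions for $K$ are provided:

* `dof = "nested"` (default): fixed-effect dimensions **nested within the
  cluster dimension** (user effects under user clustering) are excluded from
  $K$. This is the convention of the field's high-dimensional FE estimators.
  The within transformation has already removed cluster means, and counting
  thousands of absorbed user effects inflates SEs (about 4.5% at 5,000 users
  times 12 months), pushing CI coverage visibly above nominal — the
  package's coverage study was the motivation for making this the default.
* `dof = "conventional"`: every absorbed parameter counts, with the absorbed
  rank computed exactly (levels minus connected components for the two-way
  case). This matches the textbook HC1 sandwich on the explicit dummy
  design, and is the mode in which the engine is compared against
  `sandwich::vcovCL`.

The absorbed rank uses connected-component accounting: for user and
month-by-subgroup dimensions the bipartite graph has one component per
subgroup, and the dummy-OLS oracle (`fit_dummy_ols()`, an independent
`lm()`-based path) reproduces both coefficients and SEs to $10^{-8}$ on
randomized small panels.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions the pipeline targets:

* 12 calendar months (2019), adoption uniform over April–September (the
  empirical adoption-month distribution is not published; uniform is the
  assumption).
* `p_used = 0.08`: the used subgroup is a small minority of adopters
  (≈ 21.4k of 267.7k in the motivating population).
* Consumption levels drawn 40/40/20 (low/medium/high); installed-app counts
  log-normal with mean ≈ 35.7 and SD ≈ 29.8; city tiers 15/25/30/30 (tier
  shares are not published; these are plausible for a Chinese
  mobile-user panel).
* Latent outcome $\eta_{it} = \alpha + \gamma_i + \delta_t +
  m_i \beta_{r}\,U_i + \varepsilon_{it}$ on the log(1+hours) scale, with
  defaults $\alpha = 1.5$, $\sigma_\gamma = 1$, $\sigma_\varepsilon = 0.5$, a
  mild seasonal $\delta_t$, and zero inflation 0.7 — together matching a
  heavy-tailed monthly outcome with mean near 2.2 hours and a large mass at
  zero. Hours are realized as `round(exp(eta) - 1)` clipped at zero; a
  realized single hour is promoted to two, since a measured visit spans at
  least two epochs. The injected dynamic effects default to the ramp
  −0.058, −0.131, −0.184 for $r = 1..3$, held at the three-month level
  thereafter (a plateau: the moderation models read the outcome three months
  ahead, so effects must persist beyond $r=3$ for that design to have an
  estimand).
* Pre-trend effects, when injected, apply to **all** adopters — an
  adoption-timed confound shared by both subgroups, which makes the DD
  leads significant while the DDD stays clean, the scenario the third
  difference exists for.
* Monthly hours are realized as hourly runs drawn from `run_length_mix`
  (default lengths 2–6) placed at random non-overlapping positions with a
  one-hour gap so runs are maximal; a singleton-only mix deliberately
  produces streams whose qualifying total under the 2-epoch rule is zero.
  Physicians and drivers get 40 extra at-hospital hours per month injected
  so the exclusion rule has observable consequences.

Not emulated: realistic human mobility beyond hospital presence, app-use
intensity dynamics after adoption, within-month serial correlation of
visits, and any dependence of zero inflation on treatment. Passing tests
therefore certify the estimation machinery, not the behavioural realism of
the data.

## Validation-study designs

The validation studies (`study_*`, `check_*`) fix their own conditions:

* **Recovery design** (`recovery_config()`): zero inflation off, moderator
  multipliers off, baseline log-hours 3.5, $\sigma_\gamma = 0.5$,
  $\sigma_\varepsilon = 0.4$. A parameter-recovery study must hold the
  estimand equal to the injected parameter; zero inflation would attenuate
  every coefficient by the non-zero share, and at a baseline of ~33 hours
  the integer rounding of hours changes the population coefficient by less
  than $10^{-4}$ (checked by direct numerical integration). DDD recovery
  runs 200 replications of 5,000 users at `p_used = 0.3`; null calibration
  500 replications; pre-trend power 20,000 users (a −0.02 lead is then a
  ≈4σ signal for the joint Wald test).
* **Moderation-ordering design**: all adopters active (`p_used = 1`, the
  moderation models do not use the subgroup split), consumption multipliers
  0.5/1.0/1.5, 3,000 users. The cohort size was set by a power analysis of
  the Post×High vs Post×Medium comparison (~2.5σ margin); a first draft
  used 1,200 users, which left the ordering probability near the knife
  edge.
* **Visit-rule check**: 1,000 random sparse streams over a two-month span,
  compared hour-for-hour against a deliberately naive loop-based scan, plus
  monotonicity in *k* and the *k* = 1 = raw-hours identity.
* **Round trip**: with runs ≥ 2 epochs the monthly reconstruction equals
  the latent truth exactly — integers in, integers out, no tolerance.

Sizes were chosen so the whole battery runs in minutes on one core while
keeping Monte-Carlo noise well inside the assertion margins (e.g. the
recovery bias threshold of 0.005 is ≈3.5 MC standard errors at 200
replications).

## Numerical and degenerate-input choices

* Months are `"YYYY-MM"` strings on an explicit grid; event time is a plain
  integer difference of grid positions. Out-of-grid months error rather
  than coerce.
* Epoch streams are sparse (rows only for at-hospital hours); duplicate
  (user, hour) records and off-grid timestamps are data errors. Runs are
  split at month boundaries before thresholding, so monthly totals are
  locally computable and the monthly cap invariant holds.
* `log(1 + hours)` keeps the zero mass finite and makes small coefficients
  read as percentage changes.
* Empty subgroups, all-multi-category cohorts, horizons exceeding the
  window, over-capacity monthly targets, fewer than two clusters, and
  non-convergent demeaning all raise early, named errors.
* The one-sided promotion of a single realized hour to two is the only
  place the generator touches realized hours; it reflects the measurement
  rule (a visit is at least two epochs), and the round-trip test depends on
  it.

## Limitations

* Plain two-way FE event studies can mix heterogeneous cohort effects under
  staggered adoption; heterogeneity-robust estimators
  (Callaway–Sant'Anna, Sun–Abraham) are out of scope and would slot in as
  alternative `model_spec` builders.
* The DDD identifies the effect of *use* under the assumption that
  installed-but-never-used adopters differ only in use; spillovers from
  users to non-users would attenuate estimates toward zero.
* The absorbed-rank formula beyond two FE dimensions uses the standard
  connected-design convention (levels − 1 per extra dimension) rather than
  exact rank; all shipped specifications use at most two dimensions.
* The moderation models take consumption level as a given attribute; the
  upstream consumption-prediction model that would produce it on real data
  is out of scope.
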