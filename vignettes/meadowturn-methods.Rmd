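---
title: "Methods: turnover statistics, trait null models, and transition models in meadowturn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turnover statistics, trait null models, and transition models in meadowturn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meadowturn)
```

# The problem

Repeatedly surveyed plant communities often look stable when summarised by
species richness or community-mean indicator values, while the identities
of the species present change substantially between surveys. Distinguishing
real ecological turnover from observation error, and asking *which* species
come and go relative to random expectation, is the purpose of this package.
The motivating setting is presence/absence monitoring of mountain grassland
plots: small permanent plots revisited once per multi-year period, species
scored by indicator values (ordinal 1–5 scales for temperature, soil
moisture, nutrients and light, in the Landolt convention), and sites spread
along gradients of temperature, precipitation, atmospheric nitrogen
deposition and land-use intensity (proxied by inclination).

# Turnover statistics

For two surveys with species sets $A$ and $B$, the species exchange ratio
(SER) is

$$\mathrm{SER} = \frac{|A \setminus B| + |B \setminus A|}{|A \cup B|},$$

the proportion of species that differ between the two time points.

**The denominator is the union richness.** This is the species-exchange-
ratio convention; the main alternative (the mean of the two richnesses)
yields systematically larger values, so results computed with other
software may not be directly comparable. `ser()` reports gains, losses,
union richness and the ratio; `temporal_turnover()` applies it to every
consecutive transition at every site.

*Pseudo-turnover* is the same statistic computed between two same-year
surveys of one site by different surveyors (`pseudo_turnover()`). It is an
observation-error baseline: if each present species is detected
independently with probability $p$ by each surveyor, the expected SER
between the two surveys is

$$\mathrm{E[SER]} \approx \frac{2p(1-p)}{1-(1-p)^2} = \frac{2(1-p)}{2-p},$$

which is 29% at $p = 0.83$. This closed form is tested against direct
Monte-Carlo simulation of the thinning process.

`turnover_model()` fits a binomial GLMM on the aggregated counts: the
number of differing species out of the union richness, with a transition
indicator, the union richness per 10 species, the four z-standardized
gradients, and a site random intercept. Aggregated-count and per-species
Bernoulli representations of this model are equivalent, and the test suite
asserts that equivalence numerically.

# Biodiversity endpoints and trends

The community mean (CM) of an indicator dimension is the arithmetic mean of
the values of the recorded species, excluding species with a missing value
on that dimension (`community_mean()`, `endpoint_series()`).

`trend_model()` estimates the linear temporal trend of an endpoint with a
random-intercept random-slope model,
$y_{ij} = a_i + b_i t_{ij} + \varepsilon_{ij}$, with site-level intercepts
and slopes from a correlated bivariate normal. Time is the calendar
midpoint year of each period (defaults 2005, 2010, 2015), centred on the
first and divided by 10, so trends read as change per decade. CMs use
identity link and normal errors (REML); richness uses a log-link Poisson
model (ML).

Two numerical choices matter here:

* **t-based inference with between-site degrees of freedom.** With three
  time points per site, the population slope is effectively estimated from
  the site-level slopes, so intervals and tail probabilities use a t
  reference with `n_sites - 2` degrees of freedom. Normal quantiles are
  anticonservative in this design (about 86–89% empirical coverage of a
  nominal 90% band in our calibration simulations; the t correction
  restores it).
* **Degenerate-fit fallbacks.** On noise-free or variance-degenerate data
  the random-slope fit can fail or return an undefined standard error; the
  model then falls back to a random-intercept-only fit and finally to an
  ordinary regression, and the fallback actually used is recorded in the
  result's `backend` attribute.

# The standardized-CM null model

For each site with three surveys, the *total community* is the union of all
species ever recorded there. The *colonized* set contains species absent at
one survey and present at the next; the *disappeared* set the reverse; both
pool the two transitions, so a flickering species can be in both sets
(`focal_sets()`).

For a focal set of $k$ species and an indicator dimension,
`standardized_cm()` draws 1,000 uniform without-replacement subsets of size
$k$ from the total community and reports

$$\text{standardized-CM} = \mathrm{CM}(\text{focal}) -
  \overline{\mathrm{CM}(\text{random subsets})}.$$

Values below zero mean the focal species carry lower indicator values than
a random draw from the site's own pool.

Design choices:

* **Draws include the focal species** — they are part of the total
  community. Excluding them (`include_focal = FALSE`) is available but not
  the default.
* **Missing values** are excluded from both the focal CM and the draws for
  that dimension.
* **Seeding** uses one master seed spawning a substream per (site,
  direction, dimension), so results do not depend on the order in which
  sites are processed.
* Because the expected CM of a uniform without-replacement sample equals
  the pool mean, the Monte-Carlo `null_mean` must converge on the pool
  mean; the test suite checks this, and additionally checks the null mean
  against exhaustive enumeration of all subsets for small pools.

`gradient_regression()` then regresses the per-site standardized-CMs on
their paired gradient (temperature↔mean annual temperature,
moisture↔precipitation, nutrients↔N deposition, light↔inclination) with an
ordinary linear model. The gradient is centred at a reference point — 10 kg
N ha⁻¹ yr⁻¹ for deposition, the sample mean otherwise — and scaled by its
SD. The intercept is the expected deviation from random at the reference
("difference from random"); the slope is the change per gradient SD
("change along gradient"). The reference and SD are part of the output, so
coefficients can be rescaled to natural units.

**A calibration subtlety.** Under trait-neutral dynamics the standardized-
CM has expectation zero. But testing this by averaging across sites and
comparing to $2\,\mathrm{SE}$ (with $\mathrm{SE} = s/\sqrt{n}$) is only
valid when sites are independent. If species differ in their
(trait-independent) colonization or survival propensities, the same
species dominate the focal sets at many sites, site statistics become
positively correlated through shared species identities, and the
across-site SE understates the uncertainty of the mean. The package's
neutral-calibration test therefore switches off species-level
heterogeneity as well as trait effects; in that regime each focal set is an
exactly uniform subset of its site pool and the check is exact. On real
data the same caveat applies to any "average standardized-CM across sites"
summary — the gradient regressions, whose residuals absorb the shared
component, are the more robust summary.

# Colonization and local survival along the deposition gradient

`build_transitions()` turns the survey table into per-(species, site,
transition) observations. Survival rows are species present at the start of
a transition; colonization rows are species from the candidate pool absent
at the start. The outcome is presence at the next survey. Deposition is
interpolated linearly between the site's 2000 and 2015 values to the
transition midpoint year (2007.5, 2012.5); fixed-year variants are
available.

**Candidate pool.** The default pool for colonization is the site's total
community — species ever recorded at that site. This matches the null
model's pool concept and yields colonization probabilities on the scale
observed in such monitoring data; a regional-pool variant (every species in
the dataset) is a switch. The regional pool is the right choice when the
analysis must match a generative process in which any species can arrive
(the parameter-recovery tests use it); the site pool is the right
descriptive choice for real data, where most of the regional pool is never
available to a given site.

`fit_process()` fits

$$\mathrm{logit}\,P(\text{outcome}) = b_0 + b_1 N + b_2 V + b_3 N V +
  u_{\text{species}} + v_{\text{site}},$$

with $N$ centred at its sample mean and $V$ (the nutrient value) centred at
3, the midpoint separating oligotrophic ($V < 3$) from eutrophic ($V > 3$)
species. Centring is for numerical stability only; the centring constants
travel with the fit.

The *crossover deposition rate* is the $N$ at which $V$ stops mattering,
$b_2 + b_3 N_c = 0$, mapped back to the natural scale. At this deposition
rate the fitted oligotrophic and eutrophic probability curves intersect.
`crossover()` propagates uncertainty by drawing fixed-effect vectors from
their estimated multivariate normal and taking the 5%/50%/95% quantiles of
the draw-wise ratio; draws with a numerically zero interaction are dropped
and their fraction reported, and the estimate is flagged unstable when the
interaction's 90% interval includes zero (and reported as undefined when
more than half the draws are degenerate). The test suite cross-checks the
ratio against a brute-force grid search for the intersection of the two
group curves.

# Period-wise richness regressions

`fit_period_glm()` fits, separately per survey period, a log-link Poisson
GLM of species richness (oligotrophic, i.e. nutrient value < 3, by
default; total richness optionally) across sites. The default covariate
set is N deposition, elevation, precipitation, inclination, and the
site-period CMs of moisture and light; a four-gradient variant (deposition,
temperature, precipitation, inclination) is a switch, since both covariate
conventions are in circulation for this analysis. Predictors are
z-standardized; the deposition effect is reported per SD with the SD
attached, and a condition-number warning flags collinear designs.
`effect_trend()` regresses the per-period deposition effects on the period
index — the "is the spatial deposition signal steepening over time"
question.

Total richness is not the sum of the oligotrophic and eutrophic fits
except in expectation; the package deliberately does not equate them.

# The synthetic survey generator

`generate()` produces datasets with the statistical structure the analysis
assumes, plus ground truth for recovery tests:

1. **Sites.** Elevation is the leading axis (mean 1,250 m, SD 450 m);
   temperature and deposition load on it negatively (loadings −0.85 and
   −0.63) with residual SDs chosen to preserve the configured totals:
   temperature 5.85 ± 2.16 °C, precipitation 1,284.71 ± 196.53 mm,
   deposition in 2000 17.54 ± 6.47 kg N ha⁻¹ yr⁻¹, inclination
   15.87 ± 9.66°. Deposition declines by −2.70 ± 1.74 kg between 2000 and
   2015, with slightly larger decreases where deposition was high.
2. **Species.** A pool of 623 species with independent ordinal traits on
   the four dimensions (a correlation knob exists but defaults to off) and
   2% missing values per dimension (never all four missing).
3. **Initial occupancy.** A logistic niche model: baseline occupancy 0.062
   on the logit scale, plus 0.3 × (gradient z-score × centred trait value)
   for each of the four trait–gradient pairs, plus a species effect and a
   site effect. The occupancy species effect is independent of the
   transition models' species effect: tying them together would make
   transition candidacy informative about the random effect the fitted
   GLMM assumes to be exchangeable.
4. **Dynamics.** Present species persist, absent species colonize, with
   logistic probabilities in the same form the analysis fits (natural-scale
   deposition at the transition midpoint, nutrient value centred at 3,
   shared species and site random intercepts, SDs 0.8 and 0.3). Defaults:
   survival $x_0 = 2.6$, $x_V = -0.253$, $x_{NV} = 0.02$; colonization
   $x_0 = -5.2$, $x_N = -0.005$, $x_V = -0.366$, $x_{NV} = 0.03$. The
   implied crossovers, $-x_V/x_{NV}$, are 12.65 (survival) and 12.2
   (colonization) kg N ha⁻¹ yr⁻¹.
5. **Detection.** Each present species is observed with probability 0.83,
   independently per survey; replicate surveys (14 site-periods by
   default) are independent thinnings of the same latent state. False
   positives are not generated: pseudo-turnover is attributed to oversight,
   not invention.

The intercepts and detection probability are calibrations, not estimates:
detection 0.83 makes expected pseudo-turnover $2(1-p)/(2-p) \approx 29\%$;
the transition intercepts make richness stationary across periods at about
46–49 species per survey with temporal SER near 35–39%. Under the default
configuration and seed 42 the realised per-period mean richness is
48.4/47.8/47.7 and the two transition SERs are 37.6% and 39.1%.

What the generator does **not** emulate: spatial autocorrelation of
gradients or communities, dispersal limitation, abundance (and therefore
abundance-dependent detection), false-positive records, within-period
survey-year jitter, and trait correlations (by default). Passing tests on
synthetic data therefore validate the estimators under the stated
generative assumptions — they do not certify that real survey data meet
those assumptions.

# Estimation backend

All mixed models are fitted by maximum likelihood with `glmmTMB` (REML for
gaussian trend models); intervals are 90% normal-approximation (or t, where
stated) Wald intervals, and `prob_positive` is the corresponding tail
probability $\Phi(\hat\beta/\mathrm{SE})$. This is the package's
"posterior-like" contract: any backend delivering an estimate, 5%/95%
quantiles and a tail probability could be substituted, and every result
records which backend produced it in a `backend` attribute/column, so
downstream consumers can tell fits apart.

# Problem sizes used by the test suite

The suite validates the null-model machinery by exhaustive enumeration on
pools of up to 12 species, the neutral calibration on 200 fully neutral
sites, parameter recovery on 50 replicates of 100 sites × 200 species, and
trend calibration on 100 replicates of 40-site series; these sizes were
chosen so each check has adequate power while the whole suite stays quick
to run. The pipeline itself is routinely exercised at the default scale
(129 sites, 623-species pool).

# Known limitations

* Detection error is ignored by the *estimators* (as in the motivating
  analyses); only the generator models it. Colonization and survival are
  therefore apparent rates, biased by detection ~0.83 relative to latent
  rates.
* The crossover is a ratio estimate; when the interaction is weak its
  draw-wise distribution is heavy-tailed, and the unstable flag should be
  taken seriously.
* The standardized-CM's across-site mean is correlated across sites
  whenever species differ systematically in turnover propensity (see
  above); gradient regressions are the more robust summary.
* Ordinal indicator values are averaged as if interval-scaled — standard
  practice for community means of Landolt/Ellenberg values, but a known
  approximation.
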