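# meadowturn

Species turnover and trait-based null models for repeatedly surveyed plant
communities.

Presence/absence monitoring of permanent vegetation plots often shows
*apparent stability* — species richness and community-mean indicator values
barely move — while the identity of the species present changes
substantially between surveys. `meadowturn` provides the statistical
toolkit for that situation, built around four questions:

1. **How much turnover is there, and how much of it is observation error?**
   The species exchange ratio between surveys $A$ and $B$,

   $$\mathrm{SER} = \frac{|A\setminus B| + |B\setminus A|}{|A\cup B|},$$

   and its observation-error baseline, *pseudo-turnover*: the same ratio
   between two same-year surveys of one site by different surveyors. A
   binomial GLMM relates turnover to survey period, richness, and
   environmental gradients.
2. **Are the species that come and go a random sample of the site's pool?**
   The *standardized-CM*: the community mean (CM) of an ordinal indicator
   value (Landolt 1–5 scales: temperature, soil moisture, nutrients,
   light) over the colonizing (or disappearing) species, minus the mean CM
   of 1,000 equal-size random subsets of the site's total community.
   Linear models then track this deviation along paired environmental
   gradients (nutrients ↔ nitrogen deposition, etc.).
3. **Do colonization and local survival depend on nitrogen deposition?**
   Logistic mixed models per (species, site, transition),

   $$\mathrm{logit}\,P = b_0 + b_1 N + b_2 V + b_3 NV + u_{sp} + v_{site},$$

   with $N$ the site's N deposition and $V$ the species' nutrient value;
   the *crossover deposition rate* $-b_2/b_3$ is the deposition at which
   oligotrophic ($V<3$) and eutrophic ($V>3$) species have equal predicted
   probability — an empirical counterpart to a critical load.
4. **Is the spatial deposition–richness relationship changing over time?**
   Period-wise Poisson GLMs of oligotrophic species richness on deposition
   plus site covariates, and the trend of that effect across periods.

A synthetic survey generator (`generate()`) with trait-dependent dynamics,
correlated gradients, and imperfect detection provides ground truth for
calibration and parameter-recovery testing, and a pipeline driver
(`run_all()`, `scripts/run_pipeline.R`) runs every stage from one config
with full seed reproducibility.

The package is aimed at ecologists analysing repeat-survey community data
(biodiversity monitoring schemes, resurvey studies) and at methodologists
who need a tested reference implementation of turnover null models.

## Worked example

```r
library(meadowturn)

sim <- generate(synthetic_config(seed = 1))   # 129 sites, 3 surveys each

turnover_summary(temporal_turnover(sim$survey))
#> # A tibble: 2 × 4
#>   transition n_sites mean_ser sd_ser
#> 1 1->2           129    0.389 0.0702
#> 2 2->3           129    0.384 0.0699

pt <- pseudo_turnover(sim$survey)
round(100 * mean(pt$ser), 1)
#> [1] 26.9
```

About 38–39% of species differ between consecutive surveys at a site,
while two surveyors visiting the *same* site in the same year already
disagree on 27% — so a substantial share of raw turnover is observation
error, which is why the null-model comparisons below are made against the
site's own pool rather than against zero.

```r
cm  <- standardized_cm_table(sim$survey, sim$indicators,
                             n_draws = 1000, seed = 1)
reg <- gradient_regression(cm, sim$covariates, ndep_reference = 10)
subset(as.data.frame(reg), dimension == "nutrients",
       c(direction, diff_estimate, diff_q05, diff_q95, slope_estimate))
#>     direction diff_estimate diff_q05 diff_q95 slope_estimate
#> 1   colonized         0.094    0.045    0.144         -0.041
#> 2 disappeared         0.035   -0.014    0.084         -0.031
```

`diff_estimate` is the deviation of colonizing (or disappearing) species
from random draws at the reference deposition of 10 kg N ha⁻¹ yr⁻¹;
`slope_estimate` is its change per SD of deposition. In this simulation
colonizers carry slightly *higher* nutrient values than random draws from
their site pool: the generator's niche sorting makes low-deposition site
pools oligotrophic-enriched, while colonization is only weakly
trait-biased — a reminder that the statistic measures deviation from the
*site's own* pool, not from the regional flora.

```r
rows <- build_transitions(sim$survey, sim$covariates, sim$indicators,
                          "survival")
crossover(fit_process(rows, "survival"), seed = 1)
#>    process n_star   q05   q95 frac_degenerate unstable
#> 1 survival  17.14 12.08 24.67               0    FALSE
```

The fitted survival curves of oligotrophic and eutrophic species intersect
at 17.1 kg N ha⁻¹ yr⁻¹ (90% interval 12.1–24.7; the generating value
implied by the simulation's coefficients is 12.65): below that deposition
rate, species of nutrient-poor soils persist at least as well as
eutrophic species.

The same analyses run from files via `read_dataset()` (CSV/TSV; column
contracts in `?read_dataset`) or end to end:

```sh
Rscript scripts/run_pipeline.R --outdir out --seed 1
```

which writes per-stage TSVs (`turnover.tsv`, `trends.tsv`,
`standardized_cm.tsv`, `gradient_regression.tsv`, `fit_survival.tsv`,
`crossover.tsv`, `period_effects.tsv`, ...) and a `manifest.json`
recording seed, config hash and row counts. Reruns with the same config
and seed are byte-identical.

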