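# survmbma

Model-based meta-analysis (MBMA) of aggregate overall-survival curves, built
around the comparison of the three first-line **non-platinum chemotherapy
regimens** for advanced non-small cell lung cancer: gemcitabine +
vinorelbine (GV), gemcitabine + docetaxel (GD), and gemcitabine alone (G).
It is written for meta-analysts and pharmacometricians who have study-level
data only — survival probabilities digitized from published Kaplan–Meier
figures, plus per-arm response and toxicity counts — and who want a single
parametric model across trials rather than a pairwise meta-analysis.

## The model

Each treatment arm *i* contributes observations of overall survival
S(t) at months t. Three parametric proportional-hazard shapes are supported:

    constant   h(t) = β₀
    Gompertz   h(t) = β₀ e^(β₁ t)
    Weibull    h(t) = β₀ e^(β₁ ln t)

with Λ(t₀, t) = ∫ h(u) du and S(t) = e^(−Λ(0, t)). The arm-level baseline
hazard carries continuous covariates (centred at the dataset medians) and a
log-normal inter-study random effect:

    βᵢ = β_typical · exp( Σ (COVᵢ − COV_median)·θ_COV + ηᵢ ),   ηᵢ ~ N(0, ω²)

and each digitized point is observed with additive error weighted by its
standard error:

    Obsᵢⱼ = S(tⱼ; βᵢ) + SEᵢⱼ · σ_ε · zᵢⱼ,   zᵢⱼ ~ N(0, 1).

Estimation maximises the marginal likelihood with the random effect
integrated out by a **Laplace approximation** at the per-arm empirical-Bayes
mode (an adaptive Gauss–Hermite quadrature mode exists as a testing oracle).
Covariates are screened **stepwise** on objective-function-value (OFV = −2
log L) drops: forward inclusion at 3.84 (χ², α = 0.05, df = 1), backward
deletion at 6.63 (α = 0.01). Downstream, per-arm hazards are
covariate-corrected (divided by their covariate multiplier), pooled by
regimen with DerSimonian–Laird random-effects weights on the log scale, and
survival summaries (median survival time; 12/24/36-month survival) with 95%
intervals come from Monte Carlo draws of the parameter vector. Response and
grade 3–4 adverse-event proportions are pooled per regimen by single-arm
random-effects meta-analysis (logit transform, DL heterogeneity). Because
the underlying digitized study curves are not redistributable, the package
ships a synthetic-data generator that reproduces the assumed data structure
(17 studies / 20 arms, baseline covariate ranges, hazard and error model)
for recovery and calibration testing.

## Worked example

```r
library(survmbma)

# simulate a 17-study / 20-arm literature base from the assumed model
g <- generate_survival_dataset(generator_config(), seed = 42)
g$dataset
#> <mbma_dataset> 17 studies / 20 arms / 455 curve points

# fit the constant-hazard mixed-effects meta-model with age and PS2
fit <- fit_model(g$dataset,
                 covariate_terms = c("age_median", "ps2_pct"),
                 cov_refs = c(age_median = 72.5, ps2_pct = 14))
fit
#> <mbma_fit> family=constant  arms=20  obs=455  OFV=-1725.799
#>                       Value (RSE%)           95% CI
#> beta0                  0.113 (6.3)     0.0995-0.127
#> theta_age_median     0.0321 (24.8)    0.0165-0.0478
#> theta_ps2_pct    -0.000181 (796.5) -0.00301-0.00265
#> omega                0.0986 (17.3)     0.0652-0.132
#> sigma_eps              0.834 (3.4)      0.778-0.889
#> centred at: age_median=72.5, ps2_pct=14
```

The generating truth here was β₀ = 0.098, θ_age = 0.017, θ_PS2 = 0.004,
ω = 0.146, σ_ε = 0.822; one 20-arm replicate estimates β₀ within ~15% and
the covariate coefficients with the large relative standard errors such a
design implies. With the published final-model estimates and no parameter
uncertainty, the subgroup simulation collapses to the analytic curve:

```r
final <- population_params()   # β₀ = 0.098, θ_age = 0.017, θ_PS2 = 0.004
simulate_typical_os(final, scenario = list(age_median = 80, ps2_pct = 14),
                    n_draws = 10000, seed = 1)
#>     label  MST (months) 12-month survival (%) 24-month survival (%) 36-month survival (%)
#>  scenario 6.2 (6.2-6.2)      26.3 (26.3-26.3)         6.9 (6.9-6.9)         1.8 (1.8-1.8)
```

i.e. an 80-year-old cohort with 14% PS2 has a median survival of 6.2 months
and 6.9% two-year survival under the final model.

## The analysis workflow

The numbered drivers under `analysis/` run the full pipeline over a
synthetic literature base, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # arms/curves/counts CSVs + truth
Rscript analysis/02_fit_base.R          # hazard-family comparison
Rscript analysis/03_select_covariates.R # stepwise screening + final model
Rscript analysis/04_evaluate.R          # GOF, VPC, leave-one-out
Rscript analysis/05_subgroups.R         # age/PS subgroup + regimen tables
Rscript analysis/06_proportion_meta.R   # ORR and AE pooled percentages
```

Each stage reads the previous stage's files, so they can be re-run
individually; every stochastic stage takes an optional seed argument.

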