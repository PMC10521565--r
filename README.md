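# cheineq: income-related inequality in catastrophic health expenditure

`cheineq` measures and decomposes income-related inequality in catastrophic
health expenditure (CHE) from household panel surveys. It is written for
health economists and epidemiologists who work with survey data of the
CHARLS type — balanced household panels with head-of-household covariates,
income, food/non-food expenditure and out-of-pocket (OOP) health spending —
and who want the standard concentration-index toolkit as tested, reusable
code rather than ad-hoc scripts.

## The model

A household *h* incurs CHE when its out-of-pocket health spending reaches
40% of its capacity to pay (CTP, here non-food expenditure):

    CHE_h = 1  if  OOP_h / CTP_h >= 0.40,   else 0

Income-related inequality in CHE is summarised by the concentration index

    C = (2 / mu) * cov(Y_i, R_i)

where *Y* is the CHE flag, *mu* its mean, and *R* the weighted fractional
income rank (midpoint convention, mean exactly 0.5). *C* < 0 means CHE is
concentrated among the poor; the concentration curve (cumulative CHE share
against cumulative population share, poorest first) then lies above the
diagonal, and 1 − 2·(area under the curve) = C.

The index is decomposed through a probit model of the CHE flag on its
determinants. With average marginal effects *b_j*, covariate means *x̄_j*
and per-covariate concentration indices *C_j*,

    C = Σ_j (b_j * x̄_j / mu) * C_j  +  residual

so each determinant contributes its elasticity times its own
income-relatedness. Robustness stages: pooled logistic regression odds
ratios for the CHE determinants (wave fixed effects), and quantile
(pinball-loss) regression of household income on the CHE flag at
τ = 0.25/0.50/0.75.

A seeded synthetic-panel generator emulates the survey structure (2,575
households × 3 waves, covariate prevalences from the survey's baseline
table, log-normal income, OOP as a gamma share of CTP with a configurable
income gradient), so the entire pipeline is testable without restricted
microdata.

## Worked example

```r
library(cheineq)

cfg   <- panel_config(n_households = 2575, seed = 20130601)
panel <- generate_panel(cfg)

che_incidence(panel)
#> CHE incidence by wave
#>  wave    n n_che n_excluded incidence ci_low ci_high
#>  2013 2575   647          0    0.2513 0.2345  0.2680
#>  2015 2575   583          0    0.2264 0.2102  0.2426
#>  2018 2575   627          0    0.2435 0.2269  0.2601

w13  <- panel[panel$wave == 2013, ]
flag <- flag_che(w13)
concentration_index(flag, income = w13$income)
#> Concentration index: -0.1358  (SE 0.0195, 95% CI -0.1740, -0.0977; analytic)
#>   n = 2575, outcome mean = 0.2513

d <- decompose_cindex(w13)
round(d$group_totals, 2)
#> economic_status             age
#>           95.94           -1.58
```

Roughly a quarter of households cross the 40% threshold each wave. The
negative index says CHE falls disproportionately on poorer households; its
magnitude (≈ −0.14) is driven by the generator's income gradient in the OOP
share. In the decomposition, the economic-status quintile dummies absorb
essentially all of that income-relatedness (≈ 96% of C here), as expected
when income itself is the generating channel; the age contribution is small
because in this synthetic panel age raises OOP independently of income.

`run_pipeline(run_config(...))` chains every stage — incidence, index,
curves, decomposition, heterogeneity strata (age ≥ 65, chronic disease,
education; ranks recomputed within stratum), logistic and quantile
robustness — and `render_tables()` writes the delimited-text/JSON tables. A
thin command-line wrapper is installed at `inst/cli/che-pipeline.R`.

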