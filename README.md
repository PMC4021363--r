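# rrrstab

Stability analysis of reduced rank regression (RRR) dietary patterns across
repeated dietary surveys.

## What problem this solves

Nutritional epidemiology increasingly summarises diet as *patterns* rather
than single nutrients. RRR derives patterns that are, by construction,
relevant to disease: it finds linear combinations of food-group intakes
(g/day) that maximise the explained variation in a set of intermediate risk
factors — here six cardiovascular markers (BMI, systolic/diastolic blood
pressure, total and HDL cholesterol, uric acid). Before such a pattern can
anchor a diet–disease analysis with a single baseline measurement, one must
ask whether it is *stable*: do the same weights, or freshly re-estimated
ones, rank the same people similarly years later?

`rrrstab` implements that whole workflow for two measurement waves:

* **RRR core** — pattern extraction via the eigendecomposition of the OLS
  fitted-response covariance; z-scored participant scores; per-factor,
  per-response explained-variation tables; high-weight flagging
  (|w| > 0.10) and automatic pattern labels ("(low in) …").
* **Food-group screening** — backwards elimination of foods against each
  risk factor with a cross-wave retention rule (significant for ≥ 3
  responses in either wave).
* **Pattern-count selection** — Monte-Carlo cross-validated PRESS with Van
  der Voet's paired sign-flip randomization test; the "no predictive
  pattern" outcome (k = 0) is first-class.
* **Stability assessment** — exploratory scores per wave, confirmatory
  (fixed-weight) scores in both directions, sign alignment, and the full
  Pearson correlation matrix with Fisher-z confidence intervals, plus
  food-level cross-wave Spearman descriptives for skewed, zero-inflated
  intakes.
* **Synthetic two-wave cohorts** — a generator with known latent patterns
  (skewed zero-inflated intake marginals, calibrated risk-factor
  distributions, per-pattern cross-wave tracking), giving every stage a
  ground truth.

In the standard formulation: with standardized intakes $X$ and standardized
responses $Y$, factor weights $a_k$ solve the generalized eigenproblem
$S_{xy}S_{yx}a = \mu S_{xx}a$; scores are $t_k = Xa_k$ scaled to SD 1, and
the explained variation of factor $k$ in response $j$ is
$100\,\mathrm{cor}(t_k, y_j)^2$.

## A worked example

```r
library(rrrstab)

cohort <- generate_cohort(synthetic_config(seed = 7))      # 467 men, 2 waves
cfg <- pipeline_config(cv_n_splits = 200, n_randomizations = 500, seed = 8)
res <- run_pipeline(cohort$intake_wave1, cohort$response_wave1,
                    cohort$intake_wave2, cohort$response_wave2, cfg)
print(res)
```

```
Two-wave dietary pattern stability pipeline
 - screening retained 7 of 19 food groups: cheese, fruit_juices, high_fibre_bread,
   high_fibre_cereals, low_fibre_cereals, strong_alcoholic_beverages, sugar_sweetened_beverages
 - cross-validation chose k = 4 (wave 1) and k = 3 (wave 2); final k = 3
 - fitted exploratory RRR models with k = 3 in both waves
 - built cross-wave stability report
Cross-wave pattern stability (n = 467 participants, 3 factors)
Exploratory wave1 x exploratory wave2 (matched factors):
  factor1: r = 0.34 (95% CI 0.26-0.42)
  factor2: r = 0.19 (95% CI 0.11-0.28)
  factor3: r = 0.09 (95% CI -0.00-0.18)
```

Reading the output: screening kept the food groups that predict the risk
factors in both waves (the cereal-fibre and alcohol foods survive, most
inert groups do not); cross-validation supported three patterns in both
waves; and the first extracted pattern — dominated by high-fibre bread and
cereals — correlates 0.34 across the five-year gap, so independently
re-estimated weights rank the same people broadly similarly, while the
weakest pattern (factor 3, r = 0.09) is not stable at this effect size.
Realistic latent pattern strengths of a few percent explained variation put
a hard ceiling on these correlations; the methods vignette quantifies this.
`res$stability` also holds the confirmatory blocks
(fixed weights applied to the other wave's intakes), `autoplot(res$fit_wave1)`
draws the weights, and `write_pattern_report(res, "report")` emits the
tables as CSV.

A command-line front end with `simulate` and `run` verbs is installed at
`inst/cli/rrrstab-cli.R`.

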