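# riskNMF

Community screening programs for under-served populations — the motivating
case is a cost-free hepatitis-B screening cohort in which two thirds of the
300 participants were undocumented immigrants — produce clinical tables that
are chronically incomplete: not every lab is ordered for every participant,
and follow-up is rare. `riskNMF` imputes the missing laboratory values of
such a table with a **masked non-negative matrix factorization** and reads a
four-level cardiovascular risk category off the imputed
cholesterol-to-HDL ratio.

## The model

The encoded cohort is a non-negative matrix *X* (patients × 16 features:
SSN enrolment status as two complementary indicators, account number,
gender, age, race, TSH, PSA, HBsAb, HBsAg, GLU, CHOL, TG, HDL, LDL,
CHOL/HDL) with a binary observation mask *M*. The factorization solves

```
min_{U ≥ 0, V ≥ 0}  ½ Σ_{ij : M_ij = 1} (X_ij − (UV)_ij)²
```

by masked Lee–Seung multiplicative updates with an optional
orthogonality-promoting penalty λ‖UᵀU − I‖²_F on the patient factors, whose
gradient is folded into the denominator of the *U* update:

```
U ← U ∘ (M∘X)Vᵀ / [(M∘(UV))Vᵀ + λU(UᵀU − I) + δ]
```

followed by the analogous masked update for *V*. Iteration stops when the
relative objective change (*step error*) falls below ε. Missing cells are
then read off *UV*, decoded back to clinical units, and the CHOL/HDL ratio
is banded into the four ordinal risk levels (male cutpoints 4.2 / 7.4 /
11.5, female 3.9 / 5.8 / 9.0; HDL% 25 / 15 / 9), either as hard labels or
as a soft membership vector over the levels. A multinomial (softmax)
logistic regression baseline, a column-mean-imputation floor, a synthetic
cohort generator reproducing the published group-stratified marginals, and
a Table-style group-comparison summary (Welch/pooled *t*, two-proportion
χ²) complete the toolkit.

The raw screening data are available only on request from the original
study, so the package ships a **synthetic cohort generator**: per-group
truncated normals whose underlying parameters are moment-matched so the
*truncated* samples reproduce the printed mean/SD/min/max, Bernoulli
serology, demographic proportions, MCAR missingness, and PSA restricted to
a tested subset.

## Worked example

```r
library(riskNMF)

spec <- cohort_spec()                 # published marginals, n = 199 + 101
g <- generate_cohort(spec, seed = 42)
g$cohort
#> cohort_table: 300 records x 15 features (364 missing values)

ex <- run_risk_experiment(g$cohort, fraction = 0.2, k = 4, epsilon = 1e-5,
                          max_iter = 2000, seed = 42, mlr = TRUE)
ex$fit
#> ognmf_fit: rank 4, 455 iteration(s), converged (final objective 77.5702, step error 9.93e-06)
ex$result
#> eval_result: 70.18% exact-match risk accuracy on 57 held-out cells
round(100 * ex$mean_baseline_accuracy, 2)   # column-mean imputation floor
#> [1] 66.67
round(100 * ex$mlr_accuracy, 2)             # softmax-regression baseline
#> [1] 91.23

classify_ratio("M", 5.0)                    # average risk
#> [1] 2
soft_assign("M", 4.2)                       # exactly on a cutpoint
#>      level1 level2 level3 level4
#> [1,]    0.5    0.5      0      0
```

The experiment holds out 20% of the observed CHOL/HDL cells, fits the
masked factorization on the remainder, imputes the held-out ratios, and
scores exact-match agreement between the risk category of the imputed and
the true ratio. The fit converged (step error < 1e-5 after 455 iterations);
on this seed the factorization classifies 70.2% of held-out patients into
the correct risk band. The softmax baseline is strong here because the
synthetic cohort exposes CHOL and HDL directly; see the methods vignette
(`vignettes/masked-nmf-risk-imputation.Rmd`) for what the generator does
and does not emulate about the real cohort.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/risknmf.R simulate --n-ssn-neg 199 --n-ssn-pos 101 --seed 1 --out cohort.csv
Rscript inst/cli/risknmf.R classify --sex M --ratio 5.0
Rscript inst/cli/risknmf.R evaluate --input cohort.csv --holdout 0.2 --rank 4 --epsilon 1e-5 --seed 1
```

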