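# psvmatch

Prognostic risk stratification for survival cohorts, built for the setting
where a panel of continuous markers (for the packaged signature: 36 log2
microarray expression probes plus age at diagnosis, in high-grade serous
ovarian carcinoma) must be turned into a per-patient risk class — and where
no single classifier should be trusted on its own.

The package implements three layers plus an ensemble:

1. **Univariate optimal-cutoff dichotomization.** For each variable, every
   admissible cutoff `c` is scored by the Cox fit of the indicator
   `z = 1(x > c)`, and the cutoff minimizing the Wald p-value
   `p = 2(1 − Φ(|β̂|/se))` is kept, together with its *design* (direction of
   risk: design 1 = low values high-risk, design 2 = low values low-risk)
   and hazard ratio `HR = exp(|β̂|) ≥ 1`.
2. **Weighted-voting risk score.** The per-variable 0/1 risk calls `s_i` are
   averaged with normalized weights into `AWR = Σ w_i s_i ∈ [0, 1]`; two
   thresholds chosen by exhaustive log-rank optimization cut the cohort into
   low/intermediate/high risk. Six weight schemes are provided (constant,
   `1/P`, `−log P`, `HR`, and two combinations of `−log P` with `HR`).
3. **Personalized signature matching.** Each patient's risk calls, weighted
   by reverse rank of variable importance, form a prognostic signature
   vector; a new patient inherits the risk class of its Euclidean-nearest
   reference patient.
4. **Multi-classifier voting.** Six classical learners (KNN, SVM-RBF,
   SVM-linear, random forest, neural network, logistic regression) trained
   one-vs-rest on standardized signature vectors under stratified 10-fold
   cross-validation vote alongside the signature matcher; Goodman–Kruskal
   gamma quantifies method concordance.

A seeded synthetic-cohort generator with planted cutoffs, designs and hazard
structure makes every layer testable without data downloads, and the
published 37-variable signature ships as a plain-text fixture.

## Worked example

```r
library(psvmatch)

sig <- hgsc_signature()                      # packaged 37-variable signature
weight_dynamic_range(compute_weights(sig, scheme = "B"))
#> [1] 34.69094

# train a weighted-voting stratification on a synthetic 3-class cohort
co  <- simulate_classed_cohort(n_patients = 300, seed = 1)
fit <- fit_swvg(co$data, signature = co$truth$signature, scheme = "A")
fit
#> SWVg fit: 37 variables, scheme A; thresholds (0.4189, 0.6216);
#>   groups 188/69/43; log-rank p = 1.88e-10

# classify held-out patients by nearest-signature matching
te   <- simulate_classed_cohort(n_patients = 150, seed = 2)
pred <- predict_psvm(fit, te$data)
head(pred, 3)
#>   patient_id reference_id distance risk_class
#> 1 p0001      p0040           105.  high
#> 2 p0002      p0259            97.9 low
#> 3 p0003      p0113            97.9 high
mean(pred$risk_class == te$truth$class)
#> [1] 0.8
logrank_test(dplyr::mutate(te$data, risk_class = pred$risk_class),
             group = risk_class)
#> Log-rank test: chisq = 17.56 on 2 df, p = 0.0001537 (asymptotic)
```

The first number is the dynamic range of the inverse-p weights across the
packaged signature: the most significant variable carries 34.7 times the
weight of the least significant one (the reason the gentler `−log P`
weighting is the default). The fitted stratification separates the three
synthetic risk groups at `p ≈ 2e-10` on the training cohort, and the
signature matcher recovers 80% of the planted classes of a held-out cohort,
which remain survival-significant (`p ≈ 1.5e-4`).

`fit_risk_ensemble(fit, seed = 1)` trains the six learners on top of such a
fit and `predict()` on it returns the per-method vote table with the final
majority class; `gamma_matrix()` renders the method-concordance matrix.
A command-line surface for the whole pipeline (simulate / fit-ddg / weights /
fit-swvg / predict-psvm / run-ensemble) lives at
`system.file("cli", "psvmatch.R", package = "psvmatch")`.

See `vignette("prognostic-voting")` sources under `vignettes/` for the
model, its assumptions, and all numerical conventions.

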