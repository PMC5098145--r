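# Small cohort builders shared across the suite. All randomness is seeded at
# the call site so every test is reproducible in isolation.

toy_cohort <- function(time, event, ...) {
  tibble::tibble(
    patient_id = sprintf("p%02d", seq_along(time)),
    time = time, event = event, ...
  )
}

# random survival cohort with a fixed censoring fraction (for property loops)
rand_cohort <- function(n, seed, cens_prob = 0.3) {
  withr::with_seed(seed, {
    toy_cohort(
      time = round(rexp(n, 0.1), 3) + 0.001,
      event = rbinom(n, 1, 1 - cens_prob)
    )
  })
}

# independent Breslow Wald p at a fixed dichotomization, via survival::coxph
coxph_wald_p <- function(data, x, ties = "breslow") {
  fit <- survival::coxph(survival::Surv(data$time, data$event) ~ x,
                         ties = ties)
  s <- summary(fit)$coefficients
  list(beta = s[1, "coef"], p = s[1, "Pr(>|z|)"])
}
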