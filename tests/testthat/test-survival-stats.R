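test_that("Kaplan-Meier estimate matches the product-limit closed form", {
  km <- km_estimate(toy_cohort(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$estimate, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))

  one <- km_estimate(toy_cohort(5, 1))
  expect_equal(one$estimate, 0)

  # interleaved censoring, 20 patients: agree with the reference implementation
  d <- rand_cohort(20, seed = 101)
  km <- km_estimate(d)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  ref <- summary(sf, times = km$time)
  expect_equal(km$estimate, ref$surv, tolerance = 1e-12)
  expect_equal(km$n_event, ref$n.event)
})

test_that("KM with no censoring equals the empirical survival function", {
  for (s in 1:5) {
    d <- rand_cohort(40, seed = 200 + s, cens_prob = 0)
    km <- km_estimate(d)
    emp <- vapply(km$time, function(t) mean(d$time > t), 0)
    expect_equal(km$estimate, emp, tolerance = 1e-12)
  }
})

test_that("degenerate survival inputs are rejected", {
  expect_error(km_estimate(toy_cohort(numeric(0), numeric(0))), "empty")
  expect_error(km_estimate(toy_cohort(c(1, 2), c(0, 0))), "no events")
  expect_error(km_estimate(toy_cohort(c(0, 2), c(1, 1))), "positive")
  expect_error(km_estimate(toy_cohort(c(1, 2), c(1, 2))), "0.*1")
})

test_that("log-rank statistic is zero for identical groups and matches survdiff", {
  base <- rand_cohort(15, seed = 7)
  d <- dplyr::bind_rows(base, base, base)
  d$patient_id <- sprintf("p%02d", seq_len(nrow(d)))
  d$grp <- rep(1:3, each = nrow(base))
  lr <- logrank_test(d, group = grp)
  expect_equal(lr$statistic, 0, tolerance = 1e-9)
  expect_equal(lr$p_value, 1)
  expect_equal(lr$df, 2L)

  for (s in 1:10) {
    d <- rand_cohort(30, seed = 300 + s)
    d$grp <- withr::with_seed(s, sample(1:3, 30, replace = TRUE))
    lr <- logrank_test(d, group = grp)
    sref <- survival::survdiff(survival::Surv(time, event) ~ grp, data = d)
    expect_equal(lr$statistic, sref$chisq, tolerance = 1e-8)
    expect_equal(lr$p_value, pchisq(sref$chisq, 2, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("permutation log-rank p matches the exhaustive label-assignment null", {
  d <- rand_cohort(12, seed = 55, cens_prob = 0.2)
  g <- rep(1:2, each = 6)
  d$grp <- g
  prep <- survival_prep(d$time, d$event)
  obs <- logrank_stat(prep, g, 2L)
  combs <- utils::combn(12, 6)
  stats <- apply(combs, 2, function(idx) {
    gi <- rep(2L, 12); gi[idx] <- 1L
    logrank_stat(prep, gi, 2L)
  })
  p_exact <- mean(stats >= obs - 1e-12)
  lr <- logrank_test(d, group = grp, p_method = "permutation",
                     n_perm = 4000, seed = 9)
  expect_lt(abs(lr$p_value - p_exact), 0.04)
})

test_that("strongly separated exponential hazards give a vanishing log-rank p", {
  d <- withr::with_seed(11, {
    g <- rep(1:3, each = 100)
    toy_cohort(time = rexp(300, rate = c(0.05, 0.1, 0.2)[g]),
               event = rep(1, 300), grp = g)
  })
  expect_lt(logrank_test(d, group = grp)$p_value, 1e-6)
})

test_that("log-rank test is invariant to patient order and group relabeling", {
  d <- rand_cohort(40, seed = 77)
  d$grp <- withr::with_seed(78, sample(1:3, 40, replace = TRUE))
  lr <- logrank_test(d, group = grp)
  perm <- withr::with_seed(79, d[sample(40), ])
  expect_equal(logrank_test(perm, group = grp)$statistic, lr$statistic,
               tolerance = 1e-10)
  relab <- dplyr::mutate(d, grp = c(30, 10, 20)[grp])
  expect_equal(logrank_test(relab, group = grp)$statistic, lr$statistic,
               tolerance = 1e-10)
  expect_error(logrank_test(dplyr::mutate(d, grp = 1), group = grp), "2 groups")
})

test_that("binary Cox fit is null-calibrated under an independent coin covariate", {
  ps <- vapply(1:5, function(s) {
    d <- rand_cohort(200, seed = 400 + s)
    d$coin <- withr::with_seed(500 + s, rbinom(200, 1, 0.5))
    fit <- fit_binary_cox(d, coin)
    expect_lt(abs(fit$beta), 0.6)
    fit$wald_p
  }, 0)
  expect_gte(sum(ps > 0.05), 4)
})

test_that("two identical groups give beta = 0 and HR = 1", {
  base <- rand_cohort(15, seed = 21)
  d <- dplyr::bind_rows(base, base)
  d$patient_id <- sprintf("p%02d", seq_len(30))
  d$g <- rep(0:1, each = 15)
  fit <- fit_binary_cox(d, g)
  expect_equal(fit$beta, 0, tolerance = 1e-8)
  expect_equal(fit$hazard_ratio, 1, tolerance = 1e-8)
})

test_that("swapping the 0/1 coding negates beta and inverts the hazard ratio", {
  d <- rand_cohort(60, seed = 31)
  d$g <- withr::with_seed(32, rbinom(60, 1, 0.4))
  f1 <- fit_binary_cox(d, g)
  f2 <- fit_binary_cox(dplyr::mutate(d, g = 1 - g), g)
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-7)
  expect_equal(f1$hazard_ratio, 1 / f2$hazard_ratio, tolerance = 1e-7)
})

test_that("Newton-Raphson estimate matches a brute-force partial-likelihood grid", {
  d <- toy_cohort(
    time = c(2, 4, 4, 7, 9, 11, 12, 15, 18, 21),
    event = c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1),
    g = c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  )
  grid <- seq(-5, 5, by = 1e-4)
  # direct Breslow partial log-likelihood over the raw risk sets
  ll <- numeric(length(grid))
  for (t in unique(d$time[d$event == 1])) {
    dead <- which(d$event == 1 & d$time == t)
    risk <- which(d$time >= t)
    rs <- exp(outer(grid, d$g[risk]))       # grid x risk-set
    ll <- ll + sum(d$g[dead]) * grid - length(dead) * log(rowSums(rs))
  }
  beta_grid <- grid[which.max(ll)]
  fit <- fit_binary_cox(d, g)
  expect_lt(abs(fit$beta - beta_grid), 1e-3)
})

test_that("beta, se and Wald p agree with the reference survival implementation", {
  for (s in 1:50) {
    d <- rand_cohort(25, seed = 600 + s)
    d$g <- withr::with_seed(700 + s, rbinom(25, 1, 0.5))
    if (length(unique(d$g)) < 2 || sum(d$event) == 0) next
    ref <- coxph_wald_p(d, d$g)
    fit <- fit_binary_cox(d, g)
    if (fit$separation) next
    expect_equal(fit$beta, ref$beta, tolerance = 1e-6)
    expect_equal(fit$wald_p, ref$p, tolerance = 1e-6)
  }
})

test_that("Efron tie handling agrees with the reference implementation", {
  for (s in 1:10) {
    d <- withr::with_seed(800 + s, {
      toy_cohort(time = sample(1:8, 30, replace = TRUE),  # heavy ties
                 event = rbinom(30, 1, 0.7),
                 g = rbinom(30, 1, 0.5))
    })
    if (length(unique(d$g)) < 2 || sum(d$event) == 0) next
    ref <- coxph_wald_p(d, d$g, ties = "efron")
    fit <- fit_binary_cox(d, g, ties = "efron")
    if (fit$separation) next
    expect_equal(fit$beta, ref$beta, tolerance = 1e-6)
    expect_equal(fit$wald_p, ref$p, tolerance = 1e-6)
  }
})

test_that("complete separation is capped and flagged", {
  d <- toy_cohort(time = c(1, 2, 3, 10, 11, 12),
                  event = c(1, 1, 1, 1, 1, 1),
                  g = c(1, 1, 1, 0, 0, 0))
  expect_warning(fit <- fit_binary_cox(d, g), "separation")
  expect_true(fit$separation)
  expect_lte(abs(fit$beta), 15)
  expect_error(fit_binary_cox(dplyr::mutate(d, g = 1), g), "non-empty")
})
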