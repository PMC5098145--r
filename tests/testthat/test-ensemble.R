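blobs3 <- function(n_per = 30, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(
      cbind(rnorm(n_per, 0), rnorm(n_per, 0)),
      cbind(rnorm(n_per, sep), rnorm(n_per, sep)),
      cbind(rnorm(n_per, 0), rnorm(n_per, sep))
    )
    colnames(x) <- c("f1", "f2")
    list(x = x, y = risk_factor(rep(RISK_LEVELS, each = n_per)))
  })
}

test_that("feature scaling uses training statistics with population sd", {
  sc <- scale_features(matrix(c(1, 2, 3), ncol = 1),
                       test = matrix(2, ncol = 1))
  expect_equal(drop(sc$train), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  expect_equal(drop(sc$test), 0)   # test value at the training mean
  expect_warning(sc2 <- scale_features(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "constant")
  expect_true(all(sc2$train[, "a"] == 0))
  # inverse transform recovers the input
  m <- withr::with_seed(2, matrix(rnorm(40), 10, 4))
  sc3 <- scale_features(m)
  back <- sweep(sweep(sc3$train, 2, sc3$scale, `*`), 2, sc3$center, `+`)
  expect_equal(back, m, tolerance = 1e-10)
  expect_equal(unname(colMeans(sc3$train)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(colMeans(sc3$train^2)), rep(1, 4), tolerance = 1e-9)
})

test_that("stratified folds preserve class proportions within one patient", {
  lab <- rep(RISK_LEVELS, times = c(50, 30, 20))
  f <- stratified_folds(lab, k = 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  for (k in 1:10) {
    expect_equal(as.integer(table(factor(lab[f == k], levels = RISK_LEVELS))),
                 c(5L, 3L, 2L))
  }
  expect_identical(stratified_folds(lab, k = 10, seed = 3), f)

  lab349 <- rep(RISK_LEVELS, times = c(194, 114, 41))
  f349 <- stratified_folds(lab349, k = 10, seed = 5)
  sizes <- tabulate(f349, 10)
  expect_true(all(sizes >= 34 & sizes <= 35))
  global <- table(lab349) / 349
  for (k in 1:10) {
    cnt <- table(factor(lab349[f349 == k], levels = RISK_LEVELS))
    expect_true(all(abs(cnt - global[RISK_LEVELS] * sizes[k]) <= 1))
  }
  expect_length(f349, 349)   # a partition: every patient in exactly one fold
  expect_error(stratified_folds(rep(RISK_LEVELS, times = c(50, 30, 5)), k = 10),
               "at least k")
})

test_that("one-vs-rest learners separate Gaussian blobs", {
  b <- blobs3(seed = 11)
  sc <- scale_features(b$x)
  m_lin <- train_ovr(sc$train, b$y, "svm_linear", seed = 1)
  expect_equal(mean(predict(m_lin, sc$train) == b$y), 1.0)
  m_knn1 <- train_ovr(sc$train, b$y, "knn", params = list(k = 1), seed = 1)
  expect_equal(mean(predict(m_knn1, sc$train) == b$y), 1.0)  # self-neighbor
  for (ln in c("knn", "svm_rbf", "rf", "nn", "lr")) {
    m <- train_ovr(sc$train, b$y, ln, seed = 1)
    expect_gte(mean(predict(m, sc$train) == b$y), 0.95)
  }
  expect_error(train_ovr(sc$train, rep("low", nrow(sc$train)), "knn"),
               "single class")
  expect_error(train_ovr(sc$train, b$y, "boost"), "unknown learner")
})

test_that("fold consensus equals the direct vote tally with stated tie rules", {
  b <- blobs3(n_per = 20, sep = 3, seed = 13)
  sc <- scale_features(b$x)
  folds <- stratified_folds(b$y, k = 5, seed = 7)
  models <- lapply(1:5, function(f) {
    train_ovr(sc$train[folds != f, ], b$y[folds != f], "rf", seed = 100 + f)
  })
  qs <- sc$train[1:15, ]
  cons <- consensus_predict(models, qs)
  indiv <- vapply(models, function(m) as.character(predict(m, qs)), character(15))
  prev <- table(b$y)
  for (i in 1:15) {
    counts <- table(factor(indiv[i, ], levels = RISK_LEVELS))
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1) {
      expect_equal(as.character(cons[i]), top)
    } else {
      top <- top[prev[top] == max(prev[top])]
      expect_equal(as.character(cons[i]), top[1])
    }
  }
  # 10 identical models return their common prediction
  same <- consensus_predict(rep(models[1], 10), qs)
  expect_equal(as.character(same), as.character(predict(models[[1]], qs)))
})

test_that("majority vote follows the modal class with the matcher breaking ties", {
  v <- tibble::tibble(
    psvm = c("intermediate", "intermediate", "high"),
    knn = c("low", "intermediate", "high"),
    svm_rbf = c("low", "low", "high"),
    svm_linear = c("low", "low", "high"),
    rf = c("high", "intermediate", "high"),
    nn = c("intermediate", "intermediate", "high"),
    lr = c("intermediate", "low", "high")
  )
  got <- majority_vote(v)
  # row 1 ties low x3 / int x3 -> matcher says intermediate; row 2: int x4
  expect_equal(as.character(got), c("intermediate", "intermediate", "high"))
  # strict majority ignores the tie-break column
  v2 <- v
  v2$psvm <- c("high", "high", "high")
  expect_equal(as.character(majority_vote(v2))[1], "low")
  # permutation invariance in the non-psvm columns
  v3 <- v[, c("psvm", "lr", "nn", "rf", "svm_linear", "svm_rbf", "knn")]
  expect_equal(majority_vote(v3), got)
  expect_error(majority_vote(v[, -1]), "psvm")
  v4 <- v
  v4$knn[2] <- NA
  expect_error(majority_vote(v4), "missing")
})

test_that("gamma correlation equals the exhaustive concordant/discordant count", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(gamma_correlation(x, x), 1)
  expect_equal(gamma_correlation(x, rev(x)), -1)
  withr::with_seed(17, {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
  })
  C <- 0; D <- 0
  for (i in 1:29) {
    for (j in (i + 1):30) {
      s <- (a[i] - a[j]) * (b[i] - b[j])
      if (s > 0) C <- C + 1
      if (s < 0) D <- D + 1
    }
  }
  expect_equal(gamma_correlation(a, b), (C - D) / (C + D), tolerance = 1e-12)
  expect_equal(gamma_correlation(a, b), gamma_correlation(b, a))
  expect_true(abs(gamma_correlation(a, b)) <= 1)
  expect_warning(g0 <- gamma_correlation(c(1, 1, 1), c(2, 3, 4)), "tied")
  expect_true(is.na(g0))
  gm <- gamma_matrix(tibble::tibble(a = a, b = b))
  expect_equal(gm["a", "b"], gamma_correlation(a, b))
  expect_equal(diag(gm), c(a = 1, b = 1))
})

test_that("the ensemble vote tracks the planted classes at least as well as most learners", {
  tr <- simulate_classed_cohort(n_patients = 200, n_variables = 15, seed = 47)
  fit <- fit_swvg(tr$data, signature = tr$truth$signature, scheme = "A")
  ens <- fit_risk_ensemble(fit, k_folds = 10, seed = 49)
  expect_true(all(ens$cv_accuracy$cv_accuracy > 0.5))
  te <- simulate_classed_cohort(n_patients = 100, n_variables = 15, seed = 51)
  votes <- predict(ens, te$data)
  expect_equal(names(votes),
               c("patient_id", "psvm", "knn", "svm_rbf", "svm_linear",
                 "rf", "nn", "lr", "final"))
  truth <- te$truth$class
  acc <- vapply(c("psvm", LEARNERS), function(mm) mean(votes[[mm]] == truth), 0)
  final_acc <- mean(votes$final == truth)
  expect_gte(final_acc, max(acc) - 0.05)   # regression guard
  # final class always has a maximal vote count or follows the psvm tie-break
  tallies <- apply(as.matrix(votes[, c("psvm", LEARNERS)]), 1, function(v) {
    counts <- table(factor(v, levels = RISK_LEVELS))
    top <- names(counts)[counts == max(counts)]
    list(top = top, psvm = v[["psvm"]])
  })
  for (i in seq_along(tallies)) {
    tt <- tallies[[i]]
    expected <- if (length(tt$top) == 1) tt$top else tt$psvm
    expect_equal(as.character(votes$final[i]), expected)
  }
})
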