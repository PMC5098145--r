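#' Multi-classifier voting ensemble
#'
#' Trains six classical learners (KNN, SVM with RBF and linear kernels,
#' random forest, a single-hidden-layer neural network, and L2 logistic
#' regression) one-vs-rest on standardized prognostic signature vectors under
#' stratified 10-fold cross-validation; test patients are classified by the
#' consensus of the ten fold models per learner, and the seven methods
#' (nearest-signature matching plus the six learners) are combined by
#' majority vote. Method agreement is quantified by the Goodman-Kruskal gamma.
#'
#' @name ensemble
NULL

LEARNERS <- c("knn", "svm_rbf", "svm_linear", "rf", "nn", "lr")

#' Standardize features with training-set statistics
#'
#' Centers and scales each column to zero mean and unit variance using the
#' *population* standard deviation (divide by n) learned on the training set;
#' test columns are transformed with the training parameters. Constant
#' training columns get scale 1 (so they map to zeros) with a warning.
#'
#' @param train numeric matrix or data frame, patients x features.
#' @param test optional matrix/data frame with the same columns.
#' @return list with `train`, `test` (or NULL), `center`, `scale`.
#' @export
scale_features <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) abort("need at least 2 training rows to scale")
  ctr <- colMeans(train)
  sc <- sqrt(colMeans(sweep(train, 2L, ctr)^2))
  if (any(sc < 1e-12)) {
    warn("constant training feature(s): scale set to 1")
    sc[sc < 1e-12] <- 1
  }
  tr <- sweep(sweep(train, 2L, ctr), 2L, sc, `/`)
  te <- if (!is.null(test)) {
    test <- as.matrix(test)
    sweep(sweep(test, 2L, ctr), 2L, sc, `/`)
  }
  list(train = tr, test = te, center = ctr, scale = sc)
}

#' Stratified fold assignment
#'
#' Shuffles patients within each class (seeded) and deals them round-robin
#' into `k` folds, with per-class starting offsets chosen so total fold sizes
#' stay balanced. Per-fold class counts are within one patient of the global
#' class proportions.
#'
#' @param labels class label per patient (factor or coercible).
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..k, one per patient, with
#'   attribute `seed`.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  f <- factor(labels)
  sizes <- table(f)
  if (any(sizes < k)) {
    abort(sprintf("every class needs at least k = %d members", k))
  }
  fold <- integer(length(f))
  offset <- 0L
  withr::with_seed(seed, {
    for (lev in levels(f)) {
      idx <- which(f == lev)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  attr(fold, "seed") <- seed
  fold
}

# ---- one-vs-rest learners ----------------------------------------------------

default_learner_params <- function(learner, n_features, n_train) {
  switch(learner,
    knn = list(k = 5),
    svm_rbf = list(cost = 1, gamma = 1 / n_features),
    svm_linear = list(cost = 1),
    rf = list(ntree = 100),
    nn = list(size = 32, decay = 1e-3, maxit = 200),
    lr = list(lambda = 1 / n_train),
    abort(sprintf("unknown learner '%s'", learner))
  )
}

ovr_fit_one <- function(learner, x, y01, params, seed) {
  yf <- factor(y01, levels = c(0, 1))
  withr::with_seed(seed, switch(learner,
    knn = list(x = x, y = yf, k = params$k),
    svm_rbf = e1071::svm(x, yf, kernel = "radial", cost = params$cost,
                         gamma = params$gamma, scale = FALSE),
    svm_linear = e1071::svm(x, yf, kernel = "linear", cost = params$cost,
                            scale = FALSE),
    rf = randomForest::randomForest(x, yf, ntree = params$ntree),
    nn = nnet::nnet(x, y01, size = params$size, decay = params$decay,
                    maxit = params$maxit, entropy = TRUE, trace = FALSE,
                    MaxNWts = 100000),
    lr = glmnet::glmnet(x, yf, family = "binomial", alpha = 0,
                        lambda = params$lambda)
  ))
}

ovr_score_one <- function(learner, model, newx, params, seed) {
  switch(learner,
    knn = {
      pred <- withr::with_seed(seed, {
        class::knn(model$x, newx, model$y, k = model$k, prob = TRUE)
      })
      pr <- attr(pred, "prob")
      ifelse(pred == "1", pr, 1 - pr)
    },
    svm_rbf = ,
    svm_linear = {
      dv <- attr(predict(model, newx, decision.values = TRUE), "decision.values")
      labs <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
      if (labs[1] == "1") dv[, 1] else -dv[, 1]
    },
    rf = predict(model, newx, type = "prob")[, "1"],
    nn = drop(predict(model, newx)),
    lr = drop(predict(model, newx, type = "response", s = params$lambda))
  )
}

#' Train a one-vs-rest multiclass model
#'
#' Fits one binary classifier per class (that class against all others);
#' prediction picks the class with the maximal decision score (ties go to the
#' lower-risk class).
#'
#' @param x numeric feature matrix (standardized PSVs), patients x features.
#' @param labels class label per patient.
#' @param learner one of `"knn"`, `"svm_rbf"`, `"svm_linear"`, `"rf"`,
#'   `"nn"`, `"lr"`.
#' @param params named list of hyperparameters; unset entries take the
#'   defaults (knn k = 5; svm cost = 1, RBF gamma = 1/n_features; rf 100
#'   trees; nn 32 hidden units, decay 1e-3; lr ridge lambda = 1/n).
#' @param seed RNG seed for stochastic learners.
#' @return an object of class `ovr_model`.
#' @export
train_ovr <- function(x, labels, learner, params = list(), seed = 1) {
  if (!learner %in% LEARNERS) abort(sprintf("unknown learner '%s'", learner))
  x <- as.matrix(x)
  f <- factor(labels)
  if (nlevels(f) < 2) abort("labels are degenerate: a single class")
  defaults <- default_learner_params(learner, ncol(x), nrow(x))
  params <- utils::modifyList(defaults, params)
  models <- lapply(seq_len(nlevels(f)), function(i) {
    y01 <- as.numeric(f == levels(f)[i])
    ovr_fit_one(learner, x, y01, params, seed + i)
  })
  structure(
    list(learner = learner, models = models, levels = levels(f),
         params = params, seed = seed, prevalence = table(f)),
    class = "ovr_model"
  )
}

#' @rdname train_ovr
#' @param object an `ovr_model`
#' @param newx feature matrix of new patients (same standardization as `x`)
#' @param ... ignored
#' @export
predict.ovr_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  scores <- vapply(seq_along(object$models), function(i) {
    ovr_score_one(object$learner, object$models[[i]], newx, object$params,
                  object$seed + i)
  }, numeric(nrow(newx)))
  scores <- matrix(scores, nrow = nrow(newx))
  picked <- max.col(scores, ties.method = "first")
  factor(object$levels[picked], levels = object$levels, ordered = TRUE)
}

#' Consensus prediction over cross-validation fold models
#'
#' Each of the fold models predicts the query; the majority class wins. A tie
#' goes to the tied class with the larger training prevalence, a residual tie
#' to the lower-risk class.
#'
#' @param fold_models list of `ovr_model`s (one per fold, same learner).
#' @param newx standardized feature matrix of queries.
#' @param prevalence named class counts in the full training set; defaults to
#'   the prevalence stored in the first fold model.
#' @return ordered factor of consensus classes.
#' @export
consensus_predict <- function(fold_models, newx, prevalence = NULL) {
  prevalence <- prevalence %||% fold_models[[1]]$prevalence
  lv <- fold_models[[1]]$levels
  preds <- vapply(fold_models, function(m) as.character(predict(m, newx)),
                  character(nrow(as.matrix(newx))))
  preds <- matrix(preds, ncol = length(fold_models))
  out <- apply(preds, 1L, function(v) {
    vote_break_ties(table(factor(v, levels = lv)), prevalence[lv])
  })
  factor(out, levels = lv, ordered = TRUE)
}

# counts: named votes per class (in low->high order); prev: tie-break counts
vote_break_ties <- function(counts, prev) {
  top <- which(counts == max(counts))
  if (length(top) > 1L) {
    top <- top[prev[top] == max(prev[top])]
  }
  names(counts)[top[1L]]   # residual tie: first = lowest risk
}

#' Majority vote across the seven classification methods
#'
#' The final class is the modal prediction across the methods; on a tie the
#' nearest-signature-matching (`psvm`) prediction wins.
#'
#' @param votes data frame of per-patient method predictions, one column per
#'   method, including a `psvm` column; no missing predictions allowed.
#' @param psvm_col name of the tie-breaking column (default `"psvm"`).
#' @return ordered factor of final classes, one per row of `votes`.
#' @export
majority_vote <- function(votes, psvm_col = "psvm") {
  votes <- as.data.frame(votes)
  if (!psvm_col %in% names(votes)) {
    abort(sprintf("`votes` must contain a '%s' column for tie breaking", psvm_col))
  }
  m <- vapply(votes, as.character, character(nrow(votes)))
  m <- matrix(m, nrow = nrow(votes), dimnames = list(NULL, names(votes)))
  if (anyNA(m)) abort("missing method prediction")
  bad <- !m %in% RISK_LEVELS
  if (any(bad)) abort("predictions must be risk classes")
  out <- vapply(seq_len(nrow(m)), function(i) {
    counts <- table(factor(m[i, ], levels = RISK_LEVELS))
    top <- which(counts == max(counts))
    if (length(top) == 1L) names(counts)[top] else m[i, psvm_col]
  }, character(1))
  risk_factor(out)
}

# ---- Goodman-Kruskal gamma ---------------------------------------------------

#' Goodman-Kruskal gamma rank correlation
#'
#' Ordinal association between two sequences: `(C - D) / (C + D)` over all
#' patient pairs, where C counts concordant and D discordant pairs; pairs
#' tied on either sequence are excluded.
#'
#' @param x,y ordinal sequences of equal length (ordered factors or
#'   numerics).
#' @return gamma in \[-1, 1\]; `NA` (with a warning) when every pair is tied.
#' @export
gamma_correlation <- function(x, y) {
  xi <- as_ordinal_code(x)
  yi <- as_ordinal_code(y)
  if (length(xi) != length(yi)) abort("`x` and `y` lengths differ")
  if (length(xi) < 2) abort("need at least 2 observations")
  sx <- sign(outer(xi, xi, `-`))
  sy <- sign(outer(yi, yi, `-`))
  up <- upper.tri(sx)
  prod_sign <- sx[up] * sy[up]
  C <- sum(prod_sign > 0)
  D <- sum(prod_sign < 0)
  if (C + D == 0) {
    warn("all pairs tied: gamma undefined")
    return(NA_real_)
  }
  (C - D) / (C + D)
}

as_ordinal_code <- function(x) {
  if (is.factor(x)) as.integer(x) else as.numeric(x)
}

#' Pairwise gamma concordance matrix
#'
#' @param data data frame of ordinal columns (e.g. a vote table's per-method
#'   predictions plus survival time/event).
#' @return symmetric numeric matrix of pairwise gamma coefficients.
#' @export
gamma_matrix <- function(data) {
  cols <- names(data)
  k <- length(cols)
  m <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  for (i in seq_len(k)) {
    for (j in i:k) {
      g <- if (i == j) 1 else gamma_correlation(data[[i]], data[[j]])
      m[i, j] <- g
      m[j, i] <- g
    }
  }
  m
}

# ---- the ensemble ------------------------------------------------------------

#' Train the multi-classifier voting ensemble
#'
#' Builds standardized PSV features from a fitted SWVg model's training
#' cohort, assigns stratified cross-validation folds, and trains each
#' requested learner one-vs-rest on every 9-fold training split. The fitted
#' ensemble predicts new patients by per-learner fold consensus plus
#' nearest-signature matching, combined by [majority_vote()].
#'
#' @param object an `swvg_fit` from [fit_swvg()].
#' @param learners character vector of learners (default all six).
#' @param k_folds number of cross-validation folds (default 10).
#' @param seed RNG seed controlling fold shuffling and stochastic learners.
#' @param learner_params named list of per-learner hyperparameter overrides,
#'   e.g. `list(nn = list(size = 8))`.
#' @return an object of class `risk_ensemble` with per-learner
#'   cross-validation accuracies in `$cv_accuracy`.
#' @export
fit_risk_ensemble <- function(object, learners = LEARNERS, k_folds = 10,
                              seed = 1, learner_params = list()) {
  stopifnot(inherits(object, "swvg_fit"))
  bad <- setdiff(learners, LEARNERS)
  if (length(bad)) abort(paste("unknown learner(s):", paste(bad, collapse = ", ")))
  labels <- object$reference_class
  vars <- object$weights$variable
  psv_raw <- as.matrix(object$reference_psv[, vars, drop = FALSE])
  sc <- scale_features(psv_raw)
  folds <- stratified_folds(labels, k = k_folds, seed = seed)

  models <- list()
  cv_rows <- list()
  for (ln in learners) {
    params <- learner_params[[ln]] %||% list()
    fold_models <- vector("list", k_folds)
    correct <- 0L
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      fold_models[[f]] <- train_ovr(sc$train[tr, , drop = FALSE], labels[tr],
                                    ln, params = params,
                                    seed = seed + 97L * f)
      pred <- predict(fold_models[[f]], sc$train[!tr, , drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    models[[ln]] <- fold_models
    cv_rows[[ln]] <- tibble(learner = ln,
                            cv_accuracy = correct / length(labels))
  }
  structure(
    list(
      swvg = object, learners = learners, models = models,
      center = sc$center, scale = sc$scale,
      folds = folds, k_folds = k_folds, seed = seed,
      prevalence = table(labels),
      cv_accuracy = dplyr::bind_rows(cv_rows)
    ),
    class = "risk_ensemble"
  )
}

#' @export
print.risk_ensemble <- function(x, ...) {
  cat(sprintf("Risk ensemble: %s + psvm; %d-fold CV (seed %d)\n",
              paste(x$learners, collapse = ", "), x$k_folds, x$seed))
  print(x$cv_accuracy)
  invisible(x)
}

#' @rdname fit_risk_ensemble
#' @param new_data data frame of query patients with the signature variables.
#' @param missing missing-value policy for [build_pbvv()].
#' @param ... ignored.
#' @return `predict()` returns a vote table: `patient_id`, one prediction
#'   column per method (`psvm` plus each learner), and the majority-vote
#'   `final` class.
#' @export
predict.risk_ensemble <- function(object, new_data,
                                  missing = c("error", "median"), ...) {
  missing <- match.arg(missing)
  sw <- object$swvg
  psvm_pred <- predict_psvm(sw, new_data, missing = missing)
  pbvv <- build_pbvv(new_data, sw$signature, missing = missing)
  psv <- pbvv_to_psv(pbvv, sw$weights,
                     type = attr(sw$reference_psv, "psv_type") %||% "rank")
  q <- as.matrix(psv[, sw$weights$variable, drop = FALSE])
  q <- sweep(sweep(q, 2L, object$center), 2L, object$scale, `/`)

  out <- tibble(patient_id = psvm_pred$patient_id,
                psvm = psvm_pred$risk_class)
  for (ln in object$learners) {
    out[[ln]] <- consensus_predict(object$models[[ln]], q, object$prevalence)
  }
  out$final <- majority_vote(out[, c("psvm", object$learners)])
  out
}

#' @export
glance.risk_ensemble <- function(x, ...) {
  tidyr::pivot_wider(x$cv_accuracy, names_from = "learner",
                     values_from = "cv_accuracy")
}
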