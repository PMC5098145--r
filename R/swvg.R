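#' Statistically weighted voting grouping (SWVg)
#'
#' Combines the univariate 0/1 risk calls of a signature into a per-patient
#' average weighted risk (AWR) score, AWR = sum_i w_i * s_i in \[0, 1\], and
#' stratifies the cohort into three risk classes by the pair of AWR thresholds
#' whose three-group log-rank p-value is smallest.
#'
#' @name swvg
NULL

#' Average weighted risk score
#'
#' @param pbvv a prognostic binary variable vector table from [build_pbvv()]:
#'   `patient_id` plus one 0/1 column per signature variable.
#' @param weights a `weight_vector` from [compute_weights()], aligned by
#'   variable name.
#' @param missing `"error"` (default) to reject missing risk calls, or
#'   `"renormalize"` to drop a patient's missing variables and renormalize the
#'   remaining weights (such patients are flagged in the `renormalized`
#'   column).
#' @return tibble with `patient_id`, `awr` (in \[0, 1\]) and, when
#'   `missing = "renormalize"`, a logical `renormalized` column.
#' @export
compute_awr <- function(pbvv, weights, missing = c("error", "renormalize")) {
  missing <- match.arg(missing)
  vars <- weights$variable
  if (!all(vars %in% names(pbvv))) {
    abort("`pbvv` lacks columns for some weighted variables")
  }
  bits <- as.matrix(pbvv[, vars, drop = FALSE])
  if (!all(bits %in% c(0, 1, NA))) abort("risk calls must be 0/1")
  w <- weights$weight
  has_na <- apply(bits, 1L, anyNA)
  if (any(has_na) && missing == "error") {
    abort("missing risk calls; use missing = 'renormalize' to drop them per patient")
  }
  if (any(has_na)) {
    awr <- vapply(seq_len(nrow(bits)), function(i) {
      ok <- !is.na(bits[i, ])
      if (!any(ok)) abort("a patient has no observed risk calls")
      sum(bits[i, ok] * w[ok]) / sum(w[ok])
    }, 0)
    out <- tibble(patient_id = pbvv$patient_id, awr = awr, renormalized = has_na)
  } else {
    out <- tibble(patient_id = pbvv$patient_id, awr = drop(bits %*% w))
    if (missing == "renormalize") out$renormalized <- FALSE
  }
  out
}

# Exhaustive search over ordered pairs of AWR midpoints minimizing the
# 3-group log-rank p; tie -> larger smallest group, then smaller thresholds.
awr_thresholds_core <- function(awr, prep, min_fraction = 0.10) {
  M <- length(awr)
  sv <- sort(unique(awr))
  if (length(sv) < 3) abort("need at least 3 distinct AWR values to place two thresholds")
  mids <- (sv[-length(sv)] + sv[-1]) / 2
  cnt_le <- findInterval(sv, sort(awr))[-length(sv)]  # patients <= each midpoint
  m <- ceiling(min_fraction * M)
  K <- length(mids)
  best <- NULL
  for (i in seq_len(K)) {
    n1 <- cnt_le[i]
    if (n1 < m || M - n1 < 2 * m) next
    js <- which(seq_len(K) > i & cnt_le - n1 >= m & M - cnt_le >= m)
    for (j in js) {
      lab <- findInterval(awr, c(mids[i], mids[j])) + 1L
      stat <- logrank_stat(prep, lab, 3L)
      sizes <- c(n1, cnt_le[j] - n1, M - cnt_le[j])
      cand <- list(stat = stat, min_size = min(sizes), i = i, j = j, sizes = sizes)
      if (is.null(best) ||
          stat > best$stat + 1e-10 ||
          (abs(stat - best$stat) <= 1e-10 && cand$min_size > best$min_size)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    abort("no admissible threshold pair; try a smaller `min_fraction`")
  }
  p <- pchisq(best$stat, df = 2, lower.tail = FALSE)
  list(
    t_low = mids[best$i], t_high = mids[best$j],
    logrank = structure(
      list(statistic = best$stat, df = 2L, p_value = p, n = M,
           groups = RISK_LEVELS, p_method = "asymptotic"),
      class = "logrank_test"
    ),
    group_sizes = best$sizes
  )
}

#' Optimal AWR thresholds for three risk groups
#'
#' Searches every ordered pair of candidate thresholds (midpoints between
#' distinct sorted AWR values) for the three-group split with the smallest
#' log-rank p-value, subject to each group holding at least
#' `ceiling(min_fraction * M)` patients.
#'
#' @inheritParams km_estimate
#' @param awr unquoted column holding the per-patient AWR score.
#' @param min_fraction minimum fraction of the cohort per risk group;
#'   default 0.10.
#' @return list with `t_low`, `t_high`, `logrank` (a `logrank_test`) and
#'   `group_sizes`.
#' @export
fit_awr_thresholds <- function(data, awr = awr, time = time, event = event,
                               min_fraction = 0.10) {
  aa <- dplyr::pull(data, {{ awr }})
  tt <- dplyr::pull(data, {{ time }})
  ee <- dplyr::pull(data, {{ event }})
  prep <- survival_prep(tt, ee)
  awr_thresholds_core(aa, prep, min_fraction)
}

#' Assign risk classes from AWR scores
#'
#' Boundary convention: `awr <= t_low` is low risk, `t_low < awr <= t_high`
#' intermediate, `awr > t_high` high risk.
#'
#' @param awr numeric AWR scores.
#' @param t_low,t_high fitted thresholds, `t_low < t_high`.
#' @return ordered factor of risk classes.
#' @export
assign_risk_class <- function(awr, t_low, t_high) {
  if (!(t_low < t_high)) abort("t_low must be smaller than t_high")
  cut(awr, breaks = c(-Inf, t_low, t_high, Inf), labels = RISK_LEVELS,
      right = TRUE, ordered_result = TRUE)
}

#' Fit the full weighted-voting risk stratification
#'
#' End-to-end training: fit (or accept) the univariate signature, compute the
#' scheme weights, call each patient's risk bits, average them into AWR, and
#' optimize the three-group thresholds. The fitted object carries everything
#' needed to classify new patients by AWR or by nearest-signature matching
#' ([predict_psvm()]).
#'
#' @inheritParams fit_ddg_signature
#' @param id unquoted column with unique patient identifiers.
#' @param signature optional pre-fitted `ddg_signature` (e.g.
#'   [hgsc_signature()]); when `NULL` it is fitted from `vars`.
#' @param vars tidyselect of variable columns (used when `signature` is NULL).
#' @param scheme weight scheme, `"A"`..`"F"`; default `"C"` (negative log p).
#' @param min_fraction_cutoff per-variable cutoff admissibility fraction
#'   (default 0.05).
#' @param min_fraction_group three-group threshold admissibility fraction
#'   (default 0.10).
#' @return an object of class `swvg_fit`.
#' @examples
#' co <- simulate_classed_cohort(n_patients = 150, n_variables = 10, seed = 1)
#' fit <- fit_swvg(co$data, signature = co$truth$signature, scheme = "A")
#' glance(fit)
#' @export
fit_swvg <- function(data, vars = NULL, signature = NULL, scheme = "C",
                     id = patient_id, time = time, event = event,
                     min_fraction_cutoff = 0.05, min_fraction_group = 0.10,
                     ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (is.null(signature)) {
    signature <- fit_ddg_signature(data, {{ vars }}, time = {{ time }},
                                   event = {{ event }},
                                   min_fraction = min_fraction_cutoff,
                                   ties = ties)
  } else {
    signature <- as_signature(signature)
  }
  weights <- compute_weights(signature, scheme)
  pbvv <- build_pbvv(data, signature, id = {{ id }})
  awr_tbl <- compute_awr(pbvv, weights)
  tt <- dplyr::pull(data, {{ time }})
  ee <- dplyr::pull(data, {{ event }})
  prep <- survival_prep(tt, ee)
  thr <- awr_thresholds_core(awr_tbl$awr, prep, min_fraction_group)
  classes <- assign_risk_class(awr_tbl$awr, thr$t_low, thr$t_high)
  assignments <- tibble(
    patient_id = awr_tbl$patient_id,
    time = tt, event = ee,
    awr = awr_tbl$awr, risk_class = classes
  )
  psv <- pbvv_to_psv(pbvv, weights)
  structure(
    list(
      signature = signature, weights = weights, scheme = attr(weights, "scheme"),
      t_low = thr$t_low, t_high = thr$t_high,
      training_logrank = thr$logrank, group_sizes = thr$group_sizes,
      assignments = assignments,
      reference_psv = psv, reference_class = classes,
      min_fraction_cutoff = min_fraction_cutoff,
      min_fraction_group = min_fraction_group
    ),
    class = "swvg_fit"
  )
}

#' @export
print.swvg_fit <- function(x, ...) {
  cat(sprintf(
    "SWVg fit: %d variables, scheme %s; thresholds (%.4g, %.4g); groups %s; log-rank p = %.3g\n",
    nrow(x$signature), x$scheme, x$t_low, x$t_high,
    paste(x$group_sizes, collapse = "/"), x$training_logrank$p_value
  ))
  invisible(x)
}

#' @export
tidy.swvg_fit <- function(x, ...) x$assignments

#' @export
glance.swvg_fit <- function(x, ...) {
  tibble(
    n = nrow(x$assignments), n_variables = nrow(x$signature),
    scheme = x$scheme, t_low = x$t_low, t_high = x$t_high,
    logrank_statistic = x$training_logrank$statistic,
    logrank_p = x$training_logrank$p_value
  )
}

#' Classify new patients with a fitted SWVg model
#'
#' @param object an `swvg_fit`.
#' @param new_data a data frame holding the signature variables (and
#'   `patient_id`).
#' @param method `"awr"` (threshold the patient's AWR score, default) or
#'   `"psvm"` (nearest-reference signature matching, see [predict_psvm()]).
#' @param missing missing-value policy passed to [build_pbvv()].
#' @param ... ignored.
#' @return tibble with `patient_id`, `awr` (for `method = "awr"`) or the
#'   match columns (for `"psvm"`), and `risk_class`.
#' @export
predict.swvg_fit <- function(object, new_data, method = c("awr", "psvm"),
                             missing = c("error", "median"), ...) {
  method <- match.arg(method)
  missing <- match.arg(missing)
  if (method == "psvm") return(predict_psvm(object, new_data, missing = missing))
  pbvv <- build_pbvv(new_data, object$signature, missing = missing)
  awr_tbl <- compute_awr(pbvv, object$weights)
  awr_tbl$risk_class <- assign_risk_class(awr_tbl$awr, object$t_low, object$t_high)
  awr_tbl
}

#' Kaplan-Meier curves of the fitted risk groups
#'
#' @param object an `swvg_fit`
#' @param ... ignored
#' @return a ggplot object with one survival step-curve per risk class.
#' @export
autoplot.swvg_fit <- function(object, ...) {
  plot_km_by_group(object$assignments, group = risk_class) +
    ggplot2::labs(colour = "risk class")
}

#' Kaplan-Meier step curves by group
#'
#' @inheritParams logrank_test
#' @return a ggplot object.
#' @export
plot_km_by_group <- function(data, group, time = time, event = event) {
  df <- tibble(
    time = dplyr::pull(data, {{ time }}),
    event = dplyr::pull(data, {{ event }}),
    group = dplyr::pull(data, {{ group }})
  )
  curves <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      km <- km_estimate(d)
      tibble(
        time = c(0, rep(km$time, each = 2)),
        estimate = c(1, 1, rep(km$estimate, each = 2)[-(2 * nrow(km))])
      )
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time, y = .data$estimate,
                               colour = .data$group)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability")
}
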