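#' Prognostic signature vector matching (PSVM)
#'
#' Personalized risk prediction: encode each patient as the binary vector of
#' univariate risk calls (PBVV), transform it to a prognostic signature vector
#' (PSV) whose nonzero components are the reverse ranks of the variables by
#' weight, and give a query patient the risk class of its Euclidean-nearest
#' reference patient. Distances are computed on un-scaled PSVs; standardized
#' features are used only by the classical learners of the ensemble layer.
#'
#' @name psvm
NULL

#' Build the prognostic binary variable vector (PBVV) table
#'
#' Applies every fitted univariate cutoff/design of a signature to a cohort,
#' yielding one 0/1 risk call per patient per variable.
#'
#' @param data data frame holding the signature variables, one row per
#'   patient; a `patient_id` column is used as identifier when present
#'   (row-numbered ids are synthesized otherwise).
#' @param signature a `ddg_signature` table.
#' @param id unquoted patient-identifier column.
#' @param missing `"error"` (default) to reject missing variable values, or
#'   `"median"` to impute a missing value with that variable's cohort median
#'   (with a warning).
#' @return tibble with `patient_id` plus one integer 0/1 column per signature
#'   variable, in signature order.
#' @export
build_pbvv <- function(data, signature, id = patient_id,
                       missing = c("error", "median")) {
  missing <- match.arg(missing)
  signature <- as_signature(signature)
  id_name <- as_name(enquo(id))
  ids <- if (id_name %in% names(data)) {
    as.character(data[[id_name]])
  } else if (id_name == "patient_id") {
    sprintf("p%03d", seq_len(nrow(data)))
  } else {
    abort(sprintf("id column '%s' not found", id_name))
  }
  if (anyDuplicated(ids)) abort("patient ids must be unique")
  absent <- setdiff(signature$variable, names(data))
  if (length(absent)) {
    abort(paste("data lacks signature variables:", paste(absent, collapse = ", ")))
  }
  bits <- lapply(seq_len(nrow(signature)), function(i) {
    v <- signature$variable[i]
    vals <- data[[v]]
    if (anyNA(vals)) {
      if (missing == "error") {
        abort(sprintf("variable '%s' has missing values; use missing = 'median'", v))
      }
      warn(sprintf("imputing %d missing value(s) of '%s' with the cohort median",
                   sum(is.na(vals)), v))
      vals[is.na(vals)] <- median(vals, na.rm = TRUE)
    }
    apply_ddg(list(cutoff = signature$cutoff[i], design = signature$design[i]), vals)
  })
  names(bits) <- signature$variable
  dplyr::bind_cols(tibble(patient_id = ids), as_tibble(bits))
}

#' Convert risk bits to prognostic signature vectors (PSV)
#'
#' Variables are ranked by descending weight (rank 1 = most important; tied
#' weights share the minimum rank, so equally important variables contribute
#' equally to the matching distance). Component i of the PSV is
#' `bit_i * (n - rank_i + 1)` — the reverse rank where the bit is set, zero
#' elsewhere — so more important variables push matched patients further
#' apart. Setting `type = "weight"` uses `bit_i * weight_i` instead, for
#' sensitivity analysis.
#'
#' @param pbvv a PBVV table from [build_pbvv()].
#' @param weights an aligned `weight_vector`.
#' @param type `"rank"` (default) or `"weight"`.
#' @return tibble with `patient_id` plus one numeric component column per
#'   variable; attribute `psv_type` records the transform.
#' @export
pbvv_to_psv <- function(pbvv, weights, type = c("rank", "weight")) {
  type <- match.arg(type)
  vars <- weights$variable
  if (!all(vars %in% names(pbvv))) abort("`pbvv` lacks columns for some weighted variables")
  bits <- as.matrix(pbvv[, vars, drop = FALSE])
  n <- length(vars)
  score <- if (type == "rank") {
    r <- rank(-weights$weight, ties.method = "min")
    n - r + 1
  } else {
    weights$weight
  }
  comp <- sweep(bits, 2L, score, `*`)
  out <- dplyr::bind_cols(tibble(patient_id = pbvv$patient_id),
                          as_tibble(as.data.frame(comp)))
  attr(out, "psv_type") <- type
  out
}

#' Match query patients to their Euclidean-nearest reference
#'
#' @param query_psv,reference_psv PSV tables from [pbvv_to_psv()] with
#'   identical component columns (reference columns are aligned to the query's
#'   order by name).
#' @param reference_class risk classes of the reference patients (coercible
#'   with [risk_factor()]).
#' @return tibble with `query_id`, `reference_id`, `distance` and
#'   `predicted_class`. When several references tie at the minimal distance
#'   the majority risk class among them wins (residual tie: the lowest risk
#'   class); the reported `reference_id` is the first tied reference of the
#'   winning class.
#' @export
match_nearest <- function(query_psv, reference_psv, reference_class) {
  if (nrow(reference_psv) == 0) abort("reference set is empty")
  vars <- setdiff(names(query_psv), "patient_id")
  if (!setequal(vars, setdiff(names(reference_psv), "patient_id"))) {
    abort("query and reference PSVs have different components")
  }
  cls <- risk_factor(reference_class)
  if (length(cls) != nrow(reference_psv)) abort("one class per reference patient required")
  Q <- as.matrix(query_psv[, vars, drop = FALSE])
  R <- as.matrix(reference_psv[, vars, drop = FALSE])
  res <- lapply(seq_len(nrow(Q)), function(i) {
    d <- sqrt(colSums((t(R) - Q[i, ])^2))
    dmin <- min(d)
    tied <- which(d <= dmin + 1e-12)
    if (length(tied) == 1L) {
      pred <- cls[tied]
      ref <- tied
    } else {
      tab <- table(cls[tied])
      winners <- names(tab)[tab == max(tab)]
      pred_chr <- RISK_LEVELS[min(match(winners, RISK_LEVELS))]  # lowest risk on residual tie
      pred <- risk_factor(pred_chr)
      ref <- tied[which(cls[tied] == pred_chr)[1]]
    }
    tibble(
      query_id = query_psv$patient_id[i],
      reference_id = reference_psv$patient_id[ref],
      distance = dmin,
      predicted_class = pred
    )
  })
  dplyr::bind_rows(res)
}

#' Personalized risk prediction by signature matching
#'
#' Full PSVM pipeline for new patients: univariate risk calls with the fitted
#' cutoffs/designs, PSV transform with the fitted weight ranking, and
#' Euclidean nearest-reference matching against the training cohort.
#'
#' @param object an `swvg_fit` from [fit_swvg()] (or a list with `signature`,
#'   `weights`, `reference_psv`, `reference_class`).
#' @param new_data data frame of query patients holding the signature
#'   variables.
#' @param missing missing-value policy for [build_pbvv()].
#' @return tibble with `patient_id`, `reference_id`, `distance`,
#'   `risk_class`.
#' @examples
#' co <- simulate_classed_cohort(n_patients = 150, n_variables = 10, seed = 1)
#' fit <- fit_swvg(co$data, signature = co$truth$signature, scheme = "A")
#' predict_psvm(fit, co$data[1:5, ])
#' @export
predict_psvm <- function(object, new_data, missing = c("error", "median")) {
  missing <- match.arg(missing)
  pbvv <- build_pbvv(new_data, object$signature, missing = missing)
  psv_type <- attr(object$reference_psv, "psv_type") %||% "rank"
  psv <- pbvv_to_psv(pbvv, object$weights, type = psv_type)
  m <- match_nearest(psv, object$reference_psv, object$reference_class)
  tibble(
    patient_id = m$query_id,
    reference_id = m$reference_id,
    distance = m$distance,
    risk_class = m$predicted_class
  )
}
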