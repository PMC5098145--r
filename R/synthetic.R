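#' Synthetic survival cohorts with planted prognostic structure
#'
#' Two seeded generators emulate the statistical structure the univariate
#' classifier assumes — dichotomous risk acting multiplicatively on the
#' hazard — so every layer of the package can be exercised and benchmarked
#' without any real-cohort download.
#'
#' * [simulate_cohort()] plants a cutoff/design/log-hazard-ratio per variable
#'   and draws event times from the induced per-patient hazard.
#' * [simulate_classed_cohort()] plants three risk classes directly (class
#'   hazard ratios 1:2:4 by default) and draws each patient's risk bits so
#'   the class AWR centers sit where requested.
#'
#' @name synthetic
NULL

#' Simulate a cohort with planted per-variable hazard structure
#'
#' Variable values are Uniform(value_min, value_max); each variable carries a
#' planted cutoff and design giving a 0/1 risk call s_i, and a patient's
#' hazard is `baseline_hazard * exp(sum_i log_hr_i * s_i)`. Event times are
#' exponential given the hazard (memoryless, so the planted hazard ratios are
#' exact; Weibull optional); censoring times are independent exponential with
#' rate `censoring_rate`.
#'
#' @param n_patients,n_variables cohort dimensions.
#' @param cutoffs planted cutoffs, recycled over variables; default the
#'   mid-range value.
#' @param designs planted designs (1 or 2), recycled; default 2 (low values
#'   low-risk).
#' @param log_hr planted log hazard ratios (>= 0), recycled; default log(2).
#' @param baseline_hazard baseline event rate per time unit (default 0.1).
#' @param censoring_rate rate of the independent exponential censoring time
#'   (default 0.05, about a third of patients censored); 0 disables
#'   censoring.
#' @param value_min,value_max range of the uniform variable values.
#' @param event_dist `"exponential"` (default) or `"weibull"`.
#' @param weibull_shape shape for `event_dist = "weibull"`.
#' @param seed mandatory RNG seed; the same seed reproduces the cohort
#'   bit-identically.
#' @return an object of class `sim_cohort`: list with `data` (tibble
#'   `patient_id`, `time`, `event`, `v1`..`vK`) and `truth` (planted
#'   `signature` table, per-patient `risk_calls`, `linear_predictor`, and a
#'   tertile-based 3-level `class`).
#' @export
simulate_cohort <- function(n_patients = 300, n_variables = 5,
                            cutoffs = NULL, designs = 2L, log_hr = log(2),
                            baseline_hazard = 0.1, censoring_rate = 0.05,
                            value_min = 0, value_max = 10,
                            event_dist = c("exponential", "weibull"),
                            weibull_shape = 1.5, seed) {
  event_dist <- match.arg(event_dist)
  if (missing(seed)) abort("`seed` is mandatory")
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be positive")
  if (censoring_rate < 0) abort("`censoring_rate` must be >= 0")
  if (any(log_hr < 0)) abort("`log_hr` must be >= 0; risk direction is set by `designs`")
  cutoffs <- rep_len(cutoffs %||% (value_min + value_max) / 2, n_variables)
  designs <- as.integer(rep_len(designs, n_variables))
  if (!all(designs %in% c(1L, 2L))) abort("designs must be 1 or 2")
  log_hr <- rep_len(log_hr, n_variables)
  if (censoring_rate > 0 &&
      n_patients * baseline_hazard / (baseline_hazard + censoring_rate) < 1) {
    abort("infeasible: censoring rate leaves fewer than one expected event")
  }

  withr::with_seed(seed, {
    vals <- matrix(runif(n_patients * n_variables, value_min, value_max),
                   n_patients, n_variables)
    bits <- vapply(seq_len(n_variables), function(i) {
      apply_ddg(list(cutoff = cutoffs[i], design = designs[i]), vals[, i])
    }, integer(n_patients))
    bits <- matrix(bits, n_patients, n_variables)
    lp <- drop(bits %*% log_hr)
    hazard <- baseline_hazard * exp(lp)
    t_event <- rexp(n_patients, hazard)
    if (event_dist == "weibull") t_event <- t_event^(1 / weibull_shape)
    t_cens <- if (censoring_rate > 0) rexp(n_patients, censoring_rate) else Inf
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    if (sum(event) == 0) abort("simulated cohort has no events; lower the censoring rate")

    var_names <- paste0("v", seq_len(n_variables))
    colnames(vals) <- var_names
    colnames(bits) <- var_names
    ids <- sprintf("p%04d", seq_len(n_patients))
    sig <- as_signature(tibble(
      variable = var_names, description = NA_character_,
      wald_p = NA_real_, cutoff = cutoffs, design = designs,
      behaviour = ifelse(designs == 2L, "onco-like", "supp-like"),
      hazard_ratio = exp(log_hr),
      n_low_risk = NA_integer_, n_high_risk = NA_integer_
    ))
    # tertiles of the planted linear predictor, a convention for 3-group
    # tests; undefined (NA) when too few distinct risk profiles exist
    br <- unique(quantile(lp, c(0, 1 / 3, 2 / 3, 1)))
    cls <- if (length(br) == 4) {
      cut(lp, breaks = br, labels = RISK_LEVELS, include.lowest = TRUE,
          ordered_result = TRUE)
    } else {
      factor(rep(NA_character_, n_patients), levels = RISK_LEVELS,
             ordered = TRUE)
    }
    structure(
      list(
        data = dplyr::bind_cols(
          tibble(patient_id = ids, time = time, event = event),
          as_tibble(as.data.frame(vals))
        ),
        truth = list(
          signature = sig,
          risk_calls = dplyr::bind_cols(tibble(patient_id = ids),
                                        as_tibble(as.data.frame(bits))),
          linear_predictor = lp,
          class = cls
        ),
        seed = seed
      ),
      class = "sim_cohort"
    )
  })
}

#' Simulate a cohort with three planted risk classes
#'
#' Patients are assigned to low/intermediate/high risk classes in fixed
#' proportions; each patient's risk bits are Bernoulli draws centered at the
#' class AWR center, and variable values are drawn uniformly on the matching
#' side of a planted mid-range cutoff (design 2), so the generating bits are
#' exactly recoverable from the values. Event times are exponential with the
#' class hazard.
#'
#' @param n_patients,n_variables cohort dimensions (default 37 variables, the
#'   size of the packaged signature).
#' @param class_props proportions of the low/intermediate/high classes;
#'   default `c(0.556, 0.327, 0.117)`, the class ratios maintained by the
#'   stratified cross-validation folds.
#' @param awr_centers per-class expected AWR under equal weights; default
#'   `c(0.2, 0.5, 0.8)`.
#' @param hazard_ratios per-class hazard multipliers, default `c(1, 2, 4)`.
#' @param baseline_hazard,censoring_rate,seed as in [simulate_cohort()].
#' @return an object of class `sim_cohort`; `truth$class` holds the planted
#'   class of every patient.
#' @export
simulate_classed_cohort <- function(n_patients = 300, n_variables = 37,
                                    class_props = c(0.556, 0.327, 0.117),
                                    awr_centers = c(0.2, 0.5, 0.8),
                                    hazard_ratios = c(1, 2, 4),
                                    baseline_hazard = 0.1,
                                    censoring_rate = 0.05, seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (length(class_props) != 3 || length(awr_centers) != 3 ||
      length(hazard_ratios) != 3) {
    abort("class_props, awr_centers and hazard_ratios must have length 3")
  }
  if (any(class_props <= 0)) abort("class proportions must be positive")
  if (any(awr_centers <= 0 | awr_centers >= 1)) abort("awr_centers must be in (0,1)")

  withr::with_seed(seed, {
    props <- class_props / sum(class_props)
    counts <- floor(n_patients * props)
    counts[1] <- n_patients - sum(counts[-1])
    cls_idx <- sample(rep.int(1:3, counts))
    bits <- matrix(
      rbinom(n_patients * n_variables, 1L, awr_centers[cls_idx]),
      n_patients, n_variables
    )
    # values consistent with a mid-range cutoff at 5, design 2
    vals <- matrix(runif(n_patients * n_variables, 0, 5), n_patients, n_variables)
    vals <- vals + 5 * bits
    hazard <- baseline_hazard * hazard_ratios[cls_idx]
    t_event <- rexp(n_patients, hazard)
    t_cens <- if (censoring_rate > 0) rexp(n_patients, censoring_rate) else Inf
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    if (sum(event) == 0) abort("simulated cohort has no events; lower the censoring rate")

    var_names <- paste0("v", seq_len(n_variables))
    colnames(vals) <- var_names
    colnames(bits) <- var_names
    ids <- sprintf("p%04d", seq_len(n_patients))
    sig <- as_signature(tibble(
      variable = var_names, description = NA_character_,
      wald_p = NA_real_, cutoff = rep(5, n_variables),
      design = rep(2L, n_variables),
      behaviour = rep("onco-like", n_variables),
      hazard_ratio = NA_real_,
      n_low_risk = NA_integer_, n_high_risk = NA_integer_
    ))
    structure(
      list(
        data = dplyr::bind_cols(
          tibble(patient_id = ids, time = time, event = event),
          as_tibble(as.data.frame(vals))
        ),
        truth = list(
          signature = sig,
          risk_calls = dplyr::bind_cols(tibble(patient_id = ids),
                                        as_tibble(as.data.frame(bits))),
          class = factor(RISK_LEVELS[cls_idx], levels = RISK_LEVELS,
                         ordered = TRUE)
        ),
        seed = seed
      ),
      class = "sim_cohort"
    )
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d variables, %d events (seed %s)\n",
              nrow(x$data), nrow(x$truth$signature), sum(x$data$event),
              format(x$seed)))
  invisible(x)
}
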