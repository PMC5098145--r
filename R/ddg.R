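#' One-dimensional data-driven grouping (1D-DDg)
#'
#' The univariate prognostic classifier: scan every admissible cutoff of one
#' continuous variable, dichotomize the cohort at each cutoff, fit the binary
#' Cox model, and keep the cutoff whose Wald p-value is smallest. The "design"
#' records the direction of risk at the chosen cutoff: design 1 means low
#' values carry the high risk ("supp-like" behaviour), design 2 means low
#' values carry the low risk ("onco-like").
#'
#' @name ddg
NULL

#' Admissible cutoff candidates for a continuous variable
#'
#' Midpoints between consecutive distinct sorted values, restricted so that
#' both sides of every returned cutoff contain at least
#' `ceiling(min_fraction * M)` patients.
#'
#' @param values numeric vector of the variable across the cohort.
#' @param min_fraction minimum fraction of the cohort on each side of a
#'   cutoff, in (0, 0.5). Default 0.05.
#' @return increasing numeric vector of candidate cutoffs; empty if the
#'   variable is degenerate (all values identical) or no split is admissible.
#' @examples
#' candidate_cutoffs(c(1, 2, 3, 4), min_fraction = 0.25)
#' @export
candidate_cutoffs <- function(values, min_fraction = 0.05) {
  if (anyNA(values) || any(!is.finite(values))) abort("values must be finite and non-missing")
  if (min_fraction <= 0 || min_fraction >= 0.5) abort("`min_fraction` must be in (0, 0.5)")
  sv <- sort(unique(values))
  if (length(sv) < 2) return(numeric(0))
  m <- ceiling(min_fraction * length(values))
  cnt_le <- findInterval(sv, sort(values))       # patients with value <= sv[i]
  mids <- (sv[-length(sv)] + sv[-1]) / 2
  ok <- cnt_le[-length(sv)] >= m & (length(values) - cnt_le[-length(sv)]) >= m
  mids[ok]
}

# Scan all candidate cutoffs of one variable against a prepared risk-set
# structure; returns the minimal-p model. Tie on p -> most balanced split,
# residual tie -> smaller cutoff.
ddg_core <- function(values, prep, min_fraction = 0.05, ties = "breslow",
                     variable = "x") {
  cuts <- candidate_cutoffs(values, min_fraction)
  if (length(cuts) == 0) {
    abort(sprintf("variable '%s' is degenerate or has no admissible cutoff", variable))
  }
  M <- length(values)
  stats <- vapply(cuts, function(ct) {
    fit <- cox_core(prep, as.numeric(values > ct), ties = ties)
    c(fit$beta, fit$se, fit$wald_p)
  }, numeric(3))
  p <- stats[3, ]
  n_le <- vapply(cuts, function(ct) sum(values <= ct), 0L)
  tied <- which(p <= min(p) + 1e-15)
  balance <- pmin(n_le[tied], M - n_le[tied])
  best <- tied[which.max(balance)]     # first max = smallest cutoff on residual tie
  beta <- stats[1, best]
  design <- if (beta >= 0) 2L else 1L  # sign of beta for indicator(value > cutoff)
  n_gt <- M - n_le[best]
  structure(
    list(
      variable = variable,
      cutoff = cuts[best],
      design = design,
      behaviour = if (design == 2L) "onco-like" else "supp-like",
      wald_p = p[best],
      hazard_ratio = exp(abs(beta)),
      beta = beta,
      se = stats[2, best],
      n_low_risk = if (design == 2L) n_le[best] else n_gt,
      n_high_risk = if (design == 2L) n_gt else n_le[best],
      n = M,
      min_fraction = min_fraction,
      ties = ties,
      n_cutoffs = length(cuts)
    ),
    class = "ddg_fit"
  )
}

#' Fit the 1D-DDg optimal-cutoff classifier for one variable
#'
#' @inheritParams km_estimate
#' @param var unquoted column holding the continuous variable to dichotomize.
#' @param min_fraction minimum fraction of patients on each side of the
#'   cutoff; default 0.05.
#' @param ties Cox tie handling, `"breslow"` (default) or `"efron"`.
#' @return an object of class `ddg_fit`: list with `variable`, `cutoff`,
#'   `design` (1 = low values high-risk, 2 = low values low-risk),
#'   `behaviour`, `wald_p`, `hazard_ratio` (always >= 1, high-risk vs
#'   low-risk), `n_low_risk`, `n_high_risk`.
#' @examples
#' co <- simulate_cohort(n_patients = 120, n_variables = 1, seed = 7)
#' fit_ddg(co$data, var = v1)
#' @export
fit_ddg <- function(data, var, time = time, event = event,
                    min_fraction = 0.05, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  values <- dplyr::pull(data, {{ var }})
  if (anyNA(values) || any(!is.finite(values))) abort("variable values must be finite and non-missing")
  tt <- dplyr::pull(data, {{ time }})
  ee <- dplyr::pull(data, {{ event }})
  prep <- survival_prep(tt, ee)
  ddg_core(values, prep, min_fraction, ties, variable = as_name(enquo(var)))
}

#' @export
print.ddg_fit <- function(x, ...) {
  cat(sprintf(
    "1D-DDg fit for '%s': cutoff %.4g, design %d (%s), HR %.3f, Wald p %.3g [%d low / %d high risk]\n",
    x$variable, x$cutoff, x$design, x$behaviour, x$hazard_ratio, x$wald_p,
    x$n_low_risk, x$n_high_risk
  ))
  invisible(x)
}

#' @export
tidy.ddg_fit <- function(x, ...) {
  tibble(
    variable = x$variable, description = NA_character_, wald_p = x$wald_p,
    cutoff = x$cutoff, design = x$design, behaviour = x$behaviour,
    hazard_ratio = x$hazard_ratio, n_low_risk = x$n_low_risk,
    n_high_risk = x$n_high_risk
  )
}

#' Fit 1D-DDg classifiers for a set of variables
#'
#' Runs [fit_ddg()] on each selected column and collects the fitted parameters
#' into a signature table (one row per variable), the shape consumed by
#' [compute_weights()], [build_pbvv()] and [fit_swvg()].
#'
#' @inheritParams fit_ddg
#' @param vars tidyselect specification of the variable columns, e.g.
#'   `c(v1, v2)` or `dplyr::starts_with("v")`.
#' @return a `ddg_signature` tibble with columns `variable`, `description`,
#'   `wald_p`, `cutoff`, `design`, `behaviour`, `hazard_ratio`, `n_low_risk`,
#'   `n_high_risk`.
#' @export
fit_ddg_signature <- function(data, vars, time = time, event = event,
                              min_fraction = 0.05, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  var_names <- names(dplyr::select(data, {{ vars }}))
  if (length(var_names) == 0) abort("no variables selected")
  tt <- dplyr::pull(data, {{ time }})
  ee <- dplyr::pull(data, {{ event }})
  prep <- survival_prep(tt, ee)
  rows <- purrr::map(var_names, function(v) {
    values <- data[[v]]
    if (anyNA(values) || any(!is.finite(values))) {
      abort(sprintf("variable '%s' has missing or non-finite values", v))
    }
    tidy(ddg_core(values, prep, min_fraction, ties, variable = v))
  })
  sig <- dplyr::bind_rows(rows)
  as_signature(sig)
}

as_signature <- function(sig) {
  needed <- c("variable", "wald_p", "cutoff", "design", "hazard_ratio")
  missing_cols <- setdiff(needed, names(sig))
  if (length(missing_cols)) {
    abort(paste("signature table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(sig$variable)) abort("duplicated variable in signature")
  if (!all(sig$design %in% c(1L, 2L))) abort("signature design must be 1 or 2")
  sig <- as_tibble(sig)
  class(sig) <- unique(c("ddg_signature", class(sig)))
  sig
}

#' Apply a fitted 1D-DDg model to new values
#'
#' Converts continuous values into 0/1 risk calls using the model's cutoff and
#' design. Values exactly at the cutoff fall on the "low side" of the split
#' (`<= cutoff`), so they are called low-risk under design 2 and high-risk
#' under design 1.
#'
#' @param model a `ddg_fit`, or any list/one-row data frame with `cutoff` and
#'   `design` elements (e.g. a signature row).
#' @param values numeric vector of new values.
#' @return integer vector of risk calls, 1 = high risk, 0 = low risk.
#' @export
apply_ddg <- function(model, values) {
  if (anyNA(values) || any(!is.finite(values))) abort("values must be finite and non-missing")
  cutoff <- model$cutoff
  design <- model$design
  if (!design %in% c(1L, 2L)) abort("design must be 1 or 2")
  if (design == 2L) as.integer(values > cutoff) else as.integer(values <= cutoff)
}

# ---- signature table I/O -----------------------------------------------------

#' Read and write prognostic signature tables
#'
#' Signature tables are tab-separated with columns `variable`, `description`,
#' `wald_p`, `cutoff`, `design`, `behaviour`, `hazard_ratio`, `n_low_risk`,
#' `n_high_risk`. Doubles are written at full precision so a written table
#' reads back bit-exactly.
#'
#' @param sig a `ddg_signature` tibble.
#' @param path file path.
#' @return `read_signature()` returns a `ddg_signature` tibble;
#'   `write_signature()` returns `path` invisibly.
#' @export
write_signature <- function(sig, path) {
  sig <- as_signature(sig)
  out <- as.data.frame(sig)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  # base R parser: correctly rounded string -> double, so full-precision
  # tables round-trip bit-exactly
  classes <- c(
    variable = "character", description = "character", wald_p = "numeric",
    cutoff = "numeric", design = "integer", behaviour = "character",
    hazard_ratio = "numeric", n_low_risk = "integer", n_high_risk = "integer"
  )
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  sig <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = unname(classes[hdr]))
  as_signature(as_tibble(sig))
}

#' The published 37-variable ovarian-cancer prognostic signature
#'
#' Fitted 1D-DDg parameters (optimal cutoff, design, Wald p-value, hazard
#' ratio and risk-subgroup sizes) for 36 prognostic mRNA probes plus age at
#' diagnosis, estimated on a training cohort of 349 TCGA high-grade serous
#' ovarian carcinoma patients. Ships with the package as a plain-text fixture
#' so the weighting and matching layers can be exercised without any data
#' download.
#'
#' @return a `ddg_signature` tibble with 37 rows.
#' @examples
#' sig <- hgsc_signature()
#' nrow(sig)
#' @export
hgsc_signature <- function() {
  read_signature(system.file("extdata", "hgsc_signature_37.tsv",
                             package = "psvmatch", mustWork = TRUE))
}
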