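#' Prognostic variable weight schemes
#'
#' Six ways of quantifying the relative importance of each signature variable
#' from its univariate Wald p-value (P) and hazard ratio (HR):
#'
#' * **A** constant (all variables equally important)
#' * **B** inverse p-value, 1/P
#' * **C** negative log p-value, -log(P)
#' * **D** hazard ratio, HR
#' * **E** combination of -log(P) and HR by elementwise product
#' * **F** combination of -log(P) and HR by (mean) summation
#'
#' For schemes E and F each component vector (-log P and HR) is first
#' normalized to sum 1 before combination, putting the two quantities on a
#' common scale so the multiplicative/additive combination is comparable; this
#' also makes every scheme invariant to the base of the logarithm. The final
#' weight vector is always renormalized to sum 1.
#'
#' @name weights
NULL

WEIGHT_SCHEMES <- c("A", "B", "C", "D", "E", "F")

#' Compute normalized prognostic variable weights
#'
#' @param signature a data frame with columns `variable`, `wald_p` and
#'   `hazard_ratio` (e.g. a `ddg_signature` from [fit_ddg_signature()] or
#'   [hgsc_signature()]).
#' @param scheme one of `"A"`..`"F"` (see Details above); default `"C"`,
#'   the negative-log-p weighting used for risk averaging and signature
#'   ranking.
#' @param log_base base of the logarithm for schemes C, E, F. The default is
#'   the natural log; the normalized weights do not depend on this choice.
#' @return a `weight_vector` tibble with columns `variable` and `weight`
#'   (positive, summing to 1) and attribute `scheme`.
#' @examples
#' compute_weights(hgsc_signature(), scheme = "B")
#' @export
compute_weights <- function(signature, scheme = "C", log_base = exp(1)) {
  scheme <- match.arg(toupper(scheme), WEIGHT_SCHEMES)
  if (!all(c("variable", "wald_p", "hazard_ratio") %in% names(signature))) {
    abort("`signature` needs columns variable, wald_p, hazard_ratio")
  }
  p <- signature$wald_p
  hr <- signature$hazard_ratio
  if (length(p) < 1) abort("signature is empty")
  uses_p <- scheme %in% c("B", "C", "E", "F")
  uses_hr <- scheme %in% c("D", "E", "F")
  if (uses_p) {
    if (anyNA(p)) abort("signature has missing wald_p values")
    if (any(p == 0)) {
      warn("p-values of 0 floored at 1e-300")
      p[p == 0] <- 1e-300
    }
    if (any(p <= 0 | p >= 1)) abort("p-values must lie strictly inside (0, 1)")
  }
  if (uses_hr) {
    if (anyNA(hr)) abort("signature has missing hazard_ratio values")
    if (any(hr <= 0)) abort("hazard ratios must be positive")
  }

  norm1 <- function(x) x / sum(x)
  raw <- switch(scheme,
    A = rep(1, length(p)),
    B = 1 / p,
    C = -log(p, base = log_base),
    D = hr,
    E = norm1(-log(p, base = log_base)) * norm1(hr),
    F = (norm1(-log(p, base = log_base)) + norm1(hr)) / 2
  )
  out <- tibble(variable = signature$variable, weight = norm1(raw))
  class(out) <- unique(c("weight_vector", class(out)))
  attr(out, "scheme") <- scheme
  out
}

#' Dynamic range of a weight vector
#'
#' Ratio of the largest to the smallest weight; a measure of how concentrated
#' the multivariate classifier's attention is on its top variables.
#'
#' @param w a `weight_vector` (or any data frame with a `weight` column).
#' @return positive scalar `max(weight) / min(weight)`.
#' @examples
#' weight_dynamic_range(compute_weights(hgsc_signature(), "B"))
#' @export
weight_dynamic_range <- function(w) {
  if (!"weight" %in% names(w)) abort("`w` needs a `weight` column")
  max(w$weight) / min(w$weight)
}
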