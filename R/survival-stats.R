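#' Foundational survival statistics
#'
#' Kaplan-Meier estimation, the k-group log-rank test and a single
#' binary-covariate Cox proportional-hazards fit with Wald test. These are the
#' primitives every classification layer builds on; they are implemented
#' directly (Newton-Raphson partial likelihood, closed-form score/information
#' for a binary covariate) so that the optimal-cutoff scans can evaluate
#' thousands of candidate dichotomizations quickly.
#'
#' @name survival-stats
NULL

# ---- validation & shared precomputation --------------------------------------

check_survival <- function(time, event, ids = NULL) {
  if (length(time) == 0L) abort("empty cohort: no patients")
  if (length(time) != length(event)) abort("`time` and `event` lengths differ")
  if (anyNA(time) || anyNA(event)) abort("survival times/events must not be NA")
  if (any(time <= 0)) abort("survival times must be strictly positive")
  if (!all(event %in% c(0, 1))) abort("event indicators must be 0 (censored) or 1 (death)")
  if (!is.null(ids)) {
    if (length(ids) != length(time)) abort("`ids` length differs from `time`")
    if (anyDuplicated(ids)) abort("patient ids must be unique")
  }
  invisible(TRUE)
}

# Precompute the sorted risk-set structure shared by the log-rank and Cox
# routines. All quantities are in time-ascending order.
survival_prep <- function(time, event) {
  check_survival(time, event)
  if (sum(event) == 0) abort("no events: all patients censored")
  ord <- order(time)
  ts <- time[ord]
  ev <- event[ord]
  et <- unique(ts[ev == 1])            # distinct event times, ascending
  E <- length(et)
  pos <- match(et, ts)                 # first sorted index at each event time
  ev_idx <- which(ev == 1)
  etid <- match(ts[ev_idx], et)        # event-time id per event patient
  d <- tabulate(etid, nbins = E)       # deaths at each event time
  n_risk <- length(ts) - (pos - 1L)    # at-risk counts
  # (j, l) expansion for the Efron tie correction
  jj <- rep.int(seq_len(E), d)
  frac <- (unlist(lapply(d, seq_len), use.names = FALSE) - 1) / jj_d(d)
  list(
    n = length(ts), ord = ord, ts = ts, ev = ev,
    et = et, E = E, pos = pos, ev_idx = ev_idx, etid = etid,
    d = d, n_risk = n_risk, jj = jj, frac = frac
  )
}

jj_d <- function(d) rep.int(d, d)

# deaths per event time among patients flagged by `ind` (sorted order)
events_at <- function(prep, ind) {
  sel <- prep$etid[ind[prep$ev_idx] == 1]
  tabulate(sel, nbins = prep$E)
}

# at-risk count per event time among patients flagged by `ind` (sorted order)
at_risk_at <- function(prep, ind) {
  cum <- c(0, cumsum(ind))
  sum(ind) - cum[prep$pos]
}

# ---- Kaplan-Meier ------------------------------------------------------------

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function of a cohort. Censored-only times contribute
#' to the at-risk counts but produce no drop in the curve.
#'
#' @param data a data frame with one row per patient.
#' @param time,event unquoted column names holding the positive follow-up time
#'   and the 0/1 event indicator (1 = death observed).
#' @return a tibble of class `km_curve` with one row per distinct event time:
#'   `time`, `n_risk`, `n_event`, `estimate` (the product-limit survival
#'   probability just after `time`).
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3), event = c(1, 1, 1))
#' km_estimate(d)
#' @export
km_estimate <- function(data, time = time, event = event) {
  tt <- dplyr::pull(data, {{ time }})
  ee <- dplyr::pull(data, {{ event }})
  prep <- survival_prep(tt, ee)
  est <- cumprod(1 - prep$d / prep$n_risk)
  out <- tibble(
    time = prep$et,
    n_risk = prep$n_risk,
    n_event = prep$d,
    estimate = est
  )
  class(out) <- c("km_curve", class(out))
  attr(out, "n") <- prep$n
  attr(out, "n_events") <- sum(prep$d)
  out
}

#' @rdname km_estimate
#' @param object,x a `km_curve`
#' @param ... ignored
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble(
    time = c(0, rep(object$time, each = 2)),
    estimate = c(1, 1, rep(object$estimate, each = 2)[-(2 * nrow(object))])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability")
}

# ---- log-rank test -----------------------------------------------------------

# chi-square statistic for integer group labels 1..k (original patient order)
logrank_stat <- function(prep, g, k) {
  gs <- g[prep$ord]
  O <- matrix(0, prep$E, k)
  R <- matrix(0, prep$E, k)
  for (cls in seq_len(k)) {
    ind <- as.numeric(gs == cls)
    R[, cls] <- at_risk_at(prep, ind)
    O[, cls] <- events_at(prep, ind)
  }
  d <- prep$d
  nj <- prep$n_risk
  P <- R / nj
  U <- colSums(O) - colSums(d * P)
  f <- ifelse(nj > 1, d * (nj - d) / (nj - 1), 0)
  V <- diag(colSums(f * P), k) - crossprod(P, f * P)
  Uk <- U[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(
    drop(Uk %*% solve(Vk, Uk)),
    error = function(e) drop(Uk %*% svd_pinv(Vk) %*% Uk)
  )
  max(stat, 0)
}

svd_pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' k-sample log-rank test
#'
#' Tests whether k patient groups share a common survival distribution.
#'
#' @inheritParams km_estimate
#' @param group unquoted column holding the group label (any type coercible to
#'   a factor); every group must be non-empty and `k >= 2`.
#' @param p_method `"asymptotic"` (chi-square upper tail on k-1 df, default) or
#'   `"permutation"` (seeded label-permutation null, useful for tiny cohorts).
#' @param n_perm,seed number of permutations and RNG seed for
#'   `p_method = "permutation"`.
#' @return an object of class `logrank_test`: list with `statistic`, `df`,
#'   `p_value`, `n`, `groups`.
#' @export
logrank_test <- function(data, group, time = time, event = event,
                         p_method = c("asymptotic", "permutation"),
                         n_perm = 2000, seed = NULL) {
  p_method <- match.arg(p_method)
  tt <- dplyr::pull(data, {{ time }})
  ee <- dplyr::pull(data, {{ event }})
  gg <- dplyr::pull(data, {{ group }})
  gf <- factor(gg)
  k <- nlevels(gf)
  if (k < 2) abort("log-rank test needs at least 2 groups")
  if (any(table(gf) == 0)) abort("every group must be non-empty")
  prep <- survival_prep(tt, ee)
  g <- as.integer(gf)
  stat <- logrank_stat(prep, g, k)
  if (p_method == "asymptotic") {
    p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  } else {
    perm_stats <- withr::with_seed(seed %||% 1L, {
      vapply(seq_len(n_perm), function(i) logrank_stat(prep, sample(g), k), 0)
    })
    p <- (1 + sum(perm_stats >= stat - 1e-12)) / (n_perm + 1)
  }
  structure(
    list(statistic = stat, df = k - 1L, p_value = p, n = prep$n,
         groups = levels(gf), p_method = p_method),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g (%s)\n",
              x$statistic, x$df, x$p_value, x$p_method))
  invisible(x)
}

#' @export
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value, n = x$n)
}

# ---- binary-covariate Cox fit ------------------------------------------------

# Newton-Raphson maximum partial likelihood for a single 0/1 covariate.
# `x` in original patient order. Breslow ties by default, Efron optional.
cox_core <- function(prep, x, ties = "breslow", beta_cap = 15, tol = 1e-8,
                     max_iter = 100L) {
  xs <- x[prep$ord]
  n1 <- at_risk_at(prep, xs)
  d1 <- events_at(prep, xs)
  n0 <- prep$n_risk - n1
  d0 <- prep$d - d1
  d <- prep$d
  S1 <- sum(d1)

  score_info <- function(beta) {
    r <- exp(beta)
    if (ties == "breslow") {
      mu <- n1 * r / (n0 + n1 * r)
      U <- S1 - sum(d * mu)
      I <- sum(d * mu * (1 - mu))
    } else {
      jj <- prep$jj; frac <- prep$frac
      term <- (n0[jj] + n1[jj] * r) - frac * (d0[jj] + d1[jj] * r)
      a <- n1[jj] - frac * d1[jj]
      u <- r * a / term
      U <- S1 - sum(u)
      I <- sum(u * (1 - u))
    }
    c(U, I)
  }

  beta <- 0
  separation <- FALSE
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    si <- score_info(beta)
    if (!is.finite(si[2]) || si[2] <= 0) {
      separation <- TRUE
      break
    }
    step <- si[1] / si[2]
    beta <- beta + step
    if (abs(beta) >= beta_cap) {
      beta <- sign(beta) * beta_cap
      separation <- TRUE
      break
    }
    if (abs(step) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  si <- score_info(beta)
  se <- if (si[2] > 0) 1 / sqrt(si[2]) else Inf
  z <- if (is.finite(se) && se > 0) abs(beta) / se else 0
  list(
    beta = beta, se = se, hazard_ratio = exp(beta),
    wald_p = 2 * pnorm(-z),
    n_events = S1 + sum(d0),
    converged = converged, separation = separation, iter = iter, ties = ties
  )
}

#' Cox proportional-hazards fit for one binary covariate
#'
#' Maximum partial-likelihood estimate of the log hazard ratio between two
#' patient groups, with the Wald test of its significance. Ties are handled by
#' the Breslow approximation by default (Efron available). The optimizer is
#' Newton-Raphson from beta = 0 with a 1e-8 step tolerance; under complete
#' separation the coefficient is capped at +/-15 and flagged.
#'
#' @inheritParams km_estimate
#' @param group unquoted column with the binary covariate (0/1, logical, or a
#'   two-level factor); both groups must be non-empty.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return an object of class `binary_cox`: list with `beta`, `se`,
#'   `hazard_ratio` (= exp(beta)), `wald_p`, `n_events`, `converged`,
#'   `separation`.
#' @export
fit_binary_cox <- function(data, group, time = time, event = event,
                           ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  tt <- dplyr::pull(data, {{ time }})
  ee <- dplyr::pull(data, {{ event }})
  gg <- dplyr::pull(data, {{ group }})
  x <- as_binary01(gg)
  if (sum(x == 1) == 0 || sum(x == 0) == 0) abort("both covariate groups must be non-empty")
  prep <- survival_prep(tt, ee)
  fit <- cox_core(prep, x, ties = ties)
  if (fit$separation) {
    warn("complete or near separation: beta capped, estimate unreliable")
  }
  structure(fit, class = "binary_cox")
}

as_binary01 <- function(g) {
  if (is.logical(g)) return(as.numeric(g))
  if (is.factor(g)) {
    if (nlevels(g) != 2) abort("factor covariate must have exactly 2 levels")
    return(as.numeric(g) - 1)
  }
  if (!all(g %in% c(0, 1))) abort("binary covariate must be 0/1, logical, or a 2-level factor")
  as.numeric(g)
}

#' @export
print.binary_cox <- function(x, ...) {
  cat(sprintf("Binary Cox fit (%s ties): beta = %.4f (se %.4f), HR = %.3f, Wald p = %.4g\n",
              x$ties, x$beta, x$se, x$hazard_ratio, x$wald_p))
  invisible(x)
}

#' @export
tidy.binary_cox <- function(x, ...) {
  tibble(
    term = "group", estimate = x$beta, std.error = x$se,
    statistic = x$beta / x$se, p.value = x$wald_p
  )
}

#' @export
glance.binary_cox <- function(x, ...) {
  tibble(
    hazard_ratio = x$hazard_ratio, wald_p = x$wald_p, n_events = x$n_events,
    converged = x$converged, separation = x$separation
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
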