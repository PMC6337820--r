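#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator: right-continuous, non-increasing step function
#' with \eqn{S(0) = 1}.
#'
#' @param records data frame with columns `time_obs` (> 0) and `status`
#'   (0 censored / 1 event).
#' @return an object of class `km_estimate` with the event times, numbers at
#'   risk, numbers of events and the survival steps, plus `surv_fun`, a
#'   right-continuous step function of time.
#' @export
kaplan_meier <- function(records) {
  stopifnot(nrow(records) >= 1L, all(records$time_obs > 0),
            all(records$status %in% 0:1))
  sf <- survival::survfit(survival::Surv(time_obs, status) ~ 1,
                          data = records, conf.type = "none")
  fun <- stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
  structure(list(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                 surv = sf$surv, surv_fun = fun, n = nrow(records)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("<km_estimate>", x$n, "subjects,", sum(x$n_event), "events\n")
  invisible(x)
}

#' Log-rank test for survival differences between groups
#'
#' Standard log-rank chi-square statistic on `groups - 1` degrees of
#' freedom, from the hypergeometric observed-minus-expected sums at each
#' event time.
#'
#' @param records data frame with columns `time_obs` and `status`.
#' @param group group labels, one per record, at least two groups.
#' @return list with `statistic`, `df` and `p_value`.
#' @export
logrank_test <- function(records, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("log-rank test needs at least two non-empty groups")
  if (sum(records$status) < 1L) stop("log-rank test needs at least one event")
  d <- data.frame(time_obs = records$time_obs, status = records$status,
                  g = droplevels(group))
  sd <- survival::survdiff(survival::Surv(time_obs, status) ~ g, data = d)
  df <- length(sd$n) - 1L
  list(statistic = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

cox_from_coxph <- function(cf) {
  gamma <- stats::coef(cf)
  se <- sqrt(diag(stats::vcov(cf)))
  structure(list(gamma = gamma, se = se,
                 wald_p = 2 * stats::pnorm(-abs(gamma / se)),
                 loglik = cf$loglik[length(cf$loglik)],
                 loglik_null = cf$loglik[1],
                 n = cf$n, n_events = cf$nevent,
                 converged = is.null(cf$fail)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit>", x$n, "rows,", x$n_events, "events\n")
  print(data.frame(coef = x$gamma, se = x$se, p = x$wald_p))
  invisible(x)
}

#' Cox proportional-hazards regression
#'
#' Maximum partial likelihood with the Efron tie correction; Wald p-values
#' from the inverse information.
#'
#' @param records data frame with `time_obs`, `status` and the covariate
#'   columns.
#' @param covariates character vector of covariate column names.
#' @param tol,max_iter convergence control passed to the partial-likelihood
#'   maximizer.
#' @return a `cox_fit`: coefficients `gamma`, `se`, `wald_p`, the partial
#'   log-likelihood and a convergence flag.
#' @export
fit_cox <- function(records, covariates, tol = 1e-9, max_iter = 50L) {
  if (sum(records$status) < 1L) stop("no events in the data")
  fm <- stats::as.formula(paste("survival::Surv(time_obs, status) ~",
                                paste(covariates, collapse = " + ")))
  cf <- survival::coxph(fm, data = records, ties = "efron",
                        control = survival::coxph.control(
                          eps = tol, iter.max = max_iter))
  out <- cox_from_coxph(cf)
  ## monotone-likelihood (separation) guard: runaway coefficients flagged
  if (any(abs(out$gamma) > 15)) {
    out$converged <- FALSE
    warning("possibly monotone partial likelihood: coefficient(s) very large")
  }
  out
}

#' Expand survival records and a biomarker series to counting-process rows
#'
#' Builds the start/stop representation of the extended Cox model: one
#' interval per consecutive pair of a patient's measurement times, truncated
#' at the observed time, with the time-varying covariate on each interval
#' equal to the last measurement at or before the interval start (a step
#' function with jumps at the measurement times).  The event indicator sits
#' on the final interval of event patients only.  Patients with no
#' measurement before their observed time are dropped with a warning.
#'
#' @param baseline data frame with `id`, `time_obs`, `status` and baseline
#'   covariates.
#' @param longitudinal data frame with `id`, `t`, `y`.
#' @param value_name name for the time-varying covariate column.
#' @return data frame of rows `(id, start, stop, status, <value_name>,
#'   baseline covariates)`.
#' @export
to_counting_process <- function(baseline, longitudinal, value_name = "y") {
  out <- vector("list", nrow(baseline))
  base_cov <- setdiff(names(baseline), c("id", "time_obs", "status"))
  dropped <- 0L
  for (i in seq_len(nrow(baseline))) {
    bi <- baseline[i, ]
    li <- longitudinal[longitudinal$id == bi$id &
                         longitudinal$t < bi$time_obs, , drop = FALSE]
    li <- li[order(li$t), , drop = FALSE]
    if (nrow(li) == 0L) { dropped <- dropped + 1L; next }
    starts <- li$t
    stops <- c(li$t[-1L], bi$time_obs)
    keep <- starts < bi$time_obs
    starts <- starts[keep]; stops <- pmin(stops[keep], bi$time_obs)
    rows <- data.frame(id = bi$id, start = starts, stop = stops,
                       status = 0L, v = li$y[keep])
    names(rows)[names(rows) == "v"] <- value_name
    rows$status[nrow(rows)] <- bi$status
    for (cv in base_cov) rows[[cv]] <- bi[[cv]]
    out[[i]] <- rows
  }
  if (dropped > 0L)
    warning(dropped, " patient(s) without any measurement before their ",
            "observed time were dropped")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extended Cox regression on counting-process data
#'
#' Partial likelihood with interval-based risk sets: a row contributes to
#' the risk set of an event time \eqn{t} iff \eqn{start < t \le stop}
#' (left-open intervals), with the Efron tie correction.
#'
#' @param cp_rows counting-process rows from [to_counting_process()].
#' @param covariates character vector of covariate column names (may mix the
#'   time-varying value and baseline covariates).
#' @inheritParams fit_cox
#' @return a `cox_fit`.
#' @export
fit_extended_cox <- function(cp_rows, covariates, tol = 1e-9,
                             max_iter = 50L) {
  stopifnot(all(cp_rows$start < cp_rows$stop))
  fm <- stats::as.formula(paste("survival::Surv(start, stop, status) ~",
                                paste(covariates, collapse = " + ")))
  cf <- survival::coxph(fm, data = cp_rows, ties = "efron",
                        control = survival::coxph.control(
                          eps = tol, iter.max = max_iter))
  out <- cox_from_coxph(cf)
  out$n <- length(unique(cp_rows$id))
  out$n_events <- sum(cp_rows$status)
  if (any(abs(out$gamma) > 15)) {
    out$converged <- FALSE
    warning("possibly monotone partial likelihood: coefficient(s) very large")
  }
  out
}
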