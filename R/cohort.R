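#' Configuration of a synthetic bone-metastatic cohort
#'
#' Collects every quantity needed to simulate a cohort with the structure the
#' downstream analysis assumes: a measurement schedule for the log-biomarker,
#' baseline covariate distributions, a longitudinal mean structure with
#' patient-level random effects, and a proportional-hazards event process
#' whose hazard depends on the current true biomarker level,
#' \deqn{h_i(t) = h_0(t) \exp\{\gamma^T w_i + \alpha\, m_i(t)\},}
#' with a piecewise-constant baseline hazard \eqn{h_0}.
#'
#' Defaults emulate a bisphosphonate-treated bone-metastasis cohort followed
#' at months 0, 1, 3, 6, 9 and 12: a decaying log-NTX trajectory that drops
#' from roughly 80 to 30 nmol BCE/mmol creatinine over the first months of
#' bone-targeted treatment, heavy monotone attrition of the biomarker series,
#' and a high event fraction by the administrative censoring horizon.
#'
#' @param n_patients number of patients.
#' @param schedule measurement times in months, strictly increasing from 0.
#' @param covariate_spec list with elements `age = c(mean, sd)` (years),
#'   `sex = p` (probability of the level coded 1) and `extra_mets = p`
#'   (probability of extra-skeletal metastases).
#' @param traj_form `"rational"`, `"exponential"` or `"spline"` mean
#'   structure for the log-biomarker.
#' @param beta fixed-effects vector, length equal to the basis dimension.
#' @param delta,eta positive tuning parameters of the parametric forms.
#' @param knots,boundary spline knots (months), used when
#'   `traj_form = "spline"`.
#' @param D random-effects covariance matrix (symmetric positive
#'   semi-definite, basis dimension).
#' @param sigma residual SD on the log-biomarker scale.
#' @param gamma survival coefficients for `(age, sex, extra_mets)`.
#' @param alpha association between the current true log-biomarker level and
#'   the log-hazard.
#' @param h0_breaks interval bounds of the piecewise-constant baseline
#'   hazard, starting at 0 (months).
#' @param h0_heights baseline hazard heights per interval (events/month),
#'   all positive; the last height extends beyond the last break.
#' @param censor_time administrative censoring horizon in months.
#' @param dropout_prob per-visit probability of monotone dropout of the
#'   biomarker series (visits after baseline).
#' @param intermittent_miss_prob per-visit probability of an isolated
#'   missing measurement (MCAR), after dropout.
#' @param seed integer seed making [simulate_cohort()] reproducible.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 150,
                          schedule = c(0, 1, 3, 6, 9, 12),
                          covariate_spec = list(age = c(62, 11),
                                                sex = 0.3,
                                                extra_mets = 0.5),
                          traj_form = c("exponential", "rational", "spline"),
                          beta = c(3.4, 1.0),
                          delta = 0.35, eta = 1,
                          knots = c(1, 6), boundary = c(0, 12),
                          D = matrix(c(0.25, 0.05, 0.05, 0.16), 2, 2),
                          sigma = 0.35,
                          gamma = c(age = 0.02, sex = 0.3, extra_mets = 0.7),
                          alpha = 0.2,
                          h0_breaks = c(0, 2, 4, 6, 9, 12, 24),
                          h0_heights = c(0.004, 0.005, 0.005,
                                         0.004, 0.004, 0.003),
                          censor_time = 36,
                          dropout_prob = 0.15,
                          intermittent_miss_prob = 0.05,
                          seed = 1L) {
  traj_form <- match.arg(traj_form)
  schedule <- as.numeric(schedule)
  if (length(schedule) < 2L || schedule[1] != 0 || any(diff(schedule) <= 0))
    stop("'schedule' must be strictly increasing and start at 0")
  basis <- switch(traj_form,
                  exponential = basis_spec("exponential", delta = delta),
                  rational = basis_spec("rational", delta = delta, eta = eta),
                  spline = basis_spec("spline", knots = knots,
                                      boundary = boundary))
  q <- basis_dim(basis)
  if (length(beta) != q)
    stop("'beta' must have length ", q, " for the ", traj_form, " form")
  D <- as.matrix(D)
  if (nrow(D) != q || ncol(D) != q || max(abs(D - t(D))) > 1e-10)
    stop("'D' must be a symmetric ", q, "x", q, " matrix")
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("'D' must be positive semi-definite")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (length(gamma) != 3L) stop("'gamma' must have length 3 (age, sex, extra_mets)")
  if (h0_breaks[1] != 0 || any(diff(h0_breaks) <= 0))
    stop("'h0_breaks' must start at 0 and increase strictly")
  if (length(h0_heights) != length(h0_breaks) - 1L || any(h0_heights <= 0))
    stop("'h0_heights' must be positive, one per interval of 'h0_breaks'")
  if (censor_time <= 0) stop("'censor_time' must be positive")
  for (p in c(dropout_prob, intermittent_miss_prob))
    if (p < 0 || p > 1) stop("missingness probabilities must be in [0, 1]")
  structure(list(n_patients = as.integer(n_patients), schedule = schedule,
                 covariate_spec = covariate_spec, traj_form = traj_form,
                 basis = basis, beta = as.numeric(beta),
                 D = D, sigma = sigma,
                 gamma = stats::setNames(as.numeric(gamma),
                                         c("age", "sex", "extra_mets")),
                 alpha = alpha,
                 h0_breaks = as.numeric(h0_breaks),
                 h0_heights = as.numeric(h0_heights),
                 censor_time = censor_time,
                 dropout_prob = dropout_prob,
                 intermittent_miss_prob = intermittent_miss_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' True log-biomarker level of one patient
#'
#' Evaluates the noiseless trajectory
#' \eqn{m_i(t) = x^T(t)(\beta + b_i)} under the shared-basis convention
#' (identical fixed- and random-effects design).
#'
#' @param config a [cohort_config()].
#' @param b_i random-effects vector of the patient (basis dimension).
#' @param t vector of times in months, all non-negative.
#' @return numeric vector of true levels \eqn{m_i(t)}.
#' @export
simulate_trajectory <- function(config, b_i, t) {
  if (any(t < 0)) stop("'t' must be non-negative")
  q <- basis_dim(config$basis)
  if (length(b_i) != q)
    stop("'b_i' must have length ", q, " (the basis dimension)")
  drop(basis_matrix(t, config$basis) %*% (config$beta + as.numeric(b_i)))
}

## Gauss-Legendre rule on [0, 1], shared by the hazard integrals.
gl_rule <- function(n = 15L) {
  r <- pracma::gaussLegendre(n, 0, 1)
  list(x = r$x, w = r$w)
}

## Extended piece structure: append a terminal piece reaching t_max with the
## last height, so cumulative hazards are defined on the whole horizon.
extend_pieces <- function(config, t_max) {
  breaks <- config$h0_breaks
  heights <- config$h0_heights
  if (t_max > breaks[length(breaks)]) {
    breaks <- c(breaks, t_max)
    heights <- c(heights, heights[length(heights)])
  }
  list(breaks = breaks, heights = heights)
}

## Cumulative hazard H_i(t) for all patients at patient-specific times.
## coefs: q x n matrix of (beta + b_i); lp0: exp(gamma' w_i) per patient.
cumhaz_at <- function(t, coefs, lp0, alpha, config, pieces, gl, piece_int) {
  n <- length(t)
  brk <- pieces$breaks
  idx <- findInterval(pmax(t, 0), brk, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(pieces$heights)] <- length(pieces$heights)
  a <- brk[idx]
  len <- pmax(t - a, 0)
  G <- length(gl$x)
  s <- rep(a, each = G) + rep(len, each = G) * gl$x      # G*n node times
  B <- basis_matrix(s, config$basis)                      # (G*n) x q
  eta <- rowSums(B * t(coefs)[rep(seq_len(n), each = G), , drop = FALSE])
  f <- exp(alpha * eta) * gl$w
  partial <- len * colSums(matrix(f, G, n)) * pieces$heights[idx]
  before <- ifelse(idx > 1L, piece_int[cbind(pmax(idx - 1L, 1L), seq_len(n))], 0)
  lp0 * (before + partial)
}

## Per-patient cumulative integrals of h0(s) exp(alpha m_i(s)) over whole
## pieces; returns P x n matrix of cumulative sums.
piece_integrals <- function(coefs, alpha, config, pieces, gl) {
  n <- ncol(coefs)
  brk <- pieces$breaks
  P <- length(pieces$heights)
  G <- length(gl$x)
  a <- rep(brk[-length(brk)], each = G)
  len <- rep(diff(brk), each = G)
  s <- a + len * gl$x                                     # P*G shared nodes
  B <- basis_matrix(s, config$basis)                      # (P*G) x q
  eta <- B %*% coefs                                      # (P*G) x n
  f <- exp(alpha * eta) * (gl$w * len)
  ints <- rowsum(f, rep(seq_len(P), each = G)) * pieces$heights
  apply(ints, 2, cumsum)
}

solve_event_times <- function(config, W, b, u, t_max = 10 * config$censor_time,
                              tol = 1e-10) {
  n <- nrow(W)
  coefs <- config$beta + t(b)                             # q x n
  lp0 <- exp(drop(W %*% config$gamma))
  pieces <- extend_pieces(config, t_max)
  gl <- gl_rule(15L)
  pint <- piece_integrals(coefs, config$alpha, config, pieces, gl)
  target <- -log(u)
  H_max <- cumhaz_at(rep(t_max, n), coefs, lp0, config$alpha, config,
                     pieces, gl, pint)
  if (any(!is.finite(H_max))) stop("non-finite linear predictor in hazard")
  solved <- H_max >= target
  lo <- rep(0, n); hi <- rep(t_max, n)
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    Hm <- cumhaz_at(mid, coefs, lp0, config$alpha, config, pieces, gl, pint)
    below <- Hm < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out <- (lo + hi) / 2
  out[!solved] <- Inf
  out
}

#' Draw one true event time by inverse-transform sampling
#'
#' Solves \eqn{H_i(T^*) = -\log u} where \eqn{H_i} is the cumulative hazard
#' of the biomarker-dependent proportional-hazards model, by bisection on a
#' Gauss-Legendre evaluation of the cumulative hazard.  Returns `Inf` when
#' the cumulative hazard never reaches \eqn{-\log u} before the horizon
#' `10 * censor_time` (the patient outlives the search window and will be
#' censored).
#'
#' @param config a [cohort_config()].
#' @param w_i named covariate vector `(age, sex, extra_mets)`.
#' @param b_i random-effects vector of the patient.
#' @param u uniform(0,1) draw.
#' @return the true event time in months (possibly `Inf`).
#' @export
simulate_event_time <- function(config, w_i, b_i, u) {
  if (u <= 0 || u >= 1) stop("'u' must lie strictly in (0, 1)")
  W <- matrix(as.numeric(w_i[c("age", "sex", "extra_mets")]), 1, 3)
  solve_event_times(config, W, matrix(as.numeric(b_i), 1), u)
}

#' Apply monotone dropout and intermittent missingness to a cohort
#'
#' The baseline measurement is never removed.  Each post-baseline visit
#' independently triggers monotone dropout with probability `dropout_prob`,
#' removing that visit and all later ones; surviving post-baseline visits are
#' then removed singly with probability `intermittent_miss_prob`.  The truth
#' record keeps the complete (pre-missingness) series.
#'
#' @param cohort a `simulated_cohort`.
#' @param config the [cohort_config()] holding the probabilities.
#' @return the cohort with thinned `longitudinal` table.
#' @export
apply_missingness <- function(cohort, config) {
  long <- cohort$truth$y_complete
  sched <- config$schedule
  Tn <- length(sched)
  ids <- cohort$baseline$id
  n <- length(ids)
  keep <- matrix(TRUE, n, Tn)
  if (Tn > 1L) {
    drop_draw <- matrix(stats::runif(n * (Tn - 1L)) < config$dropout_prob,
                        n, Tn - 1L)
    first_drop <- apply(drop_draw, 1, function(z) {
      w <- which(z); if (length(w)) w[1] + 1L else Tn + 1L
    })
    keep <- keep & (col(keep) < first_drop)
    int_draw <- matrix(stats::runif(n * (Tn - 1L)) <
                         config$intermittent_miss_prob, n, Tn - 1L)
    keep[, -1L][int_draw] <- FALSE
    keep[, 1L] <- TRUE
  }
  vis <- match(long$t, sched)
  row_i <- match(long$id, ids)
  cohort$longitudinal <- long[keep[cbind(row_i, vis)], , drop = FALSE]
  rownames(cohort$longitudinal) <- NULL
  cohort
}

#' Simulate a complete synthetic cohort
#'
#' Draws baseline covariates, patient-level random effects and event times
#' from the biomarker-dependent hazard, censors administratively at
#' `censor_time`, lays measurements on the schedule (strictly before the
#' observed time), adds residual noise and applies the missingness
#' mechanism.  Fully reproducible given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return an object of class `simulated_cohort`: list with `baseline`
#'   (id, time_obs, status, age, sex, extra_mets), `longitudinal`
#'   (id, t, y on the log scale) and `truth` (random effects, true event
#'   times, complete series, config echo).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  n <- config$n_patients
  cs <- config$covariate_spec
  age <- stats::rnorm(n, cs$age[1], cs$age[2])
  sex <- stats::rbinom(n, 1, cs$sex)
  extra <- stats::rbinom(n, 1, cs$extra_mets)
  W <- cbind(age = age, sex = sex, extra_mets = extra)
  q <- basis_dim(config$basis)
  ev <- eigen(config$D, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q) %*% t(ev$vectors)
  b <- matrix(stats::rnorm(n * q), n, q) %*% rt          # n x q
  u <- stats::runif(n)
  t_star <- solve_event_times(config, W, b, u)
  time_obs <- pmin(t_star, config$censor_time)
  status <- as.integer(t_star <= config$censor_time)
  sched <- config$schedule
  eps <- matrix(stats::rnorm(n * length(sched), 0, config$sigma),
                n, length(sched))
  M <- basis_matrix(sched, config$basis) %*% (config$beta + t(b)) # T x n
  long <- data.frame(
    id = rep(seq_len(n), each = length(sched)),
    t = rep(sched, n),
    y = as.vector(M) + as.vector(t(eps)))
  long <- long[long$t < time_obs[long$id], , drop = FALSE]
  rownames(long) <- NULL
  cohort <- structure(list(
    baseline = data.frame(id = seq_len(n), time_obs = time_obs,
                          status = status, age = age, sex = sex,
                          extra_mets = extra),
    longitudinal = long,
    truth = list(b = b, t_star = t_star, y_complete = long,
                 config = config)),
    class = "simulated_cohort")
  apply_missingness(cohort, config)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort>", nrow(x$baseline), "patients,",
      sum(x$baseline$status), "events,",
      nrow(x$longitudinal), "biomarker measurements\n")
  invisible(x)
}

#' Write a cohort to CSV (+ truth JSON)
#'
#' Writes `baseline.csv`, `longitudinal.csv` and `truth.json` into `dir`.
#' Missing values are encoded as empty fields.
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$longitudinal, file.path(dir, "longitudinal.csv"),
                   row.names = FALSE, na = "")
  cfg <- cohort$truth$config
  truth <- list(config = cfg[setdiff(names(cfg), "basis")],
                b = cohort$truth$b, t_star = cohort$truth$t_star)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `baseline.csv` and `longitudinal.csv`.
#' @return a list with `baseline` and `longitudinal` data frames.
#' @export
read_cohort <- function(dir) {
  list(baseline = utils::read.csv(file.path(dir, "baseline.csv")),
       longitudinal = utils::read.csv(file.path(dir, "longitudinal.csv")))
}
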