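#' Piecewise-constant cumulative baseline hazard
#'
#' \eqn{H_0(t) = \sum_q h_q \times |(b_{q-1}, b_q] \cap (0, t]|}: continuous,
#' non-decreasing, \eqn{H_0(0) = 0}.  Beyond the last break the last height
#' is extrapolated (with a message).
#'
#' @param t vector of times, non-negative.
#' @param heights positive hazard heights, one per interval.
#' @param breaks interval bounds starting at 0, length `length(heights)+1`.
#' @return vector of cumulative baseline hazards.
#' @export
piecewise_cumhaz <- function(t, heights, breaks) {
  stopifnot(all(t >= 0), breaks[1] == 0, all(diff(breaks) > 0),
            length(heights) == length(breaks) - 1L, all(heights > 0))
  if (any(t > breaks[length(breaks)] + 1e-12))
    message("times beyond the last hazard break: extrapolating the last height")
  lens <- outer(t, breaks[-1], pmin) - rep(breaks[-length(breaks)],
                                           each = length(t))
  H <- drop(pmax(lens, 0) %*% heights)
  over <- t - breaks[length(breaks)]
  H + pmax(over, 0) * heights[length(heights)]
}

#' Joint model specification
#'
#' @param basis a [basis_spec()] for the longitudinal mean structure
#'   (fixed and random effects share it).
#' @param hazard_breaks optional interval bounds for the piecewise-constant
#'   baseline hazard, starting at 0 and covering the observed time range;
#'   when `NULL`, [fit_joint_model()] places `n_pieces` intervals with
#'   bounds at the observed event-time quantiles.
#' @param n_pieces number of baseline-hazard intervals when `hazard_breaks`
#'   is `NULL`.
#' @param nodes Gauss-Hermite nodes per random-effect dimension; defaults
#'   to 9 for dimension <= 2 and 5 above.
#' @param gl_nodes Gauss-Legendre nodes per baseline-hazard piece for the
#'   cumulative-hazard integral.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter cap on quasi-Newton iterations.
#' @return an object of class `joint_model_spec`.
#' @export
joint_model_spec <- function(basis, hazard_breaks = NULL, n_pieces = 6L,
                             nodes = NULL, gl_nodes = 15L,
                             tol = 1e-7, max_iter = 200L) {
  q <- basis_dim(basis)
  if (is.null(nodes)) nodes <- if (q <= 2L) 9L else 5L
  if (!is.null(hazard_breaks)) {
    if (hazard_breaks[1] != 0 || any(diff(hazard_breaks) <= 0))
      stop("'hazard_breaks' must start at 0 and increase strictly")
  }
  structure(list(basis = basis, hazard_breaks = hazard_breaks,
                 n_pieces = as.integer(n_pieces), nodes = as.integer(nodes),
                 gl_nodes = as.integer(gl_nodes), tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "joint_model_spec")
}

## multi-dimensional Gauss-Hermite grid: nodes Z (K x q) and log-weights
## including the exp(|z|^2) adaptive correction
gh_grid <- function(nodes, q) {
  gh <- pracma::gaussHermite(nodes)
  Zl <- rep(list(gh$x), q)
  Z <- as.matrix(expand.grid(Zl))
  Wl <- as.matrix(expand.grid(rep(list(log(gh$w)), q)))
  list(Z = unname(Z), lw = rowSums(Wl) + rowSums(Z^2))
}

## breaks at observed event-time quantiles, covering (0, max time]
default_breaks <- function(baseline, n_pieces) {
  evt <- baseline$time_obs[baseline$status == 1]
  if (length(evt) < n_pieces) evt <- baseline$time_obs
  qs <- stats::quantile(evt, probs = seq_len(n_pieces - 1L) / n_pieces,
                        names = FALSE, type = 7)
  brk <- c(0, sort(unique(qs)), max(baseline$time_obs))
  unique(brk[diff(c(-Inf, brk)) > 1e-10])
}

## per-patient data blocks consumed by the C++ likelihood kernel
prepare_jm_data <- function(baseline, longitudinal, basis, breaks,
                            covariates, gl_nodes = 15L) {
  gl <- gl_rule(gl_nodes)
  Q <- length(breaks) - 1L
  bmat <- function(t) suppressWarnings(basis_matrix(t, basis))
  dat <- vector("list", nrow(baseline))
  for (i in seq_len(nrow(baseline))) {
    bi <- baseline[i, ]
    li <- longitudinal[longitudinal$id == bi$id &
                         longitudinal$t < bi$time_obs, , drop = FALSE]
    Ti <- bi$time_obs
    segs <- which(breaks[-length(breaks)] < Ti)
    a <- breaks[segs]
    bseg <- pmin(breaks[segs + 1L], Ti)
    ## beyond the last break the last height extrapolates (one extra
    ## segment tied to the terminal hazard piece)
    if (Ti > breaks[length(breaks)]) {
      segs <- c(segs, Q)
      a <- c(a, breaks[length(breaks)])
      bseg <- c(bseg, Ti)
    }
    G <- length(gl$x)
    s <- rep(a, each = G) + rep(bseg - a, each = G) * gl$x
    wgl <- rep(bseg - a, each = G) * gl$w
    pgl <- rep(segs, each = G)
    ## left-open convention: an event at an interval bound belongs to the
    ## interval ending there
    pieceT <- max(findInterval(Ti, breaks, left.open = TRUE,
                               rightmost.closed = TRUE), 1L)
    pieceT <- min(pieceT, Q)
    dat[[i]] <- list(y = as.numeric(li$y), X = bmat(li$t),
                     w = as.numeric(bi[, covariates]),
                     delta = as.integer(bi$status),
                     xT = drop(bmat(Ti)), pieceT = as.integer(pieceT),
                     Bgl = bmat(s), wgl = wgl, pgl = as.integer(pgl))
  }
  list(dat = dat, ptr = jm_cache_cpp(dat), Q = Q, breaks = breaks,
       ids = baseline$id)
}

theta_pack <- function(beta, alpha, gamma, log_h, log_sigma, L) {
  q <- length(beta)
  c(beta, alpha, gamma, log_h, log_sigma,
    log(diag(L)), L[lower.tri(L)])
}

theta_unpack <- function(theta, q, p, Q) {
  beta <- theta[seq_len(q)]
  alpha <- theta[q + 1L]
  gamma <- theta[q + 1L + seq_len(p)]
  log_h <- theta[q + 1L + p + seq_len(Q)]
  log_sigma <- theta[q + p + Q + 2L]
  L <- matrix(0, q, q)
  diag(L) <- exp(theta[q + p + Q + 2L + seq_len(q)])
  if (q > 1L)
    L[lower.tri(L)] <- theta[(q + p + Q + 2L + q + 1L):length(theta)]
  list(beta = beta, alpha = alpha, gamma = gamma, log_h = log_h,
       log_sigma = log_sigma, L = L, D = tcrossprod(L),
       sigma2 = exp(2 * log_sigma), heights = exp(log_h))
}

## adaptive rule (posterior modes and curvature factors) with fallback to
## the prior for patients whose mode search fails
jm_rule <- function(theta, prep, q, p, warm = NULL) {
  warm <- if (is.null(warm)) matrix(0, 0, q) else warm
  r <- jm_modes_cpp(theta, prep$ptr, q, p, prep$Q, warm)
  if (any(r$ok == 0L)) {
    pars <- theta_unpack(theta, q, p, prep$Q)
    Cl <- t(chol(pars$D + 1e-12 * diag(q)))
    for (i in which(r$ok == 0L)) {
      r$modes[i, ] <- 0
      r$chols[, , i] <- Cl
      r$logdetC[i] <- sum(log(diag(Cl)))
    }
  }
  r
}

## adaptive Gauss-Hermite log-likelihood at theta (rule recomputed at theta)
jm_adaptive_loglik <- function(theta, prep, q, p, grid, warm = NULL) {
  rule <- jm_rule(theta, prep, q, p, warm)
  val <- jm_loglik_cpp(theta, prep$ptr, q, p, prep$Q, grid$Z, grid$lw,
                       rule$modes, rule$chols, rule$logdetC, FALSE)
  list(loglik = val$loglik, rule = rule)
}

#' Joint log-likelihood of the shared-parameter model
#'
#' Per patient, the marginal likelihood integrates the product of the
#' longitudinal Gaussian density at the observed measurements, the survival
#' density \eqn{h_i(T_i)^{\delta_i}\exp\{-\int_0^{T_i} h_i(s)\,ds\}} with
#' \eqn{h_i(t) = h_0(t)\exp\{\gamma^T w_i + \alpha m_i(t)\}}, and the
#' random-effects normal prior, over the random effects by adaptive
#' Gauss-Hermite quadrature (centered and scaled at the per-patient
#' posterior mode and curvature).  The inner cumulative-hazard integral uses
#' fixed Gauss-Legendre nodes per baseline-hazard piece.
#'
#' @param params list with `beta`, `D`, `sigma2`, `gamma`, `alpha`,
#'   `h0_heights`.
#' @param data list with `baseline` and `longitudinal` data frames.
#' @param spec a [joint_model_spec()] with non-`NULL` `hazard_breaks`.
#' @param covariates baseline covariate names entering the hazard.
#' @return scalar log-likelihood.
#' @export
joint_loglik <- function(params, data, spec,
                         covariates = c("age", "sex", "extra_mets")) {
  q <- basis_dim(spec$basis)
  p <- length(covariates)
  breaks <- spec$hazard_breaks
  if (is.null(breaks)) breaks <- default_breaks(data$baseline, spec$n_pieces)
  if (length(params$h0_heights) != length(breaks) - 1L)
    stop("'h0_heights' must have one height per hazard interval")
  prep <- prepare_jm_data(data$baseline, data$longitudinal, spec$basis,
                          breaks, covariates, spec$gl_nodes)
  L <- t(chol(params$D + 0 * diag(q)))
  theta <- theta_pack(params$beta, params$alpha, params$gamma,
                      log(params$h0_heights), 0.5 * log(params$sigma2), L)
  grid <- gh_grid(spec$nodes, q)
  jm_adaptive_loglik(theta, prep, q, p, grid)$loglik
}

## piecewise-exponential fit with alpha = 0: Poisson-likelihood trick on
## records split at the hazard breaks
fit_piecewise_exponential <- function(baseline, covariates, breaks) {
  d <- baseline[, c("id", "time_obs", "status", covariates)]
  cuts <- breaks[-c(1L, length(breaks))]
  fm <- stats::as.formula("Surv(time_obs, status) ~ .",
                          env = list2env(list(Surv = survival::Surv)))
  sp <- survival::survSplit(fm, data = d, cut = cuts, episode = "piece",
                            start = "tstart")
  sp$exposure <- sp$time_obs - sp$tstart
  sp <- sp[sp$exposure > 0, , drop = FALSE]
  sp$piece <- factor(sp$piece, levels = seq_len(length(breaks) - 1L))
  fm <- stats::as.formula(paste("status ~ 0 + piece +",
                                paste(covariates, collapse = " + "),
                                "+ offset(log(exposure))"))
  g <- suppressWarnings(stats::glm(fm, family = stats::poisson(), data = sp))
  cf <- stats::coef(g)
  log_h <- cf[paste0("piece", seq_len(length(breaks) - 1L))]
  log_h[is.na(log_h)] <- log(1e-6)   # piece without exposure/events
  gamma <- cf[covariates]
  list(gamma = unname(gamma), log_h = unname(log_h))
}

#' Fit the shared-parameter joint model by maximum likelihood
#'
#' Maximizes the adaptive Gauss-Hermite likelihood of [joint_loglik()] by
#' quasi-Newton iterations on transformed parameters (Cholesky factor of
#' `D` with log diagonal, \eqn{\log\sigma}, log hazard heights), with the
#' quadrature rule re-centered at the per-patient posterior modes between
#' inner optimizations.  Initial values come from a separate [fit_lme()]
#' and a piecewise-exponential survival fit with \eqn{\alpha = 0}.
#' Standard errors are taken from the numerically differentiated Hessian
#' at the optimum.
#'
#' @param data list with `baseline` (id, time_obs, status, covariates) and
#'   `longitudinal` (id, t, y on the log scale).  Patients with no
#'   longitudinal record contribute a survival-only likelihood with the
#'   trajectory integrated over the random-effects prior.
#' @param spec a [joint_model_spec()].
#' @param covariates baseline covariate names entering the hazard.
#' @param init optional list of starting values (`beta`, `D`, `sigma2`,
#'   `gamma`, `alpha`, `log_h`).
#' @param fix_alpha when non-`NULL`, the association \eqn{\alpha} is held
#'   fixed at this value (e.g. 0 for the no-association null fit).
#' @return an object of class `joint_model_fit` with estimates, standard
#'   errors, Wald p-values, the maximized log-likelihood, the baseline
#'   hazard (breaks and heights), posterior modes `b_modes` and convergence
#'   metadata.
#' @export
fit_joint_model <- function(data, spec,
                            covariates = c("age", "sex", "extra_mets"),
                            init = NULL, fix_alpha = NULL) {
  baseline <- data$baseline
  longitudinal <- data$longitudinal
  q <- basis_dim(spec$basis)
  p <- length(covariates)
  breaks <- spec$hazard_breaks
  if (is.null(breaks)) breaks <- default_breaks(baseline, spec$n_pieces)
  Q <- length(breaks) - 1L
  ## standardize hazard covariates internally (better-conditioned
  ## optimization); estimates and the covariance matrix are mapped back to
  ## the natural scale afterwards
  w_mu <- vapply(covariates, function(cv) mean(baseline[[cv]]), 0)
  w_sd <- vapply(covariates, function(cv) stats::sd(baseline[[cv]]), 0)
  w_sd[!is.finite(w_sd) | w_sd < 1e-12] <- 1
  baseline_std <- baseline
  for (j in seq_along(covariates))
    baseline_std[[covariates[j]]] <-
      (baseline[[covariates[j]]] - w_mu[j]) / w_sd[j]
  prep <- prepare_jm_data(baseline_std, longitudinal, spec$basis, breaks,
                          covariates, spec$gl_nodes)
  grid <- gh_grid(spec$nodes, q)
  if (is.null(init)) {
    lme0 <- fit_lme(longitudinal, spec$basis)
    pe0 <- fit_piecewise_exponential(baseline_std, covariates, breaks)
    init <- list(beta = lme0$beta, D = lme0$D, sigma2 = lme0$sigma2,
                 gamma = pe0$gamma, alpha = 0, log_h = pe0$log_h)
  } else {
    ## user-supplied init is on the natural scale
    init$log_h <- init$log_h + drop(crossprod(init$gamma, w_mu))
    init$gamma <- init$gamma * w_sd
  }
  L0 <- t(chol(init$D + 1e-8 * diag(q)))
  theta <- theta_pack(init$beta, init$alpha, init$gamma, init$log_h,
                      0.5 * log(init$sigma2), L0)
  npar <- length(theta)
  free <- rep(TRUE, npar)
  if (!is.null(fix_alpha)) {
    theta[q + 1L] <- fix_alpha
    free[q + 1L] <- FALSE
  }
  rule <- jm_rule(theta, prep, q, p)
  fn <- function(thf) {
    th <- theta; th[free] <- thf
    v <- jm_loglik_cpp(th, prep$ptr, q, p, Q, grid$Z, grid$lw,
                       rule$modes, rule$chols, rule$logdetC, FALSE)$loglik
    if (!is.finite(v)) 1e10 else -v
  }
  gr <- function(thf) {
    th <- theta; th[free] <- thf
    g <- jm_loglik_cpp(th, prep$ptr, q, p, Q, grid$Z, grid$lw,
                       rule$modes, rule$chols, rule$logdetC, TRUE)$grad
    g[!is.finite(g)] <- 0
    -g[free]
  }
  ll <- jm_loglik_cpp(theta, prep$ptr, q, p, Q, grid$Z, grid$lw,
                      rule$modes, rule$chols, rule$logdetC, FALSE)$loglik
  ## box bounds keep the transformed variance parameters away from the
  ## degenerate boundary during line searches
  lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
  ih <- q + 1L + p + seq_len(Q)           # log hazard heights
  lower[ih] <- -30; upper[ih] <- 5
  is2 <- q + p + Q + 2L                   # log sigma
  lower[is2] <- -8; upper[is2] <- 4
  idg <- q + p + Q + 2L + seq_len(q)      # log Cholesky diagonal
  lower[idg] <- -8; upper[idg] <- 8
  converged <- FALSE
  n_outer <- 0L
  for (outer in seq_len(25L)) {
    n_outer <- outer
    opt <- stats::optim(theta[free], fn, gr, method = "L-BFGS-B",
                        lower = lower[free], upper = upper[free],
                        control = list(maxit = spec$max_iter, factr = 1e6))
    theta[free] <- opt$par
    ad <- jm_adaptive_loglik(theta, prep, q, p, grid, warm = rule$modes)
    rule <- ad$rule
    if (is.finite(ad$loglik) &&
        abs(ad$loglik - ll) < spec$tol * (abs(ll) + 0.1)) {
      ll <- ad$loglik
      converged <- TRUE
      break
    }
    ll <- ad$loglik
  }
  ## observed information by central differences of the analytic gradient
  ## (quadrature rule frozen at the optimum)
  h <- 1e-4
  idx <- which(free)
  Hn <- matrix(NA_real_, length(idx), length(idx))
  gat <- function(th) jm_loglik_cpp(th, prep$ptr, q, p, Q, grid$Z, grid$lw,
                                    rule$modes, rule$chols, rule$logdetC,
                                    TRUE)$grad[idx]
  for (j in seq_along(idx)) {
    tp <- theta; tp[idx[j]] <- tp[idx[j]] + h
    tm <- theta; tm[idx[j]] <- tm[idx[j]] - h
    Hn[, j] <- (gat(tp) - gat(tm)) / (2 * h)
  }
  Hn <- (Hn + t(Hn)) / 2
  vc <- tryCatch(solve(-Hn), error = function(e) NULL)
  ## map back from standardized to natural covariate scale:
  ## gamma = gamma_std / sd,  log h = log h_std - sum(gamma_std * mu / sd)
  ig <- q + 1L + seq_len(p)
  ih <- q + 1L + p + seq_len(Q)
  Jf <- diag(npar)
  Jf[ig, ig] <- diag(1 / w_sd, p)
  Jf[ih, ig] <- matrix(rep(-w_mu / w_sd, each = Q), Q, p)
  theta_nat <- theta
  gstd <- theta_unpack(theta, q, p, Q)  # still std in gamma/log_h slots
  theta_nat[ig] <- gstd$gamma / w_sd
  theta_nat[ih] <- gstd$log_h - drop(crossprod(gstd$gamma, w_mu / w_sd))
  theta <- theta_nat
  vc <- if (!is.null(vc)) Jf[idx, idx, drop = FALSE] %*% vc %*%
    t(Jf[idx, idx, drop = FALSE]) else NULL
  se_free <- if (!is.null(vc) && all(diag(vc) > 0)) sqrt(diag(vc)) else
    rep(NA_real_, length(idx))
  se <- rep(NA_real_, npar)
  se[idx] <- se_free
  pars <- theta_unpack(theta, q, p, Q)
  nm_beta <- paste0("beta", seq_len(q) - 1L)
  est <- c(stats::setNames(pars$beta, nm_beta),
           alpha = pars$alpha,
           stats::setNames(pars$gamma, covariates))
  ses <- c(se[seq_len(q)], se[q + 1L], se[q + 1L + seq_len(p)])
  wald_p <- 2 * stats::pnorm(-abs(est / ses))
  structure(list(
    beta = stats::setNames(pars$beta, nm_beta),
    D = pars$D, sigma2 = pars$sigma2,
    gamma = stats::setNames(pars$gamma, covariates),
    alpha = pars$alpha,
    h0_heights = pars$heights, hazard_breaks = breaks,
    se = stats::setNames(ses, names(est)),
    se_log_h = se[q + 1L + p + seq_len(Q)],
    se_sigma2 = if (is.na(se[q + p + Q + 2L])) NA_real_ else
      2 * pars$sigma2 * se[q + p + Q + 2L],
    wald_p = stats::setNames(wald_p, names(est)),
    loglik = ll, converged = converged, n_iter = n_outer,
    b_modes = rule$modes, ids = prep$ids,
    theta = theta, vcov_free = vc, free = free,
    spec = spec, covariates = covariates,
    n_patients = nrow(baseline), n_events = sum(baseline$status)),
    class = "joint_model_fit")
}

#' @export
print.joint_model_fit <- function(x, ...) {
  cat("<joint_model_fit>", x$spec$basis$kind, "basis;",
      x$n_patients, "patients,", x$n_events, "events\n")
  cat("  logLik:", signif(x$loglik, 8),
      " converged:", x$converged, "\n")
  print(wald_table(x))
  invisible(x)
}

#' Wald coefficient table of a joint model fit
#'
#' Two-sided normal Wald tests per coefficient, with a significance flag at
#' the 5% level.
#'
#' @param fit a `joint_model_fit`.
#' @return data frame with columns `parameter`, `estimate`, `se`, `p`,
#'   `significant`.
#' @export
wald_table <- function(fit) {
  est <- c(fit$beta, alpha = fit$alpha, fit$gamma)
  if (all(is.na(fit$se))) stop("standard errors unavailable for this fit")
  p <- 2 * stats::pnorm(-abs(est / fit$se))
  data.frame(parameter = names(est), estimate = unname(est),
             se = unname(fit$se), p = unname(p),
             significant = unname(p < 0.05),
             row.names = NULL)
}
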