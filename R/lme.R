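## Per-pattern sufficient statistics for the marginal Gaussian likelihood.
## Patients sharing a measurement-time pattern share the design matrix and
## the marginal covariance V = X D X' + sigma^2 I, so the log-likelihood
## collapses to a handful of small-matrix operations per pattern.
lme_pattern_stats <- function(long_data) {
  split_i <- split(seq_len(nrow(long_data)), long_data$id)
  keys <- vapply(split_i, function(ix)
    paste(signif(sort(long_data$t[ix]), 12), collapse = ","), "")
  pats <- list()
  for (key in unique(keys)) {
    members <- split_i[keys == key]
    t_p <- long_data$t[members[[1]]]
    Y <- vapply(members, function(ix) long_data$y[ix][order(long_data$t[ix])],
                numeric(length(t_p)))
    Y <- matrix(Y, nrow = length(t_p))
    t_p <- sort(t_p)
    pats[[key]] <- list(t = t_p,
                        N = length(members), Sy = rowSums(Y),
                        Syy = tcrossprod(Y), Y = Y,
                        ids = names(members))
  }
  pats
}

lme_patterns <- function(long_data, spec, stats = NULL) {
  if (is.null(stats)) stats <- lme_pattern_stats(long_data)
  lapply(stats, function(p) { p$X <- basis_matrix(p$t, spec); p })
}

theta_to_DL <- function(theta, q) {
  L <- matrix(0, q, q)
  L[cbind(seq_len(q), seq_len(q))] <- exp(theta[seq_len(q)])
  if (q > 1L) L[lower.tri(L)] <- theta[(q + 1L):(q * (q + 1L) / 2L)]
  sigma <- exp(theta[length(theta)])
  list(L = L, D = tcrossprod(L), sigma = sigma)
}

## Profiled marginal log-likelihood: beta solved by GLS at each (D, sigma).
lme_profile_loglik <- function(theta, pats, q) {
  par <- theta_to_DL(theta, q)
  A <- matrix(0, q, q); cvec <- numeric(q)
  Vinvs <- vector("list", length(pats))
  for (j in seq_along(pats)) {
    p <- pats[[j]]
    V <- p$X %*% par$D %*% t(p$X) + par$sigma^2 * diag(length(p$t))
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(list(loglik = -Inf))
    Vinv <- chol2inv(cV)
    Vinvs[[j]] <- list(Vinv = Vinv, ldet = 2 * sum(log(diag(cV))))
    XtVi <- crossprod(p$X, Vinv)
    A <- A + p$N * XtVi %*% p$X
    cvec <- cvec + XtVi %*% p$Sy
  }
  beta <- tryCatch(solve(A, cvec), error = function(e) NULL)
  if (is.null(beta)) return(list(loglik = -Inf))
  ll <- 0; Ntot <- 0
  for (j in seq_along(pats)) {
    p <- pats[[j]]
    Vi <- Vinvs[[j]]$Vinv
    mu <- drop(p$X %*% beta)
    quad <- sum(Vi * p$Syy) - 2 * sum((Vi %*% mu) * p$Sy) +
      p$N * drop(crossprod(mu, Vi %*% mu))
    ll <- ll - 0.5 * (p$N * Vinvs[[j]]$ldet + quad)
    Ntot <- Ntot + p$N * length(p$t)
  }
  list(loglik = ll - 0.5 * Ntot * log(2 * pi), beta = drop(beta),
       Vinvs = Vinvs, par = par)
}

## Analytic gradient of the beta-profiled marginal log-likelihood with
## respect to (log-diag L, strict lower L, log sigma).  Beta sits at its
## GLS optimum, so by the envelope theorem only the explicit dependence on
## V = X D X' + sigma^2 I contributes:
##   dll = -1/2 sum_p tr(W_p dV),  W_p = N_p V^-1 - V^-1 M_p V^-1
## with M_p the residual second-moment matrix of pattern p.
lme_profile_grad <- function(theta, pats, q) {
  fit <- lme_profile_loglik(theta, pats, q)
  if (!is.finite(fit$loglik)) return(rep(NA_real_, length(theta)))
  L <- fit$par$L
  sig2 <- fit$par$sigma^2
  gL <- matrix(0, q, q)
  gs <- 0
  for (j in seq_along(pats)) {
    p <- pats[[j]]
    Vi <- fit$Vinvs[[j]]$Vinv
    mu <- drop(p$X %*% fit$beta)
    M <- p$Syy - tcrossprod(p$Sy, mu) - tcrossprod(mu, p$Sy) +
      p$N * tcrossprod(mu)
    W <- p$N * Vi - Vi %*% M %*% Vi
    A <- crossprod(p$X, W %*% p$X)
    gL <- gL + A %*% L
    gs <- gs + sum(diag(W))
  }
  gd <- -diag(gL) * diag(L)              # log-diagonal chain rule
  glow <- -gL[lower.tri(gL)]
  c(gd, glow, -sig2 * gs)
}

#' Marginal log-likelihood of a linear mixed-effects model
#'
#' Evaluates the exact marginal Gaussian log-likelihood of the model
#' \eqn{y_i(t) = x^T(t)\beta + x^T(t) b_i + \epsilon_i(t)} (shared basis for
#' fixed and random effects) at given parameter values, using per-patient
#' covariance \eqn{X_i D X_i^T + \sigma^2 I}.
#'
#' @param long_data data frame with columns `id`, `t`, `y`.
#' @param spec a [basis_spec()].
#' @param beta fixed-effects vector.
#' @param D random-effects covariance matrix.
#' @param sigma2 residual variance.
#' @return scalar log-likelihood.
#' @export
lme_loglik <- function(long_data, spec, beta, D, sigma2) {
  pats <- lme_patterns(long_data, spec)
  ll <- 0
  for (p in pats) {
    V <- p$X %*% D %*% t(p$X) + sigma2 * diag(length(p$t))
    cV <- chol(V)
    Vinv <- chol2inv(cV)
    mu <- drop(p$X %*% beta)
    R <- p$Y - mu
    ll <- ll - 0.5 * (p$N * (2 * sum(log(diag(cV))) +
                               length(p$t) * log(2 * pi)) +
                        sum(R * (Vinv %*% R)))
  }
  ll
}

#' Fit a linear mixed-effects model by maximum likelihood
#'
#' Maximizes the marginal Gaussian log-likelihood over \eqn{(\beta, D,
#' \sigma^2)} for a trajectory basis shared between fixed and random
#' effects.  \eqn{\beta} is profiled out by generalized least squares and
#' the optimizer works on the Cholesky factor of `D` (log diagonal) and
#' \eqn{\log\sigma}, so `D` is positive semi-definite and \eqn{\sigma^2 > 0}
#' by construction.  Estimation is plain ML (not REML) so log-likelihoods
#' are comparable across mean structures and usable to initialize the joint
#' model.
#'
#' @param long_data data frame with columns `id`, `t`, `y` (log-biomarker).
#' @param spec a [basis_spec()].
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter optimizer iteration cap.
#' @param init optional starting value for the transformed covariance
#'   parameters (internal use).
#' @param pattern_stats optional precomputed output of the internal
#'   pattern-statistics builder (used to avoid rebuilding them along a
#'   tuning-parameter grid).
#' @return an object of class `lme_fit`: `beta`, `D`, `sigma2`, per-patient
#'   empirical-Bayes modes `b_modes`, `loglik`, counts and a convergence
#'   flag.
#' @export
fit_lme <- function(long_data, spec, tol = 1e-8, max_iter = 200L,
                    init = NULL, pattern_stats = NULL) {
  q <- basis_dim(spec)
  pats <- lme_patterns(long_data, spec, pattern_stats)
  Xall <- do.call(rbind, lapply(pats, function(p)
    p$X[rep(seq_len(nrow(p$X)), p$N), , drop = FALSE]))
  if (qr(Xall)$rank < q)
    stop("singular total design: the basis is not identifiable from the ",
         "observed measurement times")
  if (is.null(init)) {
    ols <- stats::lm.fit(Xall, unlist(lapply(pats, function(p) as.vector(p$Y))))
    s0 <- max(stats::sd(ols$residuals), 1e-3)
    init <- c(rep(log(s0), q), rep(0, q * (q - 1L) / 2L), log(s0 / sqrt(2)))
  }
  negll <- function(th) {
    v <- lme_profile_loglik(th, pats, q)$loglik
    if (!is.finite(v)) 1e10 else -v
  }
  neggr <- function(th) {
    g <- lme_profile_grad(th, pats, q)
    if (any(!is.finite(g))) g[] <- 0
    -g
  }
  opt <- stats::optim(init, negll, neggr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol * 1e-2))
  fit <- lme_profile_loglik(opt$par, pats, q)
  b_modes <- matrix(NA_real_, 0, q)
  ids <- character(0)
  for (j in seq_along(pats)) {
    p <- pats[[j]]
    Vi <- fit$Vinvs[[j]]$Vinv
    R <- p$Y - drop(p$X %*% fit$beta)
    B <- t(fit$par$D %*% t(p$X) %*% Vi %*% R)   # N x q modes
    b_modes <- rbind(b_modes, B)
    ids <- c(ids, p$ids)
  }
  ord <- order(suppressWarnings(as.numeric(ids)), ids)
  structure(list(spec = spec, beta = fit$beta, D = fit$par$D,
                 sigma2 = fit$par$sigma^2,
                 b_modes = b_modes[ord, , drop = FALSE],
                 b_ids = ids[ord],
                 loglik = fit$loglik,
                 n_obs = nrow(long_data),
                 n_patients = length(unique(long_data$id)),
                 converged = opt$convergence == 0L,
                 theta = opt$par),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat("<lme_fit>", x$spec$kind, "basis;", x$n_patients, "patients,",
      x$n_obs, "observations\n")
  cat("  beta:", paste(signif(x$beta, 4), collapse = ", "), "\n")
  cat("  sigma2:", signif(x$sigma2, 4),
      " logLik:", signif(x$loglik, 8), "\n")
  invisible(x)
}

log_grid <- function(lower, upper, n) exp(seq(log(lower), log(upper),
                                              length.out = n))

#' Profile the nonlinear tuning parameters of a parametric basis
#'
#' Selects \eqn{\delta} (exponential) or \eqn{(\delta, \eta)} (rational) by
#' maximizing the [fit_lme()] marginal log-likelihood over a log-spaced grid
#' on \eqn{[10^{-2}, 10^2]} (25 points for the one-parameter exponential
#' profile, 13 per parameter for the two-parameter rational profile)
#' followed by a bounded local search; ties break toward the smaller
#' \eqn{\delta} (then smaller \eqn{\eta}).  A flat profile or an optimum at
#' the lower bound is flagged as a boundary solution.
#'
#' @param long_data data frame with columns `id`, `t`, `y`.
#' @param kind `"rational"` or `"exponential"`.
#' @param lower,upper search bounds for the tuning parameters.
#' @param n_grid grid points per parameter; defaults to 25 (exponential) or
#'   13 (rational).
#' @return list with the selected `spec` ([basis_spec()]), its `loglik`,
#'   the profiled `grid` (data frame), and a `boundary` flag.
#' @export
profile_tuning <- function(long_data, kind = c("exponential", "rational"),
                           lower = 1e-2, upper = 1e2, n_grid = NULL) {
  kind <- match.arg(kind)
  if (is.null(n_grid)) n_grid <- if (kind == "rational") 13L else 25L
  make_spec <- function(par) {
    if (kind == "exponential") basis_spec("exponential", delta = par[1])
    else basis_spec("rational", delta = par[1], eta = par[2])
  }
  ## every evaluation starts from the default initialization: warm starts
  ## along the grid can drag a whole sweep into one bad local optimum
  stats0 <- lme_pattern_stats(long_data)
  prof <- function(par, iters = 200L) {
    f <- tryCatch(fit_lme(long_data, make_spec(par), max_iter = iters,
                          pattern_stats = stats0),
                  error = function(e) NULL)
    if (is.null(f)) return(list(loglik = -Inf))
    f
  }
  dg <- log_grid(lower, upper, n_grid)
  grid <- if (kind == "exponential") data.frame(delta = dg)
          else expand.grid(delta = dg, eta = dg)
  grid$loglik <- NA_real_
  ## the grid only needs to locate the right region; the local search below
  ## polishes, so grid fits run with a reduced iteration cap
  for (i in seq_len(nrow(grid))) {
    par <- as.numeric(grid[i, setdiff(names(grid), "loglik")])
    grid$loglik[i] <- prof(par, iters = 60L)$loglik
  }
  finite <- is.finite(grid$loglik)
  if (!any(finite)) stop("tuning profile failed at every grid point")
  best_ll <- max(grid$loglik[finite])
  ## tie-break toward small delta then small eta
  cand <- which(finite & grid$loglik >= best_ll - 1e-8)
  ord <- order(grid$delta[cand],
               if (kind == "rational") grid$eta[cand] else rep(0, length(cand)))
  best <- cand[ord[1]]
  start <- log(as.numeric(grid[best, setdiff(names(grid), "loglik")]))
  negprof <- function(lp) {
    p <- exp(lp)
    if (any(p < lower) || any(p > upper)) return(1e10)
    v <- prof(p)$loglik
    if (!is.finite(v)) 1e10 else -v
  }
  if (kind == "exponential") {
    step <- log(dg[2] / dg[1])
    refine <- stats::optimize(negprof, c(start - step, start + step),
                              tol = 1e-6)
    sel <- exp(refine$minimum)
    sel_ll <- -refine$objective
  } else {
    refine <- stats::optim(start, negprof, method = "Nelder-Mead",
                           control = list(maxit = 200L, reltol = 1e-8))
    sel <- exp(refine$par)
    sel_ll <- -refine$value
  }
  if (sel_ll < best_ll) { sel <- exp(start); sel_ll <- best_ll }
  flat <- (max(grid$loglik[finite]) - min(grid$loglik[finite])) < 1e-4
  boundary <- flat || sel[1] <= lower * 1.05
  if (flat) { sel[1] <- lower; if (kind == "rational") sel[2] <- lower }
  spec <- make_spec(sel)
  list(spec = spec, loglik = sel_ll, grid = grid, boundary = boundary)
}
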