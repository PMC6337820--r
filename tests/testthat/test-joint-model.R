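test_that("piecewise cumulative hazard integrates the step function exactly", {
  expect_equal(piecewise_cumhaz(c(0, 1, 2.5), 0.3, c(0, 10)),
               0.3 * c(0, 1, 2.5))
  ## hand integral: heights (1,2), breaks (0,3,10), t=5 -> 1*3 + 2*2 = 7
  expect_equal(piecewise_cumhaz(5, c(1, 2), c(0, 3, 10)), 7)
  expect_equal(piecewise_cumhaz(0, c(1, 2), c(0, 3, 10)), 0)
  ## beyond the last break: last height extrapolated
  expect_message(H <- piecewise_cumhaz(12, c(1, 2), c(0, 3, 10)), "beyond")
  expect_equal(H, 3 + 14 + 2 * 2)
})

tiny_instance <- function() {
  list(baseline = data.frame(id = 1:2, time_obs = c(4, 7), status = c(1, 0),
                             age = c(60, 55), sex = c(1, 0),
                             extra_mets = c(0, 1)),
       longitudinal = data.frame(id = c(1, 1, 1, 2, 2),
                                 t = c(0, 1, 3, 0, 6),
                                 y = c(4.1, 3.9, 3.5, 3.0, 2.8)))
}

test_that("joint likelihood matches dense-grid integration (1 random effect)", {
  data <- tiny_instance()
  breaks <- c(0, 3, 7)
  spec <- joint_model_spec(basis_spec("constant"), hazard_breaks = breaks)
  params <- list(beta = 3.5, D = matrix(0.3), sigma2 = 0.12,
                 gamma = c(0.02, 0.3, 0.5), alpha = 0.25,
                 h0_heights = c(0.03, 0.05))
  ll <- joint_loglik(params, data, spec)
  ## dense trapezoid over b (the constant basis makes the time integral
  ## exact in closed form)
  sdb <- sqrt(params$D[1, 1])
  bgrid <- seq(-10 * sdb, 10 * sdb, length.out = 2001)
  oracle <- 0
  for (i in 1:2) {
    bi <- data$baseline[i, ]
    li <- data$longitudinal[data$longitudinal$id == bi$id, ]
    lp <- sum(params$gamma * c(bi$age, bi$sex, bi$extra_mets))
    H0T <- piecewise_cumhaz(bi$time_obs, params$h0_heights, breaks)
    h0T <- params$h0_heights[findInterval(bi$time_obs, breaks,
                                          rightmost.closed = TRUE)]
    dens <- vapply(bgrid, function(b) {
      m <- params$beta + b
      f <- prod(dnorm(li$y, m, sqrt(params$sigma2)))
      haz_mult <- exp(lp + params$alpha * m)
      surv <- exp(-H0T * haz_mult) * if (bi$status) h0T * haz_mult else 1
      f * surv * dnorm(b, 0, sdb)
    }, 0)
    oracle <- oracle +
      log(sum(diff(bgrid) * (dens[-1] + dens[-length(dens)]) / 2))
  }
  expect_equal(ll, oracle, tolerance = 1e-6)
})

test_that("joint likelihood matches dense-grid integration (2 random effects)", {
  data <- tiny_instance()
  breaks <- c(0, 7)
  basis <- basis_spec("exponential", delta = 0.4)
  spec <- joint_model_spec(basis, hazard_breaks = breaks)
  D <- matrix(c(0.25, 0.05, 0.05, 0.16), 2)
  params <- list(beta = c(3.2, 0.9), D = D, sigma2 = 0.12,
                 gamma = c(0.02, 0.3, 0.5), alpha = 0.3,
                 h0_heights = 0.04)
  ll <- joint_loglik(params, data, spec)
  ## dense 2-d trapezoid; the time integral of exp(alpha*m(s)) is done by a
  ## fine trapezoid per patient, independent of the package quadrature
  sds <- sqrt(diag(D))
  g1 <- seq(-8 * sds[1], 8 * sds[1], length.out = 401)
  g2 <- seq(-8 * sds[2], 8 * sds[2], length.out = 401)
  Dinv <- solve(D)
  oracle <- 0
  for (i in 1:2) {
    bi <- data$baseline[i, ]
    li <- data$longitudinal[data$longitudinal$id == bi$id, ]
    lp <- sum(params$gamma * c(bi$age, bi$sex, bi$extra_mets))
    tt <- seq(0, bi$time_obs, length.out = 2001)
    Bt <- basis_matrix(tt, basis)
    Xo <- basis_matrix(li$t, basis)
    xT <- basis_matrix(bi$time_obs, basis)
    logdens <- outer(g1, g2, Vectorize(function(b1, b2) {
      bb <- params$beta + c(b1, b2)
      f <- sum(dnorm(li$y, drop(Xo %*% bb), sqrt(params$sigma2), log = TRUE))
      haz <- 0.04 * exp(lp + params$alpha * drop(Bt %*% bb))
      H <- sum(diff(tt) * (haz[-1] + haz[-length(tt)]) / 2)
      ev <- if (bi$status) log(0.04) + lp + params$alpha * drop(xT %*% bb)
            else 0
      pri <- -log(2 * pi) - 0.5 * log(det(D)) -
        0.5 * drop(crossprod(c(b1, b2), Dinv %*% c(b1, b2)))
      f + ev - H + pri
    }))
    mx <- max(logdens)
    oracle <- oracle + mx +
      log(sum(exp(logdens - mx)) * diff(g1)[1] * diff(g2)[1])
  }
  expect_equal(ll, oracle, tolerance = 2e-5)
})

test_that("the likelihood factorizes when the association is severed", {
  cfg <- small_config(n = 40, seed = 25)
  co <- simulate_cohort(cfg)
  data <- list(baseline = co$baseline, longitudinal = co$longitudinal)
  basis <- basis_spec("exponential", delta = 0.35)
  breaks <- c(0, 4, 9, 36)
  spec <- joint_model_spec(basis, hazard_breaks = breaks)
  params <- list(beta = c(3.4, 1), D = cfg$D, sigma2 = 0.12,
                 gamma = c(0.02, 0.3, 0.7), alpha = 0,
                 h0_heights = c(0.04, 0.05, 0.03))
  ll <- joint_loglik(params, data, spec)
  lme_part <- lme_loglik(data$longitudinal, basis, params$beta, params$D,
                         params$sigma2)
  surv_part <- 0
  for (i in seq_len(nrow(data$baseline))) {
    bi <- data$baseline[i, ]
    lp <- sum(params$gamma * c(bi$age, bi$sex, bi$extra_mets))
    H0 <- piecewise_cumhaz(bi$time_obs, params$h0_heights, breaks)
    h0T <- params$h0_heights[findInterval(bi$time_obs, breaks,
                                          rightmost.closed = TRUE)]
    surv_part <- surv_part + bi$status * (log(h0T) + lp) - H0 * exp(lp)
  }
  expect_equal(ll, lme_part + surv_part, tolerance = 1e-8)
})

test_that("a collapsing random-effects prior recovers the plug-in likelihood", {
  data <- tiny_instance()
  breaks <- c(0, 7)
  spec <- joint_model_spec(basis_spec("constant"), hazard_breaks = breaks)
  params <- list(beta = 3.5, D = matrix(1e-12), sigma2 = 0.12,
                 gamma = c(0.02, 0.3, 0.5), alpha = 0.25,
                 h0_heights = 0.04)
  ll <- joint_loglik(params, data, spec)
  ## plug-in at b = 0
  plug <- 0
  for (i in 1:2) {
    bi <- data$baseline[i, ]
    li <- data$longitudinal[data$longitudinal$id == bi$id, ]
    lp <- sum(params$gamma * c(bi$age, bi$sex, bi$extra_mets))
    hm <- exp(lp + params$alpha * params$beta)
    plug <- plug + sum(dnorm(li$y, params$beta, sqrt(params$sigma2),
                             log = TRUE)) +
      bi$status * log(0.04 * hm) - 0.04 * bi$time_obs * hm
  }
  expect_equal(ll, plug, tolerance = 1e-4)
})

test_that("the quadrature is stable in the number of nodes", {
  cfg <- small_config(n = 50, seed = 29, alpha = 0.2)
  co <- simulate_cohort(cfg)
  data <- list(baseline = co$baseline, longitudinal = co$longitudinal)
  basis <- basis_spec("exponential", delta = 0.35)
  params <- list(beta = cfg$beta, D = cfg$D, sigma2 = cfg$sigma^2,
                 gamma = unname(cfg$gamma), alpha = cfg$alpha,
                 h0_heights = c(0.03, 0.04, 0.05))
  breaks <- c(0, 4, 9, 36)
  lls <- vapply(c(3L, 9L, 15L), function(k)
    joint_loglik(params, data,
                 joint_model_spec(basis, hazard_breaks = breaks, nodes = k)),
    0)
  expect_lt(abs(lls[3] - lls[2]), abs(lls[2] - lls[1]) + 1e-10)
  expect_lt(abs(lls[3] - lls[2]), 1e-4)
})

test_that("constraining the association to zero separates the sub-models", {
  cfg <- small_config(n = 100, seed = 35, alpha = 0.15)
  co <- simulate_cohort(cfg)
  data <- list(baseline = co$baseline, longitudinal = co$longitudinal)
  basis <- basis_spec("exponential", delta = 0.35)
  spec <- joint_model_spec(basis)
  fit0 <- fit_joint_model(data, spec, fix_alpha = 0)
  lme0 <- fit_lme(data$longitudinal, basis)
  pe0 <- bonejm:::fit_piecewise_exponential(
    data$baseline, c("age", "sex", "extra_mets"), fit0$hazard_breaks)
  expect_equal(fit0$beta, lme0$beta, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit0$sigma2, lme0$sigma2, tolerance = 1e-6)
  expect_equal(fit0$D, lme0$D, tolerance = 1e-5)
  expect_equal(unname(fit0$gamma), pe0$gamma, tolerance = 1e-6)
  expect_equal(log(fit0$h0_heights), pe0$log_h, tolerance = 1e-6)
  ## freeing alpha can only increase the maximized likelihood
  fit1 <- fit_joint_model(data, spec)
  expect_gte(fit1$loglik, fit0$loglik - 1e-6)
})

test_that("the Wald table reports normal two-sided tests", {
  cfg <- small_config(n = 80, seed = 37, alpha = 0.2)
  co <- simulate_cohort(cfg)
  fit <- fit_joint_model(list(baseline = co$baseline,
                              longitudinal = co$longitudinal),
                         joint_model_spec(basis_spec("exponential",
                                                     delta = 0.35)))
  tab <- wald_table(fit)
  expect_setequal(tab$parameter,
                  c("beta0", "beta1", "alpha", "age", "sex", "extra_mets"))
  expect_equal(tab$p, 2 * pnorm(-abs(tab$estimate / tab$se)))
  expect_identical(tab$significant, tab$p < 0.05)
})
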