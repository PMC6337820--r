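test_that("Kaplan-Meier matches hand product-limit computations", {
  r4 <- data.frame(time_obs = 1:4, status = 1)
  km <- kaplan_meier(r4)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$surv_fun(0), 1)
  expect_equal(km$surv_fun(2.5), 0.5)

  ## all censored
  rc <- data.frame(time_obs = c(2, 5, 9), status = 0)
  expect_true(all(kaplan_meier(rc)$surv == 1))

  ## events at 1, 2 with a censoring at 1.5:
  ## S(1) = 2/3, S(2) = 2/3 * (1 - 1/1) = 0
  r3 <- data.frame(time_obs = c(1, 1.5, 2), status = c(1, 0, 1))
  km3 <- kaplan_meier(r3)
  expect_equal(km3$surv_fun(1), 2 / 3)
  expect_equal(km3$surv_fun(2), 0)
})

test_that("log-rank matches a hand hypergeometric computation", {
  ## identical groups: statistic 0
  g <- data.frame(time_obs = rep(c(1, 3, 5), 2), status = 1)
  lr0 <- logrank_test(g, rep(c("a", "b"), each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  ## A events at 1,2; B events at 3,4 - hand O-E and variance sums
  d <- data.frame(time_obs = 1:4, status = 1)
  grp <- c("A", "A", "B", "B")
  # t=1: nA=2,nB=2,d=1 E_A=1/2 V=(1*2*2*3)/(4^2*3)=1/4
  # t=2: nA=1,nB=2,d=1 E_A=1/3 V=2/9
  # t=3: nA=0,nB=2,d=1 E_A=0 V=0 ; t=4 same
  oe <- (1 - 1 / 2) + (1 - 1 / 3)
  v <- 1 / 4 + 2 / 9
  lr <- logrank_test(d, grp)
  expect_equal(lr$statistic, oe^2 / v, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
})

test_that("log-rank null p-values are uniform", {
  set.seed(77)
  pv <- replicate(200, {
    n <- 60
    d <- data.frame(time_obs = rexp(n, 0.1), status = rbinom(n, 1, 0.8))
    logrank_test(d, rbinom(n, 1, 0.5))$p_value
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("Cox fits maximize the partial likelihood (grid oracle)", {
  ## 6-record binary-covariate fixture, no ties
  d <- data.frame(time_obs = c(1, 2, 3, 4, 5, 6),
                  status = c(1, 1, 0, 1, 1, 1),
                  x = c(1, 0, 1, 1, 0, 0))
  fit <- fit_cox(d, "x")
  ## dense grid search of the (untied) partial likelihood
  plik <- function(g) {
    ord <- order(d$time_obs)
    s <- 0
    for (i in ord[d$status[ord] == 1]) {
      rs <- d$time_obs >= d$time_obs[i]
      s <- s + g * d$x[i] - log(sum(exp(g * d$x[rs])))
    }
    s
  }
  grid <- seq(-4, 4, by = 1e-4)
  ghat <- grid[which.max(vapply(grid, plik, 0))]
  expect_equal(unname(fit$gamma), ghat, tolerance = 1e-4)
  ## partial loglik at the optimum >= at zero
  expect_gte(fit$loglik, plik(0))

  ## symmetric groups: coefficient ~ 0
  d2 <- data.frame(time_obs = rep(c(1, 2, 5), 2), status = 1,
                   x = rep(0:1, each = 3))
  expect_lt(abs(fit_cox(d2, "x")$gamma), 1e-8)
})

test_that("Cox recovers a known log-hazard ratio", {
  set.seed(10)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.08 * exp(0.7 * x))
  cens <- runif(n, 5, 40)
  d <- data.frame(time_obs = pmin(t_ev, cens),
                  status = as.integer(t_ev <= cens), x = x)
  fit <- fit_cox(d, "x")
  expect_lt(abs(fit$gamma - 0.7) / fit$se, 3)
})

test_that("log-rank equals the Cox score test for a binary covariate", {
  set.seed(21)
  for (r in 1:10) {
    n <- 30
    d <- data.frame(time_obs = round(rexp(n, 0.1), 6),  # no exact ties
                    status = rbinom(n, 1, 0.85),
                    x = rbinom(n, 1, 0.5))
    if (sum(d$status) < 2 || length(unique(d$x)) < 2) next
    lr <- logrank_test(d, d$x)
    sc <- survival::coxph(survival::Surv(time_obs, status) ~ x, data = d)
    expect_equal(lr$statistic, sc$score, tolerance = 1e-6)
  }
})

test_that("counting-process expansion follows the step-function convention", {
  base <- data.frame(id = 1:3, time_obs = c(5, 7, 2.5),
                     status = c(1, 0, 0), age = c(60, 55, 70))
  long <- data.frame(id = c(1, 1, 1, 2, 3, 3, 3),
                     t = c(0, 1, 3, 0, 0, 1, 3),
                     y = c(10, 11, 12, 20, 30, 31, 32))
  cp <- to_counting_process(base, long)
  p1 <- cp[cp$id == 1, ]
  expect_equal(p1$start, c(0, 1, 3))
  expect_equal(p1$stop, c(1, 3, 5))
  expect_equal(p1$y, c(10, 11, 12))
  expect_equal(p1$status, c(0, 0, 1))
  ## single baseline measurement, censored
  p2 <- cp[cp$id == 2, ]
  expect_equal(unlist(p2[, c("start", "stop", "status")], use.names = FALSE),
               c(0, 7, 0))
  ## censored between measurements: later value unused
  p3 <- cp[cp$id == 3, ]
  expect_equal(p3$stop, c(1, 2.5))
  expect_equal(p3$y, c(30, 31))
  ## patient without usable measurement is dropped with a warning
  base4 <- rbind(base, data.frame(id = 4, time_obs = 3, status = 1, age = 50))
  expect_warning(cp4 <- to_counting_process(base4, long), "dropped")
  expect_false(4 %in% cp4$id)
})

test_that("extended Cox equals ordinary Cox when the covariate is constant", {
  set.seed(31)
  n <- 60
  base <- data.frame(id = seq_len(n), time_obs = rexp(n, 0.08) + 0.5,
                     status = rbinom(n, 1, 0.7), z = rnorm(n))
  long <- do.call(rbind, lapply(seq_len(n), function(i) {
    tt <- c(0, 1, 3, 6); tt <- tt[tt < base$time_obs[i]]
    data.frame(id = i, t = tt, y = base$z[i])   # constant per patient
  }))
  cp <- to_counting_process(base, long)
  f1 <- fit_extended_cox(cp, "y")
  f2 <- fit_cox(base, "z")
  expect_equal(unname(f1$gamma), unname(f2$gamma), tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("extended Cox maximizes the time-varying partial likelihood (grid oracle)", {
  cp <- data.frame(id = c(1, 1, 2, 2, 3, 4),
                   start = c(0, 1, 0, 2, 0, 0),
                   stop = c(1, 3, 2, 4, 2.5, 5),
                   status = c(0, 1, 0, 1, 0, 1),
                   y = c(0.5, 0.2, -0.3, 0.7, 0.4, -0.2))
  fit <- fit_extended_cox(cp, "y")
  plik <- function(g) {
    s <- 0
    for (i in which(cp$status == 1)) {
      te <- cp$stop[i]
      rs <- cp$start < te & te <= cp$stop
      s <- s + g * cp$y[i] - log(sum(exp(g * cp$y[rs])))
    }
    s
  }
  grid <- seq(-6, 6, by = 1e-4)
  ghat <- grid[which.max(vapply(grid, plik, 0))]
  expect_equal(unname(fit$gamma), ghat, tolerance = 1e-4)
})

test_that("omission and LOCF give the identical extended Cox model", {
  cfg <- small_config(n = 120, seed = 13, alpha = 0.2)
  co <- simulate_cohort(cfg)
  base <- co$baseline
  M <- long_to_trajectory(co$longitudinal, cfg$schedule)
  long_locf <- trajectory_to_long(locf_impute(M))
  tmax <- base$time_obs[match(long_locf$id, base$id)]
  long_locf <- long_locf[long_locf$t < tmax, ]
  f_omit <- fit_extended_cox(to_counting_process(base, co$longitudinal),
                             c("age", "sex", "extra_mets", "y"))
  f_locf <- fit_extended_cox(to_counting_process(base, long_locf),
                             c("age", "sex", "extra_mets", "y"))
  expect_equal(f_omit$gamma, f_locf$gamma, tolerance = 1e-10)
})
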