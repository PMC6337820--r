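test_that("true trajectories follow the basis closed forms", {
  cfg <- small_config(traj_form = "rational", beta = c(1, 2),
                      delta = 1, eta = 1)
  expect_equal(simulate_trajectory(cfg, c(0, 0), 1), 1 + 2 / 2)
  ## exponential decay limit: m(t) -> beta0
  cfg2 <- small_config(traj_form = "exponential", beta = c(3.4, 1), delta = 0.5)
  expect_equal(simulate_trajectory(cfg2, c(0, 0), 1e6), 3.4)
  ## b_i = -beta cancels everything (z = x convention)
  expect_equal(simulate_trajectory(cfg2, -cfg2$beta, c(0, 1, 5, 12)),
               rep(0, 4))
  expect_error(simulate_trajectory(cfg2, 0, 1), "length")
  expect_error(simulate_trajectory(cfg2, c(0, 0), -1), "non-negative")
})

test_that("event times invert the cumulative hazard", {
  ## alpha = 0, gamma = 0, single constant piece: exponential closed form
  cfg <- small_config(alpha = 0, gamma = c(0, 0, 0),
                      h0_breaks = c(0, 1000), h0_heights = 0.05,
                      censor_time = 100)
  w <- c(age = 60, sex = 1, extra_mets = 0)
  for (u in c(0.1, 0.5, 0.9)) {
    expect_equal(simulate_event_time(cfg, w, c(0, 0), u), -log(u) / 0.05,
                 tolerance = 1e-7)
  }
  expect_error(simulate_event_time(cfg, w, c(0, 0), 0), "strictly")

  ## monotonicity in the linear predictor: same u, larger gamma'w
  cfg2 <- small_config(alpha = 0.2)
  t_lo <- simulate_event_time(cfg2, c(age = 50, sex = 0, extra_mets = 0),
                              c(0, 0), 0.4)
  t_hi <- simulate_event_time(cfg2, c(age = 80, sex = 1, extra_mets = 1),
                              c(0, 0), 0.4)
  expect_lt(t_hi, t_lo)
})

test_that("sampled event times satisfy H(T*) = -log u against a trapezoid oracle", {
  cfg <- small_config(n = 40, seed = 9, alpha = 0.25)
  set.seed(33)
  q <- basis_dim(cfg$basis)
  for (r in 1:20) {
    w <- c(age = rnorm(1, 62, 11), sex = rbinom(1, 1, 0.5),
           extra_mets = rbinom(1, 1, 0.5))
    b <- as.numeric(crossprod(chol(cfg$D), rnorm(q)))
    u <- runif(1, 0.05, 0.95)
    Tst <- simulate_event_time(cfg, w, b, u)
    if (!is.finite(Tst)) next
    ## independent fine trapezoid quadrature, piecewise so that no panel
    ## straddles a baseline-hazard jump
    brk <- c(cfg$h0_breaks, max(cfg$h0_breaks[length(cfg$h0_breaks)], Tst))
    hts <- c(cfg$h0_heights, cfg$h0_heights[length(cfg$h0_heights)])
    H <- 0
    for (p in which(brk[-length(brk)] < Tst)) {
      a <- brk[p]; bnd <- min(brk[p + 1], Tst)
      if (bnd <= a) next
      tt <- seq(a, bnd, length.out = 4001)
      m <- simulate_trajectory(cfg, b, tt)
      haz <- hts[p] * exp(sum(cfg$gamma * w) + cfg$alpha * m)
      H <- H + sum(diff(tt) * (haz[-1] + haz[-length(tt)]) / 2)
    }
    expect_equal(H, -log(u), tolerance = 1e-6)
  }
})

test_that("event sampler matches the exponential law when alpha = 0", {
  cfg <- small_config(n = 5000, seed = 17, alpha = 0,
                      gamma = c(0, 0, 0), h0_breaks = c(0, 1000),
                      h0_heights = 0.04, censor_time = 1e6,
                      dropout_prob = 0, intermittent_miss_prob = 0)
  co <- simulate_cohort(cfg)
  expect_true(all(co$baseline$status == 1))
  ks <- suppressWarnings(ks.test(co$baseline$time_obs, "pexp", 0.04))
  expect_gt(ks$p.value, 0.001)
})

test_that("missingness mechanism has the advertised structure", {
  cfg0 <- small_config(n = 100, seed = 2, dropout_prob = 0,
                       intermittent_miss_prob = 0)
  co0 <- simulate_cohort(cfg0)
  expect_identical(co0$longitudinal, co0$truth$y_complete)

  cfg1 <- small_config(n = 100, seed = 2, dropout_prob = 1)
  co1 <- simulate_cohort(cfg1)
  expect_true(all(co1$longitudinal$t == 0))
  expect_setequal(co1$longitudinal$id, co1$baseline$id)

  ## retention curve: visit k retained w.p. (1-p)^(k-1), among patients
  ## still under observation; use a long censor time to avoid death
  cfg2 <- small_config(n = 2000, seed = 8, dropout_prob = 0.15,
                       intermittent_miss_prob = 0,
                       h0_heights = rep(1e-6, 6), censor_time = 100)
  co2 <- simulate_cohort(cfg2)
  tab <- table(factor(co2$longitudinal$t, levels = cfg2$schedule))
  for (k in 2:6) {
    p_keep <- (1 - 0.15)^(k - 1)
    ci <- qbinom(c(0.0005, 0.9995), 2000, p_keep)
    expect_gte(tab[k], ci[1])
    expect_lte(tab[k], ci[2])
  }
})

test_that("cohorts are reproducible and internally consistent", {
  cfg <- small_config(n = 80, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$longitudinal, b$longitudinal)

  ## no record postdates the observed time
  tmax <- a$baseline$time_obs[match(a$longitudinal$id, a$baseline$id)]
  expect_true(all(a$longitudinal$t < tmax))
  ## observed time and status agree with the truth record
  expect_equal(a$baseline$time_obs,
               pmin(a$truth$t_star, cfg$censor_time))
  expect_identical(a$baseline$status,
                   as.integer(a$truth$t_star <= cfg$censor_time))

  ## forced censoring
  cfg0 <- small_config(n = 30, seed = 4, censor_time = 1e-3)
  expect_true(all(simulate_cohort(cfg0)$baseline$status == 0))
})

test_that("residuals around the truth have SD sigma", {
  cfg <- small_config(n = 800, seed = 5, dropout_prob = 0,
                      intermittent_miss_prob = 0)
  co <- simulate_cohort(cfg)
  m <- mapply(function(id, t)
    simulate_trajectory(cfg, co$truth$b[id, ], t),
    co$longitudinal$id, co$longitudinal$t)
  expect_equal(sd(co$longitudinal$y - m), cfg$sigma, tolerance = 0.02)
})

test_that("a positive association makes high biomarker levels fatal sooner", {
  cfg <- small_config(n = 2000, seed = 31, alpha = 0.2)
  co <- simulate_cohort(cfg)
  m6 <- basis_matrix(6, cfg$basis) %*% (cfg$beta + t(co$truth$b))
  ev <- co$baseline$status == 1
  tau <- cor(drop(m6)[ev], co$baseline$time_obs[ev], method = "kendall")
  expect_lt(tau, 0)
})

test_that("cohort round-trips through CSV", {
  cfg <- small_config(n = 20, seed = 6)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$baseline$time_obs, co$baseline$time_obs)
  expect_equal(back$longitudinal$y, co$longitudinal$y)
})
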