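# Small cohorts and configs shared across test files.

small_config <- function(n = 60, seed = 1, ...) {
  cohort_config(n_patients = n, seed = seed, ...)
}

# two well-separated slope groups on the default schedule: steep decay vs
# flat, used for clustering tests
two_group_series <- function(n_per = 20, noise_sd = 0.05, seed = 42,
                             times = c(0, 1, 3, 6, 9, 12)) {
  set.seed(seed)
  steep <- t(replicate(n_per, 4 - 0.25 * times + rnorm(length(times), 0, noise_sd)))
  flat <- t(replicate(n_per, 3 + 0.02 * times + rnorm(length(times), 0, noise_sd)))
  list(M = trajectory_matrix(rbind(steep, flat), times),
       labels = rep(1:2, each = n_per))
}

# smooth per-patient exponential-decay trajectories for mask-and-recover
smooth_trajectories <- function(n = 60, seed = 1,
                                times = c(0, 1, 3, 6, 9, 12)) {
  set.seed(seed)
  rate <- runif(n, 0.1, 0.6)
  level <- rnorm(n, 3.5, 0.5)
  amp <- rnorm(n, 1, 0.3)
  Y <- t(sapply(seq_len(n), function(i)
    level[i] + amp[i] * exp(-rate[i] * times) + rnorm(length(times), 0, 0.05)))
  trajectory_matrix(Y, times)
}
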