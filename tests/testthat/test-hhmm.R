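# hand-set small models reused across tests
toy_theta <- function(K, p, base = -1.2, wob = 0.8) {
  lapply(seq_len(K), function(j) {
    th <- matrix(0, p, K - 1)
    th[1, ] <- base + 0.3 * j
    if (p >= 3) th[2, ] <- wob * (-1)^j
    if (p >= 3) th[3, ] <- -wob / 2
    th
  })
}

test_that("forward-backward posteriors match exhaustive path enumeration", {
  # 3 states, T = 6, time-varying transitions, one missing observation
  fit3 <- hhmm_model(means = c(1, 3, 6), sds = c(0.6, 0.8, 1.1),
                     theta = toy_theta(3, 3), pi0 = c(0.5, 0.3, 0.2))
  clock <- c(0, 4, 8, 12, 16, 20)
  y <- c(1.2, 2.8, NA, 6.3, 3.1, 0.9)
  dec <- decode(fit3, y, clock)
  oracle <- brute_force_posteriors(emission_logdens(y, fit3$means, fit3$sds),
                                   fit3$pi0, fit_trans_array(fit3, clock))
  expect_lt(max(abs(dec$gamma - oracle$gamma)), 1e-10)
  expect_lt(abs(dec$loglik - oracle$loglik), 1e-10)

  # 2 states, T = 8, harmonic transitions
  th2 <- list(matrix(c(-0.5, 1.0, 0.3), 3, 1), matrix(c(-1.5, -0.6, 0.9), 3, 1))
  fit2 <- hhmm_model(means = c(0, 2), sds = c(1, 1), theta = th2,
                     pi0 = c(0.7, 0.3))
  clock2 <- seq(0, 21, by = 3)
  y2 <- c(0.4, -0.2, 1.9, 2.3, 0.1, NA, 2.2, 0.6)
  dec2 <- decode(fit2, y2, clock2)
  oracle2 <- brute_force_posteriors(emission_logdens(y2, fit2$means, fit2$sds),
                                    fit2$pi0, fit_trans_array(fit2, clock2))
  expect_lt(max(abs(dec2$gamma - oracle2$gamma)), 1e-10)
  expect_lt(abs(dec2$loglik - oracle2$loglik), 1e-10)
  expect_equal(rowSums(dec2$gamma), rep(1, 8), tolerance = 1e-8)
})

test_that("realized transition matrices are stochastic, periodic and softmax-consistent", {
  fit <- hhmm_model(means = c(1, 3, 6), sds = rep(1, 3), theta = toy_theta(3, 3))
  for (t in c(0, 3.7, 11, 23.9)) {
    P <- transition_matrix(fit, t)
    expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-12)
    expect_true(all(P > 0 & P < 1))
    expect_equal(P, transition_matrix(fit, t + 24), tolerance = 1e-12)
  }
  # zero harmonic coefficients: identical matrix at every clock time
  flat <- hhmm_model(means = c(1, 3, 6), sds = rep(1, 3),
                     theta = toy_theta(3, 3, wob = 0))
  expect_equal(transition_matrix(flat, 2), transition_matrix(flat, 14),
               tolerance = 1e-12)
  # all-zero logits give the uniform softmax row
  unif <- hhmm_model(means = c(1, 3, 6), sds = rep(1, 3),
                     theta = replicate(3, matrix(0, 3, 2), simplify = FALSE))
  expect_equal(transition_matrix(unif, 5), matrix(1 / 3, 3, 3),
               tolerance = 1e-12)
})

test_that("EM fits a synthetic subject with monotone log-likelihood and ordered states", {
  co <- generate_cohort(1, 0, n_days = 7, seed = 2)
  b5 <- subject_bins(co$subjects[[1]])
  fit <- fit_hhmm(b5$y, b5$clock, seed = 1)
  expect_true(all(diff(fit$ll_trace) > -1e-6))
  expect_true(all(diff(fit$means) > 0))
  expect_false("loglik_decrease" %in% fit$flags)
  expect_true(fit$converged)
  # emission recovery: observed sqrt of 5-min mean PA has mean ~ sqrt(mu^2+sigma^2)
  p <- co$subjects[[1]]$latent$params
  eff_means <- sqrt(p$state_means^2 + p$state_sds^2)
  expect_lt(max(abs(fit$means - eff_means)), 0.1 * diff(range(eff_means)))
})

test_that("data without circadian modulation yields a flat fitted transition curve", {
  p <- gen_params(harmonic_amp = c(0, 0, 0))
  act <- simulate_activity(schedule_spec("DS", 7), p, seed = 31)
  pa5 <- colMeans(matrix(act$pa, 5))
  y <- sqrt(pa5)
  clock <- ((seq_along(y) - 1) * 5 / 60) %% 24
  fit <- fit_hhmm(y, clock, seed = 1)
  grid <- seq(0, 23.9, by = 0.25)
  p11_t <- vapply(grid, function(t) transition_matrix(fit, t)[1, 1], 0)
  expect_lt(diff(range(p11_t)), 0.1)
})

test_that("a constant series falls back to a flagged single-state fit", {
  y <- rep(2, 600)
  fit <- fit_hhmm(y, ((seq_along(y) - 1) * 5 / 60) %% 24)
  expect_true("degenerate_single_state" %in% fit$flags)
})

test_that("fitting preconditions are enforced", {
  expect_error(fit_hhmm(rnorm(100), seq(0, 8, length.out = 100)), "2 days")
  y <- rnorm(600); y[1:350] <- NA
  expect_error(fit_hhmm(y, ((seq_len(600) - 1) / 12) %% 24), "missing")
})

test_that("widely separated emissions decode to the generating states", {
  fit <- hhmm_model(means = c(0, 10, 20), sds = c(0.01, 0.01, 0.01),
                    theta = toy_theta(3, 3))
  states <- rep(c(1, 2, 3, 2, 1), each = 20)
  y <- fit$means[states] + rnorm(100, 0, 0.005)
  dec <- decode(fit, y, ((seq_along(y) - 1) / 12) %% 24)
  expect_identical(dec$states, as.integer(states))
})

test_that("an all-missing stretch propagates the chain prior through transitions", {
  fit <- hhmm_model(means = c(1, 3, 6), sds = rep(0.8, 3),
                    theta = toy_theta(3, 3), pi0 = c(0.2, 0.5, 0.3))
  T_ <- 10
  clock <- ((seq_len(T_) - 1) * 2) %% 24
  y <- rep(NA_real_, T_)
  dec <- decode(fit, y, clock)
  marg <- fit$pi0
  expect_equal(dec$gamma[1, ], marg, tolerance = 1e-12)
  for (t in seq_len(T_ - 1)) {
    marg <- as.numeric(marg %*% transition_matrix(fit, clock[t]))
    expect_equal(dec$gamma[t + 1, ], marg, tolerance = 1e-10)
  }
})

test_that("the two-oscillator variant separates work and free-day transition curves", {
  co <- generate_cohort(0, 1, n_days = 7, seed = 4)  # NS: acrophase differs by day type
  s <- co$subjects[[1]]
  b5 <- subject_bins(s)
  part <- subject_partition(s)
  lab <- circashift:::bin_day_labels(b5$timestamp, part)
  fit <- fit_hhmm(b5$y, b5$clock, day_type = lab, seed = 1)
  expect_identical(fit$oscillator_set, c("work", "free"))
  # rest propensity into rest (row 2 -> 1) peaks at different clock times
  grid <- seq(0, 23.75, by = 0.25)
  pw <- vapply(grid, function(t) transition_matrix(fit, t, "work")[2, 1], 0)
  pf <- vapply(grid, function(t) transition_matrix(fit, t, "free")[2, 1], 0)
  expect_gt(max(abs(pw - pf)), 0.5 * max(pw - min(pw)))  # curves clearly differ
  peak_w <- grid[which.max(pw)]; peak_f <- grid[which.max(pf)]
  expect_gt(abs(circashift:::circ_diff_h(peak_w, peak_f)), 2)
  expect_error(transition_matrix(fit, 3), "day_type")
  single <- fit_hhmm(b5$y, b5$clock, seed = 1)
  expect_error(transition_matrix(single, 3, "work"), "single-oscillator")
})

test_that("AICc follows its closed form and exceeds AIC", {
  expect_equal(aicc(-5, k = 2, n = 10), 14 + 12 / 7, tolerance = 1e-12)
  expect_equal(aicc(-5, k = 0, n = 10), 10)
  for (k in 1:4) expect_gt(aicc(-5, k = k, n = 30), 2 * k + 10)
  expect_error(aicc(-5, k = 9, n = 10), "undefined")
})

test_that("fit serialization round-trips through JSON", {
  fit <- hhmm_model(means = c(1, 3, 6), sds = c(0.5, 1, 1.2),
                    theta = toy_theta(3, 3), pi0 = c(0.5, 0.3, 0.2))
  path <- withr::local_tempfile(fileext = ".json")
  write_hhmm_json(fit, path)
  back <- read_hhmm_json(path)
  expect_equal(back$means, fit$means)
  expect_equal(back$theta, fit$theta)
  expect_equal(back$pi0, fit$pi0)
  y <- c(1, 2, 6, 3, 1, 1)
  clock <- (0:5) * 4
  expect_equal(decode(back, y, clock)$gamma, decode(fit, y, clock)$gamma,
               tolerance = 1e-12)
})
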