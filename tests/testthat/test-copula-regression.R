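test_that("log odds transform matches its closed form and guards the boundary", {
  expect_equal(logit_transform(0.5), 0)
  expect_equal(logit_transform(0.96), log(24), tolerance = 1e-12)
  expect_equal(inv_logit(2.951), 0.950, tolerance = 5e-4)
  expect_equal(inv_logit(logit_transform(0.731)), 0.731, tolerance = 1e-12)
  expect_error(logit_transform(c(0.5, 1)), "0 or 1")
  expect_equal(logit_transform(1, clip = 1e-4), log((1 - 1e-4) / 1e-4))
})

test_that("independence (theta = 0) factorizes into two least-squares fits", {
  d <- sim_pair(120, theta = 0, seed = 3)
  spec <- model_spec("lop11", "ShT", "ShT")
  fit <- fit_copula(spec, d, theta_fixed = 0)
  lw <- lm(y_work ~ ShT, d); lf <- lm(y_free ~ ShT, d)
  expect_equal(unname(fit$coef_work), unname(coef(lw)), tolerance = 1e-6)
  expect_equal(unname(fit$coef_free), unname(coef(lf)), tolerance = 1e-6)
  # joint loglik equals the sum of the marginal Gaussian logliks (MLE sigma)
  ll <- function(m) {
    r <- resid(m); n <- length(r); s2 <- mean(r^2)
    -n / 2 * (log(2 * pi * s2) + 1)
  }
  expect_equal(fit$loglik, ll(lw) + ll(lf), tolerance = 1e-6)
})

test_that("Gaussian copula dependence is recovered and matches Kendall's tau", {
  d <- sim_pair(2000, theta = 0.5, seed = 7)
  fit <- fit_copula(model_spec("lop11", "ShT", "ShT"), d)
  expect_lt(abs(unname(fit$theta) - 0.5), 0.06)
  # PIT residuals: tau = 2 asin(theta) / pi = 1/3 at theta = 0.5
  u <- pnorm(d$y_work, fit$coef_work[1] + fit$coef_work[2] * d$ShT,
             fit$sigma_work)
  v <- pnorm(d$y_free, fit$coef_free[1] + fit$coef_free[2] * d$ShT,
             fit$sigma_free)
  expect_lt(abs(cor(u, v, method = "kendall") - 1 / 3), 0.05)
})

test_that("archimedean copula densities integrate the dependence correctly", {
  # Clayton / Frank / Gumbel log-densities at independence-like settings
  u <- c(0.2, 0.5, 0.8); v <- c(0.3, 0.5, 0.9)
  expect_equal(circashift:::copula_logdens(u, v, 1e-9, "clayton"), rep(0, 3),
               tolerance = 1e-5)
  expect_equal(circashift:::copula_logdens(u, v, 0, "frank"), rep(0, 3))
  expect_equal(circashift:::copula_logdens(u, v, 1, "gumbel"), rep(0, 3))
  # density integrates to ~1 over the unit square (trapezoid on a fine grid)
  g <- seq(0.0005, 0.9995, length.out = 201)
  for (fam in c("clayton", "frank", "gumbel")) {
    th <- switch(fam, clayton = 2, frank = 5, gumbel = 1.8)
    dens <- exp(outer(g, g, function(a, b)
      circashift:::copula_logdens(a, b, th, fam)))
    expect_equal(mean(dens) * 1, 1, tolerance = 0.02)
  }
})

test_that("a night-shift effect on the work margin is recovered within 2 SE", {
  d <- sim_pair(140, theta = 0.5, seed = 11)
  fit <- fit_copula(model_spec("lop11", c("ShT", "Age"), "ShT"), d)
  est <- fit$coef_work["ShT"]; se <- fit$se_work["ShT"]
  expect_lt(abs(est - (-0.35)), 2 * se)
  expect_lt(se, 0.2)
})

test_that("model specs enforce marginality and drive the model matrices", {
  expect_error(model_spec("y", c("ShT", "ShT:Age"), "ShT"), "main effects")
  sp <- model_spec("y", c("ShT", "Age", "ShT:Age"), c("ShT"))
  d <- sim_pair(50)
  expect_equal(colnames(circashift:::spec_matrix(sp$terms_work, d)),
               c("(Intercept)", "ShT", "Age", "ShT:Age"))
})

test_that("AICc prefers the true nested model and backward search respects it", {
  wins <- vapply(1:10, function(s) {
    d <- sim_pair(150, theta = 0.4, seed = 100 + s)
    full <- suppressWarnings(
      fit_copula(model_spec("y", c("ShT", "Age", "CS", "YNW"),
                            c("ShT", "Age", "CS", "YNW")), d))
    true_m <- fit_copula(model_spec("y", "ShT", "ShT"), d)
    true_m$aicc < full$aicc
  }, TRUE)
  expect_gte(mean(wins), 0.8)

  d <- sim_pair(150, theta = 0.4, seed = 55)
  best <- suppressWarnings(select_model(d, full_terms = c("ShT", "Age", "CS")))
  full <- suppressWarnings(
    fit_copula(model_spec("y", c("ShT", "Age", "CS"), c("ShT", "Age", "CS")), d))
  expect_lte(best$aicc, full$aicc)
  expect_true("ShT" %in% best$spec$terms_work)
  expect_true(length(attr(best, "search_path")) >= 1)
})

test_that("Wald z-tests reproduce estimate/SE ratios from printed coefficients", {
  fake <- structure(list(
    coef_work = c("(Intercept)" = 3.335, ShT = -0.350, Age = -0.009),
    se_work = c("(Intercept)" = 0.128, ShT = 0.073, Age = 0.003),
    coef_free = c("(Intercept)" = 2.951, ShT = -0.242),
    se_free = c("(Intercept)" = 0.062, ShT = 0.094)), class = "copula_fit")
  tab <- wald_z(fake)
  z <- tab$z.value[tab$margin == "work" & tab$term == "ShT"]
  expect_equal(z, -0.350 / 0.073, tolerance = 1e-12)
  expect_equal(round(z, 3), -4.795, tolerance = 0.02)  # printed -4.783 (rounding)
  expect_lt(tab$`Pr(>|z|)`[2], 1e-4)
  # z = 1.96 SEs -> p ~ 0.05; z = 0 -> p = 1
  f2 <- structure(list(coef_work = c(a = 1.96), se_work = c(a = 1),
                       coef_free = c(a = 0), se_free = c(a = 1)),
                  class = "copula_fit")
  t2 <- wald_z(f2)
  expect_equal(t2$`Pr(>|z|)`[1], 0.05, tolerance = 1e-3)
  expect_equal(t2$`Pr(>|z|)`[2], 1)
})

test_that("nonparametric wrappers delegate to the standard tests", {
  withr::with_seed(20, {
    a <- rnorm(60); b <- rnorm(60) + 1.2
    expect_lt(group_tests(c(a, b), rep(c("x", "y"), each = 60),
                          "mann_whitney")$p.value, 0.001)
    expect_gt(group_tests(a, a + rnorm(60, 0, 0.5),
                          "wilcoxon_signed_rank")$p.value, 0.05)
    expect_equal(unname(group_tests(1:20, (1:20)^3, "spearman")$estimate), 1)
    kw <- group_tests(c(a, b), rep(1:2, each = 60), "kruskal_wallis")
    expect_lt(kw$p.value, 0.001)
  })
})

test_that("power computations match the noncentral-t oracle", {
  expect_equal(power_sample_size(0.5, 0.05, 0.80), 64)
  n17 <- ceiling(power.t.test(delta = 1, sd = 1, sig.level = 0.05,
                              power = 0.8)$n)
  expect_equal(power_sample_size(1.0, 0.05, 0.80), n17)
  expect_equal(n17, 17)
  expect_equal(cohens_d(0.015, 0.03), 0.5)
  expect_equal(cohens_d(0.07, 0.14), 0.5)
  expect_error(power_sample_size(0), "d must be")
  expect_error(power_sample_size(0.5, 0.05, 0.04), "power")
})
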