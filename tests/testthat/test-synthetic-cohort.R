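test_that("cohort construction honours schedules, sizes and metadata ranges", {
  co <- generate_cohort(1, 1, n_days = 7, seed = 1)
  expect_length(co$subjects, 2)
  for (s in co$subjects) {
    expect_equal(nrow(s$series), 7 * 1440)
    part <- subject_partition(s)
    expect_true(eligibility(part)$eligible)
  }

  ns_only <- generate_cohort(0, 5, n_days = 7, seed = 3)
  meta <- cohort_meta(ns_only)
  expect_true(all(meta$shift_type == "NS"))
  expect_true(all(meta$age >= 22 & meta$age <= 62))
  expect_true(all(meta$chronotype_score >= 24 & meta$chronotype_score <= 74))
  expect_true(all(meta$years_night_work >= 0 & meta$years_night_work <= 35))
  for (s in ns_only$subjects) {
    work <- s$diary[s$diary$kind == "work", ]
    expect_true(all(format(work$start, "%H:%M") == "21:00"))
    expect_true(all(format(work$end, "%H:%M") == "07:00"))
    expect_equal(as.numeric(difftime(work$end, work$start, units = "hours")),
                 rep(10, nrow(work)))
  }
})

test_that("generation is byte-identical under the same seed", {
  a <- generate_cohort(2, 1, n_days = 4, seed = 7)
  b <- generate_cohort(2, 1, n_days = 4, seed = 7)
  expect_identical(a, b)
  c2 <- generate_cohort(2, 1, n_days = 4, seed = 8)
  expect_false(identical(a$subjects[[1]]$series$pa, c2$subjects[[1]]$series$pa))
})

test_that("generation refuses schedules that cannot be eligible", {
  expect_error(generate_cohort(1, 0, n_days = 1, seed = 1), "free day")
  expect_error(schedule_spec("DS", 1), "workday")
  expect_error(gen_params(state_means = c(3, 2, 6)), "increasing")
  expect_error(gen_params(missing_frac = 0.6), "0.5")
  expect_error(gen_params(ultradian_period_h = 8), "0.5, 6")
})

test_that("zero harmonic amplitude yields a time-homogeneous latent chain", {
  p <- gen_params(harmonic_amp = c(0, 0, 0))
  sch <- schedule_spec("DS", 100)  # long run for transition counts
  act <- simulate_activity(sch, p, seed = 5)
  st <- act$states
  # empirical transition counts against the constant matrix, chi-square GOF
  P <- circashift:::generator_transition(p, 0, "free")
  for (j in 1:3) {
    from <- which(st[-length(st)] == j)
    counts <- tabulate(st[from + 1L], 3)
    expect_gt(chisq.test(counts, p = P[j, ])$p.value, 0.01)
  }
})

test_that("circadian modulation places DS rest at night and NS rest after 07:00", {
  co <- generate_cohort(1, 1, n_days = 7, seed = 11)
  occupancy <- function(s, labels_wanted) {
    st <- s$latent$states
    t_bin <- (seq_along(st) - 1) * 5 / 60
    dt <- circashift:::schedule_day_type(s$schedule, t_bin)
    clock <- t_bin %% 24
    sel <- dt %in% labels_wanted
    sapply(split(st[sel] == 1, floor(clock[sel])), mean)
  }
  ds <- occupancy(co$subjects[[1]], c("work", "free"))
  expect_true(as.integer(names(which.max(ds))) %in% c(0:6, 22, 23))
  ns <- occupancy(co$subjects[[2]], "work")
  expect_gte(as.integer(names(which.max(ns))), 7)  # day-shifted rest
})

test_that("realized rest occupancy matches the occupancy implied by the generator", {
  # numeric oracle: forward-propagate the marginal distribution through the
  # generator's own transition matrices and compare occupancy
  p <- gen_params()
  sch <- schedule_spec("DS", 7)
  act <- simulate_activity(sch, p, seed = 21)
  t_bin <- (seq_len(7 * 288) - 1) * 5 / 60
  dtype <- circashift:::schedule_day_type(sch, t_bin)
  marg <- rep(1 / 3, 3)
  occ <- 0
  for (b in seq_along(t_bin)) {
    occ <- occ + marg[1]
    marg <- as.numeric(marg %*% circashift:::generator_transition(
      p, t_bin[b] %% 24, dtype[b]))
  }
  expect_lt(abs(mean(act$states == 1) - occ / length(t_bin)), 0.05)
})

test_that("an all-rest generator produces pure rest", {
  p <- gen_params(baseline_logits = rbind(c(0, -30, -30),
                                          c(30, 0, 0),
                                          c(30, 0, 0)),
                  harmonic_amp = c(0, 0, 0))
  act <- simulate_activity(schedule_spec("DS", 3), p, seed = 2)
  expect_true(all(act$states[-1] == 1))
})

test_that("temperature is built from the configured harmonics and rest-gated ultradian", {
  sch <- schedule_spec("DS", 7)
  p24 <- gen_params(temp_harmonics = data.frame(period_h = 24, amp_c = 1,
                                                phase_h = 4),
                    temp_noise_sd = 0, ultradian_amp_c = 0)
  tt <- simulate_temperature(sch, p24, rest_mask = rep(FALSE, 7 * 1440), seed = 1)
  t_h <- (seq_len(7 * 1440) - 1) / 60
  expect_equal(tt, 35 + cos(2 * pi * (t_h - 4) / 24), tolerance = 1e-12)

  # ultradian component present only where rest_mask is TRUE
  pu <- gen_params(temp_harmonics = data.frame(period_h = 24, amp_c = 0,
                                               phase_h = 0),
                   temp_noise_sd = 0, ultradian_amp_c = 0.5,
                   ultradian_period_h = 1.5)
  mask <- rep(FALSE, 7 * 1440); mask[1000:1400] <- TRUE
  tu <- simulate_temperature(sch, pu, mask, seed = 1)
  expect_true(all(tu[!mask] == 35))
  expect_gt(diff(range(tu[mask])), 0.9)
  expect_equal(tu[1000], 35.5)  # cycle restarts at bout onset
})

test_that("missingness injection hits the target fraction with bursty gaps", {
  co <- generate_cohort(1, 0, n_days = 7, seed = 1)
  s <- co$subjects[[1]]$series
  s$pa <- 1; s$temp <- 35  # reset to fully observed
  out <- inject_missingness(s, 0.0276, seed = 9)
  n_obs <- sum(!is.na(out$pa))
  expect_lt(abs(n_obs - round((1 - 0.0276) * 10080)), 150)  # gap rounding
  # gaps are contiguous blocks, not i.i.d. scatter: mean run length >> 1
  r <- rle(is.na(out$pa))
  expect_gt(mean(r$lengths[r$values]), 5)
  expect_identical(out, inject_missingness(s, 0.0276, seed = 9))
  expect_identical(s, inject_missingness(s, 0, seed = 1))
  expect_error(inject_missingness(s, 0.6, seed = 1), "0.5")
})
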