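fake_decoded <- function(g1, clock, observed = rep(TRUE, length(g1)),
                         day_type = NULL) {
  gamma <- cbind(g1, (1 - g1) / 2, (1 - g1) / 2)
  structure(list(gamma = gamma, states = max.col(gamma, "first"),
                 observed = observed, clock = clock, day_type = day_type,
                 loglik = NA_real_),
            class = "state_probabilities")
}

slot_clocks <- function(n_days) rep(((0:287) * 5 / 60), n_days)

test_that("rest profile averages posterior rest probability by clock slot", {
  clock <- slot_clocks(3)
  g1 <- as.numeric(clock %% 24 >= 1 & clock %% 24 < 5)
  dec <- fake_decoded(g1, clock)
  prof <- rest_profile(dec)
  expect_s3_class(prof, "rest_profile")
  expect_length(prof, 288)
  expect_equal(as.numeric(prof), g1[1:288])

  # two days with slot values 0.4 and 0.6 average to 0.5
  dec2 <- fake_decoded(c(rep(0.4, 288), rep(0.6, 288)), slot_clocks(2))
  expect_equal(as.numeric(rest_profile(dec2)), rep(0.5, 288))

  # a slot missing on one day is excluded from that slot's mean
  obs <- rep(TRUE, 576); obs[1] <- FALSE
  dec3 <- fake_decoded(c(rep(0.4, 288), rep(0.6, 288)), slot_clocks(2),
                       observed = obs)
  expect_equal(as.numeric(rest_profile(dec3))[1], 0.6)
})

test_that("scoped rest profiles use only the requested days", {
  start <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  ts <- start + (0:575) * 300  # two DS days of 5-min bins
  clock <- slot_clocks(2)
  g1 <- c(rep(0.9, 288), rep(0.1, 288))  # day 1 resty, day 2 not
  dec <- fake_decoded(g1, clock)
  diary <- data.frame(kind = "work", start = start + 7 * 3600,
                      end = start + 14 * 3600)
  part <- partition_days(diary, list(shift_type = "DS"),
                         c(start, start + 2 * 86400))
  expect_equal(part$label, c("work", "free"))
  pw <- rest_profile(dec, ts, part, scope = "work")
  pf <- rest_profile(dec, ts, part, scope = "free")
  expect_equal(as.numeric(pw), rep(0.9, 288))
  expect_equal(as.numeric(pf), rep(0.1, 288))
  expect_error(rest_profile(dec, ts, part[part$label == "work", ], "free"),
               "no free days")
  # anchored profiles start at the anchor clock time
  pa20 <- rest_profile(dec, ts, part, scope = "work", anchor = 20)
  expect_equal(attr(pa20, "anchor"), 20)
})

test_that("p1-1 summarizes the rest-row transition curve with occupancy weights", {
  flat_theta <- function(p11_target, p = 3) {
    a <- log((1 - p11_target) / 2 / p11_target)
    th1 <- matrix(0, p, 2); th1[1, ] <- a
    list(th1, matrix(c(-2, 0, 0, -2, 0, 0), p, 2),
         matrix(c(-2, 0, 0, -2, 0, 0), p, 2))
  }
  clock <- slot_clocks(2)
  dec <- fake_decoded(rep(0.8, 576), clock)
  f9 <- hhmm_model(c(1, 3, 6), rep(1, 3), flat_theta(0.9))
  expect_equal(p11(f9, dec), 0.9, tolerance = 1e-10)
  f1 <- hhmm_model(c(1, 3, 6), rep(1, 3), flat_theta(1 - 1e-12))
  expect_equal(p11(f1, dec), 1, tolerance = 1e-6)

  # occupancy weighting: rest concentrated where P11(t) is high
  th1 <- matrix(c(-2.2, 1.5, 0), 3, 2)  # cos harmonic on the exit logits
  fit <- hhmm_model(c(1, 3, 6), rep(1, 3),
                    list(th1, matrix(-2, 3, 2), matrix(-2, 3, 2)))
  p11_t <- vapply(clock, function(t) transition_matrix(fit, t)[1, 1], 0)
  g1 <- as.numeric(clock %% 24 < 12)
  dec_w <- fake_decoded(g1, clock)
  expected <- sum(g1[-576] * p11_t[-576]) / sum(g1[-576])
  expect_equal(p11(fit, dec_w), expected, tolerance = 1e-10)
  expect_equal(p11(fit, dec_w, weighted = FALSE), mean(p11_t[-576]),
               tolerance = 1e-10)
  expect_warning(res <- p11(fit, fake_decoded(rep(0, 576), clock)),
                 "undefined")
  expect_true(is.na(res))
})

test_that("rest amount is the area under the profile in hours", {
  expect_equal(rest_amount(rect_profile(0, 24, 1)), 24)
  expect_equal(rest_amount(rect_profile(0, 24, 0.5, 0.5)), 12)
  expect_equal(rest_amount(rect_profile(2, 6)), 4)
})

test_that("centre of rest is the circular gravity centre", {
  expect_equal(centre_of_rest(rect_profile(1, 5)), 3, tolerance = 1e-9)
  expect_equal(centre_of_rest(rect_profile(23, 1)) %% 24, 0, tolerance = 1e-9)
  # equivariance under rotation
  p0 <- rect_profile(22, 6, 0.9, 0.05)
  p2 <- rect_profile(0, 8, 0.9, 0.05)
  expect_equal((centre_of_rest(p2) - centre_of_rest(p0)) %% 24, 2,
               tolerance = 1e-9)
  expect_true(is.na(centre_of_rest(rect_profile(0, 24, 0.4, 0.4))))
})

test_that("daytime rest maximum restricts to the window with earliest-tie rule", {
  p <- rect_profile(2, 4, 1, 0)
  p[which(abs(slot_clocks(1) - 11) < 0.5 / 12)] <- 0.5  # local bump at 11:00
  expect_equal(alt_centre_max_daytime(p), 11, tolerance = 1e-9)
  flat <- rect_profile(0, 24, 0.3, 0.3)
  expect_equal(alt_centre_max_daytime(flat), 7, tolerance = 1e-9)
  ns <- rect_profile(8, 14, 0.8, 0.1)
  m <- alt_centre_max_daytime(ns)
  expect_true(m >= 7 && m <= 20)
})

test_that("Rhythm Index satisfies its boundary conditions and the direct formula", {
  expect_equal(rhythm_index(rect_profile(23, 7)), 1)
  expect_equal(rhythm_index(rect_profile(0, 24, 0.4, 0.4)), 0)
  expect_equal(rhythm_index(rect_profile(0, 24, 0, 0)), 0)
  # two-level profile: 0.8 inside its own window, 0.3 outside -> contrast 0.5
  two <- rect_profile(12 - 7.2, 12 + 7.2, 0.8, 0.3)
  expect_equal(rhythm_index(two), 0.5, tolerance = 0.02)
  # full-rest profile: RI equals the profile mean by convention
  expect_equal(rhythm_index(rect_profile(0, 24, 1, 1)), 1)
})

test_that("circadian parameters stay in range and RI is rotation invariant", {
  withr::with_seed(99, {
    for (i in 1:25) {
      v <- pmin(1, pmax(0, stats::filter(runif(288), rep(1 / 12, 12),
                                         circular = TRUE)))
      prof <- structure(as.numeric(v), anchor = 0, class = "rest_profile")
      ri <- rhythm_index(prof)
      expect_gte(ri, 0); expect_lte(ri, 1)
      ra <- rest_amount(prof)
      expect_gte(ra, 0); expect_lte(ra, 24)
      ct <- centre_of_rest(prof)
      if (!is.na(ct)) { expect_gte(ct, 0); expect_lt(ct, 24) }
      # rotating the profile leaves RI unchanged
      k <- sample(287, 1)
      rot <- structure(as.numeric(prof)[c((k + 1):288, 1:k)], anchor = 0,
                       class = "rest_profile")
      expect_equal(rhythm_index(rot), ri, tolerance = 1e-8)
    }
  })
})
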