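#' Shift schedule specification
#'
#' Describes the monitoring window of one subject: shift type, number of
#' monitored days and which days are workdays.  Day shifters (DS) alternate
#' morning (07:00--14:00) and afternoon (14:00--21:00) shifts; night shifters
#' (NS) work 21:00--07:00.  A valid schedule has at least one workday and at
#' least one free day, the eligibility rule applied to the study cohort.
#'
#' @param shift_type `"DS"` or `"NS"`.
#' @param n_days integer number of monitored calendar days (>= 2).
#' @param work_day_flags logical vector of length `n_days`; `TRUE` marks a
#'   workday.  For NS the flag refers to the 24 h span anchored at the night
#'   shift start (day `d` flagged means a shift starting 21:00 on calendar
#'   day `d`).  Default: all days but the last two are workdays.
#' @param ns_anchor clock hour at which NS shifts start (20 or 21).
#' @return An object of class `schedule_spec` with the shift intervals in
#'   hours from the start of monitoring.
#' @export
schedule_spec <- function(shift_type = c("DS", "NS"), n_days = 7,
                          work_day_flags = NULL, ns_anchor = 21) {
  shift_type <- match.arg(shift_type)
  n_days <- as.integer(n_days)
  if (n_days < 2) {
    stop_input("n_days = %d cannot satisfy >=1 workday and >=1 free day", n_days)
  }
  if (is.null(work_day_flags)) {
    work_day_flags <- rep(c(TRUE, FALSE), c(max(1L, n_days - 2L),
                                            min(2L, n_days - 1L)))
  }
  stopifnot(length(work_day_flags) == n_days, is.logical(work_day_flags))
  if (!any(work_day_flags) || all(work_day_flags)) {
    stop_input("schedule needs at least one workday and one free day")
  }
  if (!ns_anchor %in% c(20, 21)) stop_input("ns_anchor must be 20 or 21")

  work_idx <- which(work_day_flags)
  if (shift_type == "DS") {
    # alternate morning / afternoon shifts across successive workdays
    morning <- seq_along(work_idx) %% 2L == 1L
    start_h <- (work_idx - 1L) * 24 + ifelse(morning, 7, 14)
    end_h <- start_h + 7
  } else {
    start_h <- (work_idx - 1L) * 24 + ns_anchor
    end_h <- start_h + (31 - ns_anchor)  # 21:00 (or 20:00) to 07:00
  }
  structure(list(
    shift_type = shift_type, n_days = n_days,
    work_day_flags = work_day_flags, ns_anchor = ns_anchor,
    shifts = data.frame(day = work_idx, start_h = start_h, end_h = end_h)
  ), class = "schedule_spec")
}

#' Generator parameters for synthetic telemetry
#'
#' Parameters of the synthetic-cohort generator.  The latent rest/activity
#' process is a 3-state Markov chain at 5-min resolution whose transition
#' logits carry a 24 h sinusoid peaking at the rest acrophase; emissions are
#' Gaussian on the square-root activity scale and squared to (arbitrary,
#' non-negative) activity units.  Temperature is a sum of fixed harmonics, an
#' ultradian oscillation active only during rest, and white noise around a
#' 35 degC offset.
#'
#' @param state_means,state_sds Gaussian emission means/SDs on the sqrt
#'   activity scale, ordered rest < moderate < high.
#' @param baseline_logits 3x3 matrix of baseline transition logits with the
#'   self-transition as reference category (diagonal ignored).
#' @param harmonic_amp length-3 sinusoid amplitude per state row; row 1
#'   modulates exit from rest, rows 2-3 modulate entry into rest.
#' @param acrophase_work,acrophase_free clock hour of maximal rest propensity
#'   on work and free days.
#' @param temp_harmonics data frame with columns `period_h`, `amp_c`,
#'   `phase_h` describing the temperature harmonics.
#' @param ultradian_period_h period (h) of the within-rest temperature cycle,
#'   in \[0.5, 6\].
#' @param ultradian_amp_c,temp_noise_sd,temp_base_c amplitude of the
#'   ultradian component, white-noise SD and baseline offset, all in degC.
#' @param missing_frac target fraction of missing minutes (< 0.5).
#' @return An object of class `gen_params`.
#' @export
gen_params <- function(state_means = c(1, 3, 6),
                       state_sds = c(0.5, 1, 1.2),
                       baseline_logits = rbind(c(0, -2.5, -4.2),
                                               c(-3.7, 0, -2.4),
                                               c(-4.4, -2.0, 0)),
                       harmonic_amp = c(1.5, 2, 2),
                       acrophase_work = 3, acrophase_free = 3,
                       temp_harmonics = data.frame(
                         period_h = c(24, 12, 8),
                         amp_c = c(0.8, 0.3, 0.1),
                         phase_h = c(5, 2, 0)),
                       ultradian_period_h = 2.2,
                       ultradian_amp_c = 0.25,
                       temp_noise_sd = 0.15,
                       temp_base_c = 35,
                       missing_frac = 0.0276) {
  if (any(diff(state_means) <= 0)) {
    stop_input("state_means must be strictly increasing")
  }
  if (any(state_sds <= 0)) stop_input("state_sds must be positive")
  if (missing_frac >= 0.5) stop_input("missing_frac must be < 0.5")
  if (ultradian_period_h < 0.5 || ultradian_period_h > 6) {
    stop_input("ultradian_period_h must lie in [0.5, 6]")
  }
  stopifnot(is.matrix(baseline_logits), dim(baseline_logits) == c(3, 3),
            length(harmonic_amp) == 3)
  structure(list(
    state_means = state_means, state_sds = state_sds,
    baseline_logits = baseline_logits, harmonic_amp = harmonic_amp,
    acrophase_work = acrophase_work, acrophase_free = acrophase_free,
    temp_harmonics = temp_harmonics,
    ultradian_period_h = ultradian_period_h,
    ultradian_amp_c = ultradian_amp_c,
    temp_noise_sd = temp_noise_sd, temp_base_c = temp_base_c,
    missing_frac = missing_frac
  ), class = "gen_params")
}

# day type ("work"/"free") of each time point, using the study's day anchors:
# DS days are anchored at 00:00, NS days at the night-shift start clock time.
schedule_day_type <- function(schedule, t_hours) {
  anchor <- if (schedule$shift_type == "DS") 0 else schedule$ns_anchor
  day <- floor((t_hours - anchor) / 24) + 1L  # window containing the anchor day
  flags <- schedule$work_day_flags
  day[day < 1L] <- NA  # leading partial window before the first anchor
  day[day > length(flags)] <- NA
  out <- ifelse(is.na(day), FALSE, flags[pmax(day, 1L)])
  ifelse(out, "work", "free")
}

# time-varying generator transition matrix at clock hour t (5-min step scale)
generator_transition <- function(params, t_hours, day_type) {
  acro <- ifelse(day_type == "work", params$acrophase_work,
                 params$acrophase_free)
  s <- params$harmonic_amp * rep(cos(2 * pi * (t_hours - acro) / 24), each = 3)
  L <- params$baseline_logits
  diag(L) <- 0
  L[1, 2:3] <- L[1, 2:3] - s[1]   # rest exit suppressed at acrophase
  L[2, 1] <- L[2, 1] + s[2]       # rest entry boosted at acrophase
  L[3, 1] <- L[3, 1] + s[3]
  P <- exp(L)
  P / rowSums(P)
}

#' Simulate a per-minute physical-activity series
#'
#' Samples the latent 3-state chain at 5-min resolution with
#' circadian-modulated transitions, then emits one Gaussian draw per minute on
#' the sqrt scale (squared back to activity units).  NS workday schedules
#' concentrate rest propensity after the 07:00 end of shift through the
#' work-day acrophase.
#'
#' @param schedule a [schedule_spec()].
#' @param params a [gen_params()].
#' @param seed integer seed.
#' @return A list with `pa` (per-minute activity), `states` (latent state per
#'   5-min block), and `rest_mask` (per-minute logical, `TRUE` during rest).
#' @export
simulate_activity <- function(schedule, params, seed = 1) {
  stopifnot(inherits(schedule, "schedule_spec"), inherits(params, "gen_params"))
  n_bins <- schedule$n_days * 288L
  t_bin <- (seq_len(n_bins) - 1L) * 5 / 60          # hours from start
  dtype <- schedule_day_type(schedule, t_bin)
  with_seed(seed, {
    P0 <- generator_transition(params, clock_hour(t_bin[1]), dtype[1])
    pi0 <- rep(1 / 3, 3)
    for (i in 1:100) pi0 <- as.numeric(pi0 %*% P0)  # near-stationary start
    states <- integer(n_bins)
    states[1] <- sample.int(3, 1, prob = pi0)
    u <- stats::runif(n_bins - 1L)
    for (b in seq_len(n_bins - 1L)) {
      P <- generator_transition(params, clock_hour(t_bin[b]), dtype[b])
      states[b + 1L] <- findInterval(u[b], cumsum(P[states[b], ]),
                                     left.open = TRUE) + 1L
    }
    st_min <- rep(states, each = 5L)
    x <- stats::rnorm(length(st_min), params$state_means[st_min],
                      params$state_sds[st_min])
    list(pa = x^2, states = states, rest_mask = st_min == 1L)
  })
}

#' Simulate a per-minute chest-surface temperature series
#'
#' Sum of the configured harmonics (default 24 h + 12 h + 8 h), an ultradian
#' sinusoid active only during rest (its phase restarts at each rest-bout
#' onset, emulating sleep cycles), and white noise, around a ~35 degC offset.
#'
#' @inheritParams simulate_activity
#' @param rest_mask per-minute logical marking rest, as returned by
#'   [simulate_activity()].
#' @return Numeric vector of per-minute temperature (degC).
#' @export
simulate_temperature <- function(schedule, params, rest_mask, seed = 1) {
  stopifnot(inherits(schedule, "schedule_spec"), inherits(params, "gen_params"))
  n_min <- schedule$n_days * 1440L
  if (length(rest_mask) != n_min) {
    stop_input("rest_mask length %d != %d monitoring minutes",
               length(rest_mask), n_min)
  }
  t_h <- (seq_len(n_min) - 1L) / 60
  temp <- rep(params$temp_base_c, n_min)
  for (i in seq_len(nrow(params$temp_harmonics))) {
    h <- params$temp_harmonics[i, ]
    temp <- temp + h$amp_c * cos(2 * pi * (t_h - h$phase_h) / h$period_h)
  }
  # ultradian cycle phase-locked to rest-bout onsets
  r <- rle(as.logical(rest_mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    tau <- (idx - starts[k]) / 60
    temp[idx] <- temp[idx] +
      params$ultradian_amp_c * cos(2 * pi * tau / params$ultradian_period_h)
  }
  with_seed(seed, temp + stats::rnorm(n_min, 0, params$temp_noise_sd))
}

#' Inject bursty missingness into a minute series
#'
#' Marks contiguous gaps (geometric lengths, mean 30 min) as missing in both
#' the activity and temperature channels, emulating telemetry dropouts, until
#' the target missing fraction is reached.  The realized observed count is
#' `round((1 - fraction) * N)` up to the rounding of the final gap.
#'
#' @param series a per-subject minute series `data.frame` with columns
#'   `pa` and `temp` (other columns preserved).
#' @param fraction target missing fraction in \[0, 0.5).
#' @param seed integer seed.
#' @param mean_gap_min mean gap length in minutes.
#' @return The series with gap minutes set to `NA`.
#' @export
inject_missingness <- function(series, fraction, seed = 1, mean_gap_min = 30) {
  if (fraction < 0 || fraction >= 0.5) {
    stop_input("missing fraction must lie in [0, 0.5)")
  }
  if (fraction == 0) return(series)
  n <- nrow(series)
  target <- round(fraction * n)
  with_seed(seed, {
    miss <- logical(n)
    while (sum(miss) < target) {
      len <- stats::rgeom(1, 1 / mean_gap_min) + 1L
      at <- sample.int(n, 1)
      miss[at:min(n, at + len - 1L)] <- TRUE
    }
    series$pa[miss] <- NA_real_
    series$temp[miss] <- NA_real_
    series
  })
}

#' Generate a synthetic shift-worker cohort
#'
#' Builds `n_ds` day-shifter and `n_ns` night-shifter subjects with per-minute
#' activity and temperature, a work/sleep diary, and questionnaire metadata
#' (age 22--62, chronotype score 24--74, years of night work 0--35), matching
#' the statistical structure the downstream pipeline assumes.  NS subjects
#' default to a post-shift rest acrophase (11:00 on workdays) and shorter
#' ultradian temperature cycles (1.8 h vs 2.2 h for DS).
#'
#' @param n_ds,n_ns number of day / night shifters (>= 0).
#' @param n_days monitored days per subject (>= 2).
#' @param params a [gen_params()]; used as-is for DS.
#' @param ns_overrides named list of `gen_params` fields overridden for NS:
#'   by default a post-shift rest acrophase, weaker circadian modulation of
#'   the transition logits and a higher rest-exit propensity (fragmented,
#'   less rhythmic rest), and shorter ultradian cycles.
#' @param seed master integer seed; the same seed reproduces the cohort
#'   exactly.
#' @param start naive local start timestamp of monitoring.
#' @param force_ds_zero_ynw if `TRUE` (default) DS subjects get 0 years of
#'   past night work.
#' @return An object of class `cohort`: a list of subjects, each holding
#'   `series` (subject_id, timestamp, pa, temp), `diary` (kind, start, end)
#'   and `meta`.
#' @export
generate_cohort <- function(n_ds, n_ns, n_days = 7, params = gen_params(),
                            ns_overrides = list(
                              acrophase_work = 11, acrophase_free = 4,
                              harmonic_amp = c(0.9, 1.2, 1.2),
                              baseline_logits = rbind(c(0, -2.1, -3.8),
                                                      c(-3.7, 0, -2.4),
                                                      c(-4.4, -2.0, 0)),
                              ultradian_period_h = 1.8),
                            seed = 1,
                            start = as.POSIXct("2024-03-04 00:00:00", tz = "UTC"),
                            force_ds_zero_ynw = TRUE) {
  stopifnot(n_ds >= 0, n_ns >= 0, n_ds + n_ns > 0)
  if (n_days < 2) {
    stop_input("n_days = %d cannot satisfy >=1 workday and >=1 free day", n_days)
  }
  ns_params <- params
  ns_params[names(ns_overrides)] <- ns_overrides
  ns_params <- do.call(gen_params, ns_params[names(formals(gen_params))])

  n <- n_ds + n_ns
  draws <- with_seed(seed, list(
    sub_seed = matrix(sample.int(2147483646L, 3L * n), nrow = n),
    age = round(stats::runif(n, 22, 62)),
    chronotype = round(stats::runif(n, 24, 74)),
    ynw = round(stats::runif(n, 5, 35)),
    ynw_ds = round(stats::runif(n, 0, 10)),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.95, 0.05)),
    ideal_tst = pmin(9.5, pmax(6, round(stats::rnorm(n, 8, 0.5), 1))),
    tst_ds = pmin(10, pmax(3, round(stats::rnorm(n, 6.8, 0.6), 1))),
    tst_ns = pmin(10, pmax(3, round(stats::rnorm(n, 5.0, 0.6), 1)))
  ))

  subjects <- vector("list", n)
  names(subjects) <- sprintf("S%03d", seq_len(n))
  for (i in seq_len(n)) {
    is_ns <- i > n_ds
    p <- if (is_ns) ns_params else params
    sched <- schedule_spec(if (is_ns) "NS" else "DS", n_days)
    act <- simulate_activity(sched, p, seed = draws$sub_seed[i, 1])
    temp <- simulate_temperature(sched, p, act$rest_mask,
                                 seed = draws$sub_seed[i, 2])
    ts <- start + (seq_len(n_days * 1440L) - 1L) * 60
    series <- data.frame(subject_id = names(subjects)[i], timestamp = ts,
                         pa = act$pa, temp = temp)
    series <- inject_missingness(series, p$missing_frac,
                                 seed = draws$sub_seed[i, 3])
    diary <- make_diary(sched, p, start)
    meta <- list(
      subject_id = names(subjects)[i],
      shift_type = if (is_ns) "NS" else "DS",
      age = draws$age[i], chronotype_score = draws$chronotype[i],
      years_night_work = if (is_ns) draws$ynw[i] else {
        if (force_ds_zero_ynw) 0 else draws$ynw_ds[i]
      },
      sex = draws$sex[i],
      ideal_tst_h = draws$ideal_tst[i],
      reported_tst_h = if (is_ns) draws$tst_ns[i] else draws$tst_ds[i]
    )
    subjects[[i]] <- list(series = series, diary = diary, meta = meta,
                          schedule = sched,
                          latent = list(states = act$states,
                                        rest_mask = act$rest_mask,
                                        params = p))
  }
  structure(list(subjects = subjects, start = start, n_days = n_days,
                 seed = seed),
            class = "cohort")
}

# work intervals from the schedule; nominal sleep intervals centred on the
# day-type acrophase
make_diary <- function(sched, params, start) {
  work <- data.frame(kind = character(), start = as.POSIXct(character(), tz = "UTC"),
                     end = as.POSIXct(character(), tz = "UTC"))
  if (nrow(sched$shifts) > 0) {
    work <- data.frame(kind = "work",
                       start = start + sched$shifts$start_h * 3600,
                       end = start + sched$shifts$end_h * 3600)
  }
  dtype <- schedule_day_type(sched, (seq_len(sched$n_days) - 1) * 24 + 12)
  acro <- ifelse(dtype == "work", params$acrophase_work, params$acrophase_free)
  s0 <- (seq_len(sched$n_days) - 1) * 24 + acro - 3.5
  sleep <- data.frame(kind = "sleep",
                      start = start + pmax(0, s0) * 3600,
                      end = start + pmin(sched$n_days * 24, s0 + 7) * 3600)
  sleep <- sleep[sleep$end > sleep$start, ]
  rbind(work, sleep)
}

#' @export
print.cohort <- function(x, ...) {
  types <- vapply(x$subjects, function(s) s$meta$shift_type, "")
  cat(sprintf("<cohort> %d subjects (%d DS, %d NS), %d days, seed %s\n",
              length(x$subjects), sum(types == "DS"), sum(types == "NS"),
              x$n_days, format(x$seed)))
  invisible(x)
}

#' Subject metadata table of a cohort
#'
#' @param cohort a `cohort` object.
#' @return One row per subject with the questionnaire covariates.
#' @export
cohort_meta <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s) {
    as.data.frame(s$meta, stringsAsFactors = FALSE)
  }))
}
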