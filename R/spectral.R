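# Missing-tolerant least-squares periodogram: for each candidate period,
# regress the demeaned series on a cos/sin pair and take the fitted power
# (a^2 + b^2)/2.  Closed-form 2x2 normal equations per period.
ls_periodogram <- function(x, t_hours, periods) {
  ok <- which(!is.na(x))
  xd <- x[ok] - mean(x[ok])
  tt <- t_hours[ok]
  vapply(periods, function(p) {
    w <- 2 * pi / p
    cv <- cos(w * tt); sv <- sin(w * tt)
    cc <- sum(cv * cv); ss <- sum(sv * sv); cs <- sum(cv * sv)
    xc <- sum(xd * cv); xs <- sum(xd * sv)
    det <- cc * ss - cs * cs
    if (abs(det) < 1e-12) return(0)
    a <- (xc * ss - xs * cs) / det
    b <- (xs * cc - xc * cs) / det
    (a^2 + b^2) / 2
  }, 0)
}

daniell_smooth <- function(d, window = 3) {
  if (window <= 1) return(d)
  sm <- stats::filter(d, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- d[is.na(sm)]  # keep the grid ends unsmoothed
  sm
}

local_maxima <- function(d) {
  n <- length(d)
  which(d > c(-Inf, d[-n]) & d >= c(d[-1], -Inf))
}

#' Spectrum estimate with resampling confidence intervals
#'
#' Estimates a spectral density over a period grid by a missing-tolerant
#' least-squares periodogram (per-period sinusoid regression) with Daniell
#' smoothing, identifies peaks as local maxima above a noise floor, and
#' attaches 90% confidence intervals for each peak period from a day-block
#' bootstrap (5th/95th percentiles of the matched peak location across
#' resamples).  The dominant period is the highest peak; a series with no
#' peak above the floor is classified undetectable.
#'
#' @param x evenly binned values (e.g. hourly chest-temperature means), `NA`
#'   = missing.
#' @param dt_hours bin width in hours.
#' @param periods candidate period grid in hours (default 2--40 h in 0.1 h
#'   steps, truncated with a warning when the series is shorter than three
#'   cycles of the longest period).
#' @param n_boot bootstrap resamples for the peak CIs (0 disables).
#' @param seed bootstrap seed.
#' @param block_hours bootstrap block length (default one day).
#' @param floor_factor noise floor as a multiple of the median smoothed
#'   density.
#' @param smooth_window Daniell smoothing window (grid points).
#' @return A `spectrum_estimate`: list with `periods`, `density`, `peaks`
#'   (data frame: period, height, ci_lo, ci_hi), `dominant_period` (`NA`
#'   when undetectable) and `noise_floor`.
#' @export
sr_spectrum <- function(x, dt_hours = 1, periods = seq(2, 40, by = 0.1),
                        n_boot = 100, seed = 1, block_hours = 24,
                        floor_factor = 10, smooth_window = 3) {
  if (all(is.na(x))) stop_input("all values missing")
  span_h <- length(x) * dt_hours
  if (span_h < 3 * max(periods)) {
    keep <- periods <= span_h / 3
    if (!any(keep)) {
      warning("series shorter than 3 cycles of every candidate period")
      return(structure(list(periods = periods,
                            density = rep(0, length(periods)),
                            peaks = data.frame(period = numeric(),
                                               height = numeric(),
                                               ci_lo = numeric(),
                                               ci_hi = numeric()),
                            dominant_period = NA_real_,
                            noise_floor = NA_real_),
                       class = "spectrum_estimate"))
    }
    warning(sprintf("period grid truncated at %.1f h (series spans %.0f h)",
                    span_h / 3, span_h))
    periods <- periods[keep]
  }
  t_hours <- (seq_along(x) - 1) * dt_hours

  dens <- daniell_smooth(ls_periodogram(x, t_hours, periods), smooth_window)
  floor_v <- floor_factor * stats::median(dens)
  pk <- local_maxima(dens)
  pk <- pk[dens[pk] > floor_v]
  pk <- pk[order(dens[pk], decreasing = TRUE)]
  peaks <- data.frame(period = periods[pk], height = dens[pk],
                      ci_lo = rep(NA_real_, length(pk)),
                      ci_hi = rep(NA_real_, length(pk)))

  if (nrow(peaks) > 0 && n_boot > 0) {
    per_block <- max(1L, round(block_hours / dt_hours))
    blocks <- split(seq_along(x), (seq_along(x) - 1) %/% per_block)
    boot_pk <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        bi <- unlist(blocks[sample.int(length(blocks), length(blocks),
                                       replace = TRUE)], use.names = FALSE)
        xb <- x[bi]
        db <- daniell_smooth(ls_periodogram(xb, t_hours[seq_along(xb)], periods),
                             smooth_window)
        lm_i <- local_maxima(db)
        vapply(peaks$period, function(p0) {
          if (!length(lm_i)) return(NA_real_)
          periods[lm_i[which.min(abs(periods[lm_i] - p0))]]
        }, 0)
      }, numeric(nrow(peaks)))
    })
    boot_pk <- matrix(boot_pk, nrow = nrow(peaks))
    # widen by one grid step for period-grid quantization
    step <- stats::median(diff(periods))
    peaks$ci_lo <- apply(boot_pk, 1, stats::quantile, 0.05, na.rm = TRUE) - step
    peaks$ci_hi <- apply(boot_pk, 1, stats::quantile, 0.95, na.rm = TRUE) + step
  }
  structure(list(periods = periods, density = dens, peaks = peaks,
                 dominant_period = if (nrow(peaks)) peaks$period[1] else NA_real_,
                 noise_floor = floor_v),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> grid %.1f-%.1f h, dominant %s\n",
              min(x$periods), max(x$periods),
              if (is.na(x$dominant_period)) "undetectable"
              else sprintf("%.1f h", x$dominant_period)))
  if (nrow(x$peaks)) print(round(x$peaks, 2))
  invisible(x)
}

#' Classify the dominant temperature period
#'
#' Bands: circadian 20--28 h, circa-12h 10--14 h, circa-8h 7--9 h; anything
#' else is `other`, and a spectrum with no peak above the noise floor is
#' `undetectable`.
#'
#' @param spec a [sr_spectrum()] result.
#' @param bands named list of length-2 period bands (h).
#' @return One of `"circadian"`, `"circa12"`, `"circa8"`, `"other"`,
#'   `"undetectable"`.
#' @export
classify_dominant <- function(spec,
                              bands = list(circadian = c(20, 28),
                                           circa12 = c(10, 14),
                                           circa8 = c(7, 9))) {
  p <- spec$dominant_period
  if (is.na(p)) return("undetectable")
  for (nm in names(bands)) {
    if (p >= bands[[nm]][1] && p <= bands[[nm]][2]) return(nm)
  }
  "other"
}

#' Spectral gravity centre
#'
#' Density-weighted mean period (trapezoid rule) of the spectral estimate; a
#' value between 12 h and 24 h indicates that both periodicities are
#' present.
#'
#' @param spec a [sr_spectrum()] result.
#' @return Hours, or `NA` for zero total density.
#' @export
gravity_centre <- function(spec) {
  p <- spec$periods; f <- spec$density
  num <- sum(diff(p) * (p[-1] * f[-1] + p[-length(p)] * f[-length(p)]) / 2)
  den <- sum(diff(p) * (f[-1] + f[-length(f)]) / 2)
  if (den <= 0) return(NA_real_)
  num / den
}

#' Locomotor Inactivity During Sleep (LIDS) transform
#'
#' Inverse transformation amplifying low activity: a 30-min moving average of
#' the activity series followed by `100 / (activity + 1)`.  Monotone
#' decreasing in activity, making inactivity cycles during sleep visible.
#'
#' @param pa 5-min activity values (non-negative, `NA` allowed).
#' @param bin_minutes bin width of `pa`.
#' @param smooth_minutes moving-average span.
#' @return LIDS values on the same grid.
#' @export
lids <- function(pa, bin_minutes = 5, smooth_minutes = 30) {
  if (any(pa < 0, na.rm = TRUE)) stop_input("activity must be non-negative")
  k <- max(1L, round(smooth_minutes / bin_minutes))
  sm <- as.numeric(stats::filter(pa, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- pa[is.na(sm)]  # edges and missing: fall back to raw value
  100 / (sm + 1)
}

#' Extract decoded rest bouts
#'
#' Maximal runs of the most-likely rest state, merged across interruptions
#' shorter than `gap_merge_min` minutes (decode flicker), and filtered to
#' durations between 2 h and 12 h.
#'
#' @param decoded a [decode()] result.
#' @param bin_minutes decode bin width in minutes.
#' @param gap_merge_min interruptions shorter than this merge adjacent runs.
#' @param bounds_h admissible bout duration range (h).
#' @return A `data.frame` with `start_bin`, `end_bin` (inclusive bin
#'   indices) and `duration_h`.
#' @export
extract_rest_bouts <- function(decoded, bin_minutes = 5, gap_merge_min = 10,
                               bounds_h = c(2, 12)) {
  rest <- decoded$states == 1L
  # merge short non-rest gaps between rest runs
  r <- rle(rest)
  gap_bins <- gap_merge_min / bin_minutes
  inner <- which(!r$values & r$lengths < gap_bins)
  inner <- inner[inner > 1 & inner < length(r$values)]
  r$values[inner] <- TRUE
  rest <- inverse.rle(r)
  r <- rle(rest)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  dur <- r$lengths[keep] * bin_minutes / 60
  sel <- dur >= bounds_h[1] & dur <= bounds_h[2]
  data.frame(start_bin = starts[keep][sel], end_bin = ends[keep][sel],
             duration_h = dur[sel])
}

#' Ultradian sub-period within rest bouts
#'
#' Per rest bout, the dominant period of the (linearly detrended) series on a
#' grid from 0.5 h up to `min(6, duration/2)` h; the subject-level value is
#' the median over bouts.  Applied to LIDS-transformed 5-min activity or to
#' 5-min temperature.
#'
#' @param x 5-min series aligned with the decode bins (LIDS activity or
#'   temperature).
#' @param bouts a [extract_rest_bouts()] result.
#' @param bin_minutes bin width of `x` in minutes.
#' @param grid_step_h period grid resolution (h).
#' @param min_obs_h minimum observed data within a bout (h).
#' @return A list with `subject_period_h` (median over bouts, `NA` if no
#'   usable bout) and `bout_periods_h`.
#' @export
ultradian_subperiod <- function(x, bouts, bin_minutes = 5, grid_step_h = 0.05,
                                min_obs_h = 2) {
  per_bout <- rep(NA_real_, nrow(bouts))
  for (i in seq_len(nrow(bouts))) {
    idx <- bouts$start_bin[i]:bouts$end_bin[i]
    xb <- x[idx]
    tt <- (seq_along(xb) - 1) * bin_minutes / 60
    ok <- !is.na(xb)
    if (sum(ok) * bin_minutes / 60 < min_obs_h) next
    co <- stats::coef(stats::lm(xb[ok] ~ tt[ok]))
    xd <- xb
    xd[ok] <- xb[ok] - (co[1] + co[2] * tt[ok])
    pmax_h <- min(6, bouts$duration_h[i] / 2)
    if (pmax_h <= 0.5) next
    grid <- seq(0.5, pmax_h, by = grid_step_h)
    d <- ls_periodogram(xd, tt, grid)
    per_bout[i] <- grid[which.max(d)]
  }
  list(subject_period_h = if (all(is.na(per_bout))) NA_real_
       else stats::median(per_bout, na.rm = TRUE),
       bout_periods_h = per_bout)
}
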