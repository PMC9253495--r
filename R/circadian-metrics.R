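#' Daily rest profile from decoded state probabilities
#'
#' The rest profile is the curve of the probability of the rest state over
#' the 24 h clock, at 5-min resolution (288 slots): each slot is the mean
#' posterior rest probability across all days in scope at that clock slot.
#' Days whose bin at a slot is missing are excluded from that slot's mean.
#'
#' @param decoded a [decode()] result (state 1 = rest).
#' @param timestamps bin-start times aligned with the decoded bins; required
#'   for work/free scopes.
#' @param partition a [partition_days()] result; required for work/free
#'   scopes.
#' @param scope `"whole"`, `"work"` or `"free"`.
#' @param anchor clock hour anchoring slot 1 (20 for the concatenated
#'   work/free clustering vectors, 0 otherwise).
#' @return A `rest_profile`: numeric length 288 in \[0,1\] with attributes
#'   `anchor` and `day_type`.
#' @export
rest_profile <- function(decoded, timestamps = NULL, partition = NULL,
                         scope = c("whole", "work", "free"), anchor = 0) {
  scope <- match.arg(scope)
  stopifnot(inherits(decoded, "state_probabilities"))
  keep <- decoded$observed
  if (scope != "whole") {
    if (is.null(partition) || is.null(timestamps)) {
      stop_input("work/free scope needs timestamps and a day partition")
    }
    if (!any(partition$label == scope)) {
      stop_input("no %s days in the partition", scope)
    }
    idx <- findInterval(as.numeric(timestamps), as.numeric(partition$start))
    idx[idx < 1 | as.numeric(timestamps) >= as.numeric(partition$end[nrow(partition)])] <- NA
    keep <- keep & !is.na(idx) & partition$label[pmax(idx, 1L)] == scope
  }
  if (!any(keep)) stop_input("no observed bins in scope '%s'", scope)
  slot <- floor(((decoded$clock - anchor) %% 24) * 12) + 1L
  g1 <- decoded$gamma[, 1]
  num <- rowsum(g1[keep], slot[keep])
  den <- rowsum(rep(1, sum(keep)), slot[keep])
  prof <- rep(NA_real_, 288)
  prof[as.integer(rownames(num))] <- num / den
  if (anyNA(prof)) {
    # interpolate the rare all-missing slot circularly
    miss <- which(is.na(prof))
    ok <- which(!is.na(prof))
    for (m in miss) {
      d <- pmin(abs(m - ok), 288 - abs(m - ok))
      prof[m] <- mean(prof[ok[d == min(d)]])
    }
  }
  structure(pmin(1, pmax(0, prof)), anchor = anchor, day_type = scope,
            class = "rest_profile")
}

#' Construct a rest profile from slot values
#'
#' Builds a `rest_profile` object directly from 288 probability values (5-min
#' clock slots over 24 h), e.g. for boundary-condition checks or synthetic
#' profiles.
#'
#' @param values numeric length 288 in \[0, 1\]; slot `i` covers the 5 min
#'   starting at `anchor + (i-1)/12` hours.
#' @param anchor clock hour of slot 1 (0 or 20).
#' @param day_type informational tag.
#' @return A `rest_profile`.
#' @export
as_rest_profile <- function(values, anchor = 0, day_type = "whole") {
  values <- as.numeric(values)
  if (length(values) != 288) stop_input("a rest profile has 288 slots")
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stop_input("rest probabilities must lie in [0, 1]")
  }
  structure(values, anchor = anchor, day_type = day_type,
            class = "rest_profile")
}

#' Rest-persistence probability p1-1
#'
#' The probability of staying in the rest state having been at rest in the
#' previous 5-min period, summarized over time as the occupancy-weighted
#' average of the realized rest-to-rest transition probability:
#' `sum_t gamma1(t) P11(t) / sum_t gamma1(t)` with `gamma1` the posterior
#' rest probability.  Set `weighted = FALSE` for a plain clock average.
#'
#' @param fit the `hhmm_fit` the decode came from.
#' @param decoded a [decode()] result.
#' @param bins optional logical selector of bins (e.g. the bins of one
#'   scope); default all.
#' @param weighted occupancy-weight by posterior rest probability (default).
#' @return Probability in (0,1), or `NA` when rest occupancy is zero.
#' @export
p11 <- function(fit, decoded, bins = NULL, weighted = TRUE) {
  stopifnot(inherits(fit, "hhmm_fit"), inherits(decoded, "state_probabilities"))
  T_ <- nrow(decoded$gamma)
  sel <- bins %||% rep(TRUE, T_)
  sel <- sel[-T_]  # transitions t -> t+1
  two_osc <- !identical(fit$oscillator_set, "single")
  Z <- hhmm_basis(decoded$clock[-T_],
                  if (two_osc) decoded$day_type[-T_] else NULL,
                  fit$harmonics, two_osc)
  p11_t <- row_probs(fit$theta[[1]], Z, 1, length(fit$means))[, 1]
  g1 <- decoded$gamma[-T_, 1]
  w <- if (weighted) g1[sel] else rep(1, sum(sel))
  if (sum(w) <= 0) {
    warning("zero rest occupancy; p1-1 undefined")
    return(NA_real_)
  }
  sum(w * p11_t[sel]) / sum(w)
}

#' Rest amount
#'
#' Area under the rest profile: hours of rest per 24 h, in \[0, 24\].
#'
#' @param profile a [rest_profile()].
#' @return Hours.
#' @export
rest_amount <- function(profile) {
  sum(profile) * 5 / 60
}

slot_clock <- function(profile) {
  (attr(profile, "anchor") %||% 0) + (seq_len(288) - 0.5) / 12
}

#' Centre time of rest
#'
#' The gravity centre of the rest amount on the 24 h clock, computed as the
#' circular first moment of the profile; undefined (NA) for flat or empty
#' profiles (mean resultant length < 1e-6).
#'
#' @param profile a [rest_profile()].
#' @return Clock hour in \[0, 24), or `NA` when undefined.
#' @export
centre_of_rest <- function(profile) {
  w <- as.numeric(profile)
  if (sum(w) <= 0) return(NA_real_)
  th <- 2 * pi * slot_clock(profile) / 24
  re <- sum(w * cos(th)); im <- sum(w * sin(th))
  if (sqrt(re^2 + im^2) / sum(w) < 1e-6) return(NA_real_)
  (atan2(im, re) * 24 / (2 * pi)) %% 24
}

#' Daytime maximum of the rest profile
#'
#' The alternative phase marker for night shifters: the clock time at which
#' the rest probability is maximal within a daytime window (default
#' 07:00--20:00); ties resolve to the earliest time.
#'
#' @param profile a [rest_profile()].
#' @param window length-2 clock hours delimiting the search window.
#' @return Clock hour of the windowed maximum.
#' @export
alt_centre_max_daytime <- function(profile, window = c(7, 20)) {
  ck <- slot_clock(profile) %% 24
  sel <- which(ck >= window[1] & ck <= window[2])
  sel <- sel[order(ck[sel])]
  v <- as.numeric(profile)[sel]
  ck[sel[which.max(v)]] - 1 / 24  # report the slot start
}

#' Rhythm Index
#'
#' A 0--1 measure of the regularity and quality of daily rest recurrence:
#' with rest amount `A` and centre time `c`, the Rhythm Index is the mean
#' rest probability inside the circular window of width `A` centred at `c`
#' minus the mean outside it, clipped to \[0, 1\].  It equals 1 for a
#' perfectly regular probability-1 rest window and 0 for a profile with no
#' circadian cycle in rest (flat profile).  This inside-vs-outside-window
#' contrast is the package's operationalization of the index; it satisfies
#' both boundary conditions above.
#'
#' Conventions: `A = 0` gives 0; `A = 24` gives the profile mean; an
#' undefined centre (flat profile) gives 0.
#'
#' @param profile a [rest_profile()].
#' @return The Rhythm Index in \[0, 1\].
#' @export
rhythm_index <- function(profile) {
  A <- rest_amount(profile)
  if (A <= 1e-9) return(0)
  v <- as.numeric(profile)
  if (A >= 24 - 1e-9) return(mean(v))
  ctr <- centre_of_rest(profile)
  if (is.na(ctr)) return(0)
  inw <- abs(circ_diff_h(slot_clock(profile), ctr)) < A / 2
  if (!any(inw) || all(inw)) return(0)
  min(1, max(0, mean(v[inw]) - mean(v[!inw])))
}

#' All four circadian parameters for one scope
#'
#' Convenience wrapper returning p1-1, rest amount, centre time of rest, the
#' daytime-maximum phase marker and the Rhythm Index for a decoded subject.
#'
#' @inheritParams rest_profile
#' @inheritParams p11
#' @return A one-row `data.frame`.
#' @export
circadian_params <- function(fit, decoded, timestamps = NULL, partition = NULL,
                             scope = "whole") {
  prof <- rest_profile(decoded, timestamps, partition, scope)
  bins <- NULL
  if (scope != "whole") {
    idx <- findInterval(as.numeric(timestamps), as.numeric(partition$start))
    bins <- !is.na(idx) & idx >= 1 & partition$label[pmax(idx, 1L)] == scope
  }
  data.frame(scope = scope,
             p11 = p11(fit, decoded, bins = bins),
             rest_amount_h = rest_amount(prof),
             centre_time = centre_of_rest(prof),
             centre_max_daytime = alt_centre_max_daytime(prof),
             rhythm_index = rhythm_index(prof))
}
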