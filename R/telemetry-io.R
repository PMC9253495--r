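#' Write a cohort to the long-format CSV dialect
#'
#' Emits the three files the reader understands: `series.csv`
#' (`subject_id,timestamp,pa,temp`, empty cells = missing), `diary.csv`
#' (`subject_id,kind,start,end` with `kind` in work/sleep) and `meta.csv`
#' (one row per subject).
#'
#' @param cohort a `cohort` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series <- do.call(rbind, lapply(cohort$subjects, `[[`, "series"))
  diary <- do.call(rbind, lapply(names(cohort$subjects), function(id) {
    d <- cohort$subjects[[id]]$diary
    cbind(subject_id = id, d)
  }))
  meta <- cohort_meta(cohort)
  paths <- file.path(dir, c("series.csv", "diary.csv", "meta.csv"))
  fmt <- function(x) format(x, "%Y-%m-%d %H:%M:%S")
  series$timestamp <- fmt(series$timestamp)
  diary$start <- fmt(diary$start)
  diary$end <- fmt(diary$end)
  utils::write.csv(series, paths[1], row.names = FALSE, na = "")
  utils::write.csv(diary, paths[2], row.names = FALSE, na = "")
  utils::write.csv(meta, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}

parse_ts <- function(x) as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")

#' Read a cohort from CSV files
#'
#' Validates each subject's minute grid: duplicated timestamps and
#' non-monotone or non-1-minute spacing are hard errors reporting the
#' offending rows.  A missing `temp` column loads with temperature marked
#' absent; temperature-dependent stages then refuse to run.
#'
#' @param series_path,diary_path,meta_path CSV paths as written by
#'   [write_cohort()].
#' @return A `cohort` object.
#' @export
read_cohort <- function(series_path, diary_path, meta_path) {
  series <- utils::read.csv(series_path, stringsAsFactors = FALSE)
  diary <- utils::read.csv(diary_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  req <- c("subject_id", "timestamp", "pa")
  if (!all(req %in% names(series))) {
    stop_input("series file lacks columns: %s",
               paste(setdiff(req, names(series)), collapse = ", "))
  }
  has_temp <- "temp" %in% names(series)
  if (!has_temp) series$temp <- NA_real_
  series$timestamp <- parse_ts(series$timestamp)
  diary$start <- parse_ts(diary$start)
  diary$end <- parse_ts(diary$end)
  if (any(diary$end <= diary$start)) {
    stop_input("diary intervals with end <= start (rows %s)",
               paste(which(diary$end <= diary$start), collapse = ", "))
  }

  subjects <- list()
  for (id in unique(series$subject_id)) {
    rows <- which(series$subject_id == id)
    s <- series[rows, c("subject_id", "timestamp", "pa", "temp")]
    dup <- duplicated(s$timestamp)
    if (any(dup)) {
      stop_input("subject %s: duplicated minute at series row %d (%s)",
                 id, rows[which(dup)[1]] + 1L,
                 format(s$timestamp[which(dup)[1]]))
    }
    dt <- diff(as.numeric(s$timestamp))
    bad <- which(dt <= 0)
    if (length(bad)) {
      stop_input("subject %s: non-increasing timestamps at series row %d",
                 id, rows[bad[1] + 1L] + 1L)
    }
    bad <- which(dt != 60)
    if (length(bad)) {
      stop_input("subject %s: grid spacing != 1 minute at series row %d",
                 id, rows[bad[1] + 1L] + 1L)
    }
    if (any(s$pa < 0, na.rm = TRUE)) {
      stop_input("subject %s: negative activity values", id)
    }
    rownames(s) <- NULL
    d <- diary[diary$subject_id == id, c("kind", "start", "end")]
    rownames(d) <- NULL
    m <- as.list(meta[meta$subject_id == id, , drop = FALSE])
    subjects[[id]] <- list(series = s, diary = d, meta = m)
  }
  structure(list(subjects = subjects,
                 start = min(series$timestamp),
                 n_days = NA_integer_, has_temp = has_temp),
            class = "cohort")
}

#' Resample a minute series to clock-aligned bins
#'
#' Bin value is the mean of the observed minutes in the bin; a bin is missing
#' iff all its constituent minutes are missing.  Bin boundaries align to the
#' clock (:00, :05, ... for 5-min bins; whole hours for hourly bins).
#'
#' @param series per-subject series `data.frame` (`timestamp`, `pa`, `temp`).
#' @param bin `"5min"` or `"hourly"`.
#' @return A `data.frame` with one row per bin: `timestamp` (bin start),
#'   `pa`, `temp`.
#' @export
resample <- function(series, bin = c("5min", "hourly")) {
  bin <- match.arg(bin)
  width <- if (bin == "5min") 300 else 3600
  g <- floor(as.numeric(series$timestamp) / width)
  g <- g - min(g)
  bin_mean <- function(x) {
    n_obs <- rowsum(as.numeric(!is.na(x)), g)
    s <- rowsum(ifelse(is.na(x), 0, x), g)
    out <- as.numeric(s / n_obs)
    out[n_obs == 0] <- NA_real_
    out
  }
  first <- !duplicated(g)
  ts0 <- as.POSIXct(floor(as.numeric(series$timestamp[first]) / width) * width,
                    origin = "1970-01-01", tz = "UTC")
  data.frame(timestamp = ts0, pa = bin_mean(series$pa),
             temp = bin_mean(series$temp))
}

#' Square-root transform of activity
#'
#' The activity model is fitted on the square-root scale, where Gaussian
#' emissions are a reasonable approximation.  Missing values are preserved;
#' negative input is a hard error.
#'
#' @param x numeric activity vector, or a series `data.frame` whose `pa`
#'   column is transformed.
#' @return Same shape as the input.
#' @export
sqrt_pa <- function(x) {
  if (is.data.frame(x)) {
    x$pa <- sqrt_pa(x$pa)
    return(x)
  }
  if (any(x < 0, na.rm = TRUE)) stop_input("activity must be non-negative")
  sqrt(x)
}

#' Partition a monitoring span into work and free days
#'
#' Each 24 h window is anchored at 00:00 for day shifters and at the night
#' shift start (20:00 or 21:00, taken from the diary, default 21:00 when
#' ambiguous) for night shifters; windows cover the whole span without
#' overlap (the leading span before the first anchor forms a partial
#' window).  A window is a workday iff a diary work interval starts inside
#' it.
#'
#' @param diary diary `data.frame` (`kind`, `start`, `end`).
#' @param meta subject metadata list with at least `shift_type`.
#' @param span length-2 POSIXct: monitoring start and end.
#' @return A `day_partition`: `data.frame` with `day`, `start`, `end`,
#'   `label` (work/free) plus an `anchor_h` attribute.
#' @export
partition_days <- function(diary, meta, span) {
  stopifnot(length(span) == 2, span[2] > span[1])
  work <- diary[diary$kind == "work", , drop = FALSE]
  if (meta$shift_type == "DS") {
    anchor_h <- 0
  } else {
    if (nrow(work) == 0) {
      warning("NS subject with no diary work interval: labelling all days free")
      anchor_h <- 21
    } else {
      h <- clock_hour(min(work$start))
      anchor_h <- if (h %in% c(20, 21)) h else 21
    }
  }
  s0 <- as.numeric(span[1]); s1 <- as.numeric(span[2])
  first_anchor <- floor(s0 / 86400) * 86400 + anchor_h * 3600
  while (first_anchor <= s0) first_anchor <- first_anchor + 86400
  anchors <- if (first_anchor < s1) seq(first_anchor, s1, by = 86400) else numeric()
  bounds <- sort(unique(c(s0, anchors, s1)))
  bounds <- bounds[bounds >= s0 & bounds <= s1]
  starts <- utils::head(bounds, -1)
  ends <- bounds[-1]
  label <- vapply(seq_along(starts), function(i) {
    hit <- nrow(work) > 0 && any(work$start >= starts[i] & work$start < ends[i])
    if (hit) "work" else "free"
  }, "")
  structure(data.frame(day = seq_along(starts),
                       start = as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
                       end = as.POSIXct(ends, origin = "1970-01-01", tz = "UTC"),
                       label = label),
            anchor_h = anchor_h, class = c("day_partition", "data.frame"))
}

#' Eligibility for work/free-day comparison
#'
#' A subject enters the analysis only with at least one workday and at least
#' one free day in the monitoring period.
#'
#' @param partition a [partition_days()] result.
#' @return A list with `eligible` (logical) and `reason`.
#' @export
eligibility <- function(partition) {
  n_work <- sum(partition$label == "work")
  n_free <- sum(partition$label == "free")
  if (n_work >= 1 && n_free >= 1) {
    list(eligible = TRUE, reason = "ok")
  } else if (n_work == 0) {
    list(eligible = FALSE, reason = "no workday in monitoring period")
  } else {
    list(eligible = FALSE, reason = "no free day in monitoring period")
  }
}

#' Self-reported sleep debt
#'
#' Ideal total sleep time minus reported total sleep time, in hours; may be
#' negative.  Missing fields give a missing result.
#'
#' @param meta subject metadata list with `ideal_tst_h` and `reported_tst_h`.
#' @return Hours of sleep debt, or `NA`.
#' @export
sleep_debt <- function(meta) {
  ideal <- meta$ideal_tst_h %||% NA_real_
  rep_tst <- meta$reported_tst_h %||% NA_real_
  if (is.na(ideal) || is.na(rep_tst)) return(NA_real_)
  ideal - rep_tst
}
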