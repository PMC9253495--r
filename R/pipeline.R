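#' Pipeline configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline()].  Every
#' random stage carries an explicit seed.  The configuration round-trips
#' losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param synthetic list with `n_ds`, `n_ns`, `n_days`, `seed` to simulate a
#'   cohort; mutually exclusive with `input`.
#' @param input list with `series`, `diary`, `meta` CSV paths.
#' @param hmm list: `harmonics`, `restarts`, `tol`, `max_iter`, `seed`.
#' @param spectral list: `grid` (min, max, step in h), `n_boot`, `seed`, and
#'   `use_temperature`.
#' @param clustering list: `kmax`.
#' @param regression list: `family`, `model_search`, `responses`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = list(n_ds = 20, n_ns = 20, n_days = 7,
                                             seed = 1),
                            input = NULL,
                            hmm = list(), spectral = list(),
                            clustering = list(), regression = list()) {
  defaults <- list(
    hmm = list(harmonics = 1, restarts = 5, tol = 1e-5, max_iter = 500,
               seed = 11),
    spectral = list(grid = c(2, 40, 0.1), n_boot = 100, seed = 12,
                    use_temperature = TRUE),
    clustering = list(kmax = 8),
    regression = list(family = "gaussian", model_search = FALSE,
                      terms = c("ShT", "Age", "CS", "YNW"),
                      responses = c("lop11", "lori", "rest_amount_h",
                                    "centre_time"))
  )
  merge_in <- function(d, u) { d[names(u)] <- u; d }
  if (!is.null(input) && !is.null(synthetic)) {
    stop_input("give either a synthetic block or input paths, not both")
  }
  structure(list(synthetic = synthetic, input = input,
                 hmm = merge_in(defaults$hmm, hmm),
                 spectral = merge_in(defaults$spectral, spectral),
                 clustering = merge_in(defaults$clustering, clustering),
                 regression = merge_in(defaults$regression, regression)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(synthetic = raw$synthetic, input = raw$input,
                  hmm = raw$hmm %||% list(),
                  spectral = raw$spectral %||% list(),
                  clustering = raw$clustering %||% list(),
                  regression = raw$regression %||% list())
}

# per-subject 5-min sqrt-activity data ready for the HMM
prep_bins <- function(subject) {
  b5 <- resample(subject$series, "5min")
  b5$y <- sqrt_pa(b5$pa)
  b5$clock <- clock_hour(b5$timestamp)
  b5
}

bin_day_labels <- function(timestamps, partition) {
  idx <- findInterval(as.numeric(timestamps), as.numeric(partition$start))
  idx[idx < 1] <- 1L
  idx[idx > nrow(partition)] <- nrow(partition)
  partition$label[idx]
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort load/simulation; work/free-day partition and
#' eligibility; whole-study harmonic HMM per subject with circadian
#' parameters; hourly temperature spectra; the two-oscillator HMM with
#' work/free-day parameters and 20:00-anchored rest profiles; Ward
#' clustering of the concatenated profiles within each shift group with
#' Kruskal-Wallis cluster comparisons; bivariate copula regressions of each
#' circadian response pair on the questionnaire covariates; and ultradian
#' sub-period estimation within decoded rest bouts (LIDS activity and 5-min
#' temperature).  Every stage writes flat CSV outputs plus a JSON manifest
#' (stage status, timings, seeds, config).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "circashift",
                   version = as.character(utils::packageVersion("circashift")),
                   config = unclass(config), stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop_input("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(name = name, status = attr(res, "status") %||% "ok",
           seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }
  skipped <- function(x) structure(x, status = "skipped")

  ## 1. cohort
  cohort <- t_stage("cohort", {
    if (!is.null(config$input)) {
      read_cohort(config$input$series, config$input$diary, config$input$meta)
    } else {
      s <- config$synthetic
      generate_cohort(s$n_ds, s$n_ns, n_days = s$n_days %||% 7,
                      seed = s$seed %||% 1)
    }
  })
  write_cohort(cohort, file.path(out_dir, "cohort"))
  use_temp <- isTRUE(config$spectral$use_temperature) &&
    !isFALSE(cohort$has_temp %||% TRUE)

  ## 2. partition + eligibility
  elig <- t_stage("eligibility", {
    rows <- lapply(names(cohort$subjects), function(id) {
      s <- cohort$subjects[[id]]
      span <- range(s$series$timestamp)
      span[2] <- span[2] + 60
      part <- partition_days(s$diary, s$meta, span)
      e <- eligibility(part)
      list(id = id, partition = part, eligible = e$eligible, reason = e$reason)
    })
    names(rows) <- names(cohort$subjects)
    rows
  })
  elig_df <- do.call(rbind, lapply(elig, function(e) {
    data.frame(subject_id = e$id, eligible = e$eligible, reason = e$reason)
  }))
  utils::write.csv(elig_df, file.path(out_dir, "eligibility.csv"),
                   row.names = FALSE)
  ids <- elig_df$subject_id[elig_df$eligible]

  hm <- config$hmm
  fit_one <- function(b5, day_type = NULL) {
    fit_hhmm(b5$y, b5$clock, day_type = day_type, harmonics = hm$harmonics,
             n_restarts = hm$restarts, tol = hm$tol, max_iter = hm$max_iter,
             seed = hm$seed)
  }

  ## 3. whole-study HHMM + parameters
  whole <- t_stage("hhmm_whole", {
    out <- list()
    for (id in ids) {
      b5 <- prep_bins(cohort$subjects[[id]])
      fit <- fit_one(b5)
      dec <- decode(fit, b5$y, b5$clock)
      out[[id]] <- list(fit = fit, decoded = dec, bins = b5,
                        params = cbind(subject_id = id,
                                       circadian_params(fit, dec)))
    }
    out
  })

  ## 4. temperature spectra
  spectra <- t_stage("spectral_temp", {
    if (!use_temp) {
      skipped(list())
    } else {
      sp <- config$spectral
      out <- list()
      for (id in ids) {
        hb <- resample(cohort$subjects[[id]]$series, "hourly")
        spec <- sr_spectrum(hb$temp, dt_hours = 1,
                            periods = seq(sp$grid[1], sp$grid[2],
                                          by = sp$grid[3]),
                            n_boot = sp$n_boot, seed = sp$seed)
        out[[id]] <- list(spectrum = spec, class = classify_dominant(spec),
                          gravity = gravity_centre(spec))
      }
      out
    }
  })
  if (use_temp) {
    spec_df <- do.call(rbind, lapply(ids, function(id) {
      data.frame(subject_id = id,
                 dominant_period_h = spectra[[id]]$spectrum$dominant_period,
                 class = spectra[[id]]$class,
                 gravity_centre_h = spectra[[id]]$gravity)
    }))
    utils::write.csv(spec_df, file.path(out_dir, "spectra_summary.csv"),
                     row.names = FALSE)
  }

  ## 5. two-oscillator HHMM + per-scope parameters and profiles
  two <- t_stage("hhmm_two_oscillator", {
    out <- list()
    for (id in ids) {
      b5 <- whole[[id]]$bins
      part <- elig[[id]]$partition
      lab <- bin_day_labels(b5$timestamp, part)
      fit <- fit_one(b5, day_type = lab)
      dec <- decode(fit, b5$y, b5$clock, day_type = lab)
      profs <- lapply(c(work = "work", free = "free"), function(sc) {
        rest_profile(dec, b5$timestamp, part, scope = sc, anchor = 20)
      })
      pw <- circadian_params(fit, dec, b5$timestamp, part, "work")
      pf <- circadian_params(fit, dec, b5$timestamp, part, "free")
      out[[id]] <- list(fit = fit, decoded = dec, labels = lab,
                        profiles = profs,
                        params = cbind(subject_id = id, rbind(pw, pf)))
    }
    out
  })

  ## 6. parameter table
  par_tab <- t_stage("circadian_parameters", {
    do.call(rbind, c(lapply(whole, `[[`, "params"),
                     lapply(two, `[[`, "params")))
  })
  utils::write.csv(par_tab, file.path(out_dir, "circadian_parameters.csv"),
                   row.names = FALSE)

  meta <- cohort_meta(cohort)
  meta <- meta[meta$subject_id %in% ids, , drop = FALSE]

  ## 7. clustering within shift groups
  clusters <- t_stage("clustering", {
    out <- list()
    for (grp in unique(meta$shift_type)) {
      gids <- meta$subject_id[meta$shift_type == grp]
      if (length(gids) < 3) next
      X <- do.call(rbind, lapply(gids, function(id) {
        profile_vector(two[[id]]$profiles$work, two[[id]]$profiles$free)
      }))
      rownames(X) <- gids
      out[[grp]] <- ward_cluster(X, kmax = config$clustering$kmax)
    }
    out
  })
  if (length(clusters)) {
    lab_df <- do.call(rbind, lapply(names(clusters), function(grp) {
      data.frame(subject_id = rownames(as.matrix(clusters[[grp]]$labels)) %||%
                   names(clusters[[grp]]$labels),
                 shift_type = grp, cluster = as.integer(clusters[[grp]]$labels))
    }))
    utils::write.csv(lab_df, file.path(out_dir, "cluster_labels.csv"),
                     row.names = FALSE)
    wk_df <- do.call(rbind, lapply(names(clusters), function(grp) {
      data.frame(shift_type = grp,
                 k = seq_along(clusters[[grp]]$wk),
                 wk = as.numeric(clusters[[grp]]$wk))
    }))
    utils::write.csv(wk_df, file.path(out_dir, "elbow_wk.csv"),
                     row.names = FALSE)
  }

  ## 8. cluster comparisons
  comparisons <- t_stage("cluster_comparison", {
    out <- list()
    for (grp in names(clusters)) {
      if (length(unique(clusters[[grp]]$labels)) < 2) next
      scoped <- par_tab[par_tab$scope != "whole" &
                          par_tab$subject_id %in%
                            names(clusters[[grp]]$labels), ]
      out[[grp]] <- cluster_summary(clusters[[grp]], scoped)
    }
    if (!length(out)) skipped(out) else out
  })
  if (length(comparisons)) {
    cmp_df <- do.call(rbind, lapply(names(comparisons), function(grp) {
      cbind(shift_type = grp, comparisons[[grp]])
    }))
    utils::write.csv(cmp_df, file.path(out_dir, "cluster_comparisons.csv"),
                     row.names = FALSE)
  }

  ## 9. copula regressions
  regression <- t_stage("copula_regression", {
    rdata <- regression_data(par_tab, meta)
    out <- list()
    for (resp in config$regression$responses) {
      d <- rdata[[resp]]
      if (is.null(d) || sum(stats::complete.cases(d)) < 12) next
      out[[resp]] <- if (isTRUE(config$regression$model_search)) {
        select_model(d, response = resp, family = config$regression$family)
      } else {
        tms <- config$regression$terms
        suppressWarnings(fit_copula(model_spec(resp, tms, tms), d,
                                    family = config$regression$family))
      }
    }
    out
  })
  if (length(regression)) {
    reg_df <- do.call(rbind, lapply(names(regression), function(resp) {
      cbind(response = resp, wald_z(regression[[resp]]))
    }))
    utils::write.csv(reg_df, file.path(out_dir, "regression_coefficients.csv"),
                     row.names = FALSE)
  }

  ## 10. ultradian sub-periods
  ultradian <- t_stage("ultradian", {
    out <- list()
    for (id in ids) {
      dec <- two[[id]]$decoded
      b5 <- whole[[id]]$bins
      bouts <- extract_rest_bouts(dec)
      pa_l <- lids(b5$pa)
      up_pa <- ultradian_subperiod(pa_l, bouts)
      up_tmp <- if (use_temp) {
        t5 <- resample(cohort$subjects[[id]]$series, "5min")$temp
        ultradian_subperiod(t5, bouts)
      } else list(subject_period_h = NA_real_)
      out[[id]] <- data.frame(subject_id = id, n_bouts = nrow(bouts),
                              lids_pa_period_h = up_pa$subject_period_h,
                              temp_period_h = up_tmp$subject_period_h)
    }
    do.call(rbind, out)
  })
  utils::write.csv(ultradian, file.path(out_dir, "ultradian.csv"),
                   row.names = FALSE)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest$config_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(cohort = cohort, eligibility = elig, whole = whole,
                 spectra = spectra, two = two, parameters = par_tab,
                 clusters = clusters, comparisons = comparisons,
                 regression = regression, ultradian = ultradian,
                 manifest = manifest))
}

# reshape the per-subject parameter table into one (work, free) response pair
# per subject and response, with covariates; log-odds transforms for p1-1 and
# the Rhythm Index, linear hours for rest amount and centre time (centre
# times unwrapped past midnight so the work/free pair stays ordered).
regression_data <- function(par_tab, meta) {
  wk <- par_tab[par_tab$scope == "work", ]
  fr <- par_tab[par_tab$scope == "free", ]
  m <- merge(wk, fr, by = "subject_id", suffixes = c("_work", "_free"))
  m <- merge(m, meta, by = "subject_id")
  cov <- data.frame(ShT = as.numeric(m$shift_type == "NS"), Age = m$age,
                    CS = m$chronotype_score, YNW = m$years_night_work)
  eps <- 1e-4
  ctw <- m$centre_time_work; ctf <- m$centre_time_free
  wrap <- !is.na(ctw) & !is.na(ctf) & abs(ctw - ctf) > 12
  ctw[wrap & ctw < ctf] <- ctw[wrap & ctw < ctf] + 24
  ctf[wrap & ctf < ctw - 12] <- ctf[wrap & ctf < ctw - 12] + 24
  list(
    lop11 = cbind(data.frame(y_work = logit_transform(m$p11_work, clip = eps),
                             y_free = logit_transform(m$p11_free, clip = eps)),
                  cov),
    lori = cbind(data.frame(
      y_work = logit_transform(m$rhythm_index_work, clip = eps),
      y_free = logit_transform(m$rhythm_index_free, clip = eps)), cov),
    rest_amount_h = cbind(data.frame(y_work = m$rest_amount_h_work,
                                     y_free = m$rest_amount_h_free), cov),
    centre_time = cbind(data.frame(y_work = ctw, y_free = ctf), cov)
  )
}

#' Summarize a pipeline run
#'
#' Reads the CSV outputs of [run_pipeline()] and produces per-group
#' median/IQR tables of the four circadian parameters by scope, dominant
#' temperature-period class counts, cluster sizes and the regression
#' coefficient tables; also written to `report.txt` in the run directory.
#' Regeneration is idempotent.
#'
#' @param run_dir a completed run directory.
#' @return A list of summary tables, invisibly; printed to `report.txt`.
#' @export
report <- function(run_dir) {
  f <- function(x) file.path(run_dir, x)
  out <- list()
  meta <- utils::read.csv(f("cohort/meta.csv"))
  partial <- character()

  if (file.exists(f("circadian_parameters.csv"))) {
    pt <- merge(utils::read.csv(f("circadian_parameters.csv")),
                meta[, c("subject_id", "shift_type")], by = "subject_id")
    vars <- c("p11", "rest_amount_h", "centre_time", "rhythm_index")
    out$parameters <- do.call(rbind, lapply(split(pt, list(pt$scope, pt$shift_type)),
      function(d) {
        if (!nrow(d)) return(NULL)
        qs <- t(vapply(vars, function(v) {
          stats::quantile(d[[v]], c(0.5, 0.25, 0.75), na.rm = TRUE)
        }, numeric(3)))
        data.frame(shift_type = d$shift_type[1], scope = d$scope[1],
                   n = nrow(d), variable = vars, median = qs[, 1],
                   q25 = qs[, 2], q75 = qs[, 3], row.names = NULL)
      }))
    rownames(out$parameters) <- NULL
  } else partial <- c(partial, "circadian_parameters")

  if (file.exists(f("spectra_summary.csv"))) {
    sp <- merge(utils::read.csv(f("spectra_summary.csv")),
                meta[, c("subject_id", "shift_type")], by = "subject_id")
    out$dominant_period_classes <- as.data.frame(table(sp$shift_type, sp$class))
    names(out$dominant_period_classes) <- c("shift_type", "class", "n")
  } else partial <- c(partial, "spectra")

  if (file.exists(f("cluster_labels.csv"))) {
    cl <- utils::read.csv(f("cluster_labels.csv"))
    out$cluster_sizes <- do.call(rbind, lapply(split(cl, cl$shift_type),
      function(d) cbind(shift_type = d$shift_type[1],
                        cluster_shares(d$cluster))))
  } else partial <- c(partial, "clustering")

  if (file.exists(f("regression_coefficients.csv"))) {
    out$regression <- utils::read.csv(f("regression_coefficients.csv"),
                                      check.names = FALSE)
  } else partial <- c(partial, "regression")

  if (file.exists(f("ultradian.csv"))) {
    ud <- merge(utils::read.csv(f("ultradian.csv")),
                meta[, c("subject_id", "shift_type")], by = "subject_id")
    out$ultradian <- do.call(rbind, lapply(split(ud, ud$shift_type), function(d) {
      data.frame(shift_type = d$shift_type[1], n = nrow(d),
                 median_lids_pa_h = stats::median(d$lids_pa_period_h, na.rm = TRUE),
                 median_temp_h = stats::median(d$temp_period_h, na.rm = TRUE))
    }))
  } else partial <- c(partial, "ultradian")

  out$partial <- partial
  con <- file(f("report.txt"), "w")
  on.exit(close(con))
  if (length(partial)) {
    writeLines(sprintf("PARTIAL RUN: missing sections: %s",
                       paste(partial, collapse = ", ")), con)
  }
  for (nm in setdiff(names(out), "partial")) {
    writeLines(c(sprintf("== %s ==", nm),
                 utils::capture.output(print(out[[nm]])), ""), con)
  }
  invisible(out)
}
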