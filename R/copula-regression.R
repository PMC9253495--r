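#' Log-odds transform
#'
#' `log(x / (1 - x))` for probabilities strictly inside (0,1); used to carry
#' p1-1 (LOP1-1) and the Rhythm Index (LORI) onto the real line before
#' regression.
#'
#' @param x values in (0, 1).
#' @param clip optional small epsilon: values are clipped into
#'   \[clip, 1-clip\] first (off by default; 0/1 input is then an error).
#' @return The log odds.
#' @export
logit_transform <- function(x, clip = NULL) {
  if (!is.null(clip)) x <- pmin(1 - clip, pmax(clip, x))
  if (any(x <= 0 | x >= 1, na.rm = TRUE)) {
    stop_input("log odds undefined at 0 or 1; use clip= to winsorize")
  }
  log(x / (1 - x))
}

#' @rdname logit_transform
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

# --- copula log-densities on (u, v) in (0,1)^2 -------------------------------

copula_logdens <- function(u, v, theta, family) {
  switch(family,
    gaussian = {
      if (abs(theta) >= 1) return(rep(-Inf, length(u)))
      z1 <- stats::qnorm(u); z2 <- stats::qnorm(v)
      -0.5 * log(1 - theta^2) +
        (2 * theta * z1 * z2 - theta^2 * (z1^2 + z2^2)) / (2 * (1 - theta^2))
    },
    clayton = {
      if (theta <= 0) return(rep(0, length(u)))  # theta -> 0: independence
      log1p(theta) - (theta + 1) * (log(u) + log(v)) -
        (2 + 1 / theta) * log(u^(-theta) + v^(-theta) - 1)
    },
    frank = {
      # c = theta (1-e^-t) e^{-t(u+v)} / [1-e^-t - (1-e^-tu)(1-e^-tv)]^2
      if (abs(theta) < 1e-8) return(rep(0, length(u)))
      g <- -expm1(-theta)  # 1 - e^-theta
      den <- g - (-expm1(-theta * u)) * (-expm1(-theta * v))
      log(theta * g) - theta * (u + v) - 2 * log(abs(den))
    },
    gumbel = {
      if (theta < 1) return(rep(-Inf, length(u)))
      if (theta == 1) return(rep(0, length(u)))
      lu <- -log(u); lv <- -log(v)
      s <- lu^theta + lv^theta
      A <- s^(1 / theta)
      -A + (theta - 1) * (log(lu) + log(lv)) + (1 / theta - 2) * log(s) +
        log(A + theta - 1) + lu + lv
    },
    stop_input("unknown copula family '%s'", family)
  )
}

theta_bounds <- function(family) {
  switch(family,
    gaussian = c(-0.999, 0.999),
    clayton = c(1e-6, 50),
    frank = c(-50, 50),
    gumbel = c(1, 50))
}

#' Model specification for the bivariate copula regression
#'
#' @param response name of the circadian response (informational).
#' @param terms_work,terms_free covariate terms per margin, drawn from
#'   `ShT`, `Age`, `CS`, `YNW` and their pairwise interactions written as
#'   `"A:B"`.  Interactions require both main effects (marginality).
#' @param link_work,link_free `"identity"` or `"log"` marginal link.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, terms_work, terms_free,
                       link_work = "identity", link_free = "identity") {
  check_marginality <- function(terms) {
    for (tm in grep(":", terms, value = TRUE)) {
      mains <- strsplit(tm, ":", fixed = TRUE)[[1]]
      if (!all(mains %in% terms)) {
        stop_input("interaction %s requires both main effects", tm)
      }
    }
  }
  check_marginality(terms_work)
  check_marginality(terms_free)
  stopifnot(link_work %in% c("identity", "log"),
            link_free %in% c("identity", "log"))
  structure(list(response = response, terms_work = terms_work,
                 terms_free = terms_free, link_work = link_work,
                 link_free = link_free),
            class = "model_spec")
}

spec_matrix <- function(terms, data) {
  f <- if (length(terms)) stats::reformulate(terms) else ~1
  stats::model.matrix(f, data)
}

#' Bivariate copula regression of paired work/free-day responses
#'
#' Joint maximum likelihood for two Gaussian marginal regressions (identity
#' or log link) bound by a one-parameter copula (Gaussian, Clayton, Frank or
#' Gumbel).  Starting values come from inference-for-margins: each margin is
#' fitted separately, then the dependence parameter given the margins, then
#' everything jointly.  Standard errors come from the observed information
#' (numerical Hessian at the optimum).  With theta fixed at 0 (Gaussian
#' copula) the joint log-likelihood factorizes into the two marginal fits.
#'
#' @param spec a [model_spec()].
#' @param data `data.frame` holding `y_work`, `y_free` and the covariates.
#' @param family copula family.
#' @param theta_fixed optional fixed dependence parameter (e.g. 0 for
#'   independence); when given, theta is not estimated.
#' @return A `copula_fit`: coefficients and SEs per margin, marginal sigmas,
#'   `theta`, `loglik`, `aicc`, `n_params`, `n_obs` and convergence flags.
#' @export
fit_copula <- function(spec, data, family = c("gaussian", "clayton", "frank",
                                              "gumbel"),
                       theta_fixed = NULL) {
  family <- match.arg(family)
  cc <- stats::complete.cases(data[, c("y_work", "y_free",
                                       unique(unlist(strsplit(c(spec$terms_work,
                                                                spec$terms_free),
                                                              ":")))),
                              drop = FALSE])
  data <- data[cc, , drop = FALSE]
  Xw <- spec_matrix(spec$terms_work, data)
  Xf <- spec_matrix(spec$terms_free, data)
  n <- nrow(data)
  pw <- ncol(Xw); pf <- ncol(Xf)
  est_theta <- is.null(theta_fixed)
  if (n < 10 * max(pw, pf)) {
    warning(sprintf("only %d complete cases for %d coefficients", n, max(pw, pf)))
  }
  yw <- data$y_work; yf <- data$y_free
  linkinv <- function(link) if (link == "log") exp else identity

  margin_ll <- function(y, X, beta, lsig, link) {
    mu <- linkinv(link)(as.numeric(X %*% beta))
    stats::dnorm(y, mu, exp(lsig), log = TRUE)
  }
  margin_u <- function(y, X, beta, lsig, link) {
    mu <- linkinv(link)(as.numeric(X %*% beta))
    u <- stats::pnorm(y, mu, exp(lsig))
    pmin(1 - 1e-10, pmax(1e-10, u))
  }
  unpack <- function(par) {
    list(bw = par[seq_len(pw)], lsw = par[pw + 1],
         bf = par[pw + 1 + seq_len(pf)], lsf = par[pw + pf + 2],
         th = if (est_theta) par[pw + pf + 3] else theta_fixed)
  }
  negll <- function(par) {
    p <- unpack(par)
    bb <- theta_bounds(family)
    if (est_theta && (p$th < bb[1] || p$th > bb[2])) return(1e10)
    llw <- margin_ll(yw, Xw, p$bw, p$lsw, spec$link_work)
    llf <- margin_ll(yf, Xf, p$bf, p$lsf, spec$link_free)
    ll <- sum(llw) + sum(llf)
    if (!is.null(p$th) && !(family == "gaussian" && p$th == 0)) {
      u <- margin_u(yw, Xw, p$bw, p$lsw, spec$link_work)
      v <- margin_u(yf, Xf, p$bf, p$lsf, spec$link_free)
      ll <- ll + sum(copula_logdens(u, v, p$th, family))
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # inference-for-margins start
  ifm <- function(y, X, link) {
    if (link == "identity") {
      fit <- stats::lm.fit(X, y)
      list(beta = fit$coefficients,
           lsig = log(sqrt(mean(fit$residuals^2))))
    } else {
      fit <- stats::glm.fit(X, y, family = stats::gaussian("log"),
                            start = c(log(max(mean(y), 1e-3)),
                                      rep(0, ncol(X) - 1)))
      list(beta = fit$coefficients,
           lsig = log(sqrt(mean((y - fit$fitted.values)^2))))
    }
  }
  sw <- ifm(yw, Xw, spec$link_work)
  sf <- ifm(yf, Xf, spec$link_free)
  par0 <- c(sw$beta, sw$lsig, sf$beta, sf$lsig)
  if (est_theta) {
    bb <- theta_bounds(family)
    th0 <- stats::optimize(function(th) negll(c(par0, th)),
                           lower = bb[1], upper = bb[2])$minimum
    par0 <- c(par0, th0)
  }
  op <- stats::optim(par0, negll, method = "BFGS",
                     control = list(maxit = 500), hessian = TRUE)
  p <- unpack(op$par)
  se <- rep(NA_real_, length(op$par))
  flags <- character()
  if (op$convergence != 0) flags <- c(flags, "non_convergence")
  hinv <- try(solve(op$hessian), silent = TRUE)
  if (inherits(hinv, "try-error") || any(diag(hinv) < 0)) {
    flags <- c(flags, "singular_information")
  } else {
    se <- sqrt(diag(hinv))
  }
  bb <- theta_bounds(family)
  if (est_theta && (abs(p$th - bb[1]) < 1e-6 || abs(p$th - bb[2]) < 1e-6)) {
    flags <- c(flags, "theta_at_boundary")
  }
  k <- length(op$par)
  ll <- -op$value
  structure(list(
    spec = spec, family = family,
    coef_work = stats::setNames(p$bw, colnames(Xw)),
    coef_free = stats::setNames(p$bf, colnames(Xf)),
    se_work = stats::setNames(se[seq_len(pw)], colnames(Xw)),
    se_free = stats::setNames(se[pw + 1 + seq_len(pf)], colnames(Xf)),
    sigma_work = exp(p$lsw), sigma_free = exp(p$lsf),
    theta = p$th, theta_se = if (est_theta) se[pw + pf + 3] else NA_real_,
    theta_fixed = !est_theta,
    loglik = ll, n_params = k, n_obs = n,
    aicc = if (n > k + 1) 2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
           else NA_real_,
    flags = flags
  ), class = "copula_fit")
}

#' @export
print.copula_fit <- function(x, ...) {
  cat(sprintf("<copula_fit> %s copula, theta=%.3f%s, loglik %.2f, AICc %.2f\n",
              x$family, x$theta, if (x$theta_fixed) " (fixed)" else "",
              x$loglik, x$aicc))
  print(wald_z(x))
  invisible(x)
}

#' Wald z-tests for a copula regression
#'
#' `z = estimate / SE`, `p = 2 * Phi(-|z|)`, for both margins.
#'
#' @param fit a [fit_copula()] result.
#' @return A `data.frame` with margin, term, Estimate, Std.Error, z.value
#'   and `Pr(>|z|)`.
#' @export
wald_z <- function(fit) {
  mk <- function(margin, b, s) {
    z <- b / s
    data.frame(margin = margin, term = names(b), Estimate = as.numeric(b),
               Std.Error = as.numeric(s), z.value = as.numeric(z),
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)), check.names = FALSE)
  }
  out <- rbind(mk("work", fit$coef_work, fit$se_work),
               mk("free", fit$coef_free, fit$se_free))
  if (any(!is.na(out$Std.Error) & out$Std.Error == 0)) {
    attr(out, "flags") <- "zero_se"
  }
  rownames(out) <- NULL
  out
}

#' Backward AICc model selection
#'
#' Greedy backward elimination from the full model (all four main effects
#' plus the six pairwise interactions, per margin), respecting marginality
#' (an interaction is removed before its main effects), minimizing AICc;
#' AICc ties resolve to the model with fewer parameters.
#'
#' @param data as in [fit_copula()].
#' @param response response name (informational).
#' @param full_terms starting terms per margin.
#' @param link_work,link_free marginal links.
#' @param family copula family.
#' @param trace if `TRUE`, prints the elimination path.
#' @return The best `copula_fit`, with the search path in attribute
#'   `search_path`.
#' @export
select_model <- function(data, response = "y",
                         full_terms = c("ShT", "Age", "CS", "YNW",
                                        "ShT:Age", "ShT:CS", "ShT:YNW",
                                        "Age:CS", "Age:YNW", "CS:YNW"),
                         link_work = "identity", link_free = "identity",
                         family = "gaussian", trace = FALSE) {
  droppable <- function(terms) {
    ints <- grep(":", terms, value = TRUE)
    in_int <- unique(unlist(strsplit(ints, ":")))
    c(ints, setdiff(terms, c(ints, in_int)))
  }
  cur_w <- full_terms; cur_f <- full_terms
  fit1 <- function(tw, tf) {
    fit_copula(model_spec(response, tw, tf, link_work, link_free), data,
               family = family)
  }
  best <- fit1(cur_w, cur_f)
  path <- sprintf("full model: AICc %.3f (k=%d)", best$aicc, best$n_params)
  repeat {
    cands <- c(lapply(droppable(cur_w), function(tm)
                 list(w = setdiff(cur_w, tm), f = cur_f, lab = paste0("work -", tm))),
               lapply(droppable(cur_f), function(tm)
                 list(w = cur_w, f = setdiff(cur_f, tm), lab = paste0("free -", tm))))
    if (!length(cands)) break
    fits <- lapply(cands, function(cd) suppressWarnings(fit1(cd$w, cd$f)))
    aiccs <- vapply(fits, function(f) f$aicc %||% Inf, 0)
    ks <- vapply(fits, `[[`, 0, "n_params")
    o <- order(aiccs, ks)
    if (aiccs[o[1]] <= best$aicc + 1e-9) {
      # accept the drop (ties go to the smaller model)
      if (aiccs[o[1]] > best$aicc - 1e-9 && ks[o[1]] >= best$n_params) break
      best <- fits[[o[1]]]
      cur_w <- cands[[o[1]]]$w; cur_f <- cands[[o[1]]]$f
      path <- c(path, sprintf("%s: AICc %.3f (k=%d)",
                              cands[[o[1]]]$lab, best$aicc, best$n_params))
      if (trace) message(path[length(path)])
    } else break
  }
  attr(best, "search_path") <- path
  best
}

#' Nonparametric group tests
#'
#' Thin, logged wrapper over the standard tests used throughout the
#' analysis: Mann-Whitney U, Wilcoxon signed-rank (paired), Spearman
#' correlation, Kruskal-Wallis and chi-square.
#'
#' @param values numeric values (or first variable for `spearman`).
#' @param grouping group factor, paired second sample, second variable, or
#'   contingency counts depending on `kind`.
#' @param kind test kind.
#' @return The `htest` result.
#' @export
group_tests <- function(values, grouping,
                        kind = c("mann_whitney", "wilcoxon_signed_rank",
                                 "spearman", "kruskal_wallis", "chi_square")) {
  kind <- match.arg(kind)
  switch(kind,
    mann_whitney = {
      g <- factor(grouping)
      if (nlevels(g) != 2) stop_input("mann_whitney needs exactly 2 groups")
      stats::wilcox.test(values[g == levels(g)[1]], values[g == levels(g)[2]],
                         exact = FALSE)
    },
    wilcoxon_signed_rank = stats::wilcox.test(values, grouping, paired = TRUE,
                                              exact = FALSE),
    spearman = stats::cor.test(values, grouping, method = "spearman",
                               exact = FALSE),
    kruskal_wallis = stats::kruskal.test(values, factor(grouping)),
    chi_square = stats::chisq.test(values, grouping)
  )
}

#' Cohen's d from a mean difference and common SD
#'
#' @param delta difference in means.
#' @param sd common standard deviation.
#' @return `delta / sd`.
#' @export
cohens_d <- function(delta, sd) {
  if (sd <= 0) stop_input("sd must be positive")
  delta / sd
}

#' Per-group sample size for a two-sample t-test
#'
#' Smallest integer n per group such that a two-sided two-sample t-test at
#' level `alpha` attains at least the requested power against effect size
#' `d`, with power evaluated through the noncentral t distribution.
#'
#' @param d Cohen's d (> 0).
#' @param alpha two-sided significance level.
#' @param power target power in (alpha, 1).
#' @return Integer n per group.
#' @export
power_sample_size <- function(d, alpha = 0.05, power = 0.80) {
  if (d <= 0) stop_input("effect size d must be > 0")
  if (power <= alpha || power >= 1 || alpha <= 0) {
    stop_input("need alpha in (0,1) and power in (alpha, 1)")
  }
  power_at <- function(n) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    q <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(q, df, ncp = ncp) + stats::pt(-q, df, ncp = ncp)
  }
  n <- 2
  while (power_at(n) < power) {
    n <- n + 1
    if (n > 1e6) stop_input("sample size search did not terminate")
  }
  n
}
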