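#' @useDynLib circashift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Harmonic basis for the transition logits.  Single oscillator: intercept +
# H cos/sin pairs of fundamental period 24 h.  Two oscillators: shared
# intercept, separate cos/sin pairs gated by work/free day type.
hhmm_basis <- function(clock, day_type, harmonics, two_oscillator) {
  H <- harmonics
  ang <- outer(2 * pi * clock / 24, seq_len(H))
  C <- cos(ang); S <- sin(ang)
  if (!two_oscillator) {
    Z <- cbind(1, C, S)
    colnames(Z) <- c("(base)", paste0("cos", 1:H), paste0("sin", 1:H))
  } else {
    if (is.null(day_type)) stop_input("two-oscillator basis needs day labels")
    w <- as.numeric(day_type == "work")
    Z <- cbind(1, C * w, S * w, C * (1 - w), S * (1 - w))
    colnames(Z) <- c("(base)", paste0("cos", 1:H, ".work"),
                     paste0("sin", 1:H, ".work"),
                     paste0("cos", 1:H, ".free"), paste0("sin", 1:H, ".free"))
  }
  Z
}

# Realized transition probabilities for row j at each row of Z: softmax over
# (0 for self, Z theta_j for the non-reference columns).  Returns n x K.
row_probs <- function(theta_j, Z, j, K) {
  eta <- matrix(0, nrow(Z), K)
  eta[, setdiff(seq_len(K), j)] <- Z %*% theta_j
  m <- eta[cbind(seq_len(nrow(eta)), max.col(eta))]
  E <- exp(eta - m)
  E / rowSums(E)
}

# (K, K, T-1) array of transition matrices from the parameter list
trans_array <- function(theta, Z, K) {
  Tm1 <- nrow(Z)
  A <- array(0, c(K, K, Tm1))
  for (j in seq_len(K)) A[j, , ] <- t(row_probs(theta[[j]], Z, j, K))
  A
}

# Weighted multinomial-logit M-step for one transition row: maximizes
# sum_t sum_k W[t,k] log P_jk(t) over theta_j.
row_mstep <- function(theta_j, Z, W, j, K) {
  nonref <- setdiff(seq_len(K), j)
  p <- ncol(Z)
  Rtot <- rowSums(W)
  lse_eta <- function(par) {
    eta <- matrix(0, nrow(Z), K)
    eta[, nonref] <- Z %*% matrix(par, p, K - 1)
    m <- eta[cbind(seq_len(nrow(eta)), max.col(eta))]
    list(eta = eta, lse = m + log(rowSums(exp(eta - m))))
  }
  fn <- function(par) {
    e <- lse_eta(par)
    -sum(W * (e$eta - e$lse))
  }
  gr <- function(par) {
    e <- lse_eta(par)
    P <- exp(e$eta - e$lse)
    -as.numeric(crossprod(Z, W[, nonref, drop = FALSE] -
                               Rtot * P[, nonref, drop = FALSE]))
  }
  op <- stats::optim(as.numeric(theta_j), fn, gr, method = "BFGS",
                     control = list(maxit = 200))
  matrix(op$par, p, K - 1)
}

new_hhmm_fit <- function(means, sds, theta, pi0, harmonics, two_oscillator,
                         loglik = NA_real_, ll_trace = numeric(),
                         n_obs = NA_integer_, converged = NA, flags = character(),
                         bin_minutes = 5, restart_logliks = numeric()) {
  K <- length(means)
  p <- if (two_oscillator) 1 + 4 * harmonics else 1 + 2 * harmonics
  structure(list(
    means = means, sds = sds, theta = theta, pi0 = pi0,
    harmonics = harmonics,
    oscillator_set = if (two_oscillator) c("work", "free") else "single",
    loglik = loglik, ll_trace = ll_trace,
    n_params = 2 * K + K * (K - 1) * p + (K - 1),
    n_obs = n_obs, converged = converged, flags = flags,
    bin_minutes = bin_minutes, restart_logliks = restart_logliks
  ), class = "hhmm_fit")
}

#' Construct a harmonic HMM with known parameters
#'
#' Builds an `hhmm_fit` object directly from parameter values, e.g. for
#' simulation, decoding with a reference model, or oracle checks.
#'
#' @param means,sds Gaussian emission means and SDs per state (sqrt activity
#'   scale), means strictly increasing.
#' @param theta list of length K; element `j` is a `p x (K-1)` matrix of
#'   multinomial-logit coefficients for row `j`'s non-reference (non-self)
#'   transition targets, columns ordered by target state.  `p` is
#'   `1 + 2*harmonics` for a single oscillator and `1 + 4*harmonics` for
#'   two.
#' @param pi0 initial state distribution.
#' @param harmonics number of harmonic sin/cos pairs (fundamental 24 h).
#' @param two_oscillator if `TRUE`, separate work/free-day oscillators.
#' @param bin_minutes width of the observation bins (minutes).
#' @return An `hhmm_fit` object.
#' @export
hhmm_model <- function(means, sds, theta, pi0 = NULL, harmonics = 1,
                       two_oscillator = FALSE, bin_minutes = 5) {
  K <- length(means)
  if (any(diff(means) <= 0)) stop_input("state means must be strictly increasing")
  stopifnot(length(sds) == K, all(sds > 0), length(theta) == K)
  pi0 <- pi0 %||% rep(1 / K, K)
  p <- if (two_oscillator) 1 + 4 * harmonics else 1 + 2 * harmonics
  for (j in seq_len(K)) {
    stopifnot(nrow(theta[[j]]) == p, ncol(theta[[j]]) == K - 1)
  }
  new_hhmm_fit(means, sds, theta, pi0 / sum(pi0), harmonics, two_oscillator,
               bin_minutes = bin_minutes)
}

#' Fit a harmonic hidden Markov model to binned activity
#'
#' EM estimation of a K-state Gaussian-emission HMM whose transition
#' probabilities vary over the 24 h clock: each transition row is a
#' multinomial logit (self-transition as reference) whose non-reference
#' logits carry `harmonics` sin/cos pairs of fundamental period 24 h.  With
#' `day_type` labels the harmonic coefficients are estimated separately for
#' work and free days (two-oscillator variant) while emissions and baseline
#' logits are shared.
#'
#' States are ordered by emission mean: state 1 = inactive (rest),
#' 2 = moderately active, 3 = highly active.
#'
#' @param y square-root 5-min average activity, `NA` = missing bin.
#' @param clock clock hour in \[0, 24) of each bin.
#' @param day_type optional character vector ("work"/"free") per bin; when
#'   given, the two-oscillator model is fitted.
#' @param n_states number of latent states (default 3).
#' @param harmonics harmonic pairs H (default 1).
#' @param n_restarts random EM restarts; short runs are ranked and the best
#'   continued to convergence.
#' @param tol EM stops when the log-likelihood improves by less than `tol`.
#' @param max_iter maximum EM iterations.
#' @param seed seed controlling restart initialization.
#' @param bin_minutes bin width (minutes), used only for bookkeeping.
#' @return An `hhmm_fit` with emissions, transition coefficients, initial
#'   distribution, log-likelihood trace, parameter count and convergence
#'   flags.
#' @export
fit_hhmm <- function(y, clock, day_type = NULL, n_states = 3, harmonics = 1,
                     n_restarts = 5, tol = 1e-5, max_iter = 500, seed = 1,
                     bin_minutes = 5) {
  K <- n_states
  T_ <- length(y)
  stopifnot(length(clock) == T_)
  two_osc <- !is.null(day_type)
  if (two_osc) stopifnot(length(day_type) == T_)
  if (T_ < 2 * 24 * 60 / bin_minutes) {
    stop_input("need at least 2 days of data (%d bins given)", T_)
  }
  if (mean(is.na(y)) >= 0.5) stop_input("more than 50%% of bins missing")
  obs <- y[!is.na(y)]
  if (stats::sd(obs) < 1e-8) {
    # degenerate: a single emission distribution explains everything
    th <- replicate(K, matrix(0, if (two_osc) 1 + 4 * harmonics else
                              1 + 2 * harmonics, K - 1), simplify = FALSE)
    fit <- new_hhmm_fit(rep(mean(obs), K) + seq_len(K) * 1e-9,
                        rep(1e-3, K), th, rep(1 / K, K), harmonics, two_osc,
                        n_obs = length(obs), converged = TRUE,
                        flags = "degenerate_single_state",
                        bin_minutes = bin_minutes)
    return(fit)
  }

  Z <- hhmm_basis(clock[-T_], if (two_osc) day_type[-T_] else NULL,
                  harmonics, two_osc)
  p <- ncol(Z)
  logdens_for <- function(means, sds) {
    ld <- matrix(0, T_, K)
    ok <- !is.na(y)
    for (k in seq_len(K)) {
      ld[ok, k] <- stats::dnorm(y[ok], means[k], sds[k], log = TRUE)
    }
    ld
  }

  em_run <- function(means, sds, theta, pi0, iters) {
    ll_trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    monotone <- TRUE
    for (it in seq_len(iters)) {
      A <- trans_array(theta, Z, K)
      fb <- fb_cpp(logdens_for(means, sds), pi0, as.numeric(A))
      ll <- fb$loglik
      if (ll < ll_prev - 1e-6) monotone <- FALSE
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
      g <- fb$gamma
      ok <- !is.na(y)
      wsum <- colSums(g[ok, , drop = FALSE])
      means <- colSums(g[ok, , drop = FALSE] * y[ok]) / wsum
      sds <- sqrt(colSums(g[ok, , drop = FALSE] *
                            sweep(matrix(y[ok], sum(ok), K), 2, means)^2) / wsum)
      sds <- pmax(sds, 1e-3)
      for (j in seq_len(K)) {
        W <- fb$xi[, (seq_len(K) - 1) * K + j, drop = FALSE]  # out of state j
        theta[[j]] <- row_mstep(theta[[j]], Z, W, j, K)
      }
      pi0 <- pmax(g[1, ], 1e-12)
      pi0 <- pi0 / sum(pi0)
    }
    list(means = means, sds = sds, theta = theta, pi0 = pi0,
         loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
         converged = converged, monotone = monotone)
  }

  qs <- stats::quantile(obs, c(0.25, 0.60, 0.95), names = FALSE)
  if (K != 3) qs <- stats::quantile(obs, seq_len(K) / (K + 1), names = FALSE)
  inits <- with_seed(seed, lapply(seq_len(n_restarts), function(r) {
    mu <- if (r == 1) qs else
      sort(qs + stats::rnorm(K, 0, 0.1 * diff(range(obs))))
    list(means = mu, sds = rep(stats::sd(obs) / 3, K),
         theta = replicate(K, {
           th <- matrix(0, p, K - 1)
           th[1, ] <- log(0.1 / (K - 1) / 0.9)  # diagonal-dominant start
           th
         }, simplify = FALSE),
         pi0 = rep(1 / K, K))
  }))

  short <- lapply(inits, function(ini) {
    em_run(ini$means, ini$sds, ini$theta, ini$pi0, iters = min(25, max_iter))
  })
  restart_ll <- vapply(short, `[[`, 0, "loglik")
  best <- short[[which.max(restart_ll)]]
  run <- em_run(best$means, best$sds, best$theta, best$pi0, iters = max_iter)

  flags <- character()
  if (!run$converged) flags <- c(flags, "non_convergence")
  if (!run$monotone) flags <- c(flags, "loglik_decrease")

  # enforce mean ordering
  ord <- order(run$means)
  perm_theta <- vector("list", K)
  for (jnew in seq_len(K)) {
    jold <- ord[jnew]
    th_old <- run$theta[[jold]]             # columns: targets != jold, ascending
    old_targets <- setdiff(seq_len(K), jold)
    new_targets <- setdiff(seq_len(K), jnew)
    th_new <- matrix(0, p, K - 1)
    for (c_i in seq_len(K - 1)) {
      kold <- ord[new_targets[c_i]]
      th_new[, c_i] <- th_old[, match(kold, old_targets)]
    }
    perm_theta[[jnew]] <- th_new
  }
  new_hhmm_fit(run$means[ord], run$sds[ord], perm_theta, run$pi0[ord],
               harmonics, two_osc, loglik = run$loglik,
               ll_trace = run$ll_trace, n_obs = sum(!is.na(y)),
               converged = run$converged, flags = flags,
               bin_minutes = bin_minutes, restart_logliks = restart_ll)
}

#' Realized transition matrix at a clock time
#'
#' Softmax of the baseline plus harmonic logits at clock hour `t`, for the
#' requested day type's oscillator.  Rows sum to one; the matrix is 24 h
#' periodic in `t`.
#'
#' @param fit an `hhmm_fit`.
#' @param t clock hour (any real; reduced mod 24).
#' @param day_type `"work"` or `"free"` for a two-oscillator fit; must be
#'   omitted for a single-oscillator fit.
#' @return A K x K stochastic matrix.
#' @export
transition_matrix <- function(fit, t, day_type = NULL) {
  stopifnot(inherits(fit, "hhmm_fit"))
  two_osc <- !identical(fit$oscillator_set, "single")
  if (two_osc) {
    if (is.null(day_type) || !day_type %in% c("work", "free")) {
      stop_input("two-oscillator fit needs day_type 'work' or 'free'")
    }
  } else if (!is.null(day_type)) {
    stop_input("day_type is meaningless for a single-oscillator fit")
  }
  K <- length(fit$means)
  Z <- hhmm_basis(t %% 24, day_type, fit$harmonics, two_osc)
  P <- matrix(0, K, K)
  for (j in seq_len(K)) P[j, ] <- row_probs(fit$theta[[j]], Z, j, K)
  P
}

#' Posterior state probabilities (local decoding)
#'
#' Forward-backward smoothing with the fit's time-varying transitions.
#' Missing bins contribute emission likelihood 1 to every state, so their
#' posteriors follow the prior propagated by the transition structure.  The
#' most likely state per bin is the posterior argmax (local decoding, not
#' Viterbi).
#'
#' @inheritParams fit_hhmm
#' @param fit an `hhmm_fit`.
#' @return A `state_probabilities` object: list with `gamma` (T x K posterior
#'   matrix), `states` (argmax per bin), `observed`, `clock`, `day_type` and
#'   `loglik`.
#' @export
decode <- function(fit, y, clock, day_type = NULL) {
  stopifnot(inherits(fit, "hhmm_fit"))
  two_osc <- !identical(fit$oscillator_set, "single")
  if (two_osc && is.null(day_type)) {
    stop_input("two-oscillator fit needs per-bin day_type labels")
  }
  K <- length(fit$means)
  T_ <- length(y)
  Z <- hhmm_basis(clock[-T_], if (two_osc) day_type[-T_] else NULL,
                  fit$harmonics, two_osc)
  ld <- matrix(0, T_, K)
  ok <- !is.na(y)
  for (k in seq_len(K)) {
    ld[ok, k] <- stats::dnorm(y[ok], fit$means[k], fit$sds[k], log = TRUE)
  }
  fb <- fb_cpp(ld, fit$pi0, as.numeric(trans_array(fit$theta, Z, K)))
  structure(list(gamma = fb$gamma, states = max.col(fb$gamma, "first"),
                 observed = ok, clock = clock, day_type = day_type,
                 loglik = fb$loglik),
            class = "state_probabilities")
}

#' Corrected Akaike information criterion
#'
#' `AICc = AIC + 2k(k+1)/(n-k-1)` with `AIC = 2k - 2*loglik`; used to
#' compare fits.
#'
#' @param x an `hhmm_fit`, a `copula_fit`, or a numeric log-likelihood.
#' @param k,n parameter and observation counts (taken from the fit object
#'   when `x` is one).
#' @return The AICc value.
#' @export
aicc <- function(x, k = NULL, n = NULL) {
  if (inherits(x, c("hhmm_fit", "copula_fit"))) {
    ll <- x$loglik
    k <- k %||% x$n_params
    n <- n %||% x$n_obs
  } else {
    ll <- x
    if (is.null(k) || is.null(n)) stop_input("k and n are required")
  }
  if (n <= k + 1) stop_input("AICc undefined for n <= k + 1 (n=%s, k=%s)", n, k)
  2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
print.hhmm_fit <- function(x, ...) {
  cat(sprintf("<hhmm_fit> %d states, H=%d, oscillator: %s\n",
              length(x$means), x$harmonics,
              paste(x$oscillator_set, collapse = "/")))
  cat("  means:", signif(x$means, 4), "\n  sds:  ", signif(x$sds, 4), "\n")
  cat(sprintf("  loglik %.2f (k=%d, n=%d)%s\n", x$loglik, x$n_params, x$n_obs,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Serialize / restore a fitted HHMM
#'
#' Writes all parameters, dimensions and the convergence trace to a JSON
#' file, and reads them back into an equivalent `hhmm_fit`.
#'
#' @param fit an `hhmm_fit`.
#' @param path JSON file path.
#' @return `write_hhmm_json()` returns `path` invisibly; `read_hhmm_json()`
#'   the restored fit.
#' @export
write_hhmm_json <- function(fit, path) {
  obj <- unclass(fit)
  obj$theta <- lapply(obj$theta, function(m) list(dim = dim(m),
                                                 values = as.numeric(m)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hhmm_json
#' @export
read_hhmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) {
    v <- unlist(x)
    if (is.null(v) || !length(v)) return(NA_real_)
    suppressWarnings(as.numeric(v))
  }
  theta <- lapply(obj$theta, function(e) {
    d <- num(e$dim)
    matrix(num(e$values), d[1], d[2])
  })
  osc <- unlist(obj$oscillator_set)
  new_hhmm_fit(num(obj$means), num(obj$sds), theta, num(obj$pi0),
               num(obj$harmonics), !identical(osc, "single"),
               loglik = num(obj$loglik), ll_trace = num(obj$ll_trace),
               n_obs = num(obj$n_obs),
               converged = isTRUE(unlist(obj$converged)),
               flags = as.character(unlist(obj$flags)),
               bin_minutes = num(obj$bin_minutes),
               restart_logliks = num(obj$restart_logliks))
}
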