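# Independent oracles used across the suite.

# Exhaustive forward-backward oracle: enumerate all K^T state paths and
# marginalize the joint probability.  logdens: T x K log emission densities;
# P_arr: K x K x (T-1) transition matrices.
brute_force_posteriors <- function(logdens, pi0, P_arr) {
  T_ <- nrow(logdens); K <- ncol(logdens)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(pi0[s[1]]) + logdens[1, s[1]]
    for (t in seq_len(T_ - 1)) {
      lp <- lp + log(P_arr[s[t], s[t + 1], t]) + logdens[t + 1, s[t + 1]]
    }
    lp
  })
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  gamma <- matrix(0, T_, K)
  for (t in seq_len(T_)) {
    for (k in seq_len(K)) gamma[t, k] <- sum(w[paths[, t] == k])
  }
  list(gamma = gamma,
       loglik = log(sum(exp(logp - max(logp)))) + max(logp))
}

# Gaussian log emission matrix with missing handled as likelihood 1
emission_logdens <- function(y, means, sds) {
  K <- length(means)
  ld <- matrix(0, length(y), K)
  ok <- !is.na(y)
  for (k in seq_len(K)) ld[ok, k] <- dnorm(y[ok], means[k], sds[k], log = TRUE)
  ld
}

# transition array implied by an hhmm_fit along given clock times / labels
fit_trans_array <- function(fit, clock, day_type = NULL) {
  T_ <- length(clock)
  K <- length(fit$means)
  A <- array(0, c(K, K, T_ - 1))
  for (t in seq_len(T_ - 1)) {
    A[, , t] <- transition_matrix(fit, clock[t],
                                  if (is.null(day_type)) NULL else day_type[t])
  }
  A
}

# a small deterministic rest profile: `val_in` over a clock window (hours,
# half-open, may wrap midnight), `val_out` elsewhere
rect_profile <- function(from, to, val_in = 1, val_out = 0, anchor = 0) {
  ck <- (anchor + (seq_len(288) - 0.5) / 12) %% 24
  inw <- if (from < to) ck > from & ck < to else ck > from | ck < to
  structure(ifelse(inw, val_in, val_out), anchor = anchor, day_type = "whole",
            class = "rest_profile")
}

# quick per-subject 5-min bin frame from a generated subject
subject_bins <- function(subject) {
  b5 <- resample(subject$series, "5min")
  b5$y <- sqrt_pa(b5$pa)
  b5$clock <- (as.numeric(b5$timestamp) %% 86400) / 3600
  b5
}

subject_partition <- function(subject) {
  span <- range(subject$series$timestamp)
  span[2] <- span[2] + 60
  partition_days(subject$diary, subject$meta, span)
}

# adjusted Rand index between two partitions
adj_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) sum(x * (x - 1) / 2)
  sum_ij <- ch2(tab)
  sum_a <- ch2(rowSums(tab)); sum_b <- ch2(colSums(tab))
  n <- length(a)
  expected <- sum_a * sum_b / ch2_n(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
ch2_n <- function(n) n * (n - 1) / 2
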