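# three NS-like rest-pattern templates on the 20:00-anchored clock:
# bimodal-early, bimodal-late, unimodal
ns_templates <- function() {
  bump <- function(centre, width, height = 0.85) {
    ck <- (20 + (seq_len(288) - 0.5) / 12) %% 24
    height * exp(-0.5 * (circashift:::circ_diff_h(ck, centre) / width)^2)
  }
  list(bimodal_early = pmin(1, bump(4.4, 1.2) + bump(11.4, 1.5)),
       bimodal_late = pmin(1, bump(3.1, 1.2) + bump(8.9, 1.5)),
       unimodal = pmin(1, bump(7, 2.2)))
}

planted_cohort <- function(n_per = 10, noise = 0.04, seed = 1) {
  tpl <- ns_templates()
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_along(tpl), function(g) {
      t(vapply(seq_len(n_per), function(i) {
        pmin(1, pmax(0, c(tpl[[g]], tpl[[g]]) + rnorm(576, 0, noise)))
      }, numeric(576)))
    }))
  })
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  list(X = X, truth = rep(seq_along(tpl), each = n_per))
}

# simulate paired work/free responses from a Gaussian-copula model with
# Gaussian identity-link margins
sim_pair <- function(n, beta_w = c(3.3, -0.35), beta_f = c(2.9, -0.24),
                     sd_w = 0.3, sd_f = 0.3, theta = 0.5, seed = 1) {
  withr::with_seed(seed, {
    ShT <- rep(c(0, 1), length.out = n)
    Age <- round(runif(n, 22, 62))
    CS <- round(runif(n, 24, 74))
    YNW <- ifelse(ShT == 1, round(runif(n, 5, 35)), 0)
    z1 <- rnorm(n)
    z2 <- theta * z1 + sqrt(1 - theta^2) * rnorm(n)
    data.frame(y_work = beta_w[1] + beta_w[2] * ShT + sd_w * z1,
               y_free = beta_f[1] + beta_f[2] * ShT + sd_f * z2,
               ShT = ShT, Age = Age, CS = CS, YNW = YNW)
  })
}
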