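# shared simulation helpers for the test suite

# one-group, one-condition ex-Gaussian dataset with participant variation
sim_exgauss_trials <- function(seed, n_part = 30, n_trials = 48,
                               mu = 3.21, sigma = 0.98, tau = 1.52,
                               group = "I", condition = "angry_target",
                               spread = 0.1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_part), function(i) {
    mu_i <- rnorm(1, mu, spread * mu)
    sg_i <- rlnorm(1, log(sigma), spread)
    ta_i <- rlnorm(1, log(tau), spread)
    data.frame(participant_id = sprintf("%s_p%03d", group, i), group = group,
               condition = condition,
               rt = rexgauss(n_trials, mu_i, sg_i, ta_i, positive_only = TRUE),
               stringsAsFactors = FALSE)
  }))
}

# SDT counts for one group at given generating sensitivities
sim_sdt_counts <- function(seed, n_part = 85, d_angry = 2.87, d_happy = 2.32,
                           c_mean = 0, n_signal = 24, n_noise = 48,
                           group = "I", spread = 0.1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_part), function(i) {
    da <- rnorm(1, d_angry, spread * abs(d_angry))
    dh <- rnorm(1, d_happy, spread * abs(d_happy))
    ci <- rnorm(1, c_mean, 0.1)
    fa <- rbinom(1, n_noise, pnorm(-mean(c(da, dh)) / 2 - ci))
    data.frame(participant_id = sprintf("%s_p%03d", group, i), group = group,
               emotion = c("angry", "happy"), n_signal = as.integer(n_signal),
               n_hits = c(rbinom(1, n_signal, pnorm(da / 2 - ci)),
                          rbinom(1, n_signal, pnorm(dh / 2 - ci))),
               n_noise = as.integer(n_noise), n_false_alarms = fa,
               stringsAsFactors = FALSE)
  }))
}

# numerical convolution oracle for the ex-Gaussian density: integrate over
# the Gaussian component on the finite window that carries all the mass of
# both factors (the Gaussian is localized around mu, the exponential factor
# requires x <= t and decays with rate 1/tau below it)
exgauss_pdf_oracle <- function(t, mu, sigma, tau) {
  lo <- max(mu - 12 * sigma, t - 60 * tau)
  hi <- min(t, mu + 12 * sigma)
  if (hi <= lo) return(0)
  stats::integrate(function(x) dnorm(x, mu, sigma) * dexp(t - x, 1 / tau),
                   lo, hi, rel.tol = 1e-13, subdivisions = 5000L)$value
}

# compact layout for saliency tests that do not need full display scale
small_layout <- function(target_slot = NA_integer_, jitter = 4L) {
  grid_layout(raster_size = 192L, patch_size = 48L, jitter = jitter,
              target_slot = target_slot)
}
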