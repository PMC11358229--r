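test_that("d-prime point estimates invert the probit at known quantiles", {
  expect_equal(dprime_point(0.97725, 0.5), 2, tolerance = 1e-3)
  expect_equal(dprime_point(0.3, 0.3), 0)
  expect_equal(dprime_point(0.69146, 0.30854), 1, tolerance = 1e-4)
  expect_error(dprime_point(1.2, 0.5), "rates")
  # edge correction: 1/(2N) pulls boundary rates inward
  expect_equal(dprime_point(1, 0.5, n_signal = 24),
               qnorm(1 - 1 / 48), tolerance = 1e-10)
  expect_error(dprime_point(1, 0.5), "trial count")
})

test_that("group-level posteriors agree with an independent Gibbs sampler (JAGS)", {
  skip_if_not_installed("rjags")
  cnt <- sim_sdt_counts(99, n_part = 30, d_angry = 2.0, d_happy = 1.4,
                        c_mean = 0.1, group = "G")
  fit <- suppressWarnings(fit_hierarchical_sdt(cnt, mcmc_config("desk"), seed = 2))

  hits <- cbind(cnt$n_hits[cnt$emotion == "angry"],
                cnt$n_hits[cnt$emotion == "happy"])
  fa <- cnt$n_false_alarms[cnt$emotion == "angry"]
  mstr <- "model{
    for (i in 1:N) {
      for (e in 1:2) {
        d[i,e] ~ dnorm(Md[e], 1/(Sd[e]*Sd[e]))
        hits[i,e] ~ dbin(phi(d[i,e]/2 - c[i]), 24)
      }
      c[i] ~ dnorm(Mc, 1/(Sc*Sc))
      fa[i] ~ dbin(phi(-(d[i,1]+d[i,2])/4 - c[i]), 48)
    }
    for (e in 1:2) { Md[e] ~ dnorm(0, 0.25); Sd[e] ~ dnorm(0, 1) T(0,) }
    Mc ~ dnorm(0, 0.25); Sc ~ dnorm(0, 1) T(0,)
  }"
  jm <- rjags::jags.model(textConnection(mstr),
                          data = list(N = nrow(hits), hits = hits, fa = fa),
                          n.chains = 2, quiet = TRUE)
  stats::update(jm, 2000, progress.bar = "none")
  s <- summary(rjags::coda.samples(jm, c("Md", "Mc"), 8000,
                                   progress.bar = "none"))$statistics
  ours <- fit$summary
  expect_equal(ours$median[ours$parameter == "mu_d" & ours$emotion == "angry"],
               unname(s["Md[1]", "Mean"]), tolerance = 0.05)
  expect_equal(ours$median[ours$parameter == "mu_d" & ours$emotion == "happy"],
               unname(s["Md[2]", "Mean"]), tolerance = 0.05)
  expect_equal(ours$median[ours$parameter == "mu_c"],
               unname(s["Mc", "Mean"]), tolerance = 0.04)
})

test_that("swapping emotion labels swaps the posteriors", {
  cnt <- sim_sdt_counts(12, n_part = 40, d_angry = 2.8, d_happy = 2.0)
  fit <- suppressWarnings(fit_hierarchical_sdt(cnt, mcmc_config("desk"), seed = 5))
  swapped <- cnt
  swapped$emotion <- ifelse(cnt$emotion == "angry", "happy", "angry")
  fit_sw <- suppressWarnings(fit_hierarchical_sdt(swapped, mcmc_config("desk"), seed = 5))
  d_angry <- fit$summary$median[fit$summary$parameter == "mu_d" &
                                fit$summary$emotion == "angry"]
  d_happy_sw <- fit_sw$summary$median[fit_sw$summary$parameter == "mu_d" &
                                      fit_sw$summary$emotion == "happy"]
  expect_equal(d_angry, d_happy_sw, tolerance = 0.03)
})

test_that("participant-level estimates shrink toward the group mean", {
  cnt <- sim_sdt_counts(30, n_part = 50, d_angry = 2.5, d_happy = 2.5)
  fit <- suppressWarnings(fit_hierarchical_sdt(cnt, mcmc_config("desk"), seed = 7))
  emp <- dprime_point(cnt$n_hits[cnt$emotion == "angry"] / cnt$n_signal[cnt$emotion == "angry"],
                      cnt$n_false_alarms[cnt$emotion == "angry"] / cnt$n_noise[cnt$emotion == "angry"],
                      n_signal = 24, n_noise = 48)
  post <- fit$participant_d[["I"]][, "angry"]
  grand <- fit$summary$median[fit$summary$parameter == "mu_d" &
                              fit$summary$emotion == "angry"]
  # posterior means lie between the raw estimate and the group mean for
  # the clear majority of participants (MCMC noise allows a few crossings)
  between <- (post - emp) * (grand - emp) >= 0 | abs(post - emp) < 0.05
  expect_gt(mean(between), 0.9)
  # and the posterior spread is narrower than the raw spread
  expect_lt(sd(post), sd(emp))
})

test_that("collapsing two groups pools them into one posterior", {
  cnt <- rbind(sim_sdt_counts(41, n_part = 25, group = "V", d_angry = 3.10, d_happy = 2.74),
               sim_sdt_counts(42, n_part = 25, group = "IX", d_angry = 2.91, d_happy = 2.51))
  merged <- suppressWarnings(collapse_and_refit(cnt, c("V", "IX"),
                                                config = mcmc_config("desk"), seed = 8))
  expect_setequal(unique(merged$summary$group), "IX+V")
  d_cells <- merged$summary[merged$summary$parameter == "mu_d", ]
  expect_equal(nrow(d_cells), 2)
  # pooled medians live between the two generating truths
  ang <- d_cells$median[d_cells$emotion == "angry"]
  expect_gt(ang, 2.6); expect_lt(ang, 3.3)
  expect_error(collapse_and_refit(cnt, c("V", "V")), "two distinct")
  expect_error(collapse_and_refit(cnt, c("V", "Z")), "unknown group")
})

test_that("count validation rejects impossible inputs", {
  cnt <- sim_sdt_counts(2, n_part = 5)
  bad <- cnt; bad$n_noise <- 0L
  expect_error(fit_hierarchical_sdt(bad), "n_noise")
  zero <- cnt; zero$n_hits <- 0L; zero$n_false_alarms <- 0L
  expect_error(fit_hierarchical_sdt(zero), "degenerate")
})
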