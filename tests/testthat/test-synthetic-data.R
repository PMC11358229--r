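test_that("trial counts per participant are exact, not stochastic", {
  cfg <- simulation_config(n_participants_per_group = 3,
                           n_trials_per_participant = 96, rng_seed = 2)
  tr <- generate_behavioral_dataset(cfg)
  for (pid in unique(tr$participant_id)) {
    tab <- table(tr$condition[tr$participant_id == pid])
    expect_equal(unname(tab[["target_absent"]]), 48)
    expect_equal(unname(tab[["angry_target"]]), 24)
    expect_equal(unname(tab[["happy_target"]]), 24)
    expect_equal(mean(tr$target_present[tr$participant_id == pid]), 0.5)
  }
})

test_that("odd present-half splits alternate the extra trial deterministically", {
  cfg <- simulation_config(n_participants_per_group = 4,
                           n_trials_per_participant = 36, rng_seed = 2,
                           group_labels = "I")
  tr <- generate_behavioral_dataset(cfg)
  # 18 absent, 18 present: 9 angry + 9 happy is exact; with 18 present the
  # split is even, so use 38 trials for an odd present half
  cfg2 <- simulation_config(n_participants_per_group = 4,
                            n_trials_per_participant = 38, rng_seed = 2,
                            group_labels = "I")
  tr2 <- generate_behavioral_dataset(cfg2)
  ang <- sapply(sprintf("I_%03d", 1:4), function(p)
    sum(tr2$condition == "angry_target" & tr2$participant_id == p))
  # even participant indices get the extra angry trial
  expect_equal(unname(ang), c(9, 10, 9, 10))
  expect_true(all(table(tr$participant_id) == 36))
})

test_that("generation is a deterministic function of the config seed", {
  cfg <- simulation_config(n_participants_per_group = 3, rng_seed = 77)
  expect_identical(generate_behavioral_dataset(cfg),
                   generate_behavioral_dataset(cfg))
  cfg2 <- simulation_config(n_participants_per_group = 3, rng_seed = 78)
  expect_false(identical(generate_behavioral_dataset(cfg),
                         generate_behavioral_dataset(cfg2)))
})

test_that("a d = 0, c = 0 observer responds at chance on both trial types", {
  truth <- default_sdt_truth()
  truth$d <- 0; truth$c <- 0
  cfg <- simulation_config(n_participants_per_group = 4,
                           n_trials_per_participant = 4000,
                           sdt_truth = truth,
                           participant_sd = list(mu = 0.1, sigma = 0.1,
                                                 tau = 0.1, d = 0, c = 0),
                           rng_seed = 5)
  tr <- generate_behavioral_dataset(cfg)
  hit <- mean(tr$response[tr$target_present] == "different")
  fa <- mean(tr$response[!tr$target_present] == "different")
  n_hit <- sum(tr$target_present); n_fa <- sum(!tr$target_present)
  expect_lt(abs(hit - 0.5), 3 * sqrt(0.25 / n_hit))
  expect_lt(abs(fa - 0.5), 3 * sqrt(0.25 / n_fa))
})

test_that("empirical RT means and response rates converge to the generating model", {
  cfg <- simulation_config(n_participants_per_group = 60,
                           n_trials_per_participant = 96, rng_seed = 31,
                           group_labels = "IX",
                           participant_sd = list(mu = 0.02, sigma = 0.02,
                                                 tau = 0.02, d = 0.02, c = 0))
  tr <- generate_behavioral_dataset(cfg)
  truth <- default_exgauss_truth()
  for (cond in c("angry_target", "target_absent")) {
    row <- truth[truth$group == "IX" & truth$condition == cond, ]
    x <- tr$rt[tr$condition == cond]
    # ex-Gaussian mean is mu + tau; allow for the small participant spread
    se <- sqrt((row$sigma^2 + row$tau^2) / length(x)) + 0.02 * (row$mu + row$tau) / sqrt(60)
    expect_lt(abs(mean(x) - (row$mu + row$tau)), 3 * se + 0.02)
  }
  sdt <- default_sdt_truth()
  d_ang <- sdt$d[sdt$group == "IX" & sdt$emotion == "angry"]
  hit <- tr$response[tr$condition == "angry_target"] == "different"
  p_exp <- pnorm(d_ang / 2)
  expect_lt(abs(mean(hit) - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / length(hit)) + 0.01)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(simulation_config(n_trials_per_participant = 95), "even")
  bad <- default_exgauss_truth(); bad$sigma[1] <- -0.1
  expect_error(simulation_config(exgauss_truth = bad), "positive")
  incomplete <- default_exgauss_truth()[-1, ]
  expect_error(simulation_config(exgauss_truth = incomplete), "missing cell")
})

test_that("trial tables round-trip through CSV with true/false booleans", {
  cfg <- simulation_config(n_participants_per_group = 2, rng_seed = 9)
  tr <- generate_behavioral_dataset(cfg)
  p <- tempfile(fileext = ".csv")
  write_trial_table(tr, p)
  raw <- readLines(p, n = 2)
  expect_match(raw[1], "participant_id,group,condition,target_present,response,rt,correct")
  expect_match(raw[2], "(true|false)")
  back <- read_trial_table(p)
  expect_equal(back$rt, tr$rt, tolerance = 1e-12)
  expect_identical(back$target_present, tr$target_present)
  expect_identical(back$correct, tr$correct)
  unlink(p)
})

test_that("correctness flag encodes response == presence agreement", {
  cfg <- simulation_config(n_participants_per_group = 2, rng_seed = 12)
  tr <- generate_behavioral_dataset(cfg)
  expect_identical(tr$correct, (tr$response == "different") == tr$target_present)
  expect_identical(tr$target_present, tr$condition != "target_absent")
  expect_true(all(tr$rt > 0))
})
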