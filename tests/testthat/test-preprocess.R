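test_that("Tukey fences remove exactly the planted outliers", {
  f <- tukey_filter(c(1, 2, 3, 4, 100))
  # Q1 = 2, Q3 = 4 under linear interpolation, so the upper fence is 7
  expect_identical(f$keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(f$report$fences), c(-1, 7))
  expect_equal(f$report$n_removed, 1L)
  expect_equal(f$report$fraction_removed, 0.2)

  low <- tukey_filter(c(-50, 10, 11, 12, 13, 14))
  expect_identical(low$keep, c(FALSE, rep(TRUE, 5)))
})

test_that("constant samples yield zero-width fences and no removals", {
  f <- tukey_filter(rep(2.5, 10))
  expect_true(all(f$keep))
  expect_equal(unname(f$report$fences), c(2.5, 2.5))
})

test_that("removal fraction on a large Gaussian sample matches the tail mass", {
  set.seed(21)
  x <- rnorm(1e5)
  f <- tukey_filter(x)
  # fences sit near +-2.698 SD; both tails carry ~0.698% of the mass
  p <- 2 * pnorm(-(qnorm(0.75) + 1.5 * 2 * qnorm(0.75)))
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(f$report$fraction_removed - p), 3 * se + 5e-4)
})

test_that("filtering is idempotent and translation-equivariant", {
  set.seed(8)
  for (i in 1:10) {
    x <- rexgauss(200, 2, 0.5, 0.8)
    f1 <- tukey_filter(x)
    f2 <- tukey_filter(x[f1$keep])
    # a second pass may trim a little more, but fences cannot widen
    expect_lte(f2$report$fences[["upper"]], f1$report$fences[["upper"]] + 1e-12)
    shift <- tukey_filter(x + 10)
    expect_identical(shift$keep, f1$keep)
    expect_equal(unname(shift$report$fences),
                 unname(f1$report$fences) + 10, tolerance = 1e-12)
  }
  expect_error(tukey_filter(c(1, 2, 3)), "at least 4")
})

test_that("trial filtering works per cell and reports the pooled fraction", {
  cfg <- simulation_config(n_participants_per_group = 4, rng_seed = 14)
  tr <- generate_behavioral_dataset(cfg)
  out <- filter_trials(tr)
  expect_lt(out$report$fraction_removed, 0.2)
  expect_equal(out$report$n_removed + nrow(out$trials), out$report$n_total)
  # per-cell fences: one row per retained participant x condition
  expect_equal(nrow(out$fences), length(unique(paste(tr$participant_id, tr$condition))))
  expect_true(all(out$trials$correct))  # correct_only default
  keep_all <- filter_trials(tr, correct_only = FALSE)
  expect_gte(keep_all$report$n_total, out$report$n_total)
})

test_that("SDT count reduction matches direct enumeration on a toy participant", {
  toy <- data.frame(
    participant_id = "p1", group = "I",
    condition = c(rep("angry_target", 4), rep("happy_target", 4),
                  rep("target_absent", 8)),
    target_present = c(rep(TRUE, 8), rep(FALSE, 8)),
    response = c("different", "different", "different", "same",
                 rep("different", 4),
                 "different", rep("same", 7)),
    rt = 1, correct = NA)
  cnt <- to_sdt_counts(toy)
  ang <- cnt[cnt$emotion == "angry", ]
  hap <- cnt[cnt$emotion == "happy", ]
  expect_equal(c(ang$n_hits, ang$n_signal), c(3, 4))
  expect_equal(c(hap$n_hits, hap$n_signal), c(4, 4))
  expect_equal(c(ang$n_false_alarms, ang$n_noise), c(1, 8))
  # noise counts shared between the emotion rows
  expect_equal(hap$n_false_alarms, ang$n_false_alarms)
  expect_equal(hap$n_noise, ang$n_noise)
})

test_that("degenerate response patterns reduce to the expected counts", {
  cfg <- simulation_config(n_participants_per_group = 2, rng_seed = 4)
  tr <- generate_behavioral_dataset(cfg)
  all_same <- tr; all_same$response <- "same"
  cnt <- to_sdt_counts(all_same)
  expect_true(all(cnt$n_hits == 0) && all(cnt$n_false_alarms == 0))
  perfect <- tr
  perfect$response <- ifelse(perfect$target_present, "different", "same")
  cnt2 <- to_sdt_counts(perfect)
  expect_identical(cnt2$n_hits, cnt2$n_signal)
  expect_true(all(cnt2$n_false_alarms == 0))
  no_absent <- tr[tr$condition != "target_absent", ]
  expect_error(to_sdt_counts(no_absent), "target-absent")
})

test_that("designed signal counts are preserved through the reduction", {
  cfg <- simulation_config(n_participants_per_group = 3,
                           n_trials_per_participant = 96, rng_seed = 6)
  tr <- generate_behavioral_dataset(cfg)
  cnt <- to_sdt_counts(tr)
  for (em in c("angry", "happy"))
    expect_equal(sum(cnt$n_signal[cnt$emotion == em]), 9 * 24)
})
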