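test_that("the same seed reproduces a trial bit-identically", {
  d <- tiny_design()
  t1 <- simulate_trial(d, null_effect_spec(), seed = 9)
  t2 <- simulate_trial(d, null_effect_spec(), seed = 9)
  expect_identical(t1$subjects, t2$subjects)
  expect_identical(t1$couplings, t2$couplings)
  expect_identical(t1$recordings$S01$baseline$rest$data,
                   t2$recordings$S01$baseline$rest$data)
  t3 <- simulate_trial(d, null_effect_spec(), seed = 10)
  expect_false(identical(t1$recordings$S01$baseline$rest$data,
                         t3$recordings$S01$baseline$rest$data))
})

test_that("arm-wise covariate means track the reference parameters", {
  # Monte-Carlo check of the generator against its own parameters:
  # 50 replicates x 12 subjects per arm, means within 2 standard errors
  d <- trial_design(n_per_arm = 12)
  ref <- reference_stats()$covariates
  acc <- NULL
  for (i in 1:50) {
    set.seed(400 + i)
    acc <- rbind(acc, capen:::simulate_subjects(d))
  }
  for (v in c("age", "education", "lesion_size", "onset_weeks")) {
    for (arm in c("tDCS", "control")) {
      r <- ref[ref$variable == v & ref$arm == arm, ]
      x <- acc[acc$arm == arm, v]
      expect_lt(abs(mean(x) - r$mean), 2 * r$sd / sqrt(length(x)),
                label = paste(v, arm, "mean deviation"))
    }
  }
  # speech scores stay inside their printed ranges
  rng <- c(counting = 10, imitation = 20, alphabet = 20, mono = 10, di = 10)
  for (st in names(rng)) {
    x <- c(acc[[paste0(st, "_baseline")]], acc[[paste0(st, "_post")]])
    expect_true(all(x >= 0 & x <= rng[st]))
  }
})

test_that("a zeroed effect specification programs identical arms", {
  eff <- null_effect_spec()
  m <- build_default_montage()
  for (cond in c("rest", "task")) for (tp in c("baseline", "post"))
    expect_identical(
      capen:::coupling_profile(eff, m, "tDCS", cond, tp),
      capen:::coupling_profile(eff, m, "control", cond, tp))
})

test_that("full coupling makes a pair's channels equal up to sensor noise", {
  d <- tiny_design(noise_sd = 0.02)
  rec <- simulate_recording(c("F3-F7" = 1), duration = 1, design = d, seed = 2)
  expect_gt(cor(rec$data[, "F3"], rec$data[, "F7"]), 0.99)
  rec0 <- simulate_recording(c("F3-F7" = 0), duration = 2, design = d, seed = 2)
  expect_lt(abs(cor(rec0$data[, "F3"], rec0$data[, "F7"])), 0.2)
})

test_that("uncoupled channels give maximal asynchrony", {
  # mean pairwise C-ApEn at zero coupling exceeds the coupled settings
  p <- capen_params(epoch_len = 500)
  d <- tiny_design()
  val <- function(cpl, i) {
    rec <- simulate_recording(c("F3-F7" = cpl), duration = 1, design = d,
                              seed = 7000 + i)
    cross_apen(rec$data[, "F3"], rec$data[, "F7"], p)$value
  }
  m0 <- mean(vapply(1:30, function(i) val(0, i), 0.0))
  m5 <- mean(vapply(1:30, function(i) val(0.5, i), 0.0))
  m9 <- mean(vapply(1:30, function(i) val(0.9, i), 0.0))
  expect_gt(m0, m5)
  expect_gt(m5, m9)
})

test_that("two equal-coupling pairs are statistically indistinguishable", {
  # mirror-symmetric pairs under a symmetric profile, 100 replicates
  p <- capen_params(epoch_len = 400)
  d <- tiny_design()
  cp <- c("T5-C3" = 0.3, "T6-C4" = 0.3)
  a <- b <- numeric(100)
  for (i in 1:100) {
    rec <- simulate_recording(cp, duration = 0.8, design = d, seed = 8000 + i)
    a[i] <- cross_apen(rec$data[, "T5"], rec$data[, "C3"], p)$value
    b[i] <- cross_apen(rec$data[, "T6"], rec$data[, "C4"], p)$value
  }
  expect_gt(t.test(a, b)$p.value, 0.01)
})

test_that("an infeasible coupling pattern names the offending channel", {
  d <- tiny_design()
  expect_error(
    simulate_recording(c("F3-F7" = 0.6, "F3-P3" = 0.6), duration = 0.5,
                       design = d, seed = 1),
    "F3.*F3-F7")
  expect_error(simulate_recording(c("F3-F7" = 1.2), duration = 0.5,
                                  design = d), "\\[0, 1\\]")
  expect_error(simulate_recording(c("F3-XX" = 0.5), duration = 0.5,
                                  design = d), "unknown pairs")
})
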