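test_that("comparisons route by normality and detect separation", {
  set.seed(2)
  a <- rnorm(12); b <- rnorm(12, 5)
  cmp <- route_and_compare(a, b)
  expect_equal(cmp$test_name, "independent t-test")
  expect_lt(cmp$p_value, 0.001)
  # identical paired samples: maximal p, zero effect
  x <- rnorm(12)
  cmp2 <- route_and_compare(x, x, paired = TRUE)
  expect_equal(cmp2$p_value, 1)
  expect_equal(cmp2$effect_size, 0)
  # clearly skewed data routes to the rank test
  set.seed(2)
  e1 <- rexp(20, 0.2); e2 <- rexp(20, 1)
  expect_lt(shapiro.test(e1)$p.value, 0.05)  # routing premise
  cmp3 <- route_and_compare(e1, e2)
  expect_equal(cmp3$test_name, "Mann-Whitney U test")
  cmp4 <- route_and_compare(e1, e2 + 100, paired = TRUE)
  expect_equal(cmp4$test_name, "Wilcoxon signed-rank test")
  expect_error(route_and_compare(1:2, 1:2), "at least 3")
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(8)
  a <- rexp(15); b <- rexp(15, 0.4)
  p1 <- route_and_compare(a, b)$p_value
  p2 <- route_and_compare(log(a), log(b))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("pooled-SD effect sizes reproduce the printed table cells", {
  expect_equal(cohens_d_pooled(5.63, 2.41, 1.21, 2.10), 1.955,
               tolerance = 5e-4)
  expect_equal(cohens_d_pooled(0.09, 0.10, 0.00, 0.06), 1.091,
               tolerance = 5e-4)
  expect_equal(cohens_d_pooled(3, 1, 3, 2), 0)
  expect_error(cohens_d_pooled(1, 0, 2, 0), "zero")
  expect_error(cohens_d_pooled(1, -1, 2, 1), "non-negative")
})

test_that("chi-square matches the published baseline comparisons", {
  expect_equal(chi_square(rbind(c(10, 2), c(9, 3)))$p_value, 0.615,
               tolerance = 5e-4)
  expect_equal(chi_square(rbind(c(2, 10), c(1, 11)))$p_value, 0.537,
               tolerance = 5e-4)
  sev <- chi_square(rbind(c(5, 5, 2), c(6, 4, 2)))
  expect_equal(sev$p_value, 0.904, tolerance = 5e-4)
  expect_equal(sev$df, 2)
  sym <- chi_square(rbind(c(6, 4, 2), c(6, 4, 2)))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "zero row")
  expect_error(chi_square(rbind(c(1.5, 2), c(1, 2))), "integers")
})

test_that("screening retains p < 0.2 candidates and models them with group", {
  set.seed(4)
  n <- 24
  g <- rep(0:1, each = 12)
  x1 <- rnorm(n)
  y <- 2 * x1  # exact linear relation, no noise
  res <- suppressWarnings(  # exact fit: lm warns about perfect residuals
    screen_then_model(y, data.frame(x1 = x1, x2 = rnorm(n)), group = g))
  u <- res$univariate
  expect_equal(u$r2[u$term == "x1"], 1, tolerance = 1e-10)
  expect_true("x1" %in% res$retained)
  expect_true("group" %in% res$multivariate$term)  # group always kept
  # standardized coefficient of the exact predictor is 1
  expect_equal(u$b[u$term == "x1"], 1, tolerance = 1e-10)
  # collinear retained predictors error with the culprit named
  x3 <- x1
  expect_error(
    suppressWarnings(screen_then_model(y, data.frame(x1 = x1, x3 = x3),
                                       group = g)),
    "collinear")
})

test_that("group effects dominate the regression screen when programmed", {
  # outcome driven by arm: the group term should beat noise candidates
  wins <- 0
  for (i in 1:40) {
    set.seed(600 + i)
    g <- rep(0:1, each = 12)
    y <- 1.2 * g + rnorm(24)
    cand <- data.frame(a = rnorm(24), b = rnorm(24), c = rnorm(24))
    res <- screen_then_model(y, cand, group = g)
    u <- res$univariate
    wins <- wins + (u$p[u$term == "group"] == min(u$p))
  }
  expect_gte(wins / 40, 0.6)
})

test_that("paired-design power matches the planning computation and limits", {
  expect_equal(paired_t_power(1.0, 11, 0.05), 0.924, tolerance = 5e-3)
  expect_equal(paired_t_power(1e-12, 11, 0.05), 0.05, tolerance = 1e-6)
  expect_equal(paired_t_power(1e-12, 11, 0.05, "two.sided"), 0.05,
               tolerance = 1e-6)
  # monotone in dz and n
  dz <- seq(0.2, 2, by = 0.2)
  expect_true(all(diff(vapply(dz, paired_t_power, 0.0, n = 11)) > 0))
  ns <- c(4, 8, 16, 32)
  expect_true(all(diff(vapply(ns, function(n)
    paired_t_power(0.8, n), 0.0)) > 0))
  expect_error(paired_t_power(-1, 11), "non-negative")
  expect_error(paired_t_power(1, 1), "n >= 2")
  expect_error(paired_t_power(1, 11, 1.5), "alpha")
})

test_that("two-sided paired power agrees with Monte-Carlo simulation", {
  pw <- paired_t_power(1.0, 30, 0.05, alternative = "two.sided")
  set.seed(99)
  hits <- 0; B <- 4000
  for (i in 1:B) {
    d <- rnorm(30, 1, 1)
    hits <- hits + (t.test(d)$p.value < 0.05)
  }
  expect_equal(pw, hits / B, tolerance = 0.02)
})

test_that("worked-example recomputation covers the printed summaries", {
  ex <- reference_worked_examples()
  es <- ex$effect_sizes
  pick <- function(tab, row, arm = NULL) {
    s <- es[es$table == tab & es$row == row, ]
    if (!is.null(arm)) s <- s[s$arm == arm, ]
    s$d
  }
  expect_equal(pick("speech_prepost", "mono", "tDCS"), 1.747, tolerance = 5e-4)
  expect_equal(pick("speech_change", "imitation"), 1.955, tolerance = 5e-4)
  expect_equal(pick("connectivity_prepost", "F3-F7", "tDCS"), 1.236,
               tolerance = 5e-4)
  expect_equal(pick("connectivity_change", "T5-P3"), 1.107, tolerance = 5e-4)
  expect_equal(ex$chi_square$p[ex$chi_square$variable == "sex"], 0.615,
               tolerance = 5e-4)
  expect_equal(ex$power, 0.924, tolerance = 5e-3)
})
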