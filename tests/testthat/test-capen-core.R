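test_that("standardization is an exact affine normalization", {
  z <- standardize_epoch(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_equal(standardize_epoch(z), z, tolerance = 1e-10)  # idempotent
  expect_error(standardize_epoch(rep(2, 50)), "degenerate")
})

test_that("delay embedding follows the definition", {
  expect_equal(delay_embed(1:4, 2, 1), rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(delay_embed(1:4, 1, 1), matrix(1:4, 4, 1))
  expect_equal(delay_embed(1:5, 2, 2), rbind(c(1, 3), c(2, 4), c(3, 5)))
  expect_error(delay_embed(1:3, 5, 1), "too short")
})

test_that("match_fraction counts Chebyshev neighbourhoods", {
  expect_equal(match_fraction(c(0, 0), rbind(c(0, 0), c(1, 1)), 0.5), 0.5)
  x <- matrix(runif(20, -1, 1), 10, 2)
  expect_equal(match_fraction(c(0, 0), x, 10), 1)   # saturation
  expect_equal(match_fraction(c(50, 50), x, 0.1), 0) # far template
  expect_error(match_fraction(c(0, 0), matrix(0, 0, 2), 0.5), "empty")
})

test_that("phi averages log match fractions, with zero-match floor", {
  expect_equal(phi_stat(rbind(c(0, 0)), rbind(c(0, 0)), 0.2)$phi, 0)
  tg <- rbind(c(0, 0), c(1, 1))
  expect_equal(phi_stat(rbind(c(0.5, 0.5)), tg, 0.6)$phi, 0)  # matches both
  expect_equal(phi_stat(rbind(c(0.1, 0.1)), tg, 0.5)$phi, log(0.5))
  # 5-template toy set against enumeration by hand
  set.seed(3)
  q5 <- matrix(rnorm(10), 5, 2); t5 <- matrix(rnorm(10), 5, 2)
  expect_equal(phi_stat(q5, t5, 0.8)$phi, oracle_phi(q5, t5, 0.8),
               tolerance = 1e-12)
  far <- rbind(c(100, 100))
  expect_error(phi_stat(far, tg, 0.1, floor = FALSE), "floor")
  res <- phi_stat(far, tg, 0.1, floor = TRUE)
  expect_equal(res$n_floored, 1L)
  expect_equal(res$phi, log(1 / 2))
})

test_that("cross_apen equals the brute-force enumeration oracle", {
  set.seed(11)
  for (k in 1:6) {
    N <- sample(100:300, 1)
    m <- sample(1:3, 1); lag <- sample(1:2, 1)
    u <- rnorm(N)
    v <- as.numeric(arima.sim(list(ar = 0.7), N))
    p <- capen_params(m = m, lag = lag, r_frac = runif(1, 0.2, 0.6),
                      epoch_len = 100)
    expect_equal(cross_apen(u, v, p)$value,
                 oracle_capen(u, v, m, lag, p$r_frac), tolerance = 1e-10)
  }
})

test_that("deterministic signals match the oracle exactly", {
  # logistic map
  x <- numeric(1000); x[1] <- 0.4
  for (i in 2:1000) x[i] <- 3.9 * x[i - 1] * (1 - x[i - 1])
  p <- capen_params(m = 2, r_frac = 0.2, epoch_len = 1000)
  expect_equal(apen(x, p)$value, oracle_capen(x, x, 2, 1, 0.2),
               tolerance = 1e-12)
  # alternating +1/-1 against its one-sample shift
  u <- rep(c(1, -1), 500)
  v <- c(u[-1], u[1])
  expect_equal(cross_apen(u, v, p)$value, oracle_capen(u, v, 2, 1, 0.2),
               tolerance = 1e-12)
  # strictly periodic period-2 series at m = 1
  p1 <- capen_params(m = 1, r_frac = 0.2, epoch_len = 200)
  w <- rep(c(2, 8), 100)
  expect_equal(apen(w, p1)$value, oracle_capen(w, w, 1, 1, 0.2),
               tolerance = 1e-12)
})

test_that("self-comparison, symmetry, scale invariance and determinism hold", {
  set.seed(21)
  p <- capen_params(epoch_len = 400)
  u <- rnorm(400); v <- rnorm(400)
  expect_identical(cross_apen(u, u, p)$value, apen(u, p)$value)
  expect_identical(cross_apen(u, v, p)$value, cross_apen(v, u, p)$value)
  expect_equal(cross_apen(3 * u + 5, 0.2 * v - 7, p)$value,
               cross_apen(u, v, p)$value, tolerance = 1e-10)
  expect_identical(cross_apen(u, v, p)$value, cross_apen(u, v, p)$value)
})

test_that("degenerate (constant) epochs return 0 with a flag, not an error", {
  p <- capen_params(epoch_len = 400)
  v <- rnorm(400)
  res <- cross_apen(rep(1, 400), v, p)
  expect_equal(res$value, 0)
  expect_true(res$degenerate)
  expect_false(res$floor_triggered)
  both <- cross_apen(rep(2, 400), rep(5, 400), p)
  expect_equal(both$value, 0)
  expect_error(cross_apen(rnorm(100), rnorm(101), p), "mismatch")
})

test_that("an AR(1) series is more asynchronous with white noise than with itself", {
  # cross-comparison against an unrelated series should exceed
  # self-comparison for a structured signal
  p <- capen_params(m = 2, r_frac = 0.2, epoch_len = 1000)
  wins <- 0
  for (i in 1:50) {
    set.seed(3000 + i)
    u <- as.numeric(arima.sim(list(ar = 0.8), 1000))
    v <- rnorm(1000)
    wins <- wins + (cross_apen(u, v, p)$value > apen(u, p)$value)
  }
  expect_gte(wins / 50, 0.95)
})
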