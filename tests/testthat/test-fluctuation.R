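# Lea-Coulson median estimator, MSS distribution, and rate estimation.

test_that("lea_coulson_m solves the median equation", {
  # at m = 1 the equation reads r = 1.24 exactly
  expect_equal(lea_coulson_m(1.24), 1, tolerance = 1e-9)
  # independent bisection oracle for r = 5
  f <- function(m) 5 / m - log(m) - 1.24
  lo <- 1e-6; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(lea_coulson_m(5), (lo + hi) / 2, tolerance = 1e-8)
  expect_equal(round(lea_coulson_m(5), 2), 2.38)
  # defined fallback at zero, domain error below
  expect_identical(lea_coulson_m(0), 0)
  expect_error(lea_coulson_m(-1), "non-negative")
  # residual of the defining equation is ~0 across magnitudes
  for (r in c(0.5, 1, 3, 17, 240)) {
    m <- lea_coulson_m(r)
    expect_lt(abs(r / m - log(m) - 1.24), 1e-7)
  }
})

test_that("lea_coulson_m is strictly increasing in the median", {
  r <- c(1.24, 1.5, 2, 3, 5, 10, 30, 100, 500)
  m <- vapply(r, lea_coulson_m, 0)
  expect_true(all(diff(m) > 0))
})

test_that("ld_pmf follows the MSS recursion and normalises", {
  p <- ld_pmf(1, 10)
  expect_equal(p[1], exp(-1))              # Poisson zero class
  expect_equal(p[2], exp(-1) / 2)          # one recursion step by hand
  expect_true(all(p >= 0 & p <= 1))
  # partial sums increase monotonically and stay below 1
  for (m in c(0.5, 1, 2, 5)) {
    p <- ld_pmf(m, 1e4)
    cs <- cumsum(p)
    expect_true(all(diff(cs) >= 0))
    expect_lte(cs[length(cs)], 1)
    expect_gt(cs[length(cs)], 0.99)        # tail beyond 1e4 is < 1e-2
  }
  expect_error(ld_pmf(0, 10), "positive")
  expect_error(ld_pmf(-2, 10), "positive")
})

test_that("mle_m maximises the MSS likelihood", {
  expect_warning(m0 <- mle_m(rep(0, 20)), "zero")
  expect_identical(m0, 0)
  # single observation: brute-force grid oracle
  grid <- seq(0.01, 20, by = 0.001)
  ll <- vapply(grid, function(m) log(ld_pmf(m, 3)[4]), 0)
  expect_equal(mle_m(3), grid[which.max(ll)], tolerance = 2e-3)
  # large-sample recovery at m = 2 from the MSS sampler itself
  set.seed(421)
  p <- ld_pmf(2, 5000)
  counts <- sample(0:5000, 1000, replace = TRUE, prob = p / sum(p))
  expect_gt(mle_m(counts), 1.8)
  expect_lt(mle_m(counts), 2.2)
})

test_that("estimate_rate implements the median method with rank CI", {
  cs <- culture_set(c(2, 0, 5, 1, 3, 0, 8, 2, 1), 1e8)
  est <- estimate_rate(cs, method = "median")
  expect_s3_class(est, "rate_estimate")
  expect_equal(est$m, lea_coulson_m(2))
  expect_equal(est$rate, est$m / 1e8)
  expect_lte(est$ci_low, est$rate)
  expect_gte(est$ci_high, est$rate)
  expect_identical(est$n_cultures, 9L)
  # doubling Nt halves the rate for the same counts
  est2 <- estimate_rate(culture_set(c(2, 0, 5, 1, 3, 0, 8, 2, 1), 2e8))
  expect_equal(est2$rate, est$rate / 2)
  # plating fraction rescales the effective Nt
  est3 <- estimate_rate(culture_set(c(2, 0, 5, 1, 3, 0, 8, 2, 1), 1e8,
                                    plating_fraction = 0.5))
  expect_equal(est3$rate, est$rate * 2)
  # even n: median is the mean of the two central order statistics
  est4 <- estimate_rate(culture_set(c(0, 1, 2, 7), 1e8))
  expect_equal(est4$m, lea_coulson_m(1.5))
})

test_that("estimate_rate falls back to P0 when the median is zero", {
  cs <- culture_set(rep(0, 9), 1e8)
  expect_message(est <- estimate_rate(cs, method = "median"), "P0")
  expect_identical(est$method, "p0")
  expect_identical(est$rate, 0)
  # p0 with some mutants: m = -log(fraction of zero cultures)
  cs2 <- culture_set(c(0, 0, 0, 1, 2, 0, 0, 9, 0), 1e8)
  est2 <- estimate_rate(cs2, method = "p0")
  expect_equal(est2$m, -log(6 / 9))
  # jackpot-only sets are unidentifiable
  expect_error(estimate_rate(culture_set(c(100, 100), 100)), "jackpot")
})

test_that("simulated cultures recover the true rate", {
  cs <- simulate_cultures(mu = 1e-7, nt = 1e8, n_cultures = 45, seed = 7)
  est <- estimate_rate(cs)
  expect_gt(est$rate, 0.5e-7)
  expect_lt(est$rate, 2e-7)
})

test_that("relative_rate reproduces the printed rounding convention", {
  expect_equal(relative_rate(74.3, 10.1), 7.4)
  expect_equal(relative_rate(2720, 12.9), 211)
  expect_equal(relative_rate(5, 5), 1)
  expect_equal(relative_rate(26, 74.3), 0.3)
  expect_equal(relative_rate(74.3, 10.1, round = FALSE), 74.3 / 10.1)
  expect_error(relative_rate(5, 0), "positive")
  # works on rate_estimate objects too
  e1 <- estimate_rate(culture_set(c(2, 3, 4), 1e8))
  expect_equal(relative_rate(e1, e1), 1)
})

test_that("ci_overlap implements the closed-interval convention", {
  expect_false(ci_overlap(c(3.9, 14.6), c(72.2, 95.2)))  # "different"
  expect_true(ci_overlap(c(1, 5), c(1, 5)))
  expect_true(ci_overlap(c(0, 1), c(1, 2)))  # shared endpoint = overlap
  expect_true(ci_overlap(c(1, 10), c(2, 3)))  # nesting
  expect_false(ci_overlap(c(1, 2), c(3, 4)))
  expect_error(ci_overlap(c(2, 1), c(0, 1)), "ordered")
})

test_that("median/MLE estimators agree on simulated culture sets", {
  # oracle cross-check: the two estimators are independent routes to m
  set.seed(88)
  ok <- 0L; total <- 0L
  for (m_true in c(0.5, 1, 2, 5)) {
    for (rep in 1:50) {
      cs <- simulate_cultures(mu = m_true / (1e8 - 1), nt = 1e8,
                              n_cultures = 45,
                              seed = sample.int(2^30, 1))
      est <- suppressMessages(estimate_rate(cs))
      m_med <- est$m
      m_mle <- suppressWarnings(mle_m(cs$mutant_counts))
      total <- total + 1L
      if (m_mle > 0 && abs(m_med / m_mle - 1) <= 0.3) ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("rate recovery: median of medians within 20% of truth", {
  set.seed(4711)
  rates <- vapply(1:100, function(i) {
    cs <- simulate_cultures(mu = 1e-7, nt = 1e8, n_cultures = 45,
                            seed = sample.int(2^30, 1))
    estimate_rate(cs)$rate
  }, 0)
  expect_lt(abs(stats::median(rates) / 1e-7 - 1), 0.2)
})

test_that("rank CI on the median covers the true rate at nominal-ish level", {
  set.seed(99)
  mu <- 1e-7
  hits <- vapply(1:500, function(i) {
    cs <- simulate_cultures(mu = mu, nt = 1e8, n_cultures = 25,
                            seed = sample.int(2^30, 1))
    est <- suppressMessages(estimate_rate(cs))
    est$ci_low <= mu && mu <= est$ci_high
  }, NA)
  expect_gte(mean(hits), 0.85)  # rank CI is approximate, not exact
})
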