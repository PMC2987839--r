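# Band intensities -> per-position termination probabilities.

test_that("termination_profile implements both direction conventions", {
  syn <- lane_profile(c(`10` = 50, `20` = 50), "synthesis")
  tp <- termination_profile(syn)
  expect_equal(tp$probabilities, c(0.5, 1))
  expect_equal(tp$positions, c(10L, 20L))
  # excision mirrors the formula: denominators run over n <= N
  exo <- lane_profile(c(`57` = 50, `46` = 50), "excision")
  te <- termination_profile(exo)
  expect_equal(te$probabilities[te$positions == 57], 0.5)
  expect_equal(te$probabilities[te$positions == 46], 1)
})

test_that("constant-hazard lanes give a flat profile (geometric identity)", {
  p <- 0.2
  n <- 1:200
  ints <- stats::setNames(p * (1 - p)^(n - 1), n)
  tp <- termination_profile(lane_profile(ints, "synthesis"))
  # away from the truncation point the truncated-geometric correction
  # (1 - p)^(201 - N) is negligible and the hazard is flat at p
  head_probs <- tp$probabilities[1:150]
  expect_true(all(abs(head_probs - p) < 1e-4))
})

test_that("runoff band feeds denominators but is not reported", {
  ln <- lane_profile(c(`10` = 20, `20` = 30, `30` = 50), "synthesis",
                     runoff_position = 30)
  tp <- termination_profile(ln)
  expect_identical(tp$positions, c(10L, 20L))
  expect_equal(tp$probabilities, c(20 / 100, 30 / 80))
  # without the runoff flag the same band is termination at 30
  tp2 <- termination_profile(lane_profile(c(`10` = 20, `20` = 30,
                                            `30` = 50), "synthesis"))
  expect_identical(tp2$positions, c(10L, 20L, 30L))
  expect_equal(tp2$probabilities[3], 1)
})

test_that("zero-denominator positions are omitted with a notice", {
  ln <- lane_profile(c(`5` = 0, `10` = 50, `20` = 50), "excision")
  expect_message(tp <- termination_profile(ln), "zero denominator")
  expect_identical(tp$positions, c(10L, 20L))
})

test_that("termination events conserve the lane's intensity fractions", {
  # P(stop exactly at N) = T(N) * prod_{earlier}(1 - T) must equal the raw
  # intensity fraction, exactly, in the noise-free case
  ints <- stats::setNames(c(10, 25, 5, 40, 20), c(3, 5, 8, 13, 21))
  ln <- lane_profile(ints, "synthesis")
  tp <- termination_profile(ln)
  surv <- cumprod(1 - tp$probabilities)
  stopped <- tp$probabilities * c(1, surv[-length(surv)])
  expect_equal(stopped, unname(ints / sum(ints)))
})

test_that("reversing positions maps excision onto synthesis", {
  ints <- c(10, 25, 5, 40, 20)
  pos <- c(3L, 5L, 8L, 13L, 21L)
  exo <- termination_profile(
    lane_profile(ints, "excision", positions = pos))
  mirrored <- termination_profile(
    lane_profile(ints, "synthesis", positions = max(pos) + 1L - pos))
  expect_equal(sort(exo$probabilities),
               sort(mirrored$probabilities))
})

test_that("simulate_lane round-trips exactly at zero noise", {
  truth <- stats::setNames(c(0.1, 0.3, 0.05, 0.6, 0.25), c(51, 54, 55, 60, 63))
  for (dir in c("synthesis", "excision")) {
    ln <- simulate_lane(truth, n_molecules = 1e4, noise_cv = 0,
                        direction = dir, seed = 1)
    tp <- termination_profile(ln)
    expect_equal(stats::setNames(tp$probabilities,
                                 tp$positions)[names(truth)],
                 truth, tolerance = 1e-12)
  }
})

test_that("noisy lanes recover the truth within noise-scaled error", {
  truth <- stats::setNames(rep(0.2, 30), 31:60)
  set.seed(5)
  errs <- vapply(1:20, function(i) {
    ln <- simulate_lane(truth, 1e5, noise_cv = 0.05,
                        direction = "synthesis",
                        seed = sample.int(2^30, 1))
    tp <- termination_profile(ln)
    max(abs(tp$probabilities[match(31:55, tp$positions)] - 0.2))
  }, 0)
  expect_lt(stats::median(errs), 3 * 0.05)
})

test_that("fold_change and mean_fold_change summarise enzyme pairs", {
  t1 <- structure(list(lane_id = "a", direction = "synthesis",
                       positions = 1:4,
                       probabilities = c(0.2, 0.2, 0.2, 0.2)),
                  class = "termination_profile")
  t2 <- structure(list(lane_id = "b", direction = "synthesis",
                       positions = 1:4,
                       probabilities = c(0.1, 0.1, 0.1, 0.1)),
                  class = "termination_profile")
  fc <- fold_change(t1, t2)
  expect_equal(unname(fc), rep(2, 4))
  expect_equal(unname(fold_change(t1, t1)), rep(1, 4))
  expect_equal(as.numeric(mean_fold_change(c(2, 8))), 4)  # geometric
  expect_equal(attr(mean_fold_change(c(2, 8)), "arithmetic"), 5)
  t3 <- structure(list(lane_id = "c", direction = "excision",
                       positions = 1:4, probabilities = rep(0.1, 4)),
                  class = "termination_profile")
  expect_error(fold_change(t1, t3), "direction")
  t4 <- structure(list(lane_id = "d", direction = "synthesis",
                       positions = 11:14, probabilities = rep(0.1, 4)),
                  class = "termination_profile")
  expect_error(fold_change(t1, t4), "shared")
})

test_that("geometric hazard-ratio pair lands in the stated fold range", {
  pos <- 41:80
  ta <- stats::setNames(rep(0.4, 40), pos)
  tb <- stats::setNames(rep(0.2, 40), pos)
  la <- simulate_lane(ta, 1e5, noise_cv = 0.05, direction = "synthesis",
                      seed = 31)
  lb <- simulate_lane(tb, 1e5, noise_cv = 0.05, direction = "synthesis",
                      seed = 32)
  fc <- fold_change(termination_profile(la), termination_profile(lb))
  mfc <- mean_fold_change(fc)
  expect_gt(as.numeric(mfc), 1.5)
  expect_lt(as.numeric(mfc), 3)
  # hazard ratio 2.5 averages between two and three
  tc <- stats::setNames(pmin(rep(0.2 * 2.5, 40), 1), pos)
  lc <- simulate_lane(tc, 1e5, noise_cv = 0.05, direction = "synthesis",
                      seed = 33)
  mfc2 <- mean_fold_change(fold_change(termination_profile(lc),
                                       termination_profile(lb)))
  expect_gt(as.numeric(mfc2), 2)
  expect_lt(as.numeric(mfc2), 3)
})
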