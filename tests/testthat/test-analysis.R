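test_that("percent correct aggregates per cell", {
  rec <- data.frame(participant = rep(1:2, each = 16),
                    session = "vision",
                    chose_near_optimal = c(rep(1, 12), rep(0, 4), rep(c(1, 0), 8)))
  pc <- percent_correct(rec)
  expect_equal(pc$percent_correct, c(75, 50))
  expect_equal(pc$n_trials, c(16, 16))
  rec$chose_near_optimal <- 1
  expect_equal(percent_correct(rec)$percent_correct, c(100, 100))
})

test_that("t-tests match closed forms and reject degenerate input", {
  r <- one_sample_t(c(60, 70, 80), 50)
  expect_equal(r$t, 20 / (10 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$mean_diff, 20)
  expect_error(one_sample_t(c(50, 50, 50)), "zero variance")
  expect_error(one_sample_t(55), "n >= 2")

  # paired: one-sample on differences; closed-form oracle on random data
  set.seed(4)
  for (rep in 1:10) {
    a <- rnorm(15, 60, 8); b <- rnorm(15, 55, 8)
    r <- paired_t(a, b)
    dbar <- mean(a - b); sdd <- sd(a - b)
    expect_equal(r$t, dbar / (sdd / sqrt(15)), tolerance = 1e-12)
    expect_equal(r$df, 14)
    expect_equal(r$p, 2 * pt(-abs(r$t), 14), tolerance = 1e-12)
  }
  expect_error(paired_t(1:3, 1:4), "length mismatch")
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "zero variance")

  # unpaired: pooled df is n1 + n2 - 2; Welch df is not larger
  a <- rnorm(12, 70, 10); b <- rnorm(15, 60, 15)
  expect_equal(unpaired_t(a, b, pooled = TRUE)$df, 25)
  expect_lte(unpaired_t(a, b)$df, 25)
})

test_that("bootstrap CI of the mean is seeded and matches the analytic interval", {
  expect_equal(bootstrap_ci(rep(7, 5)), c(7, 7))
  set.seed(100)
  x <- rnorm(1000)
  ci <- bootstrap_ci(x, reps = 5000, seed = 9)
  expect_identical(ci, bootstrap_ci(x, reps = 5000, seed = 9))
  analytic <- mean(x) + c(-1, 1) * 1.96 * sd(x) / sqrt(1000)
  expect_equal(ci, analytic, tolerance = 0.25)
  expect_lt(ci[1], mean(x)); expect_gt(ci[2], mean(x))
})

test_that("effect sizes are standardized mean differences", {
  expect_equal(effect_size(c(60, 70, 80), 50), 2)
  expect_equal(effect_size(c(45, 50, 55), 50), 0)
  a <- c(60, 72, 68); b <- c(55, 60, 70)
  expect_equal(effect_size_paired(a, b), -effect_size_paired(b, a))
  expect_error(effect_size(rep(50, 4), 50), "zero standard deviation")
})

test_that("HDI and ROPE match Gaussian quantile oracles on injected samples", {
  set.seed(2024)
  z <- rnorm(2e5)
  expect_equal(hdi(z, 0.95), c(-1.959964, 1.959964), tolerance = 0.03)
  expect_equal(rope_fraction(z, c(-0.4, 0.4)), pnorm(0.4) - pnorm(-0.4),
               tolerance = 0.01)
  # symmetric unimodal sample: HDI equals the central interval
  expect_equal(hdi(z, 0.95), unname(quantile(z, c(0.025, 0.975))), tolerance = 0.03)
  expect_equal(hdi(rep(0, 50)), c(0, 0))
  expect_equal(rope_fraction(rep(0, 50)), 1)
  # permutation invariance and bounds
  x <- runif(500, -1, 1)
  expect_equal(rope_fraction(x), rope_fraction(sample(x)))
  expect_true(rope_fraction(x) >= 0 && rope_fraction(x) <= 1)
  expect_error(rope_fraction(z, c(0.4, -0.4)), "ordered")
})

test_that("Bayesian estimation is consistent with the data at large n", {
  set.seed(8)
  y <- rnorm(300, 65, 10)
  be <- bayes_estimate(y, chance = 50, draws = 3000, burn = 1000, seed = 17)
  expect_lte(be$rhat, 1.1)
  mc_se <- sd(be$mu) / sqrt(100)  # generous: heavy autocorrelation
  expect_lt(abs(mean(be$mu) - (mean(y) - 50)), max(4 * sd(y) / sqrt(300), 40 * mc_se))
  # frequentist and Bayesian mean-difference estimates agree
  tt <- one_sample_t(y, 50)
  expect_equal(mean(be$mu), tt$mean_diff, tolerance = 0.15)
  # effect-size posterior centers near the sample effect size
  expect_equal(mean(be$effect_size), effect_size(y, 50), tolerance = 0.1)
  expect_true(be$hdi95[1] < mean(be$mu) && mean(be$mu) < be$hdi95[2])
  expect_true(be$rope_fraction >= 0 && be$rope_fraction <= 1)
  expect_error(bayes_estimate(rep(50, 5)), "nonzero variance")
})

test_that("paired and two-group Bayesian forms estimate the group difference", {
  set.seed(19)
  a <- rnorm(40, 75, 8); b <- rnorm(40, 65, 8)
  bp <- bayes_estimate(a, b = b, paired = TRUE, draws = 2000, burn = 500, seed = 3)
  expect_equal(mean(bp$mu), mean(a - b), tolerance = 1)
  bu <- bayes_estimate(a, b = b, paired = FALSE, draws = 2000, burn = 500, seed = 3)
  expect_equal(mean(bu$mu), mean(a) - mean(b), tolerance = 1.5)
  expect_lte(bu$rhat, 1.1)
})

test_that("replication-subset selection recovers the constructed object profiles", {
  # records built directly with known per-object/session accuracies:
  # objects A,B at chance in vision and strong in grasping; C above chance in
  # vision; D at chance in both
  set.seed(77)
  p_map <- list(A = c(vision = 0.5, grasping = 0.9),
                B = c(vision = 0.5, grasping = 0.85),
                C = c(vision = 0.8, grasping = 0.9),
                D = c(vision = 0.5, grasping = 0.5))
  rec <- do.call(rbind, lapply(names(p_map), function(o) {
    do.call(rbind, lapply(c("vision", "grasping"), function(s) {
      data.frame(participant = rep(1:25, each = 8), session = s, object = o,
                 chose_near_optimal = rbinom(200, 1, p_map[[o]][[s]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  sel <- select_replication_subset(rec, reps = 1000, seed = 5)
  expect_true(all(c("A", "B") %in% sel))
  expect_false("C" %in% sel)
  expect_false("D" %in% sel)
})

test_that("learning-trend statistics are null for stationary observers", {
  d <- stub_design(17, deltas = rep(0.6, 17))
  obs <- observer_model(sensitivity = c(vision = 1), lapse = 0, seed = 23)
  rec <- simulate_experiment(d, obs, 21, "vision")
  tr <- learning_trend(rec)
  expect_lt(abs(tr$mean_slope), 0.01)
  expect_gt(tr$p, 0.05)
  # a perfectly alternating sequence over an odd trial count has zero slope
  one <- data.frame(participant = 1, session = "vision", trial = 1:17,
                    chose_near_optimal = rep_len(c(1, 0), 17))
  expect_equal(learning_trend(one)$mean_slope, 0)
  expect_error(learning_trend(one[1, ]), "single-trial")
  expect_error(learning_trend(one[, -3]), "trial index")
})

test_that("the null rejection rate of the slope test is calibrated", {
  # under a stationary observer the slope test should rarely reject
  d <- stub_design(17, deltas = rep(0.6, 17))
  rejections <- vapply(1:30, function(s) {
    obs <- observer_model(sensitivity = c(vision = 1), lapse = 0, seed = 1000 + s)
    learning_trend(simulate_experiment(d, obs, 12, "vision"))$p < 0.05
  }, TRUE)
  expect_lte(mean(rejections), 0.1)
})
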