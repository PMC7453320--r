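test_that("power of the designed feasibility trial exceeds 80%", {
  pw <- power_two_proportions(0.40, 0.20, alpha = 0.2, n_total = 72,
                              dropout = 0.10)
  expect_gte(pw, 0.80)
  expect_equal(pw, 0.8310641, tolerance = 1e-6)  # frozen closed-form value
})

test_that("equal proportions give power equal to alpha (null case)", {
  expect_equal(power_two_proportions(0.3, 0.3, alpha = 0.2, n_total = 100),
               0.2, tolerance = 1e-12)
  expect_equal(power_two_proportions(0.3, 0.3, alpha = 0.05, n_total = 50),
               0.05, tolerance = 1e-12)
})

test_that("power is monotone in sample size and effect size", {
  ns <- seq(20, 200, by = 20)
  pws <- vapply(ns, function(n) power_two_proportions(0.4, 0.2, 0.2, n),
                numeric(1))
  expect_true(all(diff(pws) > 0))
  p2s <- seq(0.35, 0.05, by = -0.05)
  pwe <- vapply(p2s, function(p2) power_two_proportions(0.4, p2, 0.2, 72),
                numeric(1))
  expect_true(all(diff(pwe) > 0))
})

test_that("sample size is the smallest even n reaching the target power", {
  n <- sample_size_two_proportions(0.40, 0.20, alpha = 0.2,
                                   target_power = 0.80, dropout = 0.10)
  expect_gte(power_two_proportions(0.40, 0.20, 0.2, n, 0.10), 0.80)
  expect_lt(power_two_proportions(0.40, 0.20, 0.2, n - 2, 0.10), 0.80)
  expect_equal(n %% 2, 0)

  # near-alpha target needs very little data; doubling the effect shrinks n
  tiny <- sample_size_two_proportions(0.4, 0.2, 0.2, 0.21)
  expect_lte(tiny, 8)
  n_small_eff <- sample_size_two_proportions(0.4, 0.3, 0.2, 0.8)
  n_big_eff <- sample_size_two_proportions(0.4, 0.2, 0.2, 0.8)
  expect_lt(n_big_eff, n_small_eff)

  expect_error(sample_size_two_proportions(0.3, 0.3, 0.2, 0.8), "differ")
  expect_error(sample_size_two_proportions(0.4, 0.2, 0.2, 1), "below 1")
})

test_that("ANCOVA recovers exact effects in noise-free designs", {
  # followup identical to baseline: zero difference, p = 1
  rec <- data.frame(group = rep(c("active", "control"), each = 6),
                    site = rep(c("A", "B"), 6),
                    baseline = rep(c(10, 12, 14), 4))
  rec$followup <- rec$baseline
  fit <- ews_ancova(rec)
  expect_equal(fit$adjusted_mean_difference, 0, tolerance = 1e-10)
  expect_equal(fit$p_two_tailed, 1, tolerance = 1e-10)

  # constant +delta on the active arm is recovered exactly
  rec2 <- rec
  rec2$followup <- rec2$baseline + 2.5 * (rec2$group == "active")
  fit2 <- ews_ancova(rec2)
  expect_equal(fit2$adjusted_mean_difference, 2.5, tolerance = 1e-10)
})

test_that("ANCOVA matches a normal-equations oracle on a noisy fixture", {
  set.seed(404)
  rec <- simulate_endpoint_trial(12, effect = -2)
  fit <- ews_ancova(rec)
  # independent oracle: solve the normal equations directly
  X <- cbind(1, as.numeric(rec$group == "active"), rec$baseline,
             as.numeric(rec$site == "siteB"))
  beta <- solve(t(X) %*% X, t(X) %*% rec$followup)
  expect_equal(fit$adjusted_mean_difference, beta[2, 1], tolerance = 1e-10)
  # and the t-based p agrees with R's reference implementation
  ref <- stats::lm(followup ~ group + site + baseline, data = rec)
  sm <- summary(ref)$coefficients
  expect_equal(fit$p_two_tailed, sm["groupcontrol", "Pr(>|t|)"],
               tolerance = 1e-10)
  expect_equal(fit$se, sm["groupcontrol", "Std. Error"], tolerance = 1e-10)
})

test_that("one-tailed p halves the two-tailed p only in the hypothesized direction", {
  set.seed(7)
  rec <- simulate_endpoint_trial(40, effect = -3)
  fit <- ews_ancova(rec, direction = "less")
  if (fit$adjusted_mean_difference < 0) {
    expect_equal(fit$p_one_tailed, fit$p_two_tailed / 2)
  }
  flipped <- ews_ancova(rec, direction = "greater")
  expect_equal(flipped$p_one_tailed, 1 - fit$p_two_tailed / 2,
               tolerance = 1e-12)
})

test_that("degenerate designs are handled: one site warns, confounding errors", {
  set.seed(12)
  rec <- simulate_endpoint_trial(20, effect = 0)
  rec$site <- "only"
  expect_warning(fit <- ews_ancova(rec), "one site")
  expect_true(is.finite(fit$adjusted_mean_difference))

  conf <- simulate_endpoint_trial(20, effect = 0)
  conf$site <- ifelse(conf$group == "active", "A", "B")
  expect_error(ews_ancova(conf), "confounded")

  short <- simulate_endpoint_trial(20, effect = 0)
  short$group <- c("active", rep("control", 19))
  expect_error(ews_ancova(short), "2 analyzable")
})

test_that("listwise deletion drops and counts incomplete records", {
  set.seed(3)
  rec <- simulate_endpoint_trial(30, effect = 0)
  rec$followup[c(2, 5)] <- NA
  fit <- ews_ancova(rec)
  expect_equal(fit$n_dropped, 2)
  expect_equal(fit$n_used, 28)
})

test_that("CI brackets the estimate and recovery holds on average", {
  set.seed(2024)
  est <- se <- numeric(200)
  for (i in 1:200) {
    rec <- simulate_endpoint_trial(72, effect = -3)
    f <- ews_ancova(rec)
    est[i] <- f$adjusted_mean_difference
    expect_lte(f$ci_low, f$adjusted_mean_difference)
    expect_gte(f$ci_high, f$adjusted_mean_difference)
  }
  mc_se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) + 3), 3 * mc_se)
})
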