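test_that("the noiseless event-free limit gives constant scores and no alerts", {
  cfg <- trajectory_config(n_participants = 2, n_days = 10,
                           innovation_sd = 0, relapse_rate = 0, p_resp = 1,
                           mu = 2, seed = 5)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$events), 0)
  prof <- ews_profile("x", stats::setNames(rep(3L, 12),
                                           default_catalogue()$item_id))
  for (s in sim$streams) {
    expect_true(all(s$prompts$status == "completed"))
    fit <- ews_monitor(s, prof)
    expect_true(all(fit$scores$score == 2))
    expect_equal(nrow(fit$alerts), 0)
  }
})

test_that("simulation is reproducible from the seed", {
  cfg <- trajectory_config(n_participants = 3, n_days = 21, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$events, b$events)
  for (i in seq_along(a$streams)) {
    expect_identical(a$streams[[i]]$prompts, b$streams[[i]]$prompts)
    expect_identical(a$streams[[i]]$responses, b$streams[[i]]$responses)
  }
  c <- simulate_cohort(trajectory_config(n_participants = 3, n_days = 21,
                                         seed = 100))
  expect_false(identical(a$streams[[1]]$responses, c$streams[[1]]$responses))
})

test_that("infeasible configurations are rejected", {
  expect_error(trajectory_config(rho = 1), "rho")
  expect_error(trajectory_config(p_resp = 0), "p_resp")
  expect_error(trajectory_config(prodrome_range = c(0, 5)), "prodrome_range")
  expect_error(trajectory_config(dysphoric_lead = 6), "lead")
})

test_that("empirical item means recover mu", {
  # exact recovery in the noiseless limit
  cfg0 <- trajectory_config(n_participants = 1, n_days = 10, prompts_per_day = 2,
                            innovation_sd = 0, relapse_rate = 0, p_resp = 1,
                            mu = 3, seed = 2)
  s0 <- simulate_cohort(cfg0)$streams[[1]]
  expect_true(all(s0$responses$rating == 3))

  # with noise: item means within 3 SE at ~2000 prompts
  cfg <- trajectory_config(n_participants = 4, n_days = 84, prompts_per_day = 3,
                           innovation_sd = 0.5, rho = 0.7, relapse_rate = 0,
                           p_resp = 1, mu = 3, seed = 8)
  sim <- simulate_cohort(cfg)
  r <- do.call(rbind, lapply(sim$streams, function(s) s$responses))
  r <- r[r$item_id == "anxious", ]  # a root item, never branch-skipped
  # SE of the mean of an AR(1) mean-reverting series, inflated for
  # autocorrelation: var * (1+rho)/(1-rho) / n (ratings are also rounded,
  # which only shrinks dispersion here)
  n <- nrow(r)
  sigma2 <- 0.5^2 / (1 - 0.7^2)
  se <- sqrt(sigma2 * (1 + 0.7) / (1 - 0.7) / n)
  expect_lt(abs(mean(r$rating) - 3), 3 * se + 0.05)  # 0.05 for rounding bias
})

test_that("empirical completion rate matches p_resp within 3 SE", {
  cfg <- trajectory_config(n_participants = 6, n_days = 84, prompts_per_day = 2,
                           relapse_rate = 0, p_resp = 0.7, seed = 21)
  sim <- simulate_cohort(cfg)
  status <- unlist(lapply(sim$streams, function(s) s$prompts$status))
  n <- length(status)
  phat <- mean(status == "completed")
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(phat - 0.7), 3 * se)
})

test_that("a large noiseless prodrome is always detected and dated correctly", {
  cfg <- trajectory_config(n_participants = 8, n_days = 42,
                           innovation_sd = 0, relapse_rate = 1.5, p_resp = 1,
                           psychotic_amplitude = 4, dysphoric_amplitude = 3,
                           seed = 17)
  sim <- simulate_cohort(cfg)
  expect_gt(nrow(sim$events), 0)
  expect_true(all(sim$events$prodrome_start < sim$events$relapse_day))
  len_days <- as.numeric(sim$events$relapse_day - sim$events$prodrome_start,
                         units = "days")
  expect_true(all(len_days >= 1 & len_days <= 5))

  prof <- ews_profile("x", stats::setNames(rep(3L, 12),
                                           default_catalogue()$item_id))
  alerts <- do.call(rbind, lapply(sim$streams, function(s) {
    p <- prof; p$participant_id <- s$participant_id
    ews_monitor(s, p)$alerts
  }))
  es <- episode_sensitivity(alerts, sim$events)
  expect_equal(es$sensitivity, 1)
})

test_that("scripted streams hit the target trajectory exactly", {
  prof <- ews_profile("p1", stats::setNames(c(3L, 2L, 1L, rep(0L, 9)),
                                            default_catalogue()$item_id))
  target <- c(2, 2, 2, 2.0, 2.9)
  st <- scripted_stream(target, prof)
  expect_length(validate_stream(st), 0)
  expect_equal(score_stream(st, prof)$score, target)
  fit <- ews_monitor(st, prof)
  expect_equal(nrow(fit$alerts), 1)
  expect_equal(fit$alerts$rule, "single_point")

  # constant trajectory: no alerts
  flat <- scripted_stream(rep(2, 6), prof)
  expect_equal(nrow(ews_monitor(flat, prof)$alerts), 0)

  # exactly 1.25B at two consecutive points: one two_consecutive alert
  thr <- scripted_stream(c(2, 2, 2, 2.5, 2.5), prof)
  a <- ews_monitor(thr, prof)$alerts
  expect_equal(nrow(a), 1)
  expect_equal(a$rule, "two_consecutive")

  expect_error(scripted_stream(c(2, 9), prof), "unreachable")
})
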