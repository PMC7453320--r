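# a 4-item flat-catalogue stream with given ratings per prompt (rows = prompts)
ratings_stream <- function(mat, times = daily_times(nrow(mat)),
                           status = rep("completed", nrow(mat))) {
  fc <- flat_catalogue(4)
  keep <- status != "missed"
  resp <- do.call(rbind, lapply(which(keep), function(i)
    data.frame(prompt_time = times[i], item_id = paste0("it", 1:4),
               rating = mat[i, ])))
  ema_stream("p1", fc, data.frame(prompt_time = times, status = status),
             resp, study_start = as.Date("2024-01-01"))
}

test_that("the composite score is the weighted sum of ratings", {
  st <- ratings_stream(matrix(c(4, 2, 6, 1), nrow = 1))
  sc <- score_stream(st, abc_profile())
  expect_equal(sc$score, 0.5 * 4 + 0.3 * 2 + 0.2 * 6)  # 3.8; it4 unweighted
})

test_that("all-minimum ratings score at the scale minimum and missed prompts score nothing", {
  st <- ratings_stream(matrix(1, nrow = 3, ncol = 4))
  expect_equal(score_stream(st, abc_profile())$score, rep(1, 3))

  st2 <- ratings_stream(matrix(1, nrow = 2, ncol = 4),
                        status = c("missed", "missed"))
  expect_equal(nrow(score_stream(st2, abc_profile())), 0)
})

test_that("branch-skipped children are imputed at the scale minimum", {
  cat12 <- default_catalogue()
  rel <- stats::setNames(rep(0L, 12), cat12$item_id)
  rel[c("voices", "voices_distress")] <- c(3L, 3L)
  prof <- ews_profile("p1", rel)   # each weighted 0.5
  roots <- cat12$item_id[is.na(cat12$branch_parent)]
  t1 <- daily_times(1)
  resp <- data.frame(prompt_time = t1,
                     item_id = roots,
                     rating = ifelse(roots == "voices", 1, 2))
  st <- ema_stream("p1", cat12,
                   data.frame(prompt_time = t1, status = "completed"),
                   resp, study_start = as.Date("2024-01-01"))
  # voices=1 so voices_distress is skipped -> imputed at 1: 0.5*1 + 0.5*1
  expect_equal(score_stream(st, prof)$score, 1)
})

test_that("a completed prompt missing a weighted root item is a scoring error", {
  st <- ratings_stream(matrix(c(2, 2, 2, 2), nrow = 1))
  st$responses <- st$responses[st$responses$item_id != "it1", ]
  expect_error(score_stream(st, abc_profile()), "it1")
})

test_that("the baseline is the mean score over the first days, calendar-windowed", {
  times <- daily_times(4, by_hours = 18)  # days 0,0,1,2
  sc <- make_scores(times, c(2, 2, 2, 2))
  expect_equal(compute_baseline(sc, 3, as.Date("2024-01-01")), 2)

  times2 <- c(daily_times(2, by_hours = 30), daily_times(2) + 10 * 86400)
  sc2 <- make_scores(times2, c(1, 3, 9, 9))
  expect_equal(compute_baseline(sc2, 3, as.Date("2024-01-01")), 2)

  sc3 <- make_scores(daily_times(2) + 5 * 86400, c(2, 2))
  expect_error(compute_baseline(sc3, 3, as.Date("2024-01-01")),
               "insufficient baseline")
})

test_that("the two alert rules fire per the 40% and 25% thresholds", {
  prof <- abc_profile()
  B <- 2.0
  # single-point: 2.9 >= 2.8
  a1 <- detect_alerts(make_scores(daily_times(2), c(2.0, 2.9)), B, prof)
  expect_equal(nrow(a1), 1)
  expect_equal(a1$rule, "single_point")
  expect_equal(a1$score, 2.9)
  expect_equal(a1$baseline, B)

  # two-consecutive: both 2.6 >= 2.5, neither >= 2.8 (6 h apart)
  a2 <- detect_alerts(make_scores(daily_times(2, by_hours = 6), c(2.6, 2.6)),
                      B, prof)
  expect_equal(nrow(a2), 1)
  expect_equal(a2$rule, "two_consecutive")

  # no rule satisfied
  a3 <- detect_alerts(make_scores(daily_times(3), c(2.6, 2.4, 2.6)), B, prof)
  expect_equal(nrow(a3), 0)

  # refractory: two qualifying points 1 h apart give one alert only
  a4 <- detect_alerts(make_scores(daily_times(2, by_hours = 1), c(2.9, 2.9)),
                      B, prof)
  expect_equal(nrow(a4), 1)
})

test_that("thresholds are attained at equality and gaps break consecutiveness", {
  prof <- abc_profile()
  B <- 2.0
  eq <- detect_alerts(make_scores(daily_times(1), 2.8), B, prof)
  expect_equal(eq$rule, "single_point")

  # two 1.25B points 30 h apart are not consecutive under the 24 h max gap
  far <- detect_alerts(make_scores(daily_times(2, by_hours = 30), c(2.5, 2.5)),
                       B, prof)
  expect_equal(nrow(far), 0)
  near <- detect_alerts(make_scores(daily_times(2, by_hours = 23), c(2.5, 2.5)),
                        B, prof)
  expect_equal(near$rule, "two_consecutive")
})

test_that("a nonpositive baseline is a configuration error", {
  expect_error(detect_alerts(make_scores(daily_times(1), 2), 0, abc_profile()),
               "baseline")
})

test_that("raising any single rating never decreases the score", {
  prof <- abc_profile()
  set.seed(42)
  for (rep in 1:20) {
    m <- matrix(sample(1:6, 4, replace = TRUE), nrow = 1)
    s0 <- score_stream(ratings_stream(m), prof)$score
    j <- sample(1:4, 1)
    m2 <- m; m2[1, j] <- m2[1, j] + 1
    s1 <- score_stream(ratings_stream(m2), prof)$score
    expect_gte(s1, s0)
  }
})

test_that("alerts are invariant to jointly rescaling scores and baseline", {
  prof <- abc_profile()
  set.seed(7)
  sc <- make_scores(daily_times(20), runif(20, 1.8, 3.2))
  a <- detect_alerts(sc, 2, prof, refractory_hours = 0)
  sc2 <- sc; sc2$score <- sc$score * 3.7
  a2 <- detect_alerts(sc2, 2 * 3.7, prof, refractory_hours = 0)
  expect_equal(a2$alert_time, a$alert_time)
  expect_equal(a2$rule, a$rule)
})

test_that("lowering thresholds never removes an alert (refractory disabled)", {
  set.seed(11)
  sc <- make_scores(daily_times(30, by_hours = 12), runif(30, 1.5, 3.5))
  hi <- ews_profile("p1", c(it1 = 3L), single_point_rise = 0.40,
                    consecutive_rise = 0.25)
  lo <- ews_profile("p1", c(it1 = 3L), single_point_rise = 0.30,
                    consecutive_rise = 0.15)
  a_hi <- detect_alerts(sc, 2, hi, refractory_hours = 0)
  a_lo <- detect_alerts(sc, 2, lo, refractory_hours = 0)
  expect_true(all(a_hi$alert_time %in% a_lo$alert_time))
})

test_that("detect_alerts matches the brute-force inequality oracle on random series", {
  prof <- abc_profile()
  set.seed(314)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    times <- as.POSIXct("2024-01-04", tz = "UTC") +
      cumsum(runif(n, 1, 30)) * 3600
    sc <- make_scores(times, runif(n, 1.0, 3.5))
    mine <- detect_alerts(sc, 2, prof, refractory_hours = 0)
    oracle <- brute_force_alerts(sc, 2)
    expect_equal(mine$alert_time, oracle$alert_time)
    expect_equal(mine$rule, oracle$rule)
  }
})

test_that("ews_monitor freezes the baseline and never alerts inside the baseline window", {
  prof <- abc_profile()
  # scores: flat 2.0 for 3 days, then a spike; the day-2 spike must not alert
  mat <- matrix(1, nrow = 6, ncol = 4)
  mat[, 1] <- c(3, 3, 7, 3, 3, 7)  # it1 weight 0.5
  st <- ratings_stream(mat, times = daily_times(6, by_hours = 12))
  fit <- ews_monitor(st, prof)
  # scores are 2,2,4,2,2 in the first 3 days (the day-2 spike included in the
  # baseline, not alerted on) and 4 on day 4
  expect_equal(fit$baseline, 2.4)
  expect_true(all(fit$alerts$alert_time >= as.POSIXct("2024-01-04", tz = "UTC")))
  expect_equal(nrow(fit$alerts), 1)
  expect_equal(fit$alerts$rule, "single_point")  # 4 >= 1.4 * 2.4
})
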