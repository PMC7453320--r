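#' Weighted EWS scores for a stream
#'
#' Computes the composite early-warning-sign score at each completed prompt:
#' the weighted sum of item ratings under the profile's tier weights. Since
#' the weights sum to 1 the score lives on the rating scale itself. Items the
#' branching rules skipped are imputed at the scale minimum (skipping encodes
#' symptom absence). Missed prompts yield no score; partial prompts are
#' excluded by default.
#'
#' @param stream an [ema_stream()].
#' @param profile an [ews_profile()].
#' @param include_partial score partial prompts too, imputing unanswered
#'   weighted items at the scale minimum (default `FALSE`).
#' @return data frame of class `ews_scores` with columns `prompt_time`
#'   (`POSIXct`) and `score`.
#' @export
score_stream <- function(stream, profile, include_partial = FALSE) {
  catalogue <- stream$catalogue
  sc <- attr(catalogue, "scale")
  w <- profile$weights
  unknown <- setdiff(names(w), catalogue$item_id)
  if (length(unknown) > 0L)
    stop("profile weights items absent from the catalogue: ",
         paste(unknown, collapse = ", "))
  statuses <- if (include_partial) c("completed", "partial") else "completed"
  keep <- stream$prompts$status %in% statuses
  times <- stream$prompts$prompt_time[keep]
  status <- stream$prompts$status[keep]
  r <- stream$responses
  scores <- numeric(length(times))
  for (i in seq_along(times)) {
    resp <- r[r$prompt_time == times[i], , drop = FALSE]
    ratings <- stats::setNames(resp$rating, resp$item_id)
    missing_items <- setdiff(names(w)[w > 0], names(ratings))
    if (length(missing_items) > 0L) {
      # branch-skipped children are imputed at the scale minimum; a missing
      # weighted ROOT item on a completed prompt has no imputation rule
      roots <- root_items(catalogue)
      bad <- intersect(missing_items, roots)
      if (length(bad) > 0L && status[i] == "completed")
        stop(sprintf("prompt at %s: completed prompt lacks rating for weighted item(s) %s",
                     format(times[i], tz = "UTC"), paste(bad, collapse = ", ")))
      imputed <- stats::setNames(rep(sc[1], length(missing_items)), missing_items)
      ratings <- c(ratings, imputed)
    }
    pos <- names(w)[w > 0]
    scores[i] <- sum(w[pos] * ratings[pos])
  }
  out <- data.frame(prompt_time = times, score = scores)
  class(out) <- c("ews_scores", "data.frame")
  out
}

#' Baseline EWS score
#'
#' The alerting baseline is the mean composite score over the first
#' `baseline_days` calendar days of recording, a fixed reference the alert
#' thresholds are expressed against.
#'
#' @param scores an `ews_scores` data frame from [score_stream()].
#' @param baseline_days length of the baseline window in days (default 3).
#' @param study_start `Date`, the first day of recording.
#' @return the baseline score (numeric scalar).
#' @export
compute_baseline <- function(scores, baseline_days = 3L, study_start) {
  t0 <- as.POSIXct(paste0(format(as.Date(study_start)), " 00:00:00"), tz = "UTC")
  t1 <- t0 + as.numeric(baseline_days) * 86400
  in_window <- scores$prompt_time >= t0 & scores$prompt_time < t1
  if (!any(in_window))
    stop(sprintf("insufficient baseline data: no completed scores in the first %g days",
                 as.numeric(baseline_days)))
  mean(scores$score[in_window])
}

#' Threshold alert detection
#'
#' Applies the two personalized alert rules to a time-ordered score series:
#' a `single_point` alert when a score reaches `(1 + single_point_rise)`
#' times the baseline (default 40% above), and a `two_consecutive` alert
#' when a score and the immediately preceding completed score -- no more
#' than `max_gap_hours` apart -- both reach `(1 + consecutive_rise)` times
#' the baseline (default 25% above). Thresholds are attained at equality.
#' When both rules fire at the same prompt the single-point rule is
#' recorded. After an alert fires, further alerts are suppressed for a
#' refractory period to avoid alert storms.
#'
#' @param scores an `ews_scores` data frame (time-ordered; baseline-window
#'   points should already be excluded, as [ews_monitor()] does).
#' @param baseline baseline score, must be positive.
#' @param profile an [ews_profile()] supplying the rise thresholds.
#' @param max_gap_hours maximum spacing for two prompts to count as
#'   consecutive (default 24).
#' @param refractory_hours suppression window after an alert (default 24;
#'   use 0 to disable).
#' @return data frame of class `ews_alerts` with columns `participant_id`,
#'   `alert_time`, `rule`, `score`, `baseline`.
#' @export
detect_alerts <- function(scores, baseline, profile,
                          max_gap_hours = 24, refractory_hours = 24) {
  if (!is.numeric(baseline) || baseline <= 0)
    stop("baseline must be positive (guaranteed when ratings >= 1 and weights sum to 1)")
  thr_single <- baseline * (1 + profile$single_point_rise)
  thr_consec <- baseline * (1 + profile$consecutive_rise)
  t <- as.numeric(scores$prompt_time)
  if (is.unsorted(t)) stop("scores must be time-ordered")
  s <- scores$score
  n <- length(s)
  idx <- integer(0); rule <- character(0)
  last_alert <- -Inf
  for (i in seq_len(n)) {
    fired <- NULL
    if (s[i] >= thr_single) {
      fired <- "single_point"
    } else if (i > 1L && s[i] >= thr_consec && s[i - 1L] >= thr_consec &&
               (t[i] - t[i - 1L]) <= max_gap_hours * 3600) {
      fired <- "two_consecutive"
    }
    if (!is.null(fired)) {
      if (t[i] > last_alert + refractory_hours * 3600) {
        idx <- c(idx, i); rule <- c(rule, fired)
        last_alert <- t[i]
      }
    }
  }
  out <- data.frame(
    participant_id = rep(profile$participant_id, length(idx)),
    alert_time = scores$prompt_time[idx],
    rule = rule,
    score = s[idx],
    baseline = rep(baseline, length(idx)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ews_alerts", "data.frame")
  out
}

#' Fit the EWS alerting model to an observation stream
#'
#' The one-stop monitor: scores the stream under the profile's tier weights,
#' estimates the baseline from the first `baseline_days` of recording, and
#' runs the alert rules on all post-baseline scores (baseline-window points
#' never trigger alerts; the baseline is frozen thereafter).
#'
#' @param stream an [ema_stream()].
#' @param profile an [ews_profile()].
#' @inheritParams detect_alerts
#' @inheritParams score_stream
#' @return An object of class `ews_monitor` with components `participant_id`,
#'   `scores`, `baseline`, `alerts`, `profile` and the alerting settings.
#'   Methods: `print`, `summary`, `plot`.
#' @export
#' @examples
#' cat12 <- default_catalogue()
#' prof <- ews_profile("p1", stats::setNames(c(3, 2, 1, rep(0, 9)),
#'                                           cat12$item_id))
#' sim <- simulate_cohort(trajectory_config(n_participants = 1, n_days = 14,
#'                                          seed = 42))
#' fit <- ews_monitor(sim$streams[[1]], prof)
#' fit
ews_monitor <- function(stream, profile, max_gap_hours = 24,
                        refractory_hours = 24, include_partial = FALSE) {
  scores <- score_stream(stream, profile, include_partial = include_partial)
  baseline <- compute_baseline(scores, profile$baseline_days, stream$study_start)
  t0 <- as.POSIXct(paste0(format(stream$study_start), " 00:00:00"), tz = "UTC")
  cutoff <- t0 + as.numeric(profile$baseline_days) * 86400
  post <- scores[scores$prompt_time >= cutoff, , drop = FALSE]
  alerts <- detect_alerts(post, baseline, profile,
                          max_gap_hours = max_gap_hours,
                          refractory_hours = refractory_hours)
  structure(list(participant_id = stream$participant_id,
                 scores = scores, baseline = baseline, alerts = alerts,
                 profile = profile,
                 settings = list(max_gap_hours = max_gap_hours,
                                 refractory_hours = refractory_hours,
                                 include_partial = include_partial)),
            class = "ews_monitor")
}

#' @export
print.ews_monitor <- function(x, ...) {
  cat(sprintf("EWS monitor: participant %s\n", x$participant_id))
  cat(sprintf("  %d scored prompts; baseline %.3f (first %d days)\n",
              nrow(x$scores), x$baseline, x$profile$baseline_days))
  cat(sprintf("  %d alert(s): %d single-point, %d two-consecutive\n",
              nrow(x$alerts), sum(x$alerts$rule == "single_point"),
              sum(x$alerts$rule == "two_consecutive")))
  invisible(x)
}

#' @export
summary.ews_monitor <- function(object, ...) {
  s <- object$scores$score
  out <- list(
    participant_id = object$participant_id,
    n_scores = length(s),
    baseline = object$baseline,
    score_range = range(s),
    threshold_single = object$baseline * (1 + object$profile$single_point_rise),
    threshold_consecutive = object$baseline * (1 + object$profile$consecutive_rise),
    n_alerts = nrow(object$alerts),
    alerts = object$alerts
  )
  class(out) <- "summary.ews_monitor"
  out
}

#' @export
print.summary.ews_monitor <- function(x, ...) {
  cat(sprintf("EWS monitor summary -- participant %s\n", x$participant_id))
  cat(sprintf("  scores: n = %d, range %.2f to %.2f\n",
              x$n_scores, x$score_range[1], x$score_range[2]))
  cat(sprintf("  baseline %.3f; single-point threshold %.3f; two-consecutive threshold %.3f\n",
              x$baseline, x$threshold_single, x$threshold_consecutive))
  if (x$n_alerts == 0) cat("  no alerts\n") else {
    cat(sprintf("  %d alert(s):\n", x$n_alerts))
    print(data.frame(time = format(x$alerts$alert_time, tz = "UTC"),
                     rule = x$alerts$rule,
                     score = round(x$alerts$score, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
#' @rdname ews_monitor
#' @param x an `ews_monitor` fit.
#' @param ... further arguments passed to [graphics::plot()].
plot.ews_monitor <- function(x, ...) {
  s <- x$scores
  thr1 <- x$baseline * (1 + x$profile$single_point_rise)
  thr2 <- x$baseline * (1 + x$profile$consecutive_rise)
  graphics::plot(s$prompt_time, s$score, type = "b", pch = 16, cex = 0.6,
                 xlab = "time", ylab = "EWS score",
                 ylim = range(c(s$score, thr1, x$baseline)),
                 main = sprintf("Participant %s", x$participant_id), ...)
  graphics::abline(h = x$baseline, lty = 1, col = "grey40")
  graphics::abline(h = thr2, lty = 3, col = "darkorange")
  graphics::abline(h = thr1, lty = 2, col = "firebrick")
  if (nrow(x$alerts) > 0)
    graphics::points(x$alerts$alert_time, x$alerts$score, pch = 8,
                     col = "firebrick", cex = 1.2)
  graphics::legend("topleft", bty = "n", cex = 0.8,
                   legend = c("baseline", "25% rise", "40% rise", "alert"),
                   lty = c(1, 3, 2, NA), pch = c(NA, NA, NA, 8),
                   col = c("grey40", "darkorange", "firebrick", "firebrick"))
  invisible(x)
}
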