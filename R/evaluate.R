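#' Score alerts against early-warning episodes
#'
#' Partitions each participant's observation span into consecutive windows
#' (default 7 days) and cross-tabulates them against alert output and
#' ground-truth (or chart-annotated) early-warning episodes. A window is
#' positive if it overlaps any episode -- an episode runs from prodrome onset
#' to relapse day, so alerts during the prodrome count as true positives,
#' which is the point of pre-relapse detection. A window counts as alerted
#' if at least one alert falls inside it.
#'
#' @param alerts an `ews_alerts` data frame (may be empty) with columns
#'   `participant_id`, `alert_time`.
#' @param episodes data frame with columns `participant_id`, `start`, `end`
#'   (`POSIXct`); [simulate_cohort()]'s `events` frame is accepted directly
#'   (its `prodrome_start`/`relapse_day` columns are used).
#' @param span data frame with one row per participant: `participant_id`,
#'   `start`, `end` (`POSIXct`), the monitored period to partition. Every
#'   participant monitored must appear here, including those with no alerts
#'   and no episodes (they contribute true negatives).
#' @param window_days evaluation window length (default 7).
#' @return An object of class `ews_evaluation`: list with `unit`, counts
#'   `tp`, `fp`, `fn`, `tn`, `n_windows`, `prevalence`, and rates
#'   `sensitivity`, `specificity`, `ppv` (a rate with a zero denominator is
#'   `NA`, never 0).
#' @export
evaluate_alerts <- function(alerts, episodes, span, window_days = 7) {
  if (!is.null(episodes) && nrow(episodes) > 0L &&
      all(c("prodrome_start", "relapse_day") %in% names(episodes))) {
    episodes <- data.frame(participant_id = episodes$participant_id,
                           start = episodes$prodrome_start,
                           end = episodes$relapse_day)
  }
  if (nrow(episodes) > 0L) {
    for (pid in unique(episodes$participant_id)) {
      e <- episodes[episodes$participant_id == pid, , drop = FALSE]
      if (any(e$start >= e$end))
        stop("episode with start >= end for participant ", pid)
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)]))
        stop("overlapping episode windows for participant ", pid)
    }
  }
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(span))) {
    pid <- span$participant_id[i]
    t0 <- as.numeric(span$start[i]); t1 <- as.numeric(span$end[i])
    edges <- seq(t0, t1, by = window_days * 86400)
    if (edges[length(edges)] < t1) edges <- c(edges, t1)
    ep <- episodes[episodes$participant_id == pid, , drop = FALSE]
    al_t <- as.numeric(alerts$alert_time[alerts$participant_id == pid])
    for (k in seq_len(length(edges) - 1L)) {
      w0 <- edges[k]; w1 <- edges[k + 1L]
      positive <- nrow(ep) > 0L &&
        any(as.numeric(ep$start) < w1 & as.numeric(ep$end) >= w0)
      alerted <- any(al_t >= w0 & al_t < w1)
      if (positive && alerted) tp <- tp + 1L
      else if (!positive && alerted) fp <- fp + 1L
      else if (positive && !alerted) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  n <- tp + fp + fn + tn
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(unit = "episode_window", window_days = window_days,
                 tp = tp, fp = fp, fn = fn, tn = tn, n_windows = n,
                 prevalence = rate(tp + fn, n),
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 ppv = rate(tp, tp + fp)),
            class = "ews_evaluation")
}

#' @export
print.ews_evaluation <- function(x, ...) {
  cat(sprintf("Alert evaluation (%g-day windows): %d windows, prevalence %.3f\n",
              x$window_days, x$n_windows, x$prevalence))
  cat(sprintf("  tp %d  fp %d  fn %d  tn %d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv)))
  invisible(x)
}

#' Episode-level sensitivity
#'
#' The alternative unit of analysis: the fraction of episodes with at least
#' one alert between `lead_margin_days` before prodrome onset and the
#' relapse day.
#'
#' @inheritParams evaluate_alerts
#' @param lead_margin_days tolerance before prodrome onset (default 0).
#' @return list with `n_episodes`, `n_detected`, `sensitivity` (`NA` when
#'   there are no episodes).
#' @export
episode_sensitivity <- function(alerts, episodes, lead_margin_days = 0) {
  if (!is.null(episodes) && nrow(episodes) > 0L &&
      all(c("prodrome_start", "relapse_day") %in% names(episodes))) {
    episodes <- data.frame(participant_id = episodes$participant_id,
                           start = episodes$prodrome_start,
                           end = episodes$relapse_day)
  }
  n_ep <- nrow(episodes)
  if (n_ep == 0L)
    return(list(n_episodes = 0L, n_detected = 0L, sensitivity = NA_real_))
  detected <- logical(n_ep)
  for (j in seq_len(n_ep)) {
    al <- alerts[alerts$participant_id == episodes$participant_id[j], , drop = FALSE]
    lo <- episodes$start[j] - lead_margin_days * 86400
    detected[j] <- nrow(al) > 0L &&
      any(al$alert_time >= lo & al$alert_time <= episodes$end[j])
  }
  list(n_episodes = n_ep, n_detected = sum(detected),
       sensitivity = mean(detected))
}

#' Positive predictive value from sensitivity, specificity and prevalence
#'
#' The Bayes identity linking the three reported alert-performance figures:
#' `ppv = sens * prev / (sens * prev + (1 - spec) * (1 - prev))`. Useful as
#' a consistency check on a reported (sensitivity, specificity, PPV) triple
#' given the episode prevalence.
#'
#' @param sensitivity,specificity,prevalence fractions in `[0, 1]`.
#' @return the implied PPV.
#' @export
#' @examples
#' ppv_from_rates(0.75, 0.08, 0.33)  # ~0.29
ppv_from_rates <- function(sensitivity, specificity, prevalence) {
  vals <- c(sensitivity, specificity, prevalence)
  if (any(vals < 0 | vals > 1)) stop("all inputs must be fractions in [0, 1]")
  num <- sensitivity * prevalence
  den <- num + (1 - specificity) * (1 - prevalence)
  if (den == 0) stop("undefined result: zero denominator (no predicted positives)")
  num / den
}
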