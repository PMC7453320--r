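#' Tiered relevance weights for the early-warning-sign score
#'
#' Each symptom item is assigned a relevance score 0--3 by the care
#' coordinator, encoding how strongly it featured in the participant's
#' historical relapse signature. The composite EWS score weights items so
#' that, collectively, relevance-1 items contribute 20% of the score,
#' relevance-2 items 30%, and relevance-3 items 50%; relevance-0 items are
#' rated but carry zero weight. Within a tier, items share the tier's
#' allocation equally. If a tier is unoccupied its share is redistributed
#' proportionally across the occupied tiers, so the weights always sum to 1.
#'
#' @param relevance named integer vector with values in `0:3` (names are
#'   item ids). At least one item must have relevance above 0.
#' @param tier_shares shares of the total score allocated to relevance tiers
#'   1, 2, 3 (must sum to 1).
#' @return named numeric weights vector on the same items, summing to 1.
#' @export
#' @examples
#' compute_weights(c(A = 3, B = 2, C = 1, D = 0))
#' # A 0.5, B 0.3, C 0.2, D 0
compute_weights <- function(relevance, tier_shares = c(`1` = 0.2, `2` = 0.3, `3` = 0.5)) {
  if (is.null(names(relevance)) || any(names(relevance) == ""))
    stop("relevance must be a named vector of item ids")
  if (!all(relevance %in% 0:3))
    stop("relevance scores must be integers in 0..3")
  if (length(tier_shares) != 3L || abs(sum(tier_shares) - 1) > 1e-12)
    stop("tier_shares must give shares for tiers 1, 2, 3 summing to 1")
  if (all(relevance == 0))
    stop("no monitorable items: every relevance score is 0")
  counts <- vapply(1:3, function(t) sum(relevance == t), numeric(1))
  occupied <- counts > 0
  shares <- as.numeric(tier_shares)
  total <- sum(shares[occupied])
  w <- stats::setNames(numeric(length(relevance)), names(relevance))
  for (t in which(occupied)) {
    w[relevance == t] <- (shares[t] / total) / counts[t]
  }
  w
}

#' Early-warning-sign personalization profile
#'
#' Bundles a participant's relevance map, the derived tier weights, and the
#' alerting parameters: the single-point rise threshold (default 40% above
#' baseline), the two-consecutive rise threshold (default 25% above baseline
#' at two successive completed prompts), and the baseline window (mean score
#' over the first 3 days of recording).
#'
#' @param participant_id character scalar.
#' @param relevance named integer vector in `0:3`; see [compute_weights()].
#' @param single_point_rise fractional rise over baseline that triggers a
#'   single-point alert (default 0.40).
#' @param consecutive_rise fractional rise over baseline that, sustained over
#'   two consecutive completed prompts, triggers an alert (default 0.25).
#' @param baseline_days calendar days of recording used for the baseline
#'   mean (default 3).
#' @param tier_shares see [compute_weights()].
#' @return An object of class `ews_profile`.
#' @export
ews_profile <- function(participant_id, relevance,
                        single_point_rise = 0.40, consecutive_rise = 0.25,
                        baseline_days = 3L,
                        tier_shares = c(`1` = 0.2, `2` = 0.3, `3` = 0.5)) {
  if (single_point_rise <= 0 || consecutive_rise <= 0)
    stop("rise thresholds must be positive fractions")
  if (baseline_days < 1L) stop("baseline_days must be at least 1")
  weights <- compute_weights(relevance, tier_shares)
  structure(list(participant_id = as.character(participant_id),
                 relevance = relevance,
                 tier_shares = tier_shares,
                 weights = weights,
                 single_point_rise = single_point_rise,
                 consecutive_rise = consecutive_rise,
                 baseline_days = as.integer(baseline_days)),
            class = "ews_profile")
}

#' @export
print.ews_profile <- function(x, ...) {
  cat(sprintf("EWS profile for participant %s\n", x$participant_id))
  cat(sprintf("  %d weighted items (of %d rated); baseline window %d days\n",
              sum(x$weights > 0), length(x$relevance), x$baseline_days))
  cat(sprintf("  alert rules: score >= %.0f%% above baseline at one prompt, or >= %.0f%% at two consecutive prompts\n",
              100 * x$single_point_rise, 100 * x$consecutive_rise))
  df <- data.frame(item = names(x$relevance), relevance = as.integer(x$relevance),
                   weight = round(unname(x$weights[names(x$relevance)]), 4))
  print(df[order(-df$relevance, df$item), ], row.names = FALSE)
  invisible(x)
}

#' @rdname ews_profile
#' @param path file path of a profile JSON with fields `participant_id`,
#'   `relevance` (object item -> 0..3), `thresholds`
#'   (`single_point_rise`, `consecutive_rise`) and `baseline_days`.
#' @export
read_profile_json <- function(path) {
  raw <- jsonlite::fromJSON(path)
  thr <- raw$thresholds
  ews_profile(
    participant_id = raw$participant_id,
    relevance = unlist(raw$relevance),
    single_point_rise = if (!is.null(thr$single_point_rise)) thr$single_point_rise else 0.40,
    consecutive_rise = if (!is.null(thr$consecutive_rise)) thr$consecutive_rise else 0.25,
    baseline_days = if (!is.null(raw$baseline_days)) raw$baseline_days else 3L
  )
}

#' @rdname ews_profile
#' @param profile an `ews_profile`.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(list(
    participant_id = profile$participant_id,
    relevance = as.list(profile$relevance),
    thresholds = list(single_point_rise = profile$single_point_rise,
                      consecutive_rise = profile$consecutive_rise),
    baseline_days = profile$baseline_days
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
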