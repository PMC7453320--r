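# shared fixtures: small catalogues, profiles, and an independent
# brute-force alert checker used as the oracle for detect_alerts

# n root items, no branching, alternating domains
flat_catalogue <- function(n = 4, scale = c(1L, 7L)) {
  ema_catalogue(data.frame(
    item_id = paste0("it", seq_len(n)),
    label = paste("item", seq_len(n)),
    domain_tag = rep(c("psychotic", "dysphoric"), length.out = n),
    branch_parent = NA_character_,
    stringsAsFactors = FALSE
  ), scale = scale)
}

# profile whose weights are exactly {0.5, 0.3, 0.2} on it1..it3 of a
# 4-item flat catalogue (it4 rated but unweighted)
abc_profile <- function(participant_id = "p1") {
  ews_profile(participant_id,
              c(it1 = 3L, it2 = 2L, it3 = 1L, it4 = 0L))
}

make_scores <- function(times, scores) {
  out <- data.frame(prompt_time = times, score = scores)
  class(out) <- c("ews_scores", "data.frame")
  out
}

daily_times <- function(n, start = "2024-01-01 12:00:00", by_hours = 24) {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * by_hours * 3600
}

# independent alert oracle: checks every point and every adjacent pair
# against the two inequalities directly; no refractory logic
brute_force_alerts <- function(scores, baseline, single_point_rise = 0.40,
                               consecutive_rise = 0.25, max_gap_hours = 24) {
  s <- scores$score
  t <- as.numeric(scores$prompt_time)
  rule <- rep(NA_character_, length(s))
  for (i in seq_along(s)) {
    if (s[i] >= baseline * (1 + single_point_rise)) {
      rule[i] <- "single_point"
    } else if (i > 1 &&
               s[i] >= baseline * (1 + consecutive_rise) &&
               s[i - 1] >= baseline * (1 + consecutive_rise) &&
               t[i] - t[i - 1] <= max_gap_hours * 3600) {
      rule[i] <- "two_consecutive"
    }
  }
  keep <- !is.na(rule)
  data.frame(alert_time = scores$prompt_time[keep], rule = rule[keep],
             score = s[keep], stringsAsFactors = FALSE)
}
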