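#' Per-participant adherence summary
#'
#' Adherence is judged at the prompt level: a prompt counts as responded to
#' when it was completed. Classes follow the feasibility thresholds used for
#' EMA monitoring: *acceptable* adherence means responding to more than a
#' third of issued prompts, *good* adherence more than half. Retention at
#' study end means at least one completed prompt in the final 7 days of the
#' study window.
#'
#' @param stream an [ema_stream()].
#' @param study_length_days length of the monitoring period in days
#'   (default 84, i.e. 12 weeks).
#' @return one-row data frame of class `adherence_summary` with columns
#'   `participant_id`, `prompts_issued`, `prompts_completed`,
#'   `response_rate`, `adherence_class` (`none`/`acceptable`/`good`) and
#'   `retained_at_end`.
#' @export
summarize_adherence <- function(stream, study_length_days = 84L) {
  issued <- nrow(stream$prompts)
  if (issued == 0L) stop("stream has zero issued prompts")
  completed <- sum(stream$prompts$status == "completed")
  rate <- completed / issued
  cls <- if (rate > 1 / 2) "good" else if (rate > 1 / 3) "acceptable" else "none"
  t0 <- as.POSIXct(paste0(format(stream$study_start), " 00:00:00"), tz = "UTC")
  wk_start <- t0 + (as.numeric(study_length_days) - 7) * 86400
  wk_end <- t0 + as.numeric(study_length_days) * 86400
  final_week <- stream$prompts$status == "completed" &
    stream$prompts$prompt_time >= wk_start & stream$prompts$prompt_time < wk_end
  out <- data.frame(participant_id = stream$participant_id,
                    prompts_issued = issued,
                    prompts_completed = completed,
                    response_rate = rate,
                    adherence_class = cls,
                    retained_at_end = any(final_week),
                    stringsAsFactors = FALSE)
  class(out) <- c("adherence_summary", "data.frame")
  out
}

#' Group-level adherence proportions
#'
#' @param summaries a list of [summarize_adherence()] results, or a single
#'   data frame of stacked rows.
#' @return list with `n`, `prop_acceptable` (rate > 1/3, includes good),
#'   `prop_good` (rate > 1/2), `prop_none`, and `prop_retained`.
#' @export
group_adherence <- function(summaries) {
  if (is.data.frame(summaries)) df <- summaries
  else df <- do.call(rbind, summaries)
  if (is.null(df) || nrow(df) == 0L) stop("no adherence summaries supplied")
  n <- nrow(df)
  list(n = n,
       prop_acceptable = mean(df$adherence_class %in% c("acceptable", "good")),
       prop_good = mean(df$adherence_class == "good"),
       prop_none = mean(df$adherence_class == "none"),
       prop_retained = mean(df$retained_at_end))
}
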