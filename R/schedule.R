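#' Semi-random EMA prompt schedule
#'
#' Generates prompt instants for an EMA study using stratified-uniform bins,
#' the standard experience-sampling compromise between unpredictability and
#' coverage: each day's prompting window is split into `prompts_per_day`
#' equal bins and one instant is drawn uniformly within each bin, subject to
#' a minimum same-day gap between consecutive prompts.
#'
#' @param n_days number of study days.
#' @param prompts_per_day prompts per day, 2 to 4.
#' @param window_start,window_end daily prompting window as clock hours
#'   (decimal, e.g. `9` and `21` for 09:00--21:00).
#' @param min_gap_hours minimum gap between consecutive same-day prompts.
#' @param start_date first study day (`Date` or coercible).
#' @param seed optional integer; if supplied the schedule is reproducible on
#'   its own, otherwise draws come from the current RNG stream.
#' @return `POSIXct` (UTC) vector of length `n_days * prompts_per_day`,
#'   strictly increasing.
#' @export
#' @examples
#' s <- generate_schedule(7, 2, seed = 1)
#' length(s)  # 14
generate_schedule <- function(n_days, prompts_per_day = 2L,
                              window_start = 9, window_end = 21,
                              min_gap_hours = 2, start_date = as.Date("2024-01-01"),
                              seed = NULL) {
  if (n_days < 1L) stop("n_days must be at least 1")
  if (prompts_per_day < 2L || prompts_per_day > 4L)
    stop("prompts_per_day must be between 2 and 4")
  if (window_end <= window_start)
    stop("window_end must be after window_start")
  len <- window_end - window_start
  bin_width <- len / prompts_per_day
  if (min_gap_hours > bin_width)
    stop(sprintf(
      "infeasible schedule: min gap %.2g h exceeds bin width %.2g h (window %.2g h / %d prompts)",
      min_gap_hours, bin_width, len, prompts_per_day))
  if (!is.null(seed)) set.seed(seed)
  start_date <- as.Date(start_date)
  day0 <- as.POSIXct(paste0(format(start_date), " 00:00:00"), tz = "UTC")
  out <- numeric(n_days * prompts_per_day)
  k <- 0L
  for (d in seq_len(n_days) - 1L) {
    prev <- -Inf
    for (b in seq_len(prompts_per_day)) {
      lo <- window_start + (b - 1L) * bin_width
      hi <- window_start + b * bin_width
      lo <- max(lo, prev + min_gap_hours)  # feasible because min_gap <= bin_width
      h <- stats::runif(1, lo, hi)
      prev <- h
      k <- k + 1L
      out[k] <- as.numeric(day0) + d * 86400 + h * 3600
    }
  }
  as.POSIXct(out, origin = "1970-01-01", tz = "UTC")
}
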