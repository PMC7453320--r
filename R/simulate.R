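#' Synthetic symptom-trajectory configuration
#'
#' Parameters of the cohort simulator. Each participant's latent item
#' severities follow an AR(1) process around per-item baseline means,
#' clipped to the ordinal scale and rounded at observation time. Relapse
#' prodromes are injected as additive linear ramps on the item means:
#' dysphoric items begin rising at prodrome onset, psychotic items after a
#' configurable lead, both peaking on the relapse day -- the classic
#' two-stage early-warning signature in which dysphoria precedes attenuated
#' psychotic symptoms by 1--5 days.
#'
#' @param n_participants cohort size.
#' @param n_days study length in days (default 84, i.e. 12 weeks).
#' @param prompts_per_day prompts per day, 2--4 (default 2).
#' @param catalogue an [ema_catalogue()] (default [default_catalogue()]).
#' @param mu per-item latent baseline means: scalar or named vector on the
#'   catalogue items (default 2).
#' @param rho AR(1) autocorrelation between consecutive prompts, in `[0, 1)`.
#' @param innovation_sd AR(1) innovation standard deviation.
#' @param relapse_rate expected relapse events per participant over the
#'   study (Poisson; default 1).
#' @param prodrome_range integer range of prodrome lengths in days, within
#'   1--5.
#' @param dysphoric_lead days by which the dysphoric rise precedes the
#'   psychotic rise (default 1; must not exceed the longest prodrome).
#' @param psychotic_amplitude peak additive rise of affected psychotic item
#'   means at relapse day (default 3 scale points).
#' @param dysphoric_amplitude peak additive rise of affected dysphoric item
#'   means (default 2 scale points).
#' @param p_resp per-prompt completion probability in `(0, 1]` (default 0.7).
#' @param severity_missingness optional nonnegative coefficient linking the
#'   current latent mean severity to extra missingness (0 = missing
#'   completely at random, the default).
#' @param window_start,window_end,min_gap_hours prompting window, passed to
#'   [generate_schedule()].
#' @param start_date first study day.
#' @param seed integer master seed; all schedule, dynamics and missingness
#'   draws flow from it via per-participant substreams.
#' @return a `trajectory_config` list, validated.
#' @export
trajectory_config <- function(n_participants = 12L, n_days = 84L,
                              prompts_per_day = 2L,
                              catalogue = default_catalogue(),
                              mu = 2, rho = 0.7, innovation_sd = 0.5,
                              relapse_rate = 1, prodrome_range = c(1L, 5L),
                              dysphoric_lead = 1,
                              psychotic_amplitude = 3, dysphoric_amplitude = 2,
                              p_resp = 0.7, severity_missingness = 0,
                              window_start = 9, window_end = 21,
                              min_gap_hours = 2,
                              start_date = as.Date("2024-01-01"), seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (p_resp <= 0 || p_resp > 1) stop("p_resp must be in (0, 1]")
  if (prodrome_range[1] < 1 || prodrome_range[2] > 5 ||
      prodrome_range[1] > prodrome_range[2])
    stop("prodrome_range must lie within 1..5 days")
  if (dysphoric_lead > prodrome_range[2])
    stop("infeasible config: dysphoric lead exceeds the longest possible prodrome")
  if (length(mu) == 1L) mu <- stats::setNames(rep(mu, nrow(catalogue)),
                                              catalogue$item_id)
  miss <- setdiff(catalogue$item_id, names(mu))
  if (length(miss) > 0L) stop("mu missing items: ", paste(miss, collapse = ", "))
  sc <- attr(catalogue, "scale")
  if (any(mu < sc[1] | mu > sc[2])) stop("mu outside the rating scale")
  structure(list(n_participants = as.integer(n_participants),
                 n_days = as.integer(n_days),
                 prompts_per_day = as.integer(prompts_per_day),
                 catalogue = catalogue, mu = mu, rho = rho,
                 innovation_sd = innovation_sd, relapse_rate = relapse_rate,
                 prodrome_range = as.integer(prodrome_range),
                 dysphoric_lead = dysphoric_lead,
                 psychotic_amplitude = psychotic_amplitude,
                 dysphoric_amplitude = dysphoric_amplitude,
                 p_resp = p_resp, severity_missingness = severity_missingness,
                 window_start = window_start, window_end = window_end,
                 min_gap_hours = min_gap_hours,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "trajectory_config")
}

# draw non-overlapping relapse events for one participant
.draw_events <- function(config) {
  k <- stats::rpois(1, config$relapse_rate)
  if (k == 0L) return(NULL)
  # relapse days must leave room for the prodrome after the baseline week
  lo <- 8L
  hi <- config$n_days
  if (hi < lo) return(NULL)
  days <- integer(0)
  for (j in seq_len(k)) {
    cand <- sample(lo:hi, 1)
    # enforce >= 10-day spacing so prodromes never overlap
    if (all(abs(cand - days) >= 10)) days <- c(days, cand)
  }
  days <- sort(days)
  len <- sample(seq(config$prodrome_range[1], config$prodrome_range[2]),
                length(days), replace = TRUE)
  data.frame(relapse_day = days, prodrome_len = len)
}

# additive mean shift at time h (days since study start) for one event
.prodrome_lift <- function(h, relapse_day, prodrome_len, lead, amp_psy, amp_dys) {
  start <- relapse_day - prodrome_len
  dys <- 0; psy <- 0
  if (h >= start && h <= relapse_day) {
    dys <- amp_dys * (h - start) / prodrome_len
    psy_start <- start + min(lead, prodrome_len)
    if (h >= psy_start && relapse_day > psy_start)
      psy <- amp_psy * (h - psy_start) / (relapse_day - psy_start)
    else if (h >= psy_start)  # zero-length psychotic ramp: step at relapse
      psy <- amp_psy
  }
  c(dysphoric = dys, psychotic = psy)
}

#' Simulate a synthetic EMA cohort with ground-truth relapse events
#'
#' Generates one observation stream per participant under a
#' [trajectory_config()]: prompts from the semi-random scheduler, latent
#' AR(1) item severities with prodromal mean ramps, integer ratings clipped
#' to the scale, branch-skipping applied, and per-prompt missingness. The
#' ground-truth prodrome windows are returned alongside, so alert output can
#' be scored against known episodes.
#'
#' @param config a [trajectory_config()].
#' @return list with `streams` (list of [ema_stream()]) and `events`
#'   (data frame of class `relapse_events`: `participant_id`,
#'   `prodrome_start`, `relapse_day` as `POSIXct`, `items` as a
#'   semicolon-separated id list).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  catalogue <- config$catalogue
  sc <- attr(catalogue, "scale")
  items <- catalogue$item_id
  dys_items <- items[catalogue$domain_tag == "dysphoric"]
  psy_items <- items[catalogue$domain_tag == "psychotic"]
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_participants)
  t0 <- as.POSIXct(paste0(format(config$start_date), " 00:00:00"), tz = "UTC")
  streams <- vector("list", config$n_participants)
  events_list <- list()
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("sim%03d", p)
    set.seed(sub_seeds[p])
    times <- generate_schedule(config$n_days, config$prompts_per_day,
                               config$window_start, config$window_end,
                               config$min_gap_hours, config$start_date)
    ev <- .draw_events(config)
    n_t <- length(times)
    h_days <- as.numeric(times - t0, units = "days")
    # latent AR(1) per item around the (possibly prodrome-shifted) mean
    m <- matrix(rep(config$mu[items], each = n_t), nrow = n_t,
                dimnames = list(NULL, items))
    if (!is.null(ev)) {
      for (j in seq_len(nrow(ev))) {
        lift <- t(vapply(h_days, .prodrome_lift,
                         FUN.VALUE = c(dysphoric = 0, psychotic = 0),
                         relapse_day = ev$relapse_day[j],
                         prodrome_len = ev$prodrome_len[j],
                         lead = config$dysphoric_lead,
                         amp_psy = config$psychotic_amplitude,
                         amp_dys = config$dysphoric_amplitude))
        m[, dys_items] <- m[, dys_items] + lift[, "dysphoric"]
        m[, psy_items] <- m[, psy_items] + lift[, "psychotic"]
      }
    }
    x <- matrix(0, nrow = n_t, ncol = length(items),
                dimnames = list(NULL, items))
    eps <- matrix(stats::rnorm(n_t * length(items), 0, config$innovation_sd),
                  nrow = n_t)
    x[1, ] <- m[1, ] + eps[1, ]
    if (n_t > 1) for (i in 2:n_t)
      x[i, ] <- m[i, ] + config$rho * (x[i - 1, ] - m[i - 1, ]) + eps[i, ]
    ratings_full <- pmin(pmax(round(x), sc[1]), sc[2])
    # missingness: completely at random, optionally severity-linked
    p_miss_extra <- if (config$severity_missingness > 0)
      pmin(0.9, config$severity_missingness *
             pmax(0, rowMeans(m) - mean(config$mu))) else 0
    completed <- stats::runif(n_t) < config$p_resp * (1 - p_miss_extra)
    status <- ifelse(completed, "completed", "missed")
    resp_list <- list()
    for (i in which(completed)) {
      pres <- apply_branching(catalogue,
                              stats::setNames(ratings_full[i, ], items))$presented
      resp_list[[length(resp_list) + 1L]] <-
        data.frame(prompt_time = times[i], item_id = names(pres),
                   rating = as.numeric(pres))
    }
    responses <- if (length(resp_list) > 0) do.call(rbind, resp_list) else NULL
    streams[[p]] <- ema_stream(pid, catalogue,
                               data.frame(prompt_time = times, status = status),
                               responses, study_start = config$start_date)
    if (!is.null(ev)) {
      events_list[[length(events_list) + 1L]] <- data.frame(
        participant_id = pid,
        prodrome_start = t0 + (ev$relapse_day - ev$prodrome_len) * 86400,
        relapse_day = t0 + ev$relapse_day * 86400,
        items = paste(items, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events_list) > 0) do.call(rbind, events_list) else
    data.frame(participant_id = character(),
               prodrome_start = as.POSIXct(character(), tz = "UTC"),
               relapse_day = as.POSIXct(character(), tz = "UTC"),
               items = character(), stringsAsFactors = FALSE)
  rownames(events) <- NULL
  class(events) <- c("relapse_events", "data.frame")
  list(streams = streams, events = events)
}

#' Deterministic stream with a prescribed score trajectory
#'
#' Builds an observation stream whose composite EWS score under a given
#' profile equals a prescribed trajectory exactly, by inverting the weighting
#' for one designated item while holding every other item at the scale
#' minimum. Useful for engineering threshold-crossing scenarios with known
#' ground truth.
#'
#' @param target_scores numeric vector, the desired score at each prompt.
#' @param profile an [ews_profile()].
#' @param catalogue an [ema_catalogue()]; must contain every weighted item.
#' @param item id of the item whose rating absorbs the target (default: the
#'   highest-weight item).
#' @param times `POSIXct` prompt instants (default: daily at 12:00 UTC from
#'   `start_date`).
#' @param start_date used when `times` is not given.
#' @return an [ema_stream()] whose [score_stream()] output equals
#'   `target_scores`.
#' @export
scripted_stream <- function(target_scores, profile, catalogue = default_catalogue(),
                            item = NULL, times = NULL,
                            start_date = as.Date("2024-01-01")) {
  sc <- attr(catalogue, "scale")
  w <- profile$weights
  if (is.null(item)) item <- names(w)[which.max(w)]
  if (!item %in% names(w) || w[[item]] <= 0)
    stop("designated item must carry positive weight")
  # guard: adjusting item must be presentable (a root, or parent always above threshold)
  if (!item %in% root_items(catalogue))
    stop("designated item must be a root item so it is always presented")
  n <- length(target_scores)
  if (is.null(times))
    times <- as.POSIXct(paste0(format(start_date), " 12:00:00"), tz = "UTC") +
      (seq_len(n) - 1) * 86400
  base <- sum(w) * sc[1]  # score with all items at minimum
  r_item <- sc[1] + (target_scores - base) / w[[item]]
  if (any(r_item < sc[1] - 1e-9 | r_item > sc[2] + 1e-9))
    stop(sprintf("unreachable target score: needed rating outside [%g, %g] on item '%s'",
                 sc[1], sc[2], item))
  resp <- do.call(rbind, lapply(seq_len(n), function(i) {
    full <- stats::setNames(rep(sc[1], nrow(catalogue)), catalogue$item_id)
    full[item] <- r_item[i]
    pres <- apply_branching(catalogue, full)$presented
    data.frame(prompt_time = times[i], item_id = names(pres),
               rating = as.numeric(pres))
  }))
  ema_stream(profile$participant_id, catalogue,
             data.frame(prompt_time = times,
                        status = rep("completed", n)),
             resp, study_start = start_date)
}
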