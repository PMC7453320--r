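#' Read and write response-stream CSV files
#'
#' The long-format stream dialect: comma-separated, UTF-8, header required,
#' columns `participant_id`, `prompt_time` (ISO-8601 UTC), `prompt_status`,
#' `item_id`, `rating`. A completed or partial prompt contributes one row
#' per answered item; a missed prompt appears as a single row with empty
#' `item_id` and `rating`. Streams are grouped by participant and sorted in
#' time, and validated on read.
#'
#' @param path CSV file path.
#' @param catalogue an [ema_catalogue()] the streams refer to.
#' @param study_start optional `Date`; defaults per participant to the date
#'   of their first prompt.
#' @return list of [ema_stream()] objects, one per participant, in order of
#'   first appearance.
#' @export
read_stream_csv <- function(path, catalogue = default_catalogue(),
                            study_start = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       prompt_time = "character",
                                       prompt_status = "character",
                                       item_id = "character",
                                       rating = "character"))
  need <- c("participant_id", "prompt_time", "prompt_status", "item_id", "rating")
  if (!all(need %in% names(df)))
    stop("stream CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  tt <- as.POSIXct(df$prompt_time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  bad <- which(is.na(tt))
  if (length(bad) > 0L)
    stop(sprintf("malformed timestamp '%s' at row %d", df$prompt_time[bad[1]],
                 bad[1] + 1L))  # +1 for the header line
  df$prompt_time <- tt
  has_item <- !is.na(df$item_id) & df$item_id != ""
  unknown <- has_item & !df$item_id %in% catalogue$item_id
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop(sprintf("unknown item '%s' at row %d", df$item_id[i], i + 1L))
  }
  rating <- suppressWarnings(as.numeric(df$rating))
  bad_rating <- has_item & is.na(rating)
  if (any(bad_rating)) {
    i <- which(bad_rating)[1]
    stop(sprintf("non-numeric rating '%s' at row %d", df$rating[i], i + 1L))
  }
  sc <- attr(catalogue, "scale")
  oob <- has_item & (rating < sc[1] | rating > sc[2])
  if (any(oob)) {
    i <- which(oob)[1]
    stop(sprintf("rating %g outside scale [%g, %g] at row %d",
                 rating[i], sc[1], sc[2], i + 1L))
  }
  key <- paste(df$participant_id, format(df$prompt_time, tz = "UTC"), df$item_id)
  if (anyDuplicated(key[has_item])) {
    i <- which(duplicated(key) & has_item)[1]
    stop(sprintf("duplicate (participant, prompt_time, item) at row %d", i + 1L))
  }
  df$rating <- rating
  lapply(unique(df$participant_id), function(pid) {
    d <- df[df$participant_id == pid, , drop = FALSE]
    prompts <- unique(d[, c("prompt_time", "prompt_status")])
    names(prompts) <- c("prompt_time", "status")
    resp <- d[!is.na(d$rating) & d$item_id != "",
              c("prompt_time", "item_id", "rating")]
    s <- ema_stream(pid, catalogue, prompts, resp, study_start = study_start)
    v <- validate_stream(s)
    if (length(v) > 0L)
      warning(sprintf("stream for %s has %d validation issue(s); first: %s",
                      pid, length(v), v[1]))
    s
  })
}

#' @rdname read_stream_csv
#' @param streams a list of [ema_stream()] objects (or a single one).
#' @export
write_stream_csv <- function(streams, path) {
  if (inherits(streams, "ema_stream")) streams <- list(streams)
  rows <- lapply(streams, function(s) {
    p <- s$prompts
    r <- s$responses
    out <- lapply(seq_len(nrow(p)), function(i) {
      t_i <- p$prompt_time[i]
      resp <- r[r$prompt_time == t_i, , drop = FALSE]
      if (nrow(resp) == 0L) {
        data.frame(participant_id = s$participant_id,
                   prompt_time = .iso8601(t_i),
                   prompt_status = p$status[i],
                   item_id = "", rating = "", stringsAsFactors = FALSE)
      } else {
        data.frame(participant_id = s$participant_id,
                   prompt_time = .iso8601(t_i),
                   prompt_status = p$status[i],
                   item_id = resp$item_id,
                   rating = .num_str(resp$rating), stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, out)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
.num_str <- function(x) {
  s <- format(x, trim = TRUE, scientific = FALSE, digits = 15)
  ifelse(grepl("\\.", s), sub("\\.?0+$", "", s), s)
}

#' Read and write alert-log CSV files
#'
#' Columns: `participant_id`, `alert_time` (ISO-8601 UTC), `rule`, `score`,
#' `baseline`.
#'
#' @param alerts an `ews_alerts` data frame, or a list of `ews_monitor`
#'   fits whose alerts are stacked.
#' @param path CSV file path.
#' @export
write_alert_csv <- function(alerts, path) {
  if (is.list(alerts) && !is.data.frame(alerts))
    alerts <- do.call(rbind, lapply(alerts, function(m) m$alerts))
  df <- data.frame(participant_id = alerts$participant_id,
                   alert_time = .iso8601(alerts$alert_time),
                   rule = alerts$rule,
                   score = alerts$score,
                   baseline = alerts$baseline, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_alert_csv
#' @export
read_alert_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  df$alert_time <- as.POSIXct(df$alert_time, format = "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  class(df) <- c("ews_alerts", "data.frame")
  df
}

#' Read and write ground-truth relapse-event CSV files
#'
#' Columns: `participant_id`, `prodrome_start`, `relapse_day` (ISO-8601
#' UTC), `items` (semicolon-separated ids).
#'
#' @param events a `relapse_events` data frame from [simulate_cohort()].
#' @param path CSV file path.
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(participant_id = events$participant_id,
                   prodrome_start = .iso8601(events$prodrome_start),
                   relapse_day = .iso8601(events$relapse_day),
                   items = events$items, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  df$prodrome_start <- as.POSIXct(df$prodrome_start,
                                  format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df$relapse_day <- as.POSIXct(df$relapse_day,
                               format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  class(df) <- c("relapse_events", "data.frame")
  df
}

#' Run the full monitoring pipeline on a simulated cohort
#'
#' Executes simulate -> score -> alerts -> adherence -> evaluate and writes
#' every artifact to an output directory: the stream and ground-truth event
#' CSVs, the stacked alert log, per-participant adherence CSV with a group
#' JSON, and the evaluation report JSON. Fully deterministic under the
#' config's seed.
#'
#' @param config either a [trajectory_config()], a path to a JSON file of
#'   `trajectory_config` arguments, or a list of such arguments.
#' @param profile an [ews_profile()] applied to every participant, or
#'   `NULL` for a default profile weighting all psychotic items at
#'   relevance 3 and all dysphoric items at relevance 1.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress the per-stage log (default `FALSE`).
#' @return invisibly, a list with the artifact paths and the in-memory
#'   results (`streams`, `events`, `alerts`, `adherence`, `group`,
#'   `evaluation`).
#' @export
run_pipeline <- function(config, profile = NULL, out_dir = tempdir(),
                         quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  if (!inherits(config, "trajectory_config")) {
    if (!is.null(config$start_date)) config$start_date <- as.Date(config$start_date)
    config <- do.call(trajectory_config, config)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(profile)) {
    catal <- config$catalogue
    rel <- ifelse(catal$domain_tag == "psychotic", 3L, 1L)
    profile <- ews_profile("default", stats::setNames(rel, catal$item_id))
  }
  sim <- simulate_cohort(config)
  log("simulate: %d streams, %d relapse events", length(sim$streams),
      nrow(sim$events))
  paths <- list(streams = file.path(out_dir, "streams.csv"),
                events = file.path(out_dir, "events.csv"),
                alerts = file.path(out_dir, "alerts.csv"),
                adherence = file.path(out_dir, "adherence.csv"),
                group = file.path(out_dir, "adherence_group.json"),
                evaluation = file.path(out_dir, "evaluation.json"))
  write_stream_csv(sim$streams, paths$streams)
  write_events_csv(sim$events, paths$events)
  monitors <- lapply(sim$streams, function(s) {
    prof <- profile
    prof$participant_id <- s$participant_id
    tryCatch(ews_monitor(s, prof),
             error = function(e) NULL)  # e.g. empty baseline window
  })
  dropped <- sum(vapply(monitors, is.null, logical(1)))
  if (dropped > 0) log("score/alerts: %d stream(s) skipped (no baseline data)", dropped)
  monitors <- Filter(Negate(is.null), monitors)
  alerts <- if (length(monitors) > 0)
    do.call(rbind, c(lapply(monitors, function(m) m$alerts),
                     list(make.row.names = FALSE)))
  else
    structure(data.frame(participant_id = character(),
                         alert_time = as.POSIXct(character(), tz = "UTC"),
                         rule = character(), score = numeric(),
                         baseline = numeric()),
              class = c("ews_alerts", "data.frame"))
  log("alerts: %d fired across %d participants", nrow(alerts), length(monitors))
  write_alert_csv(alerts, paths$alerts)
  adher <- do.call(rbind, lapply(sim$streams, summarize_adherence,
                                 study_length_days = config$n_days))
  utils::write.csv(adher, paths$adherence, row.names = FALSE, quote = FALSE)
  grp <- group_adherence(adher)
  jsonlite::write_json(grp, paths$group, auto_unbox = TRUE, digits = NA)
  log("adherence: acceptable %.0f%%, good %.0f%%, retained %.0f%%",
      100 * grp$prop_acceptable, 100 * grp$prop_good, 100 * grp$prop_retained)
  t0 <- as.POSIXct(paste0(format(config$start_date), " 00:00:00"), tz = "UTC")
  span <- data.frame(
    participant_id = vapply(sim$streams, `[[`, character(1), "participant_id"),
    start = t0, end = t0 + config$n_days * 86400)
  ev <- evaluate_alerts(alerts, sim$events, span)
  jsonlite::write_json(ev[c("unit", "window_days", "tp", "fp", "fn", "tn",
                            "sensitivity", "specificity", "ppv")],
                       paths$evaluation, auto_unbox = TRUE, digits = NA,
                       na = "null")
  log("evaluate: tp %d fp %d fn %d tn %d", ev$tp, ev$fp, ev$fn, ev$tn)
  invisible(list(paths = paths, streams = sim$streams, events = sim$events,
                 alerts = alerts, adherence = adher, group = grp,
                 evaluation = ev))
}
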