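#' Observation streams
#'
#' An observation stream is one participant's raw EMA record: an ordered
#' sequence of prompts, each `completed`, `partial`, or `missed`, with the
#' item ratings given at each completed or partial prompt.
#'
#' @param participant_id character scalar.
#' @param catalogue an [ema_catalogue()].
#' @param prompts data frame with columns `prompt_time` (`POSIXct`, UTC) and
#'   `status` (one of `"completed"`, `"partial"`, `"missed"`).
#' @param responses data frame with columns `prompt_time`, `item_id`,
#'   `rating`; empty for streams with only missed prompts.
#' @param study_start `Date` of study day 1; defaults to the date of the
#'   first prompt.
#' @return An object of class `ema_stream`.
#' @export
ema_stream <- function(participant_id, catalogue, prompts, responses = NULL,
                       study_start = NULL) {
  prompts <- as.data.frame(prompts)
  if (!all(c("prompt_time", "status") %in% names(prompts)))
    stop("prompts needs columns prompt_time, status")
  if (is.null(responses) || nrow(as.data.frame(responses)) == 0L) {
    responses <- data.frame(prompt_time = as.POSIXct(character(), tz = "UTC"),
                            item_id = character(), rating = numeric())
  }
  responses <- as.data.frame(responses)
  prompts <- prompts[order(prompts$prompt_time), , drop = FALSE]
  responses <- responses[order(responses$prompt_time, responses$item_id), , drop = FALSE]
  rownames(prompts) <- NULL
  rownames(responses) <- NULL
  if (is.null(study_start)) {
    study_start <- if (nrow(prompts) > 0L)
      as.Date(min(prompts$prompt_time), tz = "UTC") else as.Date("2024-01-01")
  }
  structure(list(participant_id = as.character(participant_id),
                 catalogue = catalogue,
                 prompts = prompts,
                 responses = responses,
                 study_start = as.Date(study_start)),
            class = "ema_stream")
}

#' @export
print.ema_stream <- function(x, ...) {
  n <- nrow(x$prompts)
  nc <- sum(x$prompts$status == "completed")
  cat(sprintf("EMA stream for participant %s: %d prompts (%d completed, %d missed, %d partial) from %s\n",
              x$participant_id, n, nc, sum(x$prompts$status == "missed"),
              sum(x$prompts$status == "partial"), format(x$study_start)))
  invisible(x)
}

#' Validate an observation stream
#'
#' Checks the structural invariants of an [ema_stream()] and returns the
#' violations found; it never throws on content, so it can be used to triage
#' malformed field data. Rules checked: prompt times strictly increasing;
#' every response attached to a known prompt; responses only on catalogued
#' items; ratings within the scale bounds; missed prompts carry no responses;
#' completed prompts answer every item the branching rules present.
#'
#' @param stream an [ema_stream()].
#' @return character vector of violation messages, empty if the stream is
#'   well formed. Each message names the offending prompt.
#' @export
validate_stream <- function(stream) {
  v <- character(0)
  p <- stream$prompts
  r <- stream$responses
  catalogue <- stream$catalogue
  sc <- attr(catalogue, "scale")
  if (nrow(p) > 1L) {
    dt <- diff(as.numeric(p$prompt_time))
    for (i in which(dt <= 0))
      v <- c(v, sprintf("prompt %d: prompt_time not strictly after prompt %d",
                        i + 1L, i))
  }
  if (!all(p$status %in% c("completed", "partial", "missed")))
    v <- c(v, "unknown prompt status value(s)")
  if (nrow(r) > 0L) {
    bad_item <- !r$item_id %in% catalogue$item_id
    for (i in which(bad_item))
      v <- c(v, sprintf("prompt at %s: response on uncatalogued item '%s'",
                        format(r$prompt_time[i], tz = "UTC"), r$item_id[i]))
    out_of_range <- !is.na(r$rating) & (r$rating < sc[1] | r$rating > sc[2])
    for (i in which(out_of_range))
      v <- c(v, sprintf("prompt at %s: rating %g outside scale [%g, %g] on item '%s'",
                        format(r$prompt_time[i], tz = "UTC"), r$rating[i],
                        sc[1], sc[2], r$item_id[i]))
    orphan <- !r$prompt_time %in% p$prompt_time
    for (i in which(orphan))
      v <- c(v, sprintf("response at %s matches no prompt",
                        format(r$prompt_time[i], tz = "UTC")))
  }
  for (i in seq_len(nrow(p))) {
    t_i <- p$prompt_time[i]
    resp_i <- r[r$prompt_time == t_i & r$item_id %in% catalogue$item_id, , drop = FALSE]
    if (p$status[i] == "missed" && nrow(resp_i) > 0L)
      v <- c(v, sprintf("prompt %d (%s): missed prompt has responses",
                        i, format(t_i, tz = "UTC")))
    if (p$status[i] == "completed" && nrow(resp_i) > 0L) {
      ratings <- stats::setNames(resp_i$rating, resp_i$item_id)
      roots <- root_items(catalogue)
      if (all(roots %in% names(ratings))) {
        expected <- names(apply_branching(catalogue, ratings)$presented)
        miss <- setdiff(expected, names(ratings))
        if (length(miss) > 0L)
          v <- c(v, sprintf("prompt %d (%s): completed prompt missing presented item(s) %s",
                            i, format(t_i, tz = "UTC"), paste(miss, collapse = ", ")))
      } else {
        v <- c(v, sprintf("prompt %d (%s): completed prompt missing root item(s) %s",
                          i, format(t_i, tz = "UTC"),
                          paste(setdiff(roots, names(ratings)), collapse = ", ")))
      }
    }
    if (p$status[i] == "completed" && nrow(resp_i) == 0L)
      v <- c(v, sprintf("prompt %d (%s): completed prompt has no responses",
                        i, format(t_i, tz = "UTC")))
  }
  v
}
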