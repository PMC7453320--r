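#' Symptom-item catalogues
#'
#' A catalogue is the set of branching self-report items a participant is
#' prompted with. Each item has a short key, a human-readable label, a domain
#' tag (`"psychotic"` or `"dysphoric"`), and optionally a branch parent: a
#' child item is only presented when its parent's rating reaches the branch
#' threshold, mirroring branching questionnaires in which follow-up probes are
#' skipped when the stem symptom is absent.
#'
#' @param items data frame with columns `item_id`, `label`, `domain_tag`,
#'   `branch_parent` (NA for root items) and optionally `branch_threshold`
#'   (NA means one step above the scale minimum).
#' @param scale integer length-2 vector, the ordinal rating scale bounds.
#'   Defaults to 1--7, the item range of the clinician-rated instrument the
#'   self-report items were validated against.
#'
#' @return An object of class `ema_catalogue`: the item data frame with a
#'   `scale` attribute.
#' @export
#' @examples
#' cat12 <- default_catalogue()
#' nrow(cat12)            # 12 items
#' attr(cat12, "scale")   # 1 7
ema_catalogue <- function(items, scale = c(1L, 7L)) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  required <- c("item_id", "label", "domain_tag", "branch_parent")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0L)
    stop("catalogue is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"branch_threshold" %in% names(items))
    items$branch_threshold <- NA_real_
  if (anyDuplicated(items$item_id))
    stop("item_id values must be unique within a catalogue")
  if (!all(items$domain_tag %in% c("psychotic", "dysphoric")))
    stop("domain_tag must be 'psychotic' or 'dysphoric'")
  parents <- items$branch_parent
  known <- is.na(parents) | parents %in% items$item_id
  if (!all(known))
    stop("branch_parent refers to unknown item(s): ",
         paste(unique(parents[!known]), collapse = ", "))
  if (length(scale) != 2L || !is.numeric(scale) || scale[1] >= scale[2])
    stop("scale must be two increasing numbers")
  # default branch threshold: child presented only if parent rose above minimum
  items$branch_threshold <- ifelse(is.na(items$branch_threshold),
                                   scale[1] + 1, items$branch_threshold)
  .check_acyclic(items)
  structure(items, scale = as.numeric(scale),
            class = c("ema_catalogue", "data.frame"))
}

.check_acyclic <- function(items) {
  # follow parent chains; a cycle revisits a node before reaching a root
  idx <- match(items$branch_parent, items$item_id)
  for (i in seq_len(nrow(items))) {
    seen <- integer(0)
    j <- i
    while (!is.na(idx[j])) {
      if (j %in% seen) stop("branch graph contains a cycle at item ",
                            items$item_id[i])
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  invisible(TRUE)
}

#' @rdname ema_catalogue
#' @details `default_catalogue()` ships an illustrative 12-item catalogue
#'   (7 psychotic, 5 dysphoric, 3 of them branch children). The item set is a
#'   plausible stand-in constructed for simulation and testing; it is not a
#'   published instrument.
#' @export
default_catalogue <- function(scale = c(1L, 7L)) {
  ema_catalogue(data.frame(
    item_id = c("voices", "voices_distress", "suspicious", "persecution",
                "reference", "grandiosity", "thought_disorder",
                "anxious", "sad", "hopeless", "stressed", "sleep"),
    label = c("I have been hearing voices",
              "The voices have been distressing",
              "I have felt suspicious of other people",
              "I have felt that people intend me harm",
              "Things around me have carried special messages for me",
              "I have felt I have special powers",
              "My thoughts have been jumbled or racing",
              "I have felt anxious",
              "I have felt low in mood",
              "I have felt hopeless about the future",
              "I have felt stressed or under pressure",
              "I have slept badly"),
    domain_tag = c(rep("psychotic", 7), rep("dysphoric", 5)),
    branch_parent = c(NA, "voices", NA, "suspicious", NA, NA, NA,
                      NA, NA, "sad", NA, NA),
    stringsAsFactors = FALSE
  ), scale = scale)
}

#' @rdname ema_catalogue
#' @param path file path of a catalogue JSON: an array of objects with fields
#'   `item_id`, `label`, `domain_tag`, `branch_parent`, `branch_threshold`
#'   (the latter two may be null).
#' @export
read_catalogue_json <- function(path, scale = c(1L, 7L)) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!"branch_parent" %in% names(raw)) raw$branch_parent <- NA_character_
  ema_catalogue(raw, scale = scale)
}

#' @rdname ema_catalogue
#' @param catalogue an `ema_catalogue`.
#' @export
write_catalogue_json <- function(catalogue, path) {
  df <- as.data.frame(catalogue)[, c("item_id", "label", "domain_tag",
                                     "branch_parent", "branch_threshold")]
  jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.ema_catalogue <- function(x, ...) {
  sc <- attr(x, "scale")
  cat(sprintf("EMA item catalogue: %d items (%d psychotic, %d dysphoric), scale %g-%g\n",
              nrow(x), sum(x$domain_tag == "psychotic"),
              sum(x$domain_tag == "dysphoric"), sc[1], sc[2]))
  print.data.frame(x[, c("item_id", "domain_tag", "branch_parent")], row.names = FALSE)
  invisible(x)
}

root_items <- function(catalogue) catalogue$item_id[is.na(catalogue$branch_parent)]

#' Apply branching rules to a full ratings map
#'
#' Given ratings for every item, retain only those a branching questionnaire
#' would have presented: a child item is presented when its parent's rating is
#' at or above the branch threshold. Skipped children are reported as skipped,
#' never coerced to a minimum rating.
#'
#' @param catalogue an [ema_catalogue()].
#' @param ratings named numeric vector of ratings covering at least all root
#'   items (names are item ids).
#' @param strict if `TRUE`, a rating supplied for an item the branching rules
#'   would not have presented is a validation error (use when checking an
#'   observed response set); if `FALSE` (default), such ratings are dropped
#'   and the item reported as skipped (use when simulating presentation from
#'   a full latent ratings map).
#' @return list with `presented` (named numeric vector of retained ratings)
#'   and `skipped` (character vector of branch-skipped item ids).
#' @export
#' @examples
#' cat12 <- default_catalogue()
#' r <- stats::setNames(rep(1, nrow(cat12)), cat12$item_id)
#' apply_branching(cat12, r)$skipped  # all children skipped at scale minimum
apply_branching <- function(catalogue, ratings, strict = FALSE) {
  if (is.null(names(ratings)) || any(names(ratings) == ""))
    stop("ratings must be a named vector")
  unknown <- setdiff(names(ratings), catalogue$item_id)
  if (length(unknown) > 0L)
    stop("ratings on uncatalogued item(s): ", paste(unknown, collapse = ", "))
  roots <- root_items(catalogue)
  miss <- setdiff(roots, names(ratings))
  if (length(miss) > 0L)
    stop("ratings must cover all root items; missing: ",
         paste(miss, collapse = ", "))
  # items are resolved parent-before-child: repeat until no change (graph acyclic)
  status <- stats::setNames(rep(NA, nrow(catalogue)), catalogue$item_id)
  status[roots] <- TRUE
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(catalogue))) {
      id <- catalogue$item_id[i]
      if (!is.na(status[id])) next
      parent <- catalogue$branch_parent[i]
      if (is.na(status[parent])) next
      if (isTRUE(status[[parent]])) {
        pr <- ratings[[parent]]
        status[id] <- pr >= catalogue$branch_threshold[i]
      } else {
        status[id] <- FALSE  # parent itself skipped
      }
      changed <- TRUE
    }
    if (!changed) break
  }
  presented <- names(status)[vapply(status, isTRUE, logical(1))]
  skipped <- setdiff(catalogue$item_id, presented)
  extra <- intersect(names(ratings), skipped)
  if (strict && length(extra) > 0L)
    stop("rating present for unpresented child item(s): ",
         paste(extra, collapse = ", "))
  presented <- intersect(presented, names(ratings))
  list(presented = ratings[presented], skipped = skipped)
}
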