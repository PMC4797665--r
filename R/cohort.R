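# Cohort filtering and export: the bridge from a visual usage pattern to
# statistical analysis. Filters select participants by page-group exposure
# (seen / not seen / reused / not reused) or by user-table attributes, and
# the resulting cohort exports with its user data for follow-up tests.

#' Exposure filter: participants who did (not) see or reuse a page group
#'
#' @param group_label A page-group label from the coding map.
#' @param mode One of `"seen"`, `"not_seen"`, `"reused"`, `"not_reused"`.
#'   "Reused" means viewed on a session occasion later than first exposure
#'   (see [flow_occasions()]).
#' @return An `exposure_filter` object usable in [apply_filters()].
#' @export
exposure_filter <- function(group_label,
                            mode = c("seen", "not_seen", "reused",
                                     "not_reused")) {
  mode <- match.arg(mode)
  structure(list(group_label = group_label, mode = mode),
            class = c("exposure_filter", "usage_filter"))
}

#' Variable filter: participants matching a predicate on a user attribute
#'
#' @param attribute Column name in the user table.
#' @param op Comparison: one of `"=="`, `"!="`, `"<"`, `"<="`, `">"`,
#'   `">="`, `"in"`.
#' @param value Comparison value (a vector for `"in"`).
#' @return A `variable_filter` object usable in [apply_filters()].
#' @export
variable_filter <- function(attribute,
                            op = c("==", "!=", "<", "<=", ">", ">=", "in"),
                            value) {
  op <- match.arg(op)
  structure(list(attribute = attribute, op = op, value = value),
            class = c("variable_filter", "usage_filter"))
}

filter_label <- function(f) {
  if (inherits(f, "exposure_filter")) {
    paste0(f$mode, "(", f$group_label, ")")
  } else {
    paste0(f$attribute, " ", f$op, " ", paste(f$value, collapse = ","))
  }
}

# user ids matched by one filter, against the full user universe
match_filter <- function(dataset, f, gap_minutes) {
  universe <- dataset$users$user_id
  if (inherits(f, "exposure_filter")) {
    if (!f$group_label %in% dataset$coding$group_label) {
      stop("unknown group label: ", f$group_label, call. = FALSE)
    }
    seen <- unique(
      dataset$flow$user_id[dataset$flow$group_label == f$group_label])
    switch(f$mode,
           seen = intersect(universe, seen),
           not_seen = setdiff(universe, seen),
           reused = intersect(universe,
                              reusers_of(dataset, f$group_label,
                                         gap_minutes)),
           not_reused = setdiff(universe,
                                reusers_of(dataset, f$group_label,
                                           gap_minutes)))
  } else if (inherits(f, "variable_filter")) {
    if (!f$attribute %in% names(dataset$users)) {
      stop("unknown attribute: ", f$attribute, call. = FALSE)
    }
    x <- dataset$users[[f$attribute]]
    if (f$op %in% c("<", "<=", ">", ">=") &&
        (!is.numeric(x) || !is.numeric(f$value))) {
      stop("ordered comparison on non-numeric attribute: ", f$attribute,
           call. = FALSE)
    }
    keep <- switch(f$op,
                   "==" = x == f$value,
                   "!=" = x != f$value,
                   "<" = x < f$value,
                   "<=" = x <= f$value,
                   ">" = x > f$value,
                   ">=" = x >= f$value,
                   "in" = x %in% f$value)
    keep[is.na(keep)] <- FALSE
    universe[keep]
  } else {
    stop("not a usage_filter: ", paste(class(f), collapse = "/"),
         call. = FALSE)
  }
}

#' Apply filters to a dataset
#'
#' Filters combine by conjunction (AND); the result is order-independent.
#' An empty filter list returns all users. Provenance records every filter
#' applied, so an exported cohort documents how it was selected.
#'
#' @param dataset A `usage_dataset`.
#' @param filters List of [exposure_filter()] / [variable_filter()] objects.
#' @param gap_minutes Occasion boundary for "reused" modes.
#' @return A `cohort`: list with `user_ids` (ordered as in the user table)
#'   and `provenance` (character descriptions of the filters).
#' @export
apply_filters <- function(dataset, filters = list(), gap_minutes = 60) {
  ids <- dataset$users$user_id
  for (f in filters) {
    ids <- intersect(ids, match_filter(dataset, f, gap_minutes))
  }
  structure(list(user_ids = ids[order(match(ids, dataset$users$user_id))],
                 provenance = vapply(filters, filter_label, character(1))),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$user_ids), " user(s)\n", sep = "")
  if (length(x$provenance) > 0) {
    cat("  filters: ", paste(x$provenance, collapse = " AND "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Export a cohort with its user data
#'
#' Writes one row per cohort member: `user_id`, every user-table column,
#' one 0/1 indicator column per provenance filter, and `total_blocks`
#' (total viewing time in 30-second blocks). CSV is the canonical,
#' bit-reproducible format.
#'
#' @param dataset A `usage_dataset`.
#' @param cohort A `cohort` from [apply_filters()].
#' @param path Output CSV path.
#' @param filters The filter list that produced the cohort (optional;
#'   regenerates the indicator columns).
#' @param gap_minutes Occasion boundary for "reused" indicators.
#' @return The exported tibble, invisibly.
#' @export
export_cohort <- function(dataset, cohort, path, filters = list(),
                          gap_minutes = 60) {
  out <- dataset$users[match(cohort$user_ids, dataset$users$user_id), ]
  for (f in filters) {
    nm <- filter_label(f)
    out[[nm]] <- as.integer(
      out$user_id %in% match_filter(dataset, f, gap_minutes))
  }
  lens <- sequence_lengths(build_sequences(dataset))
  out$total_blocks <- lens$total_blocks[match(out$user_id, lens$user_id)]
  out$total_blocks[is.na(out$total_blocks)] <- 0L
  readr::write_csv(out, path, progress = FALSE)
  invisible(out)
}

#' Add a usage-indicator column to the user table
#'
#' Creates the "new usage variable" used in moderator analysis: a named 0/1
#' column that marks which participants match an exposure filter (e.g.
#' reused the steps diary). The returned dataset's user table carries the
#' column; a name collision with an existing attribute is an error.
#'
#' @param dataset A `usage_dataset`.
#' @param filter An [exposure_filter()].
#' @param name Name for the new column; defaults to a label derived from
#'   the filter.
#' @param gap_minutes Occasion boundary for "reused" modes.
#' @return The dataset with the indicator column added to `users`.
#' @export
usage_indicator <- function(dataset, filter, name = NULL, gap_minutes = 60) {
  if (is.null(name)) name <- filter_label(filter)
  if (name %in% names(dataset$users)) {
    stop("attribute already exists: ", name, call. = FALSE)
  }
  matched <- match_filter(dataset, filter, gap_minutes)
  dataset$users[[name]] <- as.integer(dataset$users$user_id %in% matched)
  dataset
}
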