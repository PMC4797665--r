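# Per-participant time-binned page-group sequences: the objects the stacked
# visualizations draw, plus the usage/reuse summary tables built from them.

BLOCK_SECONDS <- 30

#' Number of 30-second blocks for a page view
#'
#' Views are binned into 30-second blocks for plotting. Partial blocks round
#' up, with a one-block floor, so every visited page is visible in the plot
#' no matter how brief the view.
#'
#' @param duration_s View duration(s) in seconds; non-negative.
#' @param block_seconds Block width in seconds (30 by default).
#' @return Integer block count(s), `max(1, ceiling(duration_s / block_seconds))`.
#' @export
blocks_for <- function(duration_s, block_seconds = BLOCK_SECONDS) {
  if (any(duration_s < 0)) stop("negative duration", call. = FALSE)
  pmax(1L, as.integer(ceiling(duration_s / block_seconds)))
}

#' Build binned page-group sequences
#'
#' Converts each participant's page views into an ordered run-length
#' sequence of (code, blocks): views are sorted by start time (ties by file
#' order), durations binned with [blocks_for()], and adjacent views sharing a
#' code merged into one run. Calendar gaps between views carry no width —
#' the x-axis of the plots is cumulative viewing time, not real time.
#'
#' @param dataset A `usage_dataset` from [assemble_dataset()].
#' @param block_seconds Block width in seconds.
#' @return A `binned_sequences` tibble with columns `user_id`, `run_index`,
#'   `code`, `group_label`, `blocks`. Users with no views are absent.
#' @export
build_sequences <- function(dataset, block_seconds = BLOCK_SECONDS) {
  flow <- dataset$flow
  if (nrow(flow) == 0) {
    return(empty_sequences())
  }
  flow$.row <- seq_len(nrow(flow))
  flow <- dplyr::arrange(flow, .data$user_id, .data$start, .data$.row)
  flow$blocks <- blocks_for(flow$duration_s, block_seconds)
  groups <- dplyr::distinct(flow, .data$code, .data$group_label)
  runs <- flow |>
    dplyr::group_by(.data$user_id) |>
    dplyr::reframe({
      r <- rle(code)
      tibble::tibble(
        run_index = seq_along(r$values),
        code = r$values,
        blocks = as.integer(tapply(blocks, rep(seq_along(r$values),
                                               r$lengths), sum))
      )
    }) |>
    dplyr::left_join(groups, by = "code") |>
    dplyr::select("user_id", "run_index", "code", "group_label", "blocks")
  structure(runs, class = c("binned_sequences", class(tibble::tibble())))
}

empty_sequences <- function() {
  structure(
    tibble::tibble(user_id = character(), run_index = integer(),
                   code = integer(), group_label = character(),
                   blocks = integer()),
    class = c("binned_sequences", class(tibble::tibble())))
}

#' Total blocks per participant ("sequence length")
#'
#' Sequence length is total viewing time in 30-second blocks, the key by
#' which participants are stacked in the plots.
#'
#' @param sequences A `binned_sequences` tibble.
#' @return A tibble with `user_id` and `total_blocks`.
#' @export
sequence_lengths <- function(sequences) {
  sequences |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(total_blocks = sum(.data$blocks), .groups = "drop")
}

#' Order participants by sequence length
#'
#' Returns the sequences with participants ordered by total viewing time:
#' ascending by default, so those who spent least time sit at the bottom of
#' the plot and those who spent most at the top. Ties break lexicographically
#' on `user_id` for determinism.
#'
#' @param sequences A `binned_sequences` tibble.
#' @param direction `"asc"` (default; least time first) or `"desc"`.
#' @return The sequences tibble, rows sorted to the participant order, with
#'   attribute `user_order` holding the ordered `user_id` vector (first =
#'   bottom lane).
#' @export
order_participants <- function(sequences, direction = c("asc", "desc")) {
  direction <- match.arg(direction)
  lens <- sequence_lengths(sequences)
  lens <- lens[order(lens$total_blocks, lens$user_id,
                     decreasing = c(direction == "desc", FALSE),
                     method = "radix"), ]
  out <- sequences[order(match(sequences$user_id, lens$user_id),
                         sequences$run_index), ]
  attr(out, "user_order") <- lens$user_id
  out
}

#' Percentage, truncated to one decimal
#'
#' One-decimal percentages in the summary tables are truncated, not rounded:
#' 104/132 prints as 78.7 and 76/132 as 57.5.
#'
#' @param n Numerator count(s).
#' @param denominator Denominator count.
#' @return `floor(1000 * n / denominator) / 10`.
#' @export
pct_trunc1 <- function(n, denominator) {
  floor(1000 * n / denominator + 1e-9) / 10
}

#' Percentage, rounded to integer
#'
#' Whole-number percentages round half away from zero: 120/132 prints as 91.
#'
#' @inheritParams pct_trunc1
#' @return Integer percentage(s).
#' @export
pct_round_int <- function(n, denominator) {
  as.integer(floor(100 * n / denominator + 0.5 + 1e-9))
}

#' Summarise usage by page group
#'
#' For each page group, counts the distinct participants with at least one
#' view of any page in the group, and reports the percentage in both printed
#' conventions: one-decimal truncated (`pct_1dp`) and integer-rounded
#' (`pct_int`).
#'
#' @param dataset A `usage_dataset`.
#' @param group_labels Page-group labels to summarise; `NULL` for all groups
#'   in the coding map.
#' @param denominator Denominator for percentages; defaults to the number of
#'   participants with at least one page view.
#' @return A tibble with columns `group_label`, `code`, `n_viewed`,
#'   `denominator`, `pct_1dp`, `pct_int`, in the order requested.
#' @export
usage_summary <- function(dataset, group_labels = NULL, denominator = NULL) {
  all_groups <- dplyr::distinct(dataset$coding, .data$group_label, .data$code)
  if (is.null(group_labels)) {
    group_labels <- all_groups$group_label
  } else {
    unknown <- setdiff(group_labels, all_groups$group_label)
    if (length(unknown) > 0) {
      stop("unknown group label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(denominator)) {
    denominator <- dplyr::n_distinct(dataset$flow$user_id)
  }
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  viewed <- dataset$flow |>
    dplyr::distinct(.data$group_label, .data$user_id) |>
    dplyr::count(.data$group_label, name = "n_viewed")
  tibble::tibble(group_label = group_labels) |>
    dplyr::left_join(all_groups, by = "group_label") |>
    dplyr::left_join(viewed, by = "group_label") |>
    dplyr::mutate(
      n_viewed = dplyr::coalesce(.data$n_viewed, 0L),
      denominator = denominator,
      pct_1dp = pct_trunc1(.data$n_viewed, denominator),
      pct_int = pct_round_int(.data$n_viewed, denominator)
    )
}

#' Split a participant's views into session occasions
#'
#' A new occasion (login/sitting) starts whenever the gap between two
#' consecutive views exceeds `gap_minutes`. Occasions operationalize "reuse":
#' viewing a tool on a later occasion than the one on which it was first
#' seen.
#'
#' @param dataset A `usage_dataset`.
#' @param gap_minutes Gap, in minutes, that separates two occasions (60 by
#'   default).
#' @return The dataset's flow tibble with an integer `occasion` column
#'   (1-based, per user, in temporal order).
#' @export
flow_occasions <- function(dataset, gap_minutes = 60) {
  flow <- dataset$flow
  if (nrow(flow) == 0) {
    flow$occasion <- integer()
    return(flow)
  }
  flow$.row <- seq_len(nrow(flow))
  flow <- dplyr::arrange(flow, .data$user_id, .data$start, .data$.row)
  flow |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(occasion = 1L + cumsum(
      c(0, as.numeric(diff(.data$start), units = "mins") > gap_minutes))) |>
    dplyr::ungroup() |>
    dplyr::select(-".row")
}

#' Summarise reuse by page group
#'
#' Counts participants who viewed a group's pages on a session occasion
#' *after* the occasion of first exposure — i.e. came back to the group on a
#' later sitting. Occasion boundaries follow [flow_occasions()].
#'
#' @inheritParams usage_summary
#' @inheritParams flow_occasions
#' @return As [usage_summary()], with `n_viewed` counting reusers.
#' @export
reuse_summary <- function(dataset, group_labels = NULL, denominator = NULL,
                          gap_minutes = 60) {
  all_groups <- dplyr::distinct(dataset$coding, .data$group_label, .data$code)
  if (is.null(group_labels)) {
    group_labels <- all_groups$group_label
  } else {
    unknown <- setdiff(group_labels, all_groups$group_label)
    if (length(unknown) > 0) {
      stop("unknown group label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(denominator)) {
    denominator <- max(1L, dplyr::n_distinct(dataset$flow$user_id))
  }
  occ <- flow_occasions(dataset, gap_minutes)
  reusers <- if (nrow(occ) == 0) {
    tibble::tibble(group_label = character(), n_viewed = integer())
  } else {
    occ |>
      dplyr::group_by(.data$group_label, .data$user_id) |>
      dplyr::summarise(reused = max(.data$occasion) > min(.data$occasion),
                       .groups = "drop") |>
      dplyr::filter(.data$reused) |>
      dplyr::count(.data$group_label, name = "n_viewed")
  }
  tibble::tibble(group_label = group_labels) |>
    dplyr::left_join(all_groups, by = "group_label") |>
    dplyr::left_join(reusers, by = "group_label") |>
    dplyr::mutate(
      n_viewed = dplyr::coalesce(.data$n_viewed, 0L),
      denominator = denominator,
      pct_1dp = pct_trunc1(.data$n_viewed, denominator),
      pct_int = pct_round_int(.data$n_viewed, denominator)
    )
}

#' Which participants reused a page group
#'
#' @inheritParams reuse_summary
#' @param group_label A single page-group label.
#' @return Character vector of user ids who viewed the group on an occasion
#'   later than their first exposure to it.
#' @export
reusers_of <- function(dataset, group_label, gap_minutes = 60) {
  if (!group_label %in% dataset$coding$group_label) {
    stop("unknown group label: ", group_label, call. = FALSE)
  }
  occ <- flow_occasions(dataset, gap_minutes)
  occ <- occ[occ$group_label == group_label, ]
  if (nrow(occ) == 0) return(character())
  per_user <- occ |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(reused = max(.data$occasion) > min(.data$occasion),
                     .groups = "drop")
  sort(per_user$user_id[per_user$reused])
}

#' Export binned sequences as CSV
#'
#' Writes the run-length representation (`user_id`, `run_index`, `code`,
#' `blocks`) for use by external plotting tools.
#'
#' @param sequences A `binned_sequences` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(sequences, path) {
  readr::write_csv(
    sequences[c("user_id", "run_index", "code", "blocks")], path,
    progress = FALSE)
  invisible(path)
}
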