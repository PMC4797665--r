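# Readers, writers and validation for the four input files: page flow,
# coding map, color map and user data. Everything downstream consumes the
# assembled `usage_dataset`.

# reserved code for pages absent from the coding map
UNCODED_CODE <- 0L
UNCODED_GROUP <- "uncoded"
UNCODED_COLOR <- "#CCCCCC"

read_delim_quiet <- function(path, delim, col_types) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  readr::read_delim(path, delim = delim, col_types = col_types,
                    progress = FALSE, show_col_types = FALSE)
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a page-flow log
#'
#' A page-flow file has one row per page view: which participant viewed which
#' page, when the view started and how long it lasted. Rows are kept in file
#' order, which downstream code uses to break ties between views sharing a
#' start timestamp.
#'
#' @param path Path to a delimited text file with a header row naming the
#'   columns `user_id`, `page_id`, `start` (ISO 8601, UTC) and `duration_s`
#'   (non-negative seconds).
#' @param delim Field delimiter; `","` by default, pass `"\t"` for
#'   tab-separated exports.
#' @return A tibble with columns `user_id` (character), `page_id` (character),
#'   `start` (POSIXct, UTC) and `duration_s` (double), in file order.
#' @export
read_page_flow <- function(path, delim = ",") {
  df <- read_delim_quiet(path, delim,
                         readr::cols(.default = readr::col_character()))
  check_columns(df, c("user_id", "page_id", "start", "duration_s"), path)
  if (nrow(df) == 0) {
    return(tibble::tibble(user_id = character(), page_id = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          duration_s = double()))
  }
  start <- suppressWarnings(readr::parse_datetime(df$start))
  attr(start, "problems") <- NULL
  bad <- which(is.na(start) & !is.na(df$start))
  if (length(bad) > 0) {
    stop("unparsable timestamp in ", path, " at data row ", bad[1],
         " (line ", bad[1] + 1L, "): '", df$start[bad[1]], "'", call. = FALSE)
  }
  duration <- suppressWarnings(as.numeric(df$duration_s))
  bad <- which(is.na(duration))
  if (length(bad) > 0) {
    stop("unparsable duration in ", path, " at data row ", bad[1],
         " (line ", bad[1] + 1L, "): '", df$duration_s[bad[1]], "'",
         call. = FALSE)
  }
  bad <- which(duration < 0)
  if (length(bad) > 0) {
    stop("negative duration in ", path, " at data row ", bad[1],
         " (line ", bad[1] + 1L, "): ", duration[bad[1]], call. = FALSE)
  }
  if (any(!nzchar(df$user_id)) || any(!nzchar(df$page_id))) {
    stop("empty user_id or page_id in ", path, call. = FALSE)
  }
  tibble::tibble(user_id = df$user_id, page_id = df$page_id,
                 start = start, duration_s = duration)
}

#' Write a page-flow log
#'
#' Inverse of [read_page_flow()]: timestamps are serialized as ISO 8601 UTC so
#' a read/write round trip reproduces the file up to delimiter normalization.
#'
#' @param flow A page-flow tibble as returned by [read_page_flow()].
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_page_flow <- function(flow, path) {
  out <- tibble::tibble(
    user_id = flow$user_id,
    page_id = flow$page_id,
    start = format(flow$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    duration_s = flow$duration_s
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a page-coding map
#'
#' The coding file assigns every intervention page a numeric code and a
#' page-group label; codes are the unit of color and aggregation in the
#' plots. Many pages may share one code, but each page appears once and each
#' code has exactly one group label.
#'
#' @param path Delimited file with header columns `page_id`, `code`,
#'   `group_label`.
#' @inheritParams read_page_flow
#' @return A tibble with columns `page_id`, `code` (integer), `group_label`.
#' @export
read_coding <- function(path, delim = ",") {
  df <- read_delim_quiet(path, delim,
                         readr::cols(.default = readr::col_character()))
  check_columns(df, c("page_id", "code", "group_label"), path)
  if (nrow(df) == 0) stop("empty coding file: ", path, call. = FALSE)
  code <- suppressWarnings(as.integer(df$code))
  if (any(is.na(code)) || any(code < 1)) {
    stop("coding file ", path, ": codes must be positive integers",
         call. = FALSE)
  }
  dup <- unique(df$page_id[duplicated(df$page_id)])
  if (length(dup) > 0) {
    stop("duplicate page_id in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  coding <- tibble::tibble(page_id = df$page_id, code = code,
                           group_label = df$group_label)
  labels_per_code <- tapply(coding$group_label, coding$code,
                            function(g) length(unique(g)))
  if (any(labels_per_code > 1)) {
    stop("coding file ", path, ": code(s) ",
         paste(names(labels_per_code)[labels_per_code > 1], collapse = ", "),
         " mapped to more than one group_label", call. = FALSE)
  }
  coding
}

#' Read a code-to-color map
#'
#' @param path Delimited file with header columns `code`, `hex`
#'   (`#RRGGBB`).
#' @inheritParams read_page_flow
#' @return A tibble with columns `code` (integer) and `hex`.
#' @export
read_colors <- function(path, delim = ",") {
  df <- read_delim_quiet(path, delim,
                         readr::cols(.default = readr::col_character()))
  check_columns(df, c("code", "hex"), path)
  if (nrow(df) == 0) stop("empty color file: ", path, call. = FALSE)
  code <- suppressWarnings(as.integer(df$code))
  if (any(is.na(code))) {
    stop("color file ", path, ": codes must be integers", call. = FALSE)
  }
  if (anyDuplicated(code)) {
    stop("duplicate code in ", path, call. = FALSE)
  }
  bad <- !grepl("^#[0-9A-Fa-f]{6}$", df$hex)
  if (any(bad)) {
    stop("invalid hex color in ", path, ": ",
         paste(df$hex[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(code = code, hex = toupper(df$hex))
}

#' Read a user-data table
#'
#' One row per participant: characteristics, outcomes, or data entered into
#' the intervention. `user_id` is treated as an opaque string and never
#' coerced to numeric, so mixed ID schemes survive. All other columns are
#' free-form; `readr` type guessing applies.
#'
#' @param path Delimited file whose header contains a `user_id` column.
#' @inheritParams read_page_flow
#' @return A tibble with `user_id` (character) and the remaining columns.
#' @export
read_users <- function(path, delim = ",") {
  df <- read_delim_quiet(path, delim,
                         readr::cols(user_id = readr::col_character()))
  check_columns(df, "user_id", path)
  if (nrow(df) == 0) stop("empty user data file: ", path, call. = FALSE)
  dup <- unique(df$user_id[duplicated(df$user_id)])
  if (length(dup) > 0) {
    stop("duplicate user_id in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Assemble the four inputs into one dataset
#'
#' Joins page codes and group labels onto the flow, resolving every page view
#' to a code. Pages missing from the coding map are mapped to the reserved
#' code 0 ("uncoded", drawn gray) so coding-file gaps stay visible in plots
#' rather than being dropped; with `strict = TRUE` the first unresolvable
#' reference raises instead. Flow users absent from the user table are
#' counted and reported via a message.
#'
#' Assembly is idempotent: assembling an assembled dataset's parts yields an
#' equal dataset.
#'
#' @param flow Page-flow tibble ([read_page_flow()]).
#' @param coding Coding tibble ([read_coding()]).
#' @param colors Color tibble ([read_colors()]).
#' @param users User tibble ([read_users()]).
#' @param strict If `TRUE`, any page id missing from the coding map is an
#'   error naming the page.
#' @return A `usage_dataset`: a list with elements `flow` (with `code` and
#'   `group_label` columns joined on), `coding`, `colors`, `users`, and
#'   counts `n_uncoded_views` and `n_unknown_users`.
#' @export
assemble_dataset <- function(flow, coding, colors, users, strict = FALSE) {
  flow <- flow[setdiff(names(flow),
                       c("code", "group_label"))]  # re-assembly idempotence
  unknown_pages <- setdiff(unique(flow$page_id), coding$page_id)
  if (strict && length(unknown_pages) > 0) {
    stop("page id(s) not in coding map: ",
         paste(unknown_pages, collapse = ", "), call. = FALSE)
  }
  flow <- dplyr::left_join(flow, coding, by = "page_id")
  n_uncoded <- sum(is.na(flow$code))
  flow$code[is.na(flow$code)] <- UNCODED_CODE
  flow$group_label[is.na(flow$group_label)] <- UNCODED_GROUP
  if (n_uncoded > 0) {
    message(n_uncoded, " page view(s) had no coding entry; mapped to code 0")
    if (!UNCODED_CODE %in% colors$code) {
      colors <- dplyr::bind_rows(
        tibble::tibble(code = UNCODED_CODE, hex = UNCODED_COLOR), colors)
    }
  }
  unknown_users <- setdiff(unique(flow$user_id), users$user_id)
  if (length(unknown_users) > 0) {
    message(length(unknown_users),
            " flow user(s) absent from the user table: ",
            paste(utils::head(unknown_users, 5), collapse = ", "))
  }
  structure(
    list(flow = flow, coding = coding, colors = colors, users = users,
         n_uncoded_views = n_uncoded,
         n_unknown_users = length(unknown_users)),
    class = "usage_dataset")
}

#' Load and assemble a dataset from the four files
#'
#' Convenience wrapper chaining the four readers and [assemble_dataset()].
#'
#' @param page_flow,coding,colors,users Paths to the four input files.
#' @inheritParams read_page_flow
#' @inheritParams assemble_dataset
#' @return A `usage_dataset`.
#' @export
read_dataset <- function(page_flow, coding, colors, users,
                         delim = ",", strict = FALSE) {
  assemble_dataset(read_page_flow(page_flow, delim),
                   read_coding(coding, delim),
                   read_colors(colors, delim),
                   read_users(users, delim),
                   strict = strict)
}

#' @export
print.usage_dataset <- function(x, ...) {
  cat("<usage_dataset>\n")
  cat("  page views :", nrow(x$flow), "\n")
  cat("  users      :", nrow(x$users), "\n")
  cat("  page groups:", length(unique(x$coding$code)), "\n")
  if (x$n_uncoded_views > 0) {
    cat("  uncoded views:", x$n_uncoded_views, "\n")
  }
  invisible(x)
}
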