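# The four stacked sequence plot types: normal (one lane per participant),
# frequency (aggregate per page group), clustered (lanes grouped by usage
# archetype) and group (facetted by a participant attribute). All plots are
# ggplot objects; the lane/width contract is testable on the built scene,
# not the raster.

#' Specify a sequence plot
#'
#' @param plot_type One of `"normal"`, `"frequency"`, `"clustered"`,
#'   `"group"`.
#' @param block_seconds Width of one x-axis block, in seconds (30 default).
#' @param sort_direction `"asc"` (least total time at the bottom) or
#'   `"desc"`.
#' @param facet_variable User-table column to facet by; required iff
#'   `plot_type = "group"`.
#' @param cluster_k Number of clusters for `"clustered"` plots, or `"auto"`
#'   to pick k in 2..8 by mean silhouette width.
#' @param strict_colors If `TRUE`, a code without a color entry is an error;
#'   otherwise it falls back to gray.
#' @return A `plot_spec` list.
#' @export
plot_spec <- function(plot_type = c("normal", "frequency", "clustered",
                                    "group"),
                      block_seconds = BLOCK_SECONDS,
                      sort_direction = c("asc", "desc"),
                      facet_variable = NULL,
                      cluster_k = "auto",
                      strict_colors = FALSE) {
  plot_type <- match.arg(plot_type)
  sort_direction <- match.arg(sort_direction)
  if (plot_type == "group" && is.null(facet_variable)) {
    stop("group plots require facet_variable", call. = FALSE)
  }
  if (plot_type != "group" && !is.null(facet_variable)) {
    stop("facet_variable only applies to group plots", call. = FALSE)
  }
  if (!identical(cluster_k, "auto")) {
    cluster_k <- as.integer(cluster_k)
    if (is.na(cluster_k) || cluster_k < 2) {
      stop("cluster_k must be >= 2 or \"auto\"", call. = FALSE)
    }
  }
  structure(list(plot_type = plot_type, block_seconds = block_seconds,
                 sort_direction = sort_direction,
                 facet_variable = facet_variable, cluster_k = cluster_k,
                 strict_colors = strict_colors),
            class = "plot_spec")
}

# named color vector (by code) covering every code present; gray fallback
# unless strict
resolve_colors <- function(codes, colors, strict) {
  codes <- sort(unique(codes))
  pal <- stats::setNames(colors$hex, as.character(colors$code))
  missing <- setdiff(as.character(codes), names(pal))
  if (length(missing) > 0) {
    if (strict) {
      stop("no color for code(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    pal[missing] <- UNCODED_COLOR
  }
  pal[as.character(codes)]
}

# rectangles for lane-style plots: one row per run, lanes bottom-to-top in
# the given user order
lane_rects <- function(sequences, user_order) {
  seqs <- sequences[order(match(sequences$user_id, user_order),
                          sequences$run_index), ]
  seqs |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(xmax = cumsum(.data$blocks),
                  xmin = .data$xmax - .data$blocks) |>
    dplyr::ungroup() |>
    dplyr::mutate(lane = match(.data$user_id, user_order),
                  ymin = .data$lane - 0.45, ymax = .data$lane + 0.45)
}

# legend: one entry per code, ascending, labelled by group
code_legend <- function(sequences) {
  leg <- dplyr::distinct(sequences, .data$code, .data$group_label)
  leg <- leg[order(leg$code), ]
  stats::setNames(leg$group_label, as.character(leg$code))
}

lane_plot <- function(rects, sequences, colors, spec, n_lanes) {
  pal <- resolve_colors(sequences$code, colors, spec$strict_colors)
  labels <- code_legend(sequences)
  p <- ggplot2::ggplot(rects) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = factor(.data$code)),
                       linewidth = 0) +
    ggplot2::scale_fill_manual(values = pal, labels = labels,
                               name = "Page group", drop = FALSE) +
    ggplot2::labs(x = sprintf("Viewing time (%d-second blocks)",
                              as.integer(spec$block_seconds)),
                  y = "Participant") +
    ggplot2::scale_y_continuous(limits = c(0.5, max(1, n_lanes) + 0.5),
                                expand = c(0, 0)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
  p
}

#' Normal plot: one lane per participant
#'
#' Each participant is one horizontal lane; lanes are stacked bottom-to-top
#' in order of total viewing time (least at the bottom by default). Each run
#' of consecutive same-group views is a contiguous bar of its run length in
#' blocks, filled with the group's color.
#'
#' @param sequences A `binned_sequences` tibble ([build_sequences()]).
#' @param colors A color tibble ([read_colors()]).
#' @param spec A [plot_spec()]; `plot_type` is ignored here.
#' @return A ggplot object. Contract: one lane per participant with at least
#'   one view; drawn lane width equals `total_blocks` x one block unit.
#' @export
render_normal <- function(sequences, colors, spec = plot_spec("normal")) {
  ordered <- order_participants(sequences, spec$sort_direction)
  user_order <- attr(ordered, "user_order")
  if (length(user_order) == 0) {
    return(ggplot2::ggplot(tibble::tibble(x = double(), y = double()),
                           ggplot2::aes(.data$x, .data$y)) +
             ggplot2::geom_blank() +
             ggplot2::labs(x = sprintf("Viewing time (%d-second blocks)",
                                       as.integer(spec$block_seconds)),
                           y = "Participant") +
             ggplot2::theme_minimal())
  }
  rects <- lane_rects(ordered, user_order)
  lane_plot(rects, sequences, colors, spec, length(user_order))
}

#' Frequency plot: total usage per page group
#'
#' Aggregates total blocks across all participants per page group and draws
#' a horizontal bar chart sorted by usage (most-used group on top), so the
#' most and least used parts of the intervention are read off directly.
#'
#' @inheritParams render_normal
#' @return A ggplot object; bar lengths equal summed blocks per group.
#' @export
render_frequency <- function(sequences, colors,
                             spec = plot_spec("frequency")) {
  totals <- sequences |>
    dplyr::group_by(.data$code, .data$group_label) |>
    dplyr::summarise(blocks = sum(.data$blocks), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$blocks), .data$code)
  pal <- resolve_colors(totals$code, colors, spec$strict_colors)
  totals$group_label <- factor(totals$group_label,
                               levels = rev(totals$group_label))
  ggplot2::ggplot(totals,
                  ggplot2::aes(x = .data$blocks, y = .data$group_label,
                               fill = factor(.data$code))) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(x = sprintf("Total viewing time (%d-second blocks)",
                              as.integer(spec$block_seconds)),
                  y = "Page group") +
    ggplot2::theme_minimal()
}

#' Cluster participants by usage pattern
#'
#' Groups participants into statistically similar usage patterns. Each
#' participant's feature vector is their total blocks per page code,
#' L2-normalized so patterns are compared by shape rather than volume;
#' agglomerative clustering with Ward linkage on Euclidean distance follows.
#' With `k = "auto"` the number of clusters is chosen in 2..8 (capped at
#' n - 1) to maximize mean silhouette width. Deterministic given the input.
#'
#' @param sequences A `binned_sequences` tibble with at least 2 participants.
#' @param k Number of clusters, or `"auto"`.
#' @param seed Integer seed (the procedure is deterministic; the seed is
#'   accepted for interface uniformity and set for any downstream use).
#' @return Named integer vector of cluster labels, one per participant.
#' @export
cluster_usage <- function(sequences, k = "auto", seed = 1L) {
  set.seed(seed)
  feats <- sequences |>
    dplyr::group_by(.data$user_id, .data$code) |>
    dplyr::summarise(blocks = sum(.data$blocks), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "code", values_from = "blocks",
                       values_fill = 0L)
  n <- nrow(feats)
  if (n < 2) stop("clustering needs at least 2 participants", call. = FALSE)
  m <- as.matrix(feats[-1])
  norms <- sqrt(rowSums(m^2))
  norms[norms == 0] <- 1
  m <- m / norms
  d <- stats::dist(m)
  hc <- stats::hclust(d, method = "ward.D2")
  if (identical(k, "auto")) {
    ks <- 2:min(8, n - 1)
    sil <- vapply(ks, function(kk) {
      lab <- stats::cutree(hc, kk)
      mean(cluster::silhouette(lab, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  } else {
    k <- as.integer(k)
    if (k > n) stop("fewer participants than clusters", call. = FALSE)
  }
  stats::setNames(stats::cutree(hc, k), feats$user_id)
}

#' Clustered plot: lanes grouped by usage pattern
#'
#' Normal-style lanes, but participants are stacked contiguously by cluster
#' (from [cluster_usage()]), clusters separated by rule lines, and ordered
#' by total blocks within each cluster.
#'
#' @inheritParams render_normal
#' @param clusters Optional precomputed labels from [cluster_usage()];
#'   computed with `spec$cluster_k` when `NULL`.
#' @param seed Seed forwarded to [cluster_usage()].
#' @return A ggplot object.
#' @export
render_clustered <- function(sequences, colors,
                             spec = plot_spec("clustered"),
                             clusters = NULL, seed = 1L) {
  if (is.null(clusters)) {
    clusters <- cluster_usage(sequences, spec$cluster_k, seed)
  }
  lens <- sequence_lengths(sequences)
  lens$cluster <- clusters[lens$user_id]
  dec <- spec$sort_direction == "desc"
  lens <- lens[order(lens$cluster, lens$total_blocks, lens$user_id,
                     decreasing = c(FALSE, dec, FALSE), method = "radix"), ]
  user_order <- lens$user_id
  rects <- lane_rects(sequences, user_order)
  p <- lane_plot(rects, sequences, colors, spec, length(user_order))
  boundaries <- cumsum(table(lens$cluster))
  boundaries <- boundaries[-length(boundaries)]
  if (length(boundaries) > 0) {
    p <- p + ggplot2::geom_hline(yintercept = as.numeric(boundaries) + 0.5,
                                 linetype = "dashed", linewidth = 0.3)
  }
  p
}

#' Group plot: side-by-side panels by a participant attribute
#'
#' One normal-style panel per level of a categorical user-table variable
#' (e.g. trial arm), sharing the x scale, so usage patterns can be compared
#' across subgroups. Levels with no participants keep an empty, labelled
#' panel.
#'
#' @inheritParams render_normal
#' @param users The dataset's user table, holding `spec$facet_variable`.
#' @return A ggplot object with one facet per level.
#' @export
render_group <- function(sequences, colors, spec, users) {
  fv <- spec$facet_variable
  if (is.null(fv) || !fv %in% names(users)) {
    stop("facet variable not found in user table: ",
         if (is.null(fv)) "<none>" else fv, call. = FALSE)
  }
  values <- users[[fv]]
  if (is.numeric(values) && dplyr::n_distinct(values) > 12) {
    stop("facet variable must be categorical: ", fv, call. = FALSE)
  }
  fac <- if (is.factor(values)) values else factor(values)
  ordered <- order_participants(sequences, spec$sort_direction)
  user_order <- attr(ordered, "user_order")
  rects <- lane_rects(ordered, user_order)
  rects$facet <- fac[match(rects$user_id, users$user_id)]
  # lane numbering restarts within each panel
  rects <- rects |>
    dplyr::group_by(.data$facet) |>
    dplyr::mutate(lane = match(.data$user_id, unique(.data$user_id)),
                  ymin = .data$lane - 0.45, ymax = .data$lane + 0.45) |>
    dplyr::ungroup()
  pal <- resolve_colors(sequences$code, colors, spec$strict_colors)
  labels <- code_legend(sequences)
  ggplot2::ggplot(rects) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = factor(.data$code)),
                       linewidth = 0) +
    ggplot2::scale_fill_manual(values = pal, labels = labels,
                               name = "Page group", drop = FALSE) +
    ggplot2::facet_wrap(~facet, drop = FALSE) +
    ggplot2::labs(x = sprintf("Viewing time (%d-second blocks)",
                              as.integer(spec$block_seconds)),
                  y = "Participant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}

#' Render a plot from a spec
#'
#' Dispatches on `spec$plot_type` to the four renderers.
#'
#' @inheritParams render_normal
#' @param dataset The `usage_dataset` (needed for group plots' user table).
#' @param seed Seed forwarded to clustering.
#' @return A ggplot object.
#' @export
render_plot <- function(sequences, colors, spec, dataset = NULL, seed = 1L) {
  switch(spec$plot_type,
         normal = render_normal(sequences, colors, spec),
         frequency = render_frequency(sequences, colors, spec),
         clustered = render_clustered(sequences, colors, spec, seed = seed),
         group = {
           if (is.null(dataset)) {
             stop("group plots need the dataset's user table", call. = FALSE)
           }
           render_group(sequences, colors, spec, dataset$users)
         })
}

#' Save a plot to SVG or PNG
#'
#' SVG (via the cairo device) is the deterministic format: the same plot
#' yields byte-identical files across runs. PNG is offered for convenience.
#'
#' @param plot A ggplot object.
#' @param path Output path ending in `.svg` or `.png`.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
save_plot <- function(plot, path, width = 9, height = 6) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else {
    stop("unsupported format: .", ext, " (use .svg or .png)", call. = FALSE)
  }
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
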