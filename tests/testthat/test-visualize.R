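test_that("plot specs validate their fields", {
  expect_error(plot_spec("group"), "facet_variable")
  expect_error(plot_spec("normal", facet_variable = "arm"), "group plots")
  expect_error(plot_spec("clustered", cluster_k = 1), "cluster_k")
  expect_equal(plot_spec("clustered", cluster_k = "3")$cluster_k, 3L)
})

test_that("normal plot draws one lane per participant at its total width", {
  d <- tiny_dataset()
  s <- build_sequences(d)
  p <- render_normal(s, d$colors)
  geom <- lane_geometry(p)
  lens <- sequence_lengths(s)
  expect_equal(nrow(geom), nrow(lens))  # one lane per participant
  # bottom-to-top by total blocks: lane 1 is the shortest sequence
  ordered <- lens$total_blocks[order(lens$total_blocks, lens$user_id)]
  expect_equal(geom$width[order(geom$lane)], ordered)
})

test_that("a single-user sequence renders runs as contiguous blocks", {
  s <- tibble::tibble(user_id = "u1", run_index = c(1L, 2L),
                      code = c(1L, 2L), group_label = c("g1", "g2"),
                      blocks = c(2L, 1L))
  colors <- tibble::tibble(code = 1:2, hex = c("#00FF00", "#FFC0CB"))
  d <- ggplot2::layer_data(render_normal(s, colors), 1)
  d <- d[order(d$xmin), ]
  expect_equal(d$xmin, c(0, 2))
  expect_equal(d$xmax, c(2, 3))
  expect_equal(toupper(d$fill), c("#00FF00", "#FFC0CB"))
})

test_that("zero participants still yield a valid empty plot", {
  p <- render_normal(empty_seqs <- build_sequences(
    suppressMessages(assemble_dataset(tiny_flow()[0, ], tiny_coding(),
                                      tiny_colors(), tiny_users()))),
    tiny_colors())
  expect_s3_class(p, "ggplot")
  expect_equal(nrow(ggplot2::layer_data(p, 1)), 0)
})

test_that("missing colors error in strict mode, fall back to gray otherwise", {
  d <- tiny_dataset()
  s <- build_sequences(d)
  colors <- d$colors[d$colors$code != 3L, ]
  expect_error(
    render_normal(s, colors, plot_spec("normal", strict_colors = TRUE)),
    "no color for code")
  p <- render_normal(s, colors)
  expect_true("#CCCCCC" %in% ggplot2::layer_data(p, 1)$fill)
})

test_that("frequency plot bars equal per-group block totals, sorted", {
  s <- tibble::tibble(
    user_id = c("u1", "u1", "u2"), run_index = c(1L, 2L, 1L),
    code = c(1L, 2L, 1L), group_label = c("g1", "g2", "g1"),
    blocks = c(25L, 10L, 15L))
  colors <- tibble::tibble(code = 1:2, hex = c("#00FF00", "#FFC0CB"))
  p <- render_frequency(s, colors)
  d <- ggplot2::layer_data(p, 1)
  # independent recomputation: code 1 = 40 blocks, code 2 = 10; code 1 first
  totals <- tapply(s$blocks, s$code, sum)
  expect_equal(sort(d$xmax, decreasing = TRUE), c(40, 10))
  expect_equal(as.integer(totals[c("1", "2")]), c(40L, 10L))
  expect_equal(d$xmax[d$y == 2], 40)  # top bar is the most-used group
})

test_that("two users each contributing 3 blocks of one code sum to 6", {
  s <- tibble::tibble(user_id = c("a", "b"), run_index = 1L, code = 1L,
                      group_label = "g1", blocks = 3L)
  p <- render_frequency(s, tibble::tibble(code = 1L, hex = "#00FF00"))
  expect_equal(ggplot2::layer_data(p, 1)$xmax, 6)
})

test_that("clustering recovers two planted archetypes exactly", {
  set.seed(5)
  s <- archetype_sequences(n_per = 20, noise_sd = 1)
  labels <- cluster_usage(s, k = 2)
  truth <- ifelse(grepl("^core", names(labels)), 1L, 2L)
  agreement <- max(mean(labels == truth), mean(labels == 3L - truth))
  expect_equal(agreement, 1)
  # automatic k finds the two archetypes too
  labels_auto <- cluster_usage(s, k = "auto")
  expect_equal(length(unique(labels_auto)), 2L)
})

test_that("clustering is deterministic and handles the n = k edge", {
  set.seed(6)
  s <- archetype_sequences(n_per = 5, noise_sd = 0.5)
  expect_identical(cluster_usage(s, k = 3, seed = 9),
                   cluster_usage(s, k = 3, seed = 9))
  two <- s[s$user_id %in% c("core01", "both01"), ]
  labels <- cluster_usage(two, k = 2)
  expect_equal(sort(unname(labels)), c(1L, 2L))  # each its own cluster
  expect_error(cluster_usage(two, k = 5), "fewer participants")
  one <- s[s$user_id == "core01", ]
  expect_error(cluster_usage(one), "at least 2")
})

test_that("clustering is invariant to splitting a view into equal halves", {
  set.seed(7)
  s <- archetype_sequences(n_per = 10, noise_sd = 0.5)
  labels <- cluster_usage(s, k = 2)
  # split every run into two half-size runs: totals per code unchanged
  halved <- s
  halved$blocks <- as.integer(ceiling(s$blocks / 2))
  extra <- s
  extra$blocks <- as.integer(floor(s$blocks / 2))
  split_s <- dplyr::bind_rows(halved, extra)
  expect_identical(cluster_usage(split_s, k = 2), labels)
})

test_that("clustered plot groups lanes by cluster with separators", {
  set.seed(8)
  s <- archetype_sequences(n_per = 6, noise_sd = 0.5)
  p <- render_clustered(s, tibble::tibble(code = c(1:2, 5:6),
                                          hex = c("#111111", "#222222",
                                                  "#333333", "#444444")))
  geom <- lane_geometry(p)
  expect_equal(nrow(geom), 12)
  # separator rule line sits between the two clusters
  hline <- ggplot2::layer_data(p, 2)
  expect_equal(hline$yintercept, 6.5)
})

test_that("group plot facets by a categorical user variable", {
  d <- tiny_dataset()
  s <- build_sequences(d)
  p <- render_group(s, d$colors, plot_spec("group", facet_variable = "arm"),
                    d$users)
  built <- ggplot2::ggplot_build(p)
  expect_equal(length(unique(built$layout$layout$PANEL)), 2)  # web, nurse
  # a level with zero users keeps an empty labelled panel
  d$users$arm <- factor(d$users$arm, levels = c("web", "nurse", "phone"))
  p3 <- render_group(s, d$colors,
                     plot_spec("group", facet_variable = "arm"), d$users)
  expect_equal(length(unique(ggplot2::ggplot_build(p3)$layout$layout$PANEL)),
               3)
  expect_error(
    render_group(s, d$colors, plot_spec("group", facet_variable = "zzz"),
                 d$users),
    "not found")
})

test_that("one-level facet degenerates to a single normal-style panel", {
  d <- tiny_dataset()
  d$users$arm <- "web"
  s <- build_sequences(d)
  p <- render_group(s, d$colors, plot_spec("group", facet_variable = "arm"),
                    d$users)
  expect_equal(length(unique(ggplot2::ggplot_build(p)$layout$layout$PANEL)),
               1)
})

test_that("saving the same plot twice yields byte-identical SVG", {
  dir <- withr::local_tempdir()
  d <- tiny_dataset()
  p <- render_normal(build_sequences(d), d$colors)
  f1 <- file.path(dir, "a.svg"); f2 <- file.path(dir, "b.svg")
  save_plot(p, f1); save_plot(p, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(save_plot(p, file.path(dir, "a.bmp")), "unsupported format")
})
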