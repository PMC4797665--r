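# Fixtures are built in code: a tiny hand-checkable dataset, file writers
# for the reader tests, and randomized flow generators for property tests.

tiny_coding <- function() {
  tibble::tibble(
    page_id = c("ep_a", "ep_b", "sup_a", "tool_a", "rev_a"),
    code = c(1L, 1L, 2L, 3L, 4L),
    group_label = c("eating plan", "eating plan", "support",
                    "steps diary", "review"))
}

tiny_colors <- function() {
  tibble::tibble(code = 1:4,
                 hex = c("#00FF00", "#FFC0CB", "#FFA500", "#FFD700"))
}

# u1 views the steps diary on two occasions two days apart (a reuser);
# u2 sees it once; u3 never does
tiny_flow <- function() {
  t0 <- as.POSIXct("2021-03-01 10:00:00", tz = "UTC")
  tibble::tibble(
    user_id = c("u1", "u1", "u1", "u1", "u2", "u2", "u3"),
    page_id = c("ep_a", "ep_b", "tool_a", "tool_a", "ep_a", "tool_a",
                "ep_b"),
    start = t0 + c(0, 40, 50, 2 * 86400, 0, 100, 5),
    duration_s = c(40, 10, 61, 30, 75, 12, 0))
}

tiny_users <- function() {
  tibble::tibble(user_id = c("u1", "u2", "u3"),
                 age = c(60, 45, 50),
                 arm = c("web", "nurse", "web"),
                 weight_change_kg = c(5, 2, 1))
}

tiny_dataset <- function() {
  assemble_dataset(tiny_flow(), tiny_coding(), tiny_colors(), tiny_users())
}

# write the four fixture files to dir; returns named paths
write_tiny_files <- function(dir) {
  paths <- c(flow = file.path(dir, "flow.csv"),
             coding = file.path(dir, "coding.csv"),
             colors = file.path(dir, "colors.csv"),
             users = file.path(dir, "users.csv"))
  write_page_flow(tiny_flow(), paths["flow"])
  readr::write_csv(tiny_coding(), paths["coding"], progress = FALSE)
  readr::write_csv(tiny_colors(), paths["colors"], progress = FALSE)
  readr::write_csv(tiny_users(), paths["users"], progress = FALSE)
  paths
}

# random per-user view table for binning property tests
random_views <- function(n_views, n_codes = 4) {
  tibble::tibble(
    code = sample.int(n_codes, n_views, replace = TRUE),
    duration_s = stats::runif(n_views, 0, 200))
}

# dataset with n_users random users over a simple 3-page coding map
random_dataset <- function(n_users = 8, max_views = 10) {
  coding <- tibble::tibble(page_id = c("a", "b", "c"), code = c(1L, 2L, 3L),
                           group_label = c("ga", "gb", "gc"))
  colors <- tibble::tibble(code = 1:3,
                           hex = c("#111111", "#222222", "#333333"))
  t0 <- as.POSIXct("2021-01-01", tz = "UTC")
  ids <- sprintf("u%02d", seq_len(n_users))
  flow <- dplyr::bind_rows(lapply(ids, function(id) {
    n <- sample.int(max_views, 1)
    tibble::tibble(user_id = id,
                   page_id = sample(coding$page_id, n, replace = TRUE),
                   start = t0 + cumsum(stats::runif(n, 1, 7200)),
                   duration_s = stats::runif(n, 0, 120))
  }))
  users <- tibble::tibble(user_id = ids,
                          score = stats::rnorm(n_users))
  assemble_dataset(flow, coding, colors, users)
}

# two planted usage archetypes as prebuilt sequences: "core-only"
# participants spread time over codes 1-2, "core+optional" also over 5-6
archetype_sequences <- function(n_per = 20, noise_sd = 1) {
  mk <- function(ids, codes, base) {
    dplyr::bind_rows(lapply(ids, function(id) {
      blocks <- pmax(1L, as.integer(round(
        base + stats::rnorm(length(codes), 0, noise_sd))))
      tibble::tibble(user_id = id, run_index = seq_along(codes),
                     code = codes, group_label = paste0("g", codes),
                     blocks = blocks)
    }))
  }
  core <- mk(sprintf("core%02d", seq_len(n_per)), c(1L, 2L), 20)
  both <- mk(sprintf("both%02d", seq_len(n_per)), c(1L, 2L, 5L, 6L), 10)
  dplyr::bind_rows(core, both)
}

# exhaustive two-sided permutation p-value for the pooled t statistic
perm_t_p <- function(x, y) {
  pooled <- c(x, y)
  idx <- utils::combn(length(pooled), length(x))
  t_obs <- abs(pooled_t_from_samples(x, y)$statistic)
  ts <- apply(idx, 2, function(ii) {
    abs(pooled_t_from_samples(pooled[ii], pooled[-ii])$statistic)
  })
  mean(ts >= t_obs - 1e-12)
}

# lane geometry from a built lane-style ggplot: one row per lane with its
# total drawn width in block units
lane_geometry <- function(p) {
  d <- ggplot2::layer_data(p, 1)
  d$lane <- round((d$ymin + d$ymax) / 2)
  stats::aggregate(width ~ lane, transform(d, width = d$xmax - d$xmin), sum)
}
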