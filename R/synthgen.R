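# Synthetic usage-log generator. Emulates a tunnelled web intervention:
# three core sessions unlocking weekly in sequence, nine optional weekly
# sessions, a goal-and-weight review opening every post-first session,
# reusable tool pages (food diary, steps diary), weekly nonusage attrition,
# and an outcome (weight change) linked to steps-diary reuse. Emits the
# four input files plus a ground-truth record so tests never re-infer
# latent flags.

# built-in page catalogue: codes 1-4 core, 5-13 optional, 14 review,
# 15-16 reusable tools
synth_catalog <- function() {
  groups <- tibble::tibble(
    code = 1:16,
    group_label = c("Eating plan part 1", "Eating plan part 2", "Support",
                    "Physical activity", "Cravings", "Slipups",
                    "Stretching physical activity", "Tough times",
                    "Busy lives", "Setting up your environment", "Drinks",
                    "Eating out", "Maintaining weight loss",
                    "Goal and weight review", "Food diary", "Steps diary"),
    n_pages = c(3L, 3L, 3L, 3L, rep(2L, 9L), 2L, 1L, 1L)
  )
  coding <- groups |>
    dplyr::rowwise() |>
    dplyr::reframe(page_id = sprintf("g%02d_p%d", code, seq_len(n_pages)),
                   code = code, group_label = group_label)
  colors <- tibble::tibble(
    code = 1:16,
    hex = c("#90EE90", "#FFC0CB", "#696969", "#8B4513", "#FFA500",
            "#6495ED", "#20B2AA", "#9370DB", "#F08080", "#556B2F",
            "#00CED1", "#DAA520", "#708090", "#FFD700", "#FF69B4",
            "#FF8C00"))
  list(coding = coding[c("page_id", "code", "group_label")],
       colors = colors, groups = groups)
}

#' Configuration for the synthetic usage-log generator
#'
#' Defaults describe a 132-participant tunnelled intervention: weekly
#' continuation probability 0.9 with an extra early-drop multiplier 0.8 on
#' the step into session 2 (emulating the sharp first-to-second-session
#' drop typical of web interventions, ~20%), optional-session uptake 0.5,
#' log-normal page dwell times with median ~30 s, a mean of one tool-reuse
#' occasion per eligible user, and a weight-change outcome of
#' `beta0 + beta1 * reused_steps_diary + N(0, sigma_w)` kg (positive =
#' weight lost), with beta0 = 2.63, beta1 = 3.15, sigma_w = 5.7.
#'
#' @param n_users Number of participants.
#' @param q Weekly continuation probability in (0, 1].
#' @param early_drop Extra multiplier on continuation into week 2, in
#'   (0, 1]; 1 disables the early drop, giving pure geometric decay
#'   `q^(week-1)`.
#' @param p_part2 Probability a week-1 user continues into the second half
#'   of the first session.
#' @param p_opt Probability an active post-core week includes an optional
#'   session.
#' @param dwell_meanlog,dwell_sdlog Log-normal dwell-time parameters
#'   (seconds per page view).
#' @param reuse_rate Poisson mean of tool-reuse occasions per eligible
#'   user.
#' @param beta0 Mean weight change (kg lost) for non-reusers of the steps
#'   diary.
#' @param beta1 Added weight change for steps-diary reusers.
#' @param sigma_w Residual SD of weight change (kg).
#' @param n_weeks Trial length in weeks.
#' @param seed Integer seed; mandatory, the generator is deterministic
#'   given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_users = 132L, q = 0.9, early_drop = 0.8,
                       p_part2 = 0.91, p_opt = 0.5,
                       dwell_meanlog = 3.4, dwell_sdlog = 0.8,
                       reuse_rate = 1.0, beta0 = 2.63, beta1 = 3.15,
                       sigma_w = 5.7, n_weeks = 12L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  probs <- c(q = q, early_drop = early_drop, p_part2 = p_part2)
  if (any(probs <= 0 | probs > 1)) {
    stop("q, early_drop and p_part2 must lie in (0, 1]", call. = FALSE)
  }
  if (p_opt < 0 || p_opt > 1) stop("p_opt must lie in [0, 1]", call. = FALSE)
  if (dwell_sdlog <= 0 || sigma_w <= 0) {
    stop("dwell_sdlog and sigma_w must be positive", call. = FALSE)
  }
  if (n_users < 1 || n_weeks < 3) {
    stop("need n_users >= 1 and n_weeks >= 3", call. = FALSE)
  }
  if (reuse_rate < 0) stop("reuse_rate must be non-negative", call. = FALSE)
  structure(list(n_users = as.integer(n_users), q = q,
                 early_drop = early_drop, p_part2 = p_part2, p_opt = p_opt,
                 dwell_meanlog = dwell_meanlog, dwell_sdlog = dwell_sdlog,
                 reuse_rate = reuse_rate, beta0 = beta0, beta1 = beta1,
                 sigma_w = sigma_w, n_weeks = as.integer(n_weeks),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the weight-change outcome
#'
#' The generator's outcome model, exposed separately so power and type-I
#' error studies can resample outcomes over fixed reuse flags:
#' `weight_change = beta0 + beta1 * reused + N(0, sigma_w)`, in kg lost.
#'
#' @param reused Logical/0-1 vector of steps-diary reuse flags.
#' @param beta0,beta1,sigma_w Outcome-model parameters.
#' @return Numeric vector of weight changes (kg lost).
#' @export
simulate_outcomes <- function(reused, beta0 = 2.63, beta1 = 3.15,
                              sigma_w = 5.7) {
  beta0 + beta1 * as.numeric(reused) +
    stats::rnorm(length(reused), 0, sigma_w)
}

# views for one user in one week; start is numeric seconds since epoch
# (POSIXct conversion happens once, at the end of generation)
week_views <- function(pages, start, config) {
  n <- length(pages)
  durations <- stats::rlnorm(n, config$dwell_meanlog, config$dwell_sdlog)
  gaps <- stats::runif(n, 0, 30)
  starts <- start + cumsum(c(0, (durations + gaps)[-n]))
  list(page_id = pages, start = starts, duration_s = durations,
       end = starts[n] + durations[n])
}

#' Generate a synthetic usage dataset
#'
#' Simulates every participant's weekly traversal: week 1 is the first core
#' session (part 1 always, part 2 with probability `p_part2`, plus first
#' exposure to the food diary tool); continuation into each later week is
#' Bernoulli (`q`, with `early_drop` applied at week 2); weeks 2 and 3 open
#' with a goal-and-weight review followed by the remaining core sessions
#' (support, then physical activity with first steps-diary exposure);
#' later active weeks hold a review plus an optional session with
#' probability `p_opt`. Tool-reuse occasions (Poisson, mean `reuse_rate`)
#' are inserted into active weeks after first exposure. The user table
#' carries age, BMI, trial arm, eating/activity plan and the simulated
#' weight change.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes
#'   `page_flow.csv`, `users.csv`, `coding.csv`, `colors.csv` and
#'   `truth.json` (deterministic given the seed, so identical seeds yield
#'   byte-identical files).
#' @return A list: `dataset` (assembled `usage_dataset`), `truth` (per-user
#'   latent flags + config), and `paths` when `dir` was given.
#' @export
generate_usage <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cat_ <- synth_catalog()
  pages_of <- split(cat_$coding$page_id, cat_$coding$code)
  base <- as.numeric(as.POSIXct("2020-01-06 09:00:00", tz = "UTC"))
  opt_codes <- 5:13

  n_users <- config$n_users
  ids <- sprintf("u%04d", seq_len(n_users))
  u_pages <- vector("list", n_users)
  u_starts <- vector("list", n_users)
  u_durs <- vector("list", n_users)
  t_last_week <- integer(n_users)
  t_part2 <- logical(n_users)
  t_reused_food <- logical(n_users)
  t_reused_steps <- logical(n_users)

  for (i in seq_len(n_users)) {
    # weekly survival: constant hazard, sharpened into week 2
    active <- 1L
    for (w in 2:config$n_weeks) {
      p_cont <- config$q * if (w == 2) config$early_drop else 1
      if (stats::runif(1) > p_cont) break
      active <- w
    }
    part2 <- stats::runif(1) < config$p_part2
    weeks <- vector("list", active)
    jitter <- stats::runif(config$n_weeks, 0, 6 * 3600)
    for (w in seq_len(active)) {
      wk_start <- base + (w - 1) * 7 * 86400 + jitter[w]
      pages <- if (w == 1) {
        c(pages_of[["1"]],
          if (part2) pages_of[["2"]],
          pages_of[["15"]][1])          # food diary first exposure
      } else if (w == 2) {
        c(pages_of[["14"]], pages_of[["3"]])
      } else if (w == 3) {
        c(pages_of[["14"]], pages_of[["4"]],
          pages_of[["16"]][1])          # steps diary first exposure
      } else {
        c(pages_of[["14"]],
          if (stats::runif(1) < config$p_opt) {
            pages_of[[as.character(
              opt_codes[sample.int(length(opt_codes), 1)])]]
          })
      }
      weeks[[w]] <- week_views(pages, wk_start, config)
    }
    # tool reuse on occasions after first exposure
    reused <- c(`15` = FALSE, `16` = FALSE)
    for (tool in c("15", "16")) {
      exposure_week <- if (tool == "15") 1L else 3L
      eligible <- seq_len(active)
      eligible <- eligible[eligible > exposure_week]
      if (active < exposure_week || length(eligible) == 0) next
      n_occ <- min(stats::rpois(1, config$reuse_rate), length(eligible))
      if (n_occ == 0) next
      for (w in eligible[sample.int(length(eligible), n_occ)]) {
        weeks[[w]] <- {
          wk <- weeks[[w]]
          add <- week_views(pages_of[[tool]], wk$end + stats::runif(1, 5, 30),
                            config)
          list(page_id = c(wk$page_id, add$page_id),
               start = c(wk$start, add$start),
               duration_s = c(wk$duration_s, add$duration_s),
               end = add$end)
        }
      }
      reused[tool] <- TRUE
    }
    u_pages[[i]] <- unlist(lapply(weeks, `[[`, "page_id"))
    u_starts[[i]] <- unlist(lapply(weeks, `[[`, "start"))
    u_durs[[i]] <- unlist(lapply(weeks, `[[`, "duration_s"))
    t_last_week[i] <- active
    t_part2[i] <- part2
    t_reused_food[i] <- reused[["15"]]
    t_reused_steps[i] <- reused[["16"]]
  }

  flow <- tibble::tibble(
    user_id = rep(ids, lengths(u_pages)),
    page_id = unlist(u_pages),
    start = as.POSIXct(round(unlist(u_starts)), origin = "1970-01-01",
                       tz = "UTC"),
    duration_s = round(unlist(u_durs), 1))
  truth <- tibble::tibble(
    user_id = ids, last_week = t_last_week, completed_part2 = t_part2,
    reached_session3 = t_last_week >= 3L,
    reused_food_diary = t_reused_food,
    reused_steps_diary = t_reused_steps)

  users <- tibble::tibble(
    user_id = ids,
    age = round(pmax(18, stats::rnorm(n_users, 51.6, 13.0)), 1),
    bmi = round(pmax(28, stats::rnorm(n_users, 35.5, 5.7)), 1),
    arm = sample(c("web", "web_basic_nurse", "web_regular_nurse"),
                 n_users, replace = TRUE),
    eating_plan = sample(c("low_calorie", "low_carbohydrate"),
                         n_users, replace = TRUE),
    activity_plan = sample(c("walking", "mixed"), n_users,
                           replace = TRUE),
    weight_change_kg = round(
      simulate_outcomes(truth$reused_steps_diary, config$beta0,
                        config$beta1, config$sigma_w), 2))

  dataset <- suppressMessages(
    assemble_dataset(flow, cat_$coding, cat_$colors, users, strict = TRUE))
  truth_out <- list(users = truth,
                    config = unclass(config),
                    attrition = attrition_curve(dataset))

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("page_flow.csv", "users.csv", "coding.csv",
                              "colors.csv", "truth.json"))
    names(paths) <- c("page_flow", "users", "coding", "colors", "truth")
    write_page_flow(flow, paths["page_flow"])
    readr::write_csv(users, paths["users"], progress = FALSE)
    readr::write_csv(cat_$coding, paths["coding"], progress = FALSE)
    readr::write_csv(cat_$colors, paths["colors"], progress = FALSE)
    jsonlite::write_json(truth_out, paths["truth"], dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(dataset = dataset, truth = truth_out, paths = paths)
}

#' Per-session retention (nonusage attrition curve)
#'
#' For each page group, the fraction of participants with at least one view
#' of the group. Over tunnelled core sessions the curve is non-increasing,
#' and its shape (steady vs rapid early decay) is the classic diagnostic
#' for the cause of nonusage attrition.
#'
#' @param dataset A `usage_dataset`.
#' @param group_labels Groups to include, in presentation order; defaults
#'   to every group in the coding map.
#' @return A tibble with `group_label`, `code`, `n_viewed`, `fraction`
#'   (denominator = users with any view). Empty flow yields an empty
#'   tibble.
#' @export
attrition_curve <- function(dataset, group_labels = NULL) {
  if (nrow(dataset$flow) == 0) {
    return(tibble::tibble(group_label = character(), code = integer(),
                          n_viewed = integer(), fraction = double()))
  }
  s <- usage_summary(dataset, group_labels)
  tibble::tibble(group_label = s$group_label, code = s$code,
                 n_viewed = s$n_viewed,
                 fraction = s$n_viewed / s$denominator)
}
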