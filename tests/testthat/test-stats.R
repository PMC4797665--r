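test_that("pooled t from printed summaries reproduces published statistics", {
  # weight change by steps-diary reuse: non-reusers (n=119) vs reusers (n=17)
  r <- pooled_t_from_summary(list(n = 119, mean = 2.63, sd = 5.56),
                             list(n = 17, mean = 5.78, sd = 6.87))
  expect_equal(r$statistic, -2.12, tolerance = 0.005)
  expect_equal(r$df, 134)
  expect_lt(r$p, 0.05)
  # age by steps-diary reuse
  r <- pooled_t_from_summary(list(n = 119, mean = 50.52, sd = 12.45),
                             list(n = 17, mean = 58.82, sd = 14.44))
  expect_equal(r$statistic, -2.52, tolerance = 0.005)
  expect_equal(r$df, 134)
})

test_that("identical groups give t = 0 with p = 1", {
  g <- list(n = 10, mean = 4, sd = 2)
  r <- pooled_t_from_summary(g, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(welch_t(g, g)$statistic, 0)
  expect_equal(pooled_t_from_samples(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
})

test_that("sample and summary routes agree, and match the t.test oracle", {
  set.seed(31)
  for (rep in 1:20) {
    x <- stats::rnorm(sample(3:30, 1), 1, 2)
    y <- stats::rnorm(sample(3:30, 1))
    via_samples <- pooled_t_from_samples(x, y)
    via_summary <- pooled_t_from_summary(group_summary(x), group_summary(y))
    expect_equal(via_samples$statistic, via_summary$statistic,
                 tolerance = 1e-12)
    oracle <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(via_samples$statistic, unname(oracle$statistic))
    expect_equal(via_samples$p, oracle$p.value)
    w <- welch_t_from_samples(x, y)
    oracle_w <- stats::t.test(x, y)
    expect_equal(w$statistic, unname(oracle_w$statistic))
    expect_equal(w$df, unname(oracle_w$parameter))
    expect_equal(w$p, oracle_w$p.value)
  }
  expect_error(pooled_t_from_samples(1, c(1, 2)), "n >= 2")
})

test_that("welch equals pooled under equal variances and sample sizes", {
  a <- list(n = 12, mean = 3, sd = 1.5)
  b <- list(n = 12, mean = 4.2, sd = 1.5)
  expect_equal(welch_t(a, b)$statistic,
               pooled_t_from_summary(a, b)$statistic)
  expect_equal(welch_t(a, b)$df, pooled_t_from_summary(a, b)$df)
})

test_that("welch t and df match the textbook formula on a fixed case", {
  # hand-derived: se = sqrt(1/10 + 4/10), t = -1/se = -1.41421;
  # df = 0.25 / (0.01/9 + 0.16/9) = 13.2353
  r <- welch_t(list(n = 10, mean = 0, sd = 1), list(n = 10, mean = 1, sd = 2))
  expect_equal(r$statistic, -1 / sqrt(0.5), tolerance = 1e-9)
  expect_equal(r$df, 0.25 / (0.17 / 9), tolerance = 1e-9)
})

test_that("swapping groups negates t and preserves p; welch df is bounded", {
  set.seed(32)
  for (rep in 1:50) {
    a <- list(n = sample(2:40, 1), mean = stats::rnorm(1),
              sd = stats::runif(1, 0.5, 3))
    b <- list(n = sample(2:40, 1), mean = stats::rnorm(1),
              sd = stats::runif(1, 0.5, 3))
    r_ab <- pooled_t_from_summary(a, b)
    r_ba <- pooled_t_from_summary(b, a)
    expect_equal(r_ab$statistic, -r_ba$statistic)
    expect_equal(r_ab$p, r_ba$p)
    w <- welch_t(a, b)
    expect_lte(w$df, a$n + b$n - 2 + 1e-9)
    expect_equal(w$statistic, -welch_t(b, a)$statistic)
  }
})

test_that("pooled-t p agrees with the exhaustive permutation test (n <= 8)", {
  set.seed(33)
  for (rep in 1:5) {
    x <- stats::rnorm(4, 0.5)
    y <- stats::rnorm(4)
    p_t <- pooled_t_from_samples(x, y)$p
    expect_lt(abs(p_t - perm_t_p(x, y)), 0.15)
  }
})

test_that("chi-square is zero under exact independence", {
  tab <- outer(c(10, 30), c(2, 3)) / 5  # proportional to its margins
  r <- chi_square(tab)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)
})

test_that("chi-square matches the 2x2 closed form", {
  closed_form <- function(m) {
    a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
    sum(m) * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
  }
  m <- matrix(c(10, 30, 20, 40), 2)
  r <- chi_square(m)
  expect_equal(r$statistic, closed_form(m), tolerance = 1e-12)
  expect_equal(r$statistic, 0.7937, tolerance = 1e-4)
  expect_equal(r$df, 1)
  m2 <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(chi_square(m2)$statistic, 10)
  expect_equal(chi_square(m2)$df, 1)
})

test_that("chi-square is permutation-invariant and scales for fixed margins", {
  m <- matrix(c(12, 5, 7, 20, 3, 9), 2)
  r <- chi_square(m)
  expect_equal(chi_square(m[, c(3, 1, 2)])$statistic, r$statistic)
  expect_equal(chi_square(m[c(2, 1), ])$statistic, r$statistic)
  expect_equal(r$df, 2)
  m22 <- matrix(c(10, 30, 20, 40), 2)
  expect_equal(chi_square(5 * m22)$statistic,
               5 * chi_square(m22)$statistic, tolerance = 1e-12)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2)), "zero row or column")
  expect_error(chi_square(matrix(1:3, 1)), "at least 2 x 2")
})

test_that("moderator report dispatches by variable type", {
  set.seed(34)
  n <- 60
  users <- tibble::tibble(
    user_id = sprintf("u%02d", 1:n),
    used = rep(c(0L, 1L), each = n / 2),
    age = stats::rnorm(n, 50, 10) + 5 * rep(c(0, 1), each = n / 2),
    plan = sample(c("low_cal", "low_carb"), n, replace = TRUE),
    weight_change = stats::rnorm(n, 3, 5))
  d <- structure(list(flow = tiny_flow()[0, ], coding = tiny_coding(),
                      colors = tiny_colors(), users = users,
                      n_uncoded_views = 0L, n_unknown_users = 0L),
                 class = "usage_dataset")
  rep_ <- moderator_report(d, "used", c("age", "plan"),
                           outcome = "weight_change", adjust = TRUE)
  expect_equal(rep_$variable, c("age", "plan", "weight_change"))
  expect_equal(rep_$method, c("pooled t", "chi-square", "pooled t"))
  expect_equal(rep_$n0[1], 30)
  expect_true(all(rep_$p_bh >= rep_$p - 1e-12))
  # group-0-minus-group-1 convention: higher mean in group 1 gives t < 0
  expect_lt(rep_$statistic[rep_$variable == "age"], 0)
  # empty variable list: empty report
  expect_equal(nrow(moderator_report(d, "used", character())), 0)
  # constant indicator errors
  users2 <- users; users2$used <- 0L
  d2 <- d; d2$users <- users2
  expect_error(moderator_report(d2, "used", "age"), "constant")
  expect_error(moderator_report(d, "age", "plan"), "binary")
})

test_that("infinite t under zero variance with unequal means is flagged", {
  expect_warning(
    r <- pooled_t_from_summary(list(n = 5, mean = 1, sd = 0),
                               list(n = 5, mean = 2, sd = 0)),
    "infinite")
  expect_true(is.infinite(r$statistic))
})
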