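# Two-group moderator and outcome comparisons on usage-indicator variables:
# pooled and Welch t tests (computable from printed summary statistics as
# well as raw samples) and Pearson chi-square tests, matching the SPSS
# conventions of the analyses they reproduce. Sample SDs use the n - 1
# denominator throughout.

#' Summarise a sample for two-group testing
#'
#' @param x Numeric vector (NAs dropped).
#' @return A `group_summary`: list with `n`, `mean`, `sd` (sample SD,
#'   n - 1 denominator).
#' @export
group_summary <- function(x) {
  x <- x[!is.na(x)]
  structure(list(n = length(x), mean = mean(x), sd = stats::sd(x)),
            class = "group_summary")
}

as_group_summary <- function(g) {
  if (inherits(g, "group_summary")) return(g)
  if (is.list(g) && all(c("n", "mean", "sd") %in% names(g))) {
    return(structure(g[c("n", "mean", "sd")], class = "group_summary"))
  }
  stop("expected a group_summary or list(n, mean, sd)", call. = FALSE)
}

test_result <- function(statistic, df, p, method) {
  tibble::tibble(method = method, statistic = statistic, df = df, p = p)
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' The equal-variance (Student) t test computed directly from each group's
#' n, mean and SD, so printed summary tables can be re-tested without raw
#' data. The first group is conventionally the indicator-0 (non-user)
#' group; with that order the signs match the convention of reporting
#' non-users minus users.
#'
#' @param a,b `group_summary` objects or lists with `n`, `mean`, `sd`;
#'   both `n >= 2`.
#' @return A tibble with `method`, `statistic` (t), `df` (`n1 + n2 - 2`)
#'   and two-sided `p`.
#' @export
pooled_t_from_summary <- function(a, b) {
  a <- as_group_summary(a); b <- as_group_summary(b)
  if (a$n < 2 || b$n < 2) stop("both groups need n >= 2", call. = FALSE)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  if (se == 0) {
    if (a$mean == b$mean) {
      return(test_result(0, df, 1, "pooled t"))
    }
    warning("zero pooled variance with unequal means: t is infinite")
    return(test_result(sign(a$mean - b$mean) * Inf, df, 0, "pooled t"))
  }
  t <- (a$mean - b$mean) / se
  test_result(t, df, 2 * stats::pt(-abs(t), df), "pooled t")
}

#' Pooled-variance two-sample t test from raw samples
#'
#' Summarises both samples and delegates to [pooled_t_from_summary()], so
#' the raw-data and summary-statistics routes agree exactly.
#'
#' @param x,y Numeric vectors, each of length >= 2 after NA removal.
#' @return As [pooled_t_from_summary()].
#' @export
pooled_t_from_samples <- function(x, y) {
  pooled_t_from_summary(group_summary(x), group_summary(y))
}

#' Welch two-sample t test from summary statistics
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom
#' (fractional df in the output signal this variant was used).
#'
#' @inheritParams pooled_t_from_summary
#' @return A tibble with `method`, `statistic`, fractional `df`, two-sided
#'   `p`.
#' @export
welch_t <- function(a, b) {
  a <- as_group_summary(a); b <- as_group_summary(b)
  if (a$n < 2 || b$n < 2) stop("both groups need n >= 2", call. = FALSE)
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  se <- sqrt(va + vb)
  if (se == 0) {
    if (a$mean == b$mean) {
      return(test_result(0, a$n + b$n - 2, 1, "Welch t"))
    }
    warning("zero variance with unequal means: t is infinite")
    return(test_result(sign(a$mean - b$mean) * Inf, a$n + b$n - 2, 0,
                       "Welch t"))
  }
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  t <- (a$mean - b$mean) / se
  test_result(t, df, 2 * stats::pt(-abs(t), df), "Welch t")
}

#' Welch two-sample t test from raw samples
#'
#' @inheritParams pooled_t_from_samples
#' @return As [welch_t()].
#' @export
welch_t_from_samples <- function(x, y) {
  welch_t(group_summary(x), group_summary(y))
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square on an r x c contingency table with expected counts
#' from the margins; df = (r - 1)(c - 1). No continuity correction by
#' default, matching SPSS's printed Pearson statistic for tables beyond
#' 2 x 2.
#'
#' @param table An r x c matrix of non-negative counts, at least 2 x 2.
#' @param correction Apply the Yates continuity correction (2 x 2 only).
#' @return A tibble with `method`, `statistic` (chi-square), integer `df`,
#'   `p`.
#' @export
chi_square <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("table must be at least 2 x 2", call. = FALSE)
  }
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin: expected counts would be 0",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = correction))
  test_result(unname(res$statistic), unname(res$parameter),
              unname(res$p.value), "chi-square")
}

#' Moderator report: compare users vs non-users of a component
#'
#' For a binary usage indicator (see [usage_indicator()]), tests every
#' requested variable between the indicator's two groups: numeric variables
#' by two-sample t test (pooled by default, Welch on request), categorical
#' variables by Pearson chi-square on the indicator x level table. Group 0
#' (non-users) is the first group, so t signs follow the non-users-minus-
#' users convention. No multiplicity adjustment by default; `adjust = TRUE`
#' appends a Benjamini-Hochberg column.
#'
#' @param dataset A `usage_dataset` whose user table holds the indicator.
#' @param indicator Name of a 0/1 column in the user table.
#' @param variables Character vector of user-table columns to test; an
#'   empty vector yields an empty report.
#' @param outcome Optional outcome column appended to `variables`.
#' @param welch Use Welch instead of pooled t for numeric variables.
#' @param adjust Append Benjamini-Hochberg adjusted p values.
#' @return A tibble: `variable`, `method`, `statistic`, `df`, `p`, and for
#'   numeric variables `n0`, `n1`, `mean0`, `sd0`, `mean1`, `sd1`.
#' @export
moderator_report <- function(dataset, indicator, variables,
                             outcome = NULL, welch = FALSE,
                             adjust = FALSE) {
  users <- dataset$users
  if (!indicator %in% names(users)) {
    stop("unknown indicator: ", indicator, call. = FALSE)
  }
  ind <- users[[indicator]]
  if (!all(ind %in% c(0, 1))) {
    stop("indicator must be binary 0/1: ", indicator, call. = FALSE)
  }
  if (length(unique(ind)) < 2) {
    stop("indicator is constant; one group is empty", call. = FALSE)
  }
  variables <- unique(c(variables, outcome))
  rows <- lapply(variables, function(v) {
    if (!v %in% names(users)) stop("unknown variable: ", v, call. = FALSE)
    x <- users[[v]]
    if (is.numeric(x)) {
      g0 <- group_summary(x[ind == 0])
      g1 <- group_summary(x[ind == 1])
      res <- if (welch) welch_t(g0, g1) else pooled_t_from_summary(g0, g1)
      dplyr::bind_cols(tibble::tibble(variable = v), res,
                       tibble::tibble(n0 = g0$n, n1 = g1$n,
                                      mean0 = g0$mean, sd0 = g0$sd,
                                      mean1 = g1$mean, sd1 = g1$sd))
    } else {
      tab <- table(ind, x)
      res <- chi_square(tab)
      dplyr::bind_cols(tibble::tibble(variable = v), res,
                       tibble::tibble(n0 = sum(ind == 0), n1 = sum(ind == 1),
                                      mean0 = NA_real_, sd0 = NA_real_,
                                      mean1 = NA_real_, sd1 = NA_real_))
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(variable = character(), method = character(),
                          statistic = double(), df = double(), p = double(),
                          n0 = integer(), n1 = integer(), mean0 = double(),
                          sd0 = double(), mean1 = double(), sd1 = double())
  }
  if (adjust && nrow(out) > 0) {
    out$p_bh <- stats::p.adjust(out$p, method = "BH")
  }
  out
}

#' Write a moderator report as CSV
#'
#' @param report Tibble from [moderator_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  readr::write_csv(report, path, progress = FALSE)
  invisible(path)
}
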