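group_comparison <- function(method, statistic, value, df = NA_real_,
                             p_value = NA_real_, ...) {
  extra <- list(...)
  out <- tibble::tibble(method = method, statistic = statistic,
                        value = value, df = as.numeric(df),
                        p_value = p_value)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected by default: `chi2 = sum (O - E)^2 / E` with expected counts
#' from the margins and df = 1 (the variant that reproduces printed cohort
#' tables such as sex-by-group counts); Yates continuity correction is a
#' flag.
#'
#' @param counts 2x2 matrix, or length-4 vector `(a, b, c, d)` filling the
#'   table by rows (rows = groups, columns = category levels).
#' @param continuity_correction Apply Yates correction? Default `FALSE`.
#' @return A one-row tibble: `method`, `statistic`, `value`, `df`,
#'   `p_value`, `n`.
#' @export
chi_square_2x2 <- function(counts, continuity_correction = FALSE) {
  if (is.vector(counts) && length(counts) == 4L)
    counts <- matrix(counts, 2, 2, byrow = TRUE)
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L)) && !identical(dim(counts), c(2L, 2L)))
    stop("counts must form a 2x2 table", call. = FALSE)
  if (any(counts < 0) || sum(counts) < 1)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate input: a table margin is zero", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts,
                                           correct = continuity_correction))
  group_comparison("pearson_chi_square", "chi_square",
                   unname(ht$statistic), df = unname(ht$parameter),
                   p_value = ht$p.value, n = sum(counts))
}

#' Mann-Whitney U test
#'
#' Reports `U = min(U_x, U_y)` computed from mid-ranks; the p-value comes
#' from exact enumeration when `n_x * n_y <= 400` and the data are tie-free,
#' otherwise from the normal approximation with tie correction.
#'
#' @param x,y Numeric samples (both nonempty).
#' @return A one-row tibble with `value` = U and group summaries.
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("degenerate input: empty sample", call. = FALSE)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u_y <- nx * ny - u_x
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- (nx * ny <= 400) && !has_ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  group_comparison("mann_whitney_u", "U", min(u_x, u_y),
                   p_value = ht$p.value,
                   n_x = nx, n_y = ny,
                   median_x = stats::median(x), median_y = stats::median(y))
}

#' Two-sample t-test
#'
#' Pooled-variance t with `df = n_x + n_y - 2` by default; Welch's unequal
#' variance form via `pooled = FALSE`.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param pooled Pooled-variance form? Default `TRUE`.
#' @return A one-row tibble with the t statistic, df, p-value and group
#'   means/SDs.
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (pooled && stats::var(x) + stats::var(y) < 1e-24)
    stop("degenerate input: zero pooled variance", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = pooled)
  group_comparison("two_sample_t", "t", unname(ht$statistic),
                   df = unname(ht$parameter), p_value = ht$p.value,
                   n_x = length(x), n_y = length(y),
                   mean_x = mean(x), mean_y = mean(y),
                   sd_x = stats::sd(x), sd_y = stats::sd(y))
}

#' Correlation coefficient
#'
#' @param x,y Numeric vectors of equal length >= 3, non-constant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble with `value` = r and the test p-value.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15)
    stop("degenerate input: constant sample", call. = FALSE)
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  group_comparison(paste0(method, "_correlation"), "r",
                   unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Group-comparison summary table for a cohort
#'
#' Compares every requested variable between two groups, choosing the test
#' per variable: `"t"` (pooled two-sample t), `"u"` (Mann-Whitney) for
#' numeric variables, `"chisq"` for two-level categorical ones. Output rows
#' mirror a demographics table: per-group summaries plus the test statistic.
#'
#' @param data Data frame with one row per subject.
#' @param group Name of a two-level grouping column.
#' @param tests Named character vector mapping variable names to
#'   `"t"`, `"u"` or `"chisq"`.
#' @return A tibble, one row per variable.
#' @export
cohort_summary <- function(data, group, tests) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2L)
    stop("grouping column must have exactly 2 levels", call. = FALSE)
  lv <- levels(g)
  rows <- lapply(names(tests), function(v) {
    kind <- tests[[v]]
    x <- data[[v]][g == lv[1]]
    y <- data[[v]][g == lv[2]]
    res <- switch(kind,
                  t = two_sample_t(x, y),
                  u = mann_whitney_u(x, y),
                  chisq = {
                    tab <- table(g, factor(data[[v]]))
                    chi_square_2x2(matrix(as.numeric(tab), 2, 2))
                  },
                  stop("unknown test '", kind, "' for variable '", v, "'",
                       call. = FALSE))
    tibble::tibble(variable = v, test = res$method,
                   statistic = res$statistic, value = res$value,
                   df = res$df, p_value = res$p_value,
                   summary_1 = if (kind == "chisq")
                     paste(table(data[[v]][g == lv[1]]), collapse = "/")
                   else sprintf("%.1f (%.1f)", mean(x), stats::sd(x)),
                   summary_2 = if (kind == "chisq")
                     paste(table(data[[v]][g == lv[2]]), collapse = "/")
                   else sprintf("%.1f (%.1f)", mean(y), stats::sd(y)))
  })
  do.call(rbind, rows)
}
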