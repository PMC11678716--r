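#' Nonparametric test results
#'
#' Light wrapper type shared by the package's statistical tests.
#'
#' @param statistic Test statistic.
#' @param p_value P-value in (0, 1].
#' @param method Label describing the test variant actually used.
#' @param n1,n2 Sample sizes.
#' @param alternative Alternative hypothesis.
#' @return A `test_result` list.
#' @keywords internal
test_result <- function(statistic, p_value, method, n1, n2 = NA_integer_,
                        alternative = "two.sided") {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n1 = n1, n2 = n2,
                 alternative = alternative),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\nstatistic =", x$statistic, ", p =",
      format(x$p_value, digits = 4), "(", x$alternative, ", n1 =", x$n1,
      ", n2 =", x$n2, ")\n")
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test. The exact permutation distribution is used when
#' the combined sample size is at most 12 and there are no ties; otherwise
#' the normal approximation with tie and continuity correction is used. The
#' reported statistic is the rank sum of `x`; the variant actually used is
#' recorded in the `method` field.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) variant;
#'   `NULL` (default) applies the size/ties rule above.
#' @return A `test_result`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater"),
                              exact = NULL) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- (length(x) + length(y) <= 12L) && !ties
  if (exact && ties) {
    stop("exact Wilcoxon test is unavailable with ties", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  rank_sum <- unname(wt$statistic) + length(x) * (length(x) + 1) / 2
  test_result(rank_sum, wt$p.value,
              method = paste0("Wilcoxon rank-sum (",
                              if (exact) "exact" else
                                "normal approximation, tie/continuity corrected",
                              ")"),
              n1 = length(x), n2 = length(y), alternative = alternative)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with positive
#'   variance.
#' @return A list with `r` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("correlation undefined: fewer than 3 complete pairs", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: zero variance input", call. = FALSE)
  }
  list(r = stats::cor(x, y), n = length(x))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value as the total probability of tables (with the observed
#' margins) no more likely than the observed one.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, c, b, d), 2)`.
#' @return A `test_result`; the statistic is the conditional odds-ratio
#'   estimate.
#' @export
#' @examples
#' fisher_exact_2x2(2, 0, 0, 2)$p_value  # 1/3
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("all-zero table", call. = FALSE)
  m <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(m, alternative = "two.sided")
  test_result(unname(ft$estimate), ft$p.value,
              method = "Fisher's exact test (2x2, two-sided)",
              n1 = sum(m[1, ]), n2 = sum(m[2, ]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at 1, and
#' idempotent.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
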