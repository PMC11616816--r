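#' Mann-Whitney U test with rank-biserial correlation
#'
#' Rank-sum comparison of two independent samples with midrank handling of
#' ties. The p-value is exact for small samples without ties and a
#' tie-corrected normal approximation otherwise (via
#' \code{\link[stats]{wilcox.test}}). The effect size is the rank-biserial
#' correlation \code{2U / (n1 n2) - 1}, the difference between the
#' probability that an x observation exceeds a y observation and the
#' reverse.
#'
#' @param x,y numeric samples.
#' @param exact force or forbid the exact p-value (NULL = automatic).
#' @return list with \code{U} (number of (x, y) pairs with x > y, ties
#'   counting one half), \code{p}, \code{rankBiserial}, \code{n1},
#'   \code{n2}.
#' @export
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, rank-biserial = -1
mannWhitney <- function(x, y, exact = NULL) {
    n1 <- length(x); n2 <- length(y)
    if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    U <- unname(wt$statistic)
    list(U = U, p = wt$p.value, rankBiserial = 2 * U / (n1 * n2) - 1,
         n1 = n1, n2 = n2)
}
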