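#' @title Nonparametric test results
#' @description Light container shared by the nonparametric tests in this
#'   package: the statistic, a two-sided p-value, a method tag and the group
#'   sizes.
#' @name timing_test
#' @keywords internal
NULL

new_timing_test <- function(statistic, p, method, n, flag = NA_character_) {
  structure(
    list(statistic = unname(statistic),
         p_two_sided = unname(p),
         method = method,
         n = n,
         flag = flag),
    class = "timing_test")
}

#' @export
print.timing_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, two-sided p = %.4g (n = %s)%s\n",
              x$method, x$statistic, x$p_two_sided,
              paste(x$n, collapse = "/"),
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Mann-Whitney U test (exact for small tie-free samples)
#'
#' Two-sided rank-sum test used for all pairwise group contrasts. For small
#' samples without ties (`length(x) + length(y) <= exact_n_max`) the exact
#' permutation distribution of U is used; otherwise the normal approximation
#' with midrank tie correction and continuity correction.
#'
#' @param x,y Numeric vectors, both non-empty, no missing values.
#' @param exact_n_max Combined sample size at or below which the exact
#'   distribution is used (ignored when ties are present). Default 12.
#' @return A `timing_test` list: `statistic` (U for the first sample),
#'   `p_two_sided`, `method` ("exact" or "normal_approx"), `n`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact_n_max = 12) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && (length(x) + length(y)) <= exact_n_max
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  p <- ht$p.value
  # all-identical data: z = 0/0 under the tie-corrected approximation
  if (is.nan(p)) p <- 1
  new_timing_test(ht$statistic, min(1, p),
                  if (use_exact) "exact" else "normal_approx",
                  c(n_x = length(x), n_y = length(y)))
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based k-group omnibus test with midrank tie correction; the statistic
#' H is referred to a chi-square distribution with k - 1 degrees of freedom.
#' Degenerate input (every value identical) yields H = 0, p = 1 with a flag.
#'
#' @param groups A list of >= 2 non-empty numeric vectors.
#' @return A `timing_test` list.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of at least two groups")
  if (any(vapply(groups, length, 1L) < 1L)) stop("empty group")
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values)) stop("missing values are not allowed")
  if (length(unique(values)) == 1L) {
    return(new_timing_test(0, 1, "kruskal_wallis",
                           vapply(groups, length, 1L),
                           flag = "degenerate_constant"))
  }
  ht <- stats::kruskal.test(groups)
  new_timing_test(ht$statistic, ht$p.value, "kruskal_wallis",
                  vapply(groups, length, 1L))
}

#' Correlation coefficient with two-sided p-value
#'
#' Pearson or Spearman correlation with the usual t approximation for the
#' two-sided p-value. Zero-variance input is flagged and returns `NA`
#' rather than an error, so callers can mask degenerate genes.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @param method "pearson" (default) or "spearman".
#' @return List with `r`, `p_two_sided`, `method`, `n`, `flag`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_two_sided = NA_real_, method = method,
                n = length(x), flag = "zero_variance"))
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ht$estimate), p_two_sided = ht$p.value, method = method,
       n = length(x), flag = NA_character_)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with the standard monotonicity
#' enforcement (`q_i = min_{j >= i} m p_(j) / j` on the sorted p-values).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(pvals, method = "BH")
}
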