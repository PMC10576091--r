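# Statistical primitives shared by all pipeline stages. Standard tests are
# delegated to the corresponding stats:: routines; the exact rank-sum mode is
# implemented here because base R does not provide exact permutation p-values
# in the presence of ties.

#' Test result container
#'
#' @param statistic Test statistic.
#' @param p_value Two-sided p-value in `[0, 1]`.
#' @param method Human-readable method label (provenance).
#' @param n_x,n_y Sample sizes.
#' @param estimate Optional effect estimate (e.g. correlation coefficient).
#' @return Object of class `test_result`.
#' @export
test_result <- function(statistic, p_value, method, n_x, n_y = NA_integer_,
                        estimate = NULL) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stopf("p-value outside [0, 1]")
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n_x = n_x, n_y = n_y, estimate = estimate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic, digits = 6),
      " p =", format(x$p_value, digits = 6), "\n")
  if (!is.null(x$estimate))
    cat("  estimate =", format(x$estimate, digits = 6), "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment; input order is preserved. The
#' adjustment family is always an explicit argument of the callers (per mark,
#' per comparison), never pooled globally.
#'
#' @param p_values Vector of p-values in `[0, 1]`; `NA`/`NaN` is an error.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values)) stopf("bh_adjust: missing p-value")
  if (any(p_values < 0 | p_values > 1)) stopf("bh_adjust: p-value outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of at least
#' `k` successes in `n` draws without replacement from a population of `N`
#' containing `K` successes.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Number of draws.
#' @param k Observed successes.
#' @return Exact upper-tail probability.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (K > N || n > N) stopf("hypergeom: K and n must not exceed N")
  if (k < 0) stopf("hypergeom: k must be non-negative")
  if (k > K || k > n) stopf("hypergeom: impossible configuration (k > K or k > n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' `mode = "exact"` enumerates the full permutation null of the
#' Mann-Whitney U statistic (valid with ties); the two-sided p-value is
#' `P(|U - n_x n_y / 2| >= |U_obs - n_x n_y / 2|)` over all
#' `choose(n_x + n_y, n_x)` group assignments. `mode = "normal"` uses the
#' tie-corrected normal approximation with continuity correction.
#' `mode = "auto"` picks exact when `n_x + n_y <= 20`.
#'
#' @param x,y Numeric samples.
#' @param mode One of `"auto"`, `"exact"`, `"normal"`.
#' @return A [test_result()] whose statistic is the Mann-Whitney U of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stopf("wilcoxon: both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stopf("wilcoxon: missing values")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (length(unique(pooled)) == 1) {
    warnf("wilcoxon: all values tied across both samples; p = 1")
    return(test_result(u_obs, 1, "Wilcoxon rank-sum (degenerate)", nx, ny))
  }
  if (mode == "auto") mode <- if (nx + ny <= 20) "exact" else "normal"
  if (mode == "exact") {
    idx <- utils::combn(nx + ny, nx)
    rs <- matrix(r[idx], nrow = nx)
    u_all <- colSums(rs) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    return(test_result(u_obs, p, "Wilcoxon rank-sum (exact permutation)", nx, ny))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  test_result(u_obs, wt$p.value,
              "Wilcoxon rank-sum (normal approximation, tie-corrected)", nx, ny)
}

#' Welch two-sample t-test (two-sided)
#'
#' Welch statistic with Satterthwaite degrees of freedom. The degenerate case
#' of zero variance in both groups yields statistic 0 and p = 1 when the
#' means agree, and p = 0 otherwise.
#'
#' @param x,y Numeric samples with at least two values each.
#' @return A [test_result()].
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("welch_t: need >= 2 values per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(test_result(0, 1, "Welch two-sample t-test (degenerate)",
                         length(x), length(y)))
    return(test_result(Inf, 0, "Welch two-sample t-test (degenerate)",
                       length(x), length(y)))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  test_result(tt$statistic, tt$p.value, "Welch two-sample t-test",
              length(x), length(y))
}

#' Pearson correlation with two-sided test
#'
#' @param x,y Paired numeric vectors, `n >= 3`, each with non-zero variance.
#' @return A [test_result()] with `estimate` = r; p-value from the t
#'   transform with n - 2 degrees of freedom.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stopf("pearson_corr: unequal lengths")
  if (length(x) < 3) stopf("pearson_corr: need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stopf("pearson_corr: zero variance (r undefined)")
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result(ct$statistic, ct$p.value, "Pearson correlation (two-sided)",
              length(x), estimate = unname(ct$estimate))
}

#' Euclidean distance matrix between samples
#'
#' @param m Numeric matrix, samples in rows, features in columns; all values
#'   must be finite.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
euclidean_distance_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stopf("euclidean_distance_matrix: need >= 2 samples")
  if (any(!is.finite(m))) stopf("euclidean_distance_matrix: non-finite feature")
  as.matrix(stats::dist(m, method = "euclidean"))
}
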