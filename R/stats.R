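#' One-sample Wilcoxon signed-rank test
#'
#' Two-sided test of symmetry about `mu`. Zero differences are dropped
#' (Wilcoxon convention). The exact null distribution is used for n <= 25
#' when ranks are untied; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param values Numeric vector.
#' @param mu Null location (default 0).
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return One-row tibble: `statistic`, `p_value`, `method`
#'   (`signed_rank_exact` or `signed_rank_normal`), `n` (nonzero
#'   differences used).
#' @export
wilcoxon_signed_rank <- function(values, mu = 0, exact_max = 25) {
  d <- values[!is.na(values)] - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort_velo("all values equal mu: no nonzero differences")
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= exact_max && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    d, mu = 0, alternative = "two.sided", exact = exact, correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = min(1, ht$p.value),
                 method = if (exact) "signed_rank_exact" else "signed_rank_normal",
                 n = n)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test. Exact when both samples have at most
#' `exact_max` observations and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param a,b Numeric vectors.
#' @param exact_max Largest per-group n for the exact distribution
#'   (default 25).
#' @return One-row tibble: `statistic`, `p_value`, `method`, `n` (total).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 25) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) abort_velo("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= exact_max && length(b) <= exact_max && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = "two.sided", exact = exact, correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = min(1, ht$p.value),
                 method = if (exact) "rank_sum_exact" else "rank_sum_normal",
                 n = length(a) + length(b))
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Notched-boxplot summary statistics
#'
#' Hinges are the first and third quartiles (linear-interpolation quantiles,
#' type 7); notches stretch to `median +/- 1.58 * IQR / sqrt(n)`,
#' approximating a 95% confidence interval for the median; whiskers extend
#' to the most extreme data values within `1.5 * IQR` of the hinges.
#'
#' @param values Numeric vector (NAs dropped).
#' @return One-row `boxplot_summary` tibble: `n`, `median`, `hinge_lo`,
#'   `hinge_hi`, `notch_lo`, `notch_hi`, `whisker_lo`, `whisker_hi`.
#' @export
boxplot_summary <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) == 0) abort_velo("no non-missing values")
  n <- length(x)
  med <- stats::median(x)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  notch <- 1.58 * iqr / sqrt(n)
  out <- tibble::tibble(
    n = n, median = med, hinge_lo = q[1], hinge_hi = q[2],
    notch_lo = med - notch, notch_hi = med + notch,
    whisker_lo = min(x[x >= q[1] - 1.5 * iqr]),
    whisker_hi = max(x[x <= q[2] + 1.5 * iqr]))
  structure(out, class = c("boxplot_summary", class(out)))
}

#' Per-gene MA values (mean normalized count, log2 fold change)
#'
#' Counts are divided by their sample's size factor before averaging within
#' condition; the reported M value is
#' `log2((mean treated + pseudo) / (mean control + pseudo))` and A the mean
#' normalized count over all samples.
#'
#' @param counts Wide count tibble (`feature_id` x samples).
#' @param sf Size-factor tibble covering all count columns.
#' @param samples Tibble mapping `sample` to `condition`.
#' @param control,treated Condition names.
#' @param pseudo Pseudo-count (default 1).
#' @return Tibble `gene_id`, `base_mean`, `log2_fc`.
#' @export
ma_table <- function(counts, sf, samples, control = "control",
                     treated = "treated", pseudo = 1) {
  assert_columns(samples, c("sample", "condition"), "sample table")
  norm <- apply_size_factors(counts, sf)
  cols <- setdiff(names(norm), "feature_id")
  cond <- samples$condition[match(cols, samples$sample)]
  if (anyNA(cond)) abort_velo("every count column needs a condition in `samples`")
  m <- as.matrix(norm[, cols])
  mean_c <- rowMeans(m[, cond == control, drop = FALSE])
  mean_t <- rowMeans(m[, cond == treated, drop = FALSE])
  tibble::tibble(gene_id = norm$feature_id,
                 base_mean = rowMeans(m),
                 log2_fc = log2((mean_t + pseudo) / (mean_c + pseudo)))
}
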