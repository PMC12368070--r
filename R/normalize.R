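#' Median-of-ratios size factors
#'
#' For each anchor row a pseudo-reference is the geometric mean of its counts
#' across samples; rows containing any zero are excluded. A sample's size
#' factor is the median over rows of count / reference. Factors are not
#' rescaled to geometric mean 1: only their ratios matter downstream.
#'
#' @param counts Wide count tibble (`feature_id` x samples) restricted to
#'   the anchor rows (spike-ins, or non-transcribed regions for ChIP).
#' @return A size-factor tibble (`sample`, `size_factor`), all factors > 0.
#' @examples
#' counts <- tibble::tibble(feature_id = c("a", "b", "c"),
#'                          s1 = c(100L, 10L, 50L), s2 = c(200L, 20L, 100L))
#' size_factors(counts)  # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts) {
  assert_columns(counts, "feature_id", "count table")
  samples <- setdiff(names(counts), "feature_id")
  if (length(samples) == 0) abort_velo("count table has no sample columns")
  m <- as.matrix(counts[, samples])
  usable <- rowSums(m > 0) == ncol(m) & rowSums(!is.finite(m)) == 0
  if (!any(usable)) {
    abort_velo("no usable anchor rows: every row contains a zero")
  }
  m <- m[usable, , drop = FALSE]
  logref <- rowMeans(log(m))
  # median taken on the log scale (geometric interpolation at even row
  # counts), matching the DESeq2 median-of-ratios definition
  f <- exp(apply(log(m) - logref, 2, stats::median))
  tibble::tibble(sample = samples, size_factor = as.numeric(f))
}

#' Spike-in size factors (TT-seq / mNET-seq)
#'
#' Delegates to [size_factors()] on the labeled spike-in rows only: 4sU
#' selection retains labeled spikes, so they are the usable anchors.
#'
#' @param counts Wide count tibble containing spike-in rows.
#' @param spikes Spike-in annotation tibble with `spike_id` and `labeled`.
#' @return A size-factor tibble.
#' @export
spikein_size_factors <- function(counts, spikes) {
  assert_columns(spikes, c("spike_id", "labeled"), "spike table")
  keep <- counts$feature_id %in% spikes$spike_id[spikes$labeled]
  if (!any(keep)) abort_velo("no labeled spike-in rows in the count table")
  size_factors(counts[keep, ])
}

#' ChIP-seq background size factors from non-transcribed regions
#'
#' @param counts Wide count tibble of ChIP counts at non-transcribed regions
#'   (validated with [nontranscribed_regions()] at construction).
#' @return A size-factor tibble.
#' @export
background_size_factors <- function(counts) {
  size_factors(counts)
}

#' Divide counts or track values by per-sample size factors
#'
#' @param x A wide count tibble (`feature_id` x samples) or a run-length
#'   track tibble (then `sf` must be a single positive number).
#' @param sf A size-factor tibble, or a single positive number for a track.
#' @return `x` with values divided by the factor(s).
#' @export
apply_size_factors <- function(x, sf) {
  if (is.numeric(sf) && length(sf) == 1) {
    if (sf <= 0) abort_velo("size factor must be > 0")
    if (!"value" %in% names(x)) abort_velo("scalar factor requires a track")
    x$value <- x$value / sf
    return(x)
  }
  assert_columns(sf, c("sample", "size_factor"), "size factors")
  if (any(sf$size_factor <= 0)) abort_velo("size factors must be > 0")
  assert_columns(x, "feature_id", "count table")
  for (i in seq_len(nrow(sf))) {
    s <- sf$sample[i]
    if (s %in% names(x)) x[[s]] <- x[[s]] / sf$size_factor[i]
  }
  x
}
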