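test_that("scaled profiles orient, average and conserve body mass", {
  g <- toy_gene("g1", start = 1000L, end = 2000L, strand = "+")
  const <- tibble::tibble(chrom = "chr1", strand = "+", start = 0L,
                          end = 10000L, value = 4)
  p <- scaled_profile(const, g, n_body_bins = 10, flank_bp = 500,
                      flank_bins = 5)
  expect_equal(p, rep(4, 20))

  # minus-strand gene over a ramp track: profile must be decreasing
  gm <- toy_gene("gm", start = 1000L, end = 2000L, strand = "-")
  ramp <- tibble::tibble(chrom = "chr1", strand = "-",
                         start = 0:9999, end = 1:10000, value = as.numeric(0:9999))
  pm <- scaled_profile(ramp, gm, n_body_bins = 10, flank_bp = 500,
                       flank_bins = 5)
  expect_true(all(diff(pm) < 0))

  # body mass conservation: sum(bin mean x span) = per-base sum over the body
  set.seed(77)
  spots <- sort(sample(1000:1999, 30))
  spot_track <- tibble::tibble(chrom = "chr1", strand = "+",
                               start = spots, end = spots + 1L, value = 1)
  p3 <- scaled_profile(spot_track, g, n_body_bins = 10, flank_bp = 500,
                       flank_bins = 5)
  expect_equal(sum(p3[6:15] * 100), 30)
  # too-short gene skipped with a warning
  tiny <- toy_gene("t", start = 0L, end = 50L)
  expect_warning(out <- scaled_profile(spot_track, tiny, n_body_bins = 100),
                 "shorter")
  expect_null(out)
})

test_that("log2 transform with pseudo-count maps 0/1/3 to 0/1/2", {
  expect_equal(log2_pseudo(c(0, 1, 3)), c(0, 1, 2))
  expect_error(log2_pseudo(-1), "non-negative")
})

test_that("bootstrap CI collapses exactly for degenerate inputs", {
  # single gene: every resample is identical
  m1 <- matrix(c(1, 2, 3), nrow = 1)
  ci <- bootstrap_mean_ci(m1, iters = 500, seed = 1)
  expect_equal(ci$ci_lo, ci$ci_hi)
  expect_equal(ci$mean, c(1, 2, 3))
  # identical rows likewise
  m2 <- matrix(5, nrow = 10, ncol = 4)
  ci2 <- bootstrap_mean_ci(m2, iters = 500, seed = 2)
  expect_true(all(ci2$ci_lo == 5 & ci2$ci_hi == 5))
  expect_error(bootstrap_mean_ci(m2, iters = 0), "iters")
})

test_that("two-gene bootstrap matches the exact enumeration", {
  # rows {0, 2}: resampled means take values {0, 1, 2} with probabilities
  # {1/4, 1/2, 1/4}; at 95% the percentile interval is [0, 2]
  m <- matrix(c(0, 2), nrow = 2)
  ci <- bootstrap_mean_ci(m, iters = 10000, seed = 3)
  expect_equal(ci$mean, 1)
  expect_equal(c(ci$ci_lo, ci$ci_hi), c(0, 2))
  # and the resample distribution itself matches the enumeration
  set.seed(3)
  w <- stats::rmultinom(10000, 2, c(1, 1)) / 2
  boot <- as.numeric(crossprod(w, m))
  freq <- table(factor(boot, levels = c(0, 1, 2))) / 10000
  expect_lt(max(abs(as.numeric(freq) - c(0.25, 0.5, 0.25))), 0.02)
})

test_that("bootstrap is deterministic given a seed", {
  m <- matrix(rnorm(50), nrow = 10)
  a <- bootstrap_mean_ci(m, iters = 200, seed = 9)
  b <- bootstrap_mean_ci(m, iters = 200, seed = 9)
  expect_identical(a, b)
})

test_that("length quartiles partition genes with remainder-to-short rule", {
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:8), chrom = "c",
                          start = 0L, end = as.integer((1:8) * 1000),
                          strand = "+", biotype = "pc")
  q <- length_quartile_groups(genes)
  expect_equal(as.character(q$quartile),
               rep(c("shortest", "short", "long", "longest"), each = 2))
  # n = 5: sizes 2,1,1,1
  q5 <- length_quartile_groups(genes[1:5, ])
  expect_equal(as.integer(table(q5$quartile)), c(2L, 1L, 1L, 1L))
  # equal lengths: ties broken by gene_id, partition exact
  eq <- genes
  eq$end <- 1000L
  qe <- length_quartile_groups(eq)
  expect_equal(qe$quartile[order(qe$gene_id)][1:2],
               factor(c("shortest", "shortest"),
                      levels = levels(qe$quartile)))
  expect_false(anyNA(qe$quartile))
})

test_that("TSS-aligned change matrix computes log2 change with NA on silence", {
  g <- toy_gene("g1", start = 0L, end = 10000L, strand = "+")
  ctrl <- tibble::tibble(chrom = "chr1", strand = "+", start = 0L, end = 50L,
                         value = 3 / 50)
  trt <- tibble::tibble(chrom = "chr1", strand = "+", start = 0L, end = 50L,
                        value = 7 / 50)
  am <- tss_aligned_change_matrix(ctrl, trt, g, bin_width = 50,
                                  window_bp = 200)
  expect_equal(am$change[1], log2(8) - log2(4))
  expect_true(all(is.na(am$change[2:4])))  # both zero -> NA
  expect_equal(unique(am$end_bin), 200L)   # 10 kb gene at 50 bp bins
})

test_that("center-aligned matrix masks bins outside the gene body", {
  g <- toy_gene("g1", start = 1000L, end = 3000L, strand = "+")
  tr <- tibble::tibble(chrom = "chr1", strand = ".", start = 0L, end = 5000L,
                       value = 1)
  cm <- center_aligned_matrix(tr, g, bin_width = 500, window_bins = 8)
  expect_equal(sum(!is.na(cm$value)), 4)  # exactly 4 bins fully inside
  expect_true(all(cm$value[!is.na(cm$value)] == 500))
  # signal outside the body never appears: spike upstream is masked
  tr2 <- tibble::tibble(chrom = "chr1", strand = ".", start = 0L, end = 999L,
                        value = 100)
  cm2 <- center_aligned_matrix(tr2, g, bin_width = 500, window_bins = 8)
  expect_true(all(is.na(cm2$value) | cm2$value == 0))
  # symmetric signal in a symmetric gene gives a symmetric row
  tr3 <- tibble::tibble(chrom = "chr1", strand = ".",
                        start = c(1000L, 2500L), end = c(1500L, 3000L),
                        value = 2)
  cm3 <- center_aligned_matrix(tr3, g, bin_width = 500, window_bins = 8)
  v <- cm3$value
  expect_equal(v, rev(v))
})

test_that("profiles of summed replicates equal profiles of the summed track", {
  g <- toy_gene("g1", start = 0L, end = 2000L, strand = "+")
  r1 <- toy_records(seq(0, 1900, 100), seq(0, 1900, 100) + 80L, "+", sample = "a")
  r2 <- toy_records(seq(50, 1950, 100), seq(50, 1950, 100) + 80L, "+", sample = "b")
  sf <- tibble::tibble(sample = c("a", "b"), size_factor = c(1, 1))
  combined <- coverage_track(dplyr::bind_rows(r1, r2), sf)
  p_combined <- scaled_profile(combined, g, n_body_bins = 20, flank_bp = 100,
                               flank_bins = 2)
  # summing the two per-sample tracks by concatenating records is definitional
  manual <- coverage_track(dplyr::bind_rows(r1, r2))
  p_manual <- scaled_profile(manual, g, n_body_bins = 20, flank_bp = 100,
                             flank_bins = 2)
  expect_equal(p_combined, p_manual)
})

test_that("bootstrap CI approximately attains nominal coverage", {
  # 300 replicate Gaussian datasets of 100 genes; nominal 95%
  hits <- vapply(1:300, function(r) {
    m <- matrix(stats::rnorm(100, mean = 1), ncol = 1)
    ci <- bootstrap_mean_ci(m, iters = 500, seed = 1000 + r)
    ci$ci_lo[1] <= 1 && 1 <= ci$ci_hi[1]
  }, logical(1))
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})
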