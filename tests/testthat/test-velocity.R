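make_binned <- function(df, bin_width = 50) {
  structure(df, bin_width = bin_width)
}

test_that("per-bin velocity is the normalized TT/mNET ratio with NA where mNET is 0", {
  genes <- toy_gene("g1", start = 0L, end = 150L, strand = "+")
  tt <- make_binned(tibble::tibble(sample = "tt1", chrom = "chr1", strand = "+",
                                   start = c(0L, 50L), end = c(50L, 100L),
                                   value = c(200, 100)))
  mn <- make_binned(tibble::tibble(sample = "mn1", chrom = "chr1", strand = "+",
                                   start = c(0L, 100L), end = c(50L, 150L),
                                   value = c(100, 40)))
  sft <- tibble::tibble(sample = "tt1", size_factor = 1)
  sfm <- tibble::tibble(sample = "mn1", size_factor = 1)
  vm <- velocity_bins(tt, mn, sft, sfm, genes)
  expect_equal(vm$ratio, c(2, NA, 0))  # bin2: mnet 0 -> NA; bin3: tt 0/40
  # normalization: doubling the TT factor halves the ratio
  vm2 <- velocity_bins(tt, mn, tibble::tibble(sample = "tt1", size_factor = 2),
                       sfm, genes)
  expect_equal(vm2$ratio[1], 1)
  # grid mismatch is an error
  expect_error(velocity_bins(make_binned(tt, 100), mn, sft, sfm, genes),
               "mismatch")
})

test_that("minus-strand genes read velocity bins TSS-first", {
  genes <- toy_gene("gm", start = 0L, end = 100L, strand = "-")
  tt <- make_binned(tibble::tibble(sample = "t", chrom = "chr1", strand = "-",
                                   start = c(0L, 50L), end = c(50L, 100L),
                                   value = c(10, 30)))
  mn <- make_binned(tibble::tibble(sample = "m", chrom = "chr1", strand = "-",
                                   start = c(0L, 50L), end = c(50L, 100L),
                                   value = c(10, 10)))
  vm <- velocity_bins(tt, mn, tibble::tibble(sample = "t", size_factor = 1),
                      tibble::tibble(sample = "m", size_factor = 1), genes)
  # TSS of a minus gene is at the right edge: bin order reversed
  expect_equal(vm$ratio, c(3, 1))
})

test_that("per-gene velocity excludes the first kb and is scale invariant", {
  g <- toy_gene("g1", start = 0L, end = 6000L, strand = "+")
  # TT fragments: 4 in the trimmed body, 5 upstream of +1 kb (excluded)
  tt <- toy_records(c(seq(100, 900, 200), seq(2000, 5000, 1000)),
                    c(seq(100, 900, 200), seq(2000, 5000, 1000)) + 100L, "+",
                    sample = "tt1")
  mn <- toy_records(seq(1500, 5500, 2000), seq(1500, 5500, 2000) + 1L, "+",
                    sample = "mn1")
  sft <- tibble::tibble(sample = "tt1", size_factor = 1)
  sfm <- tibble::tibble(sample = "mn1", size_factor = 1)
  v <- velocity_per_gene(tt, mn, g, sft, sfm)
  expect_equal(v$tt_norm, 4)
  expect_equal(v$mnet_norm, 3)
  expect_equal(v$velocity_ratio, 4 / 3)
  # doubling both factors leaves the ratio unchanged
  v2 <- velocity_per_gene(tt, mn, g,
                          tibble::tibble(sample = "tt1", size_factor = 2),
                          tibble::tibble(sample = "mn1", size_factor = 2))
  expect_equal(v2$velocity_ratio, v$velocity_ratio)
  # short gene -> NA with warning, not an error
  gs <- toy_gene("tiny", start = 0L, end = 900L)
  expect_warning(vs <- velocity_per_gene(tt, mn, gs, sft, sfm), "shorter")
  expect_true(is.na(vs$velocity_ratio))
})

test_that("log2 velocity change divides conditions and propagates NA", {
  treated <- tibble::tibble(gene_id = c("a", "b", "c"),
                            velocity_ratio = c(1, 4, NA))
  control <- tibble::tibble(gene_id = c("a", "b", "c"),
                            velocity_ratio = c(2, 4, 5))
  chg <- velocity_log2_change(treated, control)
  expect_equal(chg$log2_change, c(-1, 0, NA))
})

test_that("tilt statistic equals the direct quartile-window averages", {
  expect_equal(tilt_statistic(rep(3, 20)), 0)
  # linear decline: oracle = mean(last quartile) - mean(first quartile)
  x <- seq(10, 2, length.out = 40)
  m <- 10
  oracle <- mean(x[31:40]) - mean(x[1:10])
  expect_equal(tilt_statistic(x), oracle)
  expect_lt(tilt_statistic(x), 0)
  # ascending profile has positive sign
  expect_gt(tilt_statistic(1:12), 0)
  # odd lengths use floor(n/4) per window
  y <- c(1, 5, 9, 2, 7)
  expect_equal(tilt_statistic(y), 7 - 1)
  expect_true(is.na(tilt_statistic(numeric(0))))
})

test_that("per-bin velocity of a constant-velocity gene flattens with depth", {
  # coefficient of variation across bins decreases as depth grows
  gn <- synthetic_genome(1, c(40e3, 40e3), seed = 6)
  kin <- kinetics_spec(4, 2)
  cond <- condition_spec("c", 1, 0)
  cv_at <- function(depth_mult, seed) {
    ds <- emit_dataset(gn, kin, cond,
                       sampling_spec(ttseq_depth = 2 * depth_mult,
                                     mnet_depth = 40 * depth_mult),
                       replicates = 1, assays = c("ttseq", "mnet"),
                       spikes = NULL, seed = seed)
    tt <- bin_track(coverage_track(fragment_midpoints(
      ds$records$ttseq)), 50)
    mn <- bin_track(coverage_track(ds$records$mnet), 50)
    vm <- velocity_bins(make_binned(dplyr::mutate(tt, sample = "t"), 50),
                        make_binned(dplyr::mutate(mn, sample = "m"), 50),
                        tibble::tibble(sample = "t", size_factor = 1),
                        tibble::tibble(sample = "m", size_factor = 1),
                        gn$genes)
    # interior bins only (edges are partially covered)
    r <- vm$ratio[10:(max(vm$bin_index) - 10)]
    stats::sd(r, na.rm = TRUE) / mean(r, na.rm = TRUE)
  }
  expect_lt(cv_at(8, seed = 41), cv_at(1, seed = 40))
})
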