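test_that("trajectory positions integrate piecewise-linear motion", {
  g <- toy_gene()
  kin <- kinetics_spec(1, 1)  # 1 kb/min
  ctrl <- condition_spec("ctrl", 1, 0)
  tr <- forced_trajectories(c(0, 10, 20), g, kin, ctrl)
  expect_equal(trajectory_positions(tr, 25), c(25000, 15000, 5000))

  # velocity halves at onset 20: 10 min at 1 kb/min + 10 min at 0.5 kb/min
  half <- condition_spec("d", 0.5, onset_time = 20)
  tr2 <- forced_trajectories(10, g, kin, half)
  expect_equal(trajectory_positions(tr2, 30), 15000)

  # piecewise profile: 2 kb/min over first 10 kb, 1 kb/min after
  kin2 <- kinetics_spec(1, c(2, 1), segment_ends = c(10000, 60000))
  tr3 <- forced_trajectories(0, g, kin2, ctrl)
  expect_equal(trajectory_positions(tr3, 5), 10000)
  expect_equal(trajectory_positions(tr3, 15), 20000)

  # not-yet-initiated trajectories are NA; terminated cap at gene length
  expect_true(is.na(trajectory_positions(forced_trajectories(50, g, kin, ctrl), 40)))
  expect_equal(trajectory_positions(forced_trajectories(0, g, kin, ctrl), 500), 60000)
})

test_that("zero initiation rate yields no trajectories; invalid specs rejected", {
  g <- toy_gene()
  tr <- simulate_trajectories(g, kinetics_spec(0, 1), condition_spec("c"),
                              horizon = 100, seed = 1)
  expect_equal(nrow(tr), 0)
  expect_error(kinetics_spec(1, 0), "velocity")
  expect_error(kinetics_spec(1, -2), "velocity")
  expect_error(simulate_trajectories(g, kinetics_spec(1, 1),
                                     condition_spec("c"), horizon = -5),
               "horizon")
  expect_error(condition_spec("c", velocity_factor = 0), "velocity_factor")
})

test_that("engaged positions map offsets to genomic bases respecting strand", {
  kin <- kinetics_spec(1, 1)
  ctrl <- condition_spec("ctrl")
  gp <- toy_gene(strand = "+")
  tags <- engaged_positions(forced_trajectories(0, gp, kin, ctrl), 25)
  expect_equal(tags$start, 26000)  # offset 25000 from TSS at 1000
  expect_equal(tags$end, 26001)
  expect_equal(tags$strand, "+")

  gm <- toy_gene(strand = "-")
  tags_m <- engaged_positions(forced_trajectories(0, gm, kin, ctrl), 25)
  expect_equal(tags_m$start, 60999 - 25000)  # reflected from the - TSS
  expect_equal(tags_m$strand, "-")

  # terminated polymerases emit nothing
  expect_equal(nrow(engaged_positions(forced_trajectories(0, gp, kin, ctrl), 100)), 0)
})

test_that("labeled intervals cover exactly the segment transcribed in the window", {
  g <- toy_gene(strand = "+")
  kin <- kinetics_spec(1, 1)
  ctrl <- condition_spec("ctrl")
  # init at 58: offsets [2000, 7000) -> genome [3000, 8000)
  iv <- labeled_intervals(forced_trajectories(58, g, kin, ctrl), c(60, 65))
  expect_equal(iv$start, 3000)
  expect_equal(iv$end, 8000)
  # initiation after the window: nothing labeled
  expect_equal(nrow(labeled_intervals(forced_trajectories(66, g, kin, ctrl),
                                      c(60, 65))), 0)
  # initiation inside the window: clipped at offset 0
  iv2 <- labeled_intervals(forced_trajectories(62, g, kin, ctrl), c(60, 65))
  expect_equal(c(iv2$start, iv2$end), c(1000, 4000))
  # minus-strand gene reflects the interval
  gm <- toy_gene(strand = "-")
  iv3 <- labeled_intervals(forced_trajectories(58, gm, kin, ctrl), c(60, 65))
  expect_equal(c(iv3$start, iv3$end), c(61000 - 7000, 61000 - 2000))
  expect_error(labeled_intervals(forced_trajectories(0, g, kin, ctrl),
                                 c(65, 60)), "window")
})

test_that("fragment sampling hits its Poisson expectation and stays in bounds", {
  iv <- tibble::tibble(chrom = "chr1", start = 10000L, end = 15000L, strand = "+")
  # expectation: 5 kb x 10/kb = 50 fragments
  n_obs <- vapply(1:1000, function(s) {
    nrow(fragment_records(iv, c(150, 300), depth_per_kb = 10, seed = s))
  }, numeric(1))
  se <- sqrt(50 / 1000)
  expect_lt(abs(mean(n_obs) - 50), 3 * se)

  fr <- fragment_records(iv, c(150, 300), depth_per_kb = 50, seed = 7)
  expect_true(all(fr$start >= 10000 & fr$end <= 15000))
  expect_true(all(fr$end > fr$start))
  expect_true(all(fr$end - fr$start <= 300))
  expect_equal(nrow(fragment_records(iv[0, ], c(150, 300), 10, seed = 1)), 0)
  expect_error(fragment_records(iv, c(300, 150), 10, seed = 1), "fragment_length")
})

test_that("spike-in emission matches copies x scale with Poisson noise", {
  spk <- spikein_set(copies = 1000)
  one <- spk[spk$labeled, ][1, ]
  n_obs <- vapply(1:500, function(s) {
    nrow(emit_spikeins(one, library_scale = 2, seed = s))
  }, numeric(1))
  se <- sqrt(2000 / 500)
  expect_lt(abs(mean(n_obs) - 2000), 3 * se)

  # perfect 4sU selection: unlabeled spikes vanish
  unl <- spk[!spk$labeled, ]
  expect_equal(nrow(emit_spikeins(unl, library_scale = 5, seed = 3)), 0)
  # doubling the scale doubles counts in expectation (paired seeds)
  r1 <- vapply(1:300, function(s) nrow(emit_spikeins(one, 1, seed = s)), 0)
  r2 <- vapply(1:300, function(s) nrow(emit_spikeins(one, 2, seed = s + 500)), 0)
  expect_lt(abs(mean(r2) / mean(r1) - 2), 0.15)
  expect_error(emit_spikeins(spk, library_scale = 0, seed = 1), "library_scale")
})

test_that("ChIP emission separates gene-body signal from scaled background", {
  gn <- synthetic_genome(20, c(5e3, 20e3), seed = 5)
  # background-only: counts scale with library_scale
  b1 <- emit_chip(gn$genes, gn$chrom_sizes, signal_rate = 0,
                  background_rate = 10, library_scale = 1, seed = 1)
  b3 <- emit_chip(gn$genes, gn$chrom_sizes, signal_rate = 0,
                  background_rate = 10, library_scale = 3, seed = 2)
  expect_lt(abs(nrow(b3) / nrow(b1) - 3), 0.1)
  expect_true(all(b1$strand == "."))
  # zero everything -> empty; empty genome rejected
  expect_equal(nrow(emit_chip(gn$genes, gn$chrom_sizes, 0, 0, seed = 1)), 0)
  expect_error(emit_chip(gn$genes, gn$chrom_sizes[0, ], 1, 1, seed = 1), "empty")
  # block signal over gene bodies: >= 95% of signal fragments touch a gene
  sig <- emit_chip(gn$genes, gn$chrom_sizes, signal_rate = 5,
                   background_rate = 0, seed = 3)
  cnt <- count_features(sig, gn$genes, ignore_strand = TRUE)
  cs <- counting_summary(cnt)
  expect_gte((cs$assigned + cs$ambiguous) / nrow(sig), 0.95)
})

test_that("steady-state occupancy and pulse laws hold", {
  # occupancy ~ I/v: halving velocity doubles mean mNET tags per bin;
  # labeled TT-seq output is velocity-invariant (both within 5%)
  gn <- synthetic_genome(60, c(10e3, 40e3), spacing = 10e3, seed = 9)
  kin <- kinetics_spec(2, 2)
  conds <- list(condition_spec("fast", 1, 0),
                condition_spec("slow", 0.5, onset_time = -1e4))
  ds <- emit_dataset(gn, kin, conds, sampling_spec(), replicates = 1,
                     assays = c("ttseq", "mnet"), seed = 17)
  body_mass <- function(rec) {
    rec <- rec[rec$chrom == "chrSim", ]
    cnt <- count_features(rec, gn$genes)
    sum(as.matrix(cnt[, -1]))
  }
  mnet_ratio <- body_mass(records_of(ds, "mnet", "slow")) /
    body_mass(records_of(ds, "mnet", "fast"))
  expect_lt(abs(mnet_ratio - 2), 0.1)
  tt_ratio <- body_mass(records_of(ds, "ttseq", "slow")) /
    body_mass(records_of(ds, "ttseq", "fast"))
  expect_lt(abs(tt_ratio - 1), 0.05)
})

test_that("after a velocity drop, labeled coverage tilts down only beyond the wavefront", {
  # with factor 0.5 at onset 0 and labeling at [60, 65] min, positions beyond
  # the post-onset wavefront are supplied at the old polymerase flux: the
  # last-10%/first-10% coverage ratio is v_new/v_old = 0.5 for very long
  # genes and ~1 for short, re-equilibrated genes
  long_genes <- tibble::tibble(gene_id = sprintf("L%02d", 1:16), chrom = "chrSim",
                               start = as.integer(seq(0, by = 160e3, length.out = 16)),
                               end = as.integer(seq(0, by = 160e3, length.out = 16) + 140e3),
                               strand = "+", biotype = "pc")
  short_genes <- tibble::tibble(gene_id = sprintf("S%02d", 1:24), chrom = "chrSim",
                                start = as.integer(seq(2.6e6, by = 40e3, length.out = 24)),
                                end = as.integer(seq(2.6e6, by = 40e3, length.out = 24) + 30e3),
                                strand = "+", biotype = "pc")
  genes <- dplyr::bind_rows(long_genes, short_genes)
  gn <- list(genes = genes, chrom_sizes = tibble::tibble(chrom = "chrSim",
                                                         size = 3.6e6))
  kin <- kinetics_spec(6, 2)
  depl <- condition_spec("depl", 0.5, onset_time = 0)
  ds <- emit_dataset(gn, kin, depl, sampling_spec(ttseq_depth = 4),
                     replicates = 2, assays = "ttseq", spikes = NULL, seed = 23)
  tr <- coverage_track(ds$records$ttseq)
  edge_ratio <- function(g) {
    sub <- tr[tr$strand == g$strand, ]
    L <- g$end - g$start
    first <- sum(velocitt:::.track_window(sub, g$start, g$start + L %/% 10))
    last <- sum(velocitt:::.track_window(sub, g$end - L %/% 10, g$end))
    last / first
  }
  long_r <- vapply(seq_len(nrow(long_genes)),
                   function(i) edge_ratio(long_genes[i, ]), 0)
  short_r <- vapply(seq_len(nrow(short_genes)),
                    function(i) edge_ratio(short_genes[i, ]), 0)
  expect_lt(abs(mean(long_r) - 0.5), 0.1)
  expect_lt(abs(mean(short_r) - 1), 0.15)
})

test_that("emit_dataset is deterministic and bookkeeps truth", {
  gn <- synthetic_genome(5, c(5e3, 10e3), seed = 3)
  kin <- kinetics_spec(2, 2)
  conds <- list(condition_spec("control", 1, 0),
                condition_spec("treated", 0.5, 0))
  d1 <- emit_dataset(gn, kin, conds, sampling_spec(), replicates = 2, seed = 11)
  d2 <- emit_dataset(gn, kin, conds, sampling_spec(), replicates = 2, seed = 11)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$truth, d2$truth)
  # truth records the velocity ratio exactly
  tw <- tidyr::pivot_wider(d1$truth[, c("gene_id", "condition",
                                        "mean_velocity_kb_min")],
                           names_from = "condition",
                           values_from = "mean_velocity_kb_min")
  expect_equal(tw$treated / tw$control, rep(0.5, 5))
  # emitted coordinates in bounds, tags width 1
  mn <- d1$records$mnet[d1$records$mnet$chrom == "chrSim", ]
  expect_true(all(mn$end - mn$start == 1))
  expect_true(all(mn$start >= 0 & mn$end <= gn$chrom_sizes$size))
})
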