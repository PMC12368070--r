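#' Default pipeline configuration
#'
#' Analysis defaults follow the study design the package models: 50-bp
#' velocity bins, 500-bp ChIP bins, RPK > 10 expression threshold, 10,000
#' bootstrap iterations, pseudo-count 1, first 1 kb of the gene body
#' excluded from per-gene velocity, a 5-minute label pulse starting 60
#' minutes after perturbation onset, and a two-condition design (control
#' vs. velocity halved at onset 0).
#'
#' @return A nested configuration list (see the fields of the returned
#'   object); any subset of the same shape can be supplied as overrides to
#'   [pipeline_config()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    replicates = 2L,
    assays = c("ttseq", "mnet", "chip"),
    library_scales = 1,
    genome = list(n_genes = 20L, length_min = 10000L, length_max = 100000L,
                  spacing = 20000L),
    kinetics = list(initiation_rate = 2, velocity = 2),
    conditions = list(
      list(name = "control", velocity_factor = 1, onset_time = 0),
      list(name = "treated", velocity_factor = 0.5, onset_time = 0)),
    sampling = list(label_start = 60, label_duration = 5,
                    ttseq_depth = 2, mnet_depth = 40,
                    chip_signal = 2, chip_background = 20,
                    fragment_min = 150L, fragment_max = 300L,
                    spike_leakage = 0),
    spikes = list(copies = 10000, length_bp = 1500L),
    analysis = list(velocity_bin = 50L, chip_bin = 500L, rpk_threshold = 10,
                    bootstrap_iters = 10000L, pseudo_count = 1,
                    exclude_first = 1000L, n_body_bins = 100L,
                    flank_bp = 2500L, flank_bins = 50L, tss_window_bp = 10000L,
                    chip_window_bins = 40L))
}

.check_keys <- function(cfg, ref, path = "") {
  for (k in names(cfg)) {
    p <- if (path == "") k else paste0(path, ".", k)
    if (!k %in% names(ref)) {
      abort_velo(sprintf("unknown config key: %s", p))
    }
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(cfg[[k]])) {
      .check_keys(cfg[[k]], ref[[k]], p)
    }
  }
}

#' Build and validate a pipeline configuration
#'
#' Merges user overrides onto [default_config()]; unknown keys are rejected
#' with their full key path, and core numeric parameters must be positive.
#'
#' @param overrides A nested list (e.g. from [read_config()]) with any
#'   subset of the default fields.
#' @return A validated configuration list.
#' @export
pipeline_config <- function(overrides = list()) {
  ref <- default_config()
  .check_keys(overrides, ref)
  if (!is.null(overrides$conditions)) {
    for (cc in overrides$conditions) {
      .check_keys(cc, ref$conditions[[1]], "conditions[]")
    }
  }
  cfg <- utils::modifyList(ref, overrides)
  # unnamed list elements are replaced wholesale, not merged
  if (!is.null(overrides$conditions)) cfg$conditions <- overrides$conditions
  if (!is.null(overrides$assays)) cfg$assays <- overrides$assays
  for (nm in c("bootstrap_iters", "velocity_bin", "chip_bin", "pseudo_count",
               "n_body_bins", "flank_bp", "flank_bins", "rpk_threshold",
               "exclude_first")) {
    assert_scalar_number(cfg$analysis[[nm]], paste0("analysis.", nm),
                         positive = TRUE)
  }
  if (length(cfg$conditions) < 1) abort_velo("at least one condition required")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

.cfg_objects <- function(cfg) {
  list(
    genome = synthetic_genome(cfg$genome$n_genes,
                              c(cfg$genome$length_min, cfg$genome$length_max),
                              spacing = cfg$genome$spacing, seed = cfg$seed),
    kin = kinetics_spec(cfg$kinetics$initiation_rate, cfg$kinetics$velocity),
    conds = lapply(cfg$conditions, function(cc) {
      condition_spec(cc$name, cc$velocity_factor, cc$onset_time)
    }),
    samp = sampling_spec(cfg$sampling$label_start, cfg$sampling$label_duration,
                         cfg$sampling$ttseq_depth, cfg$sampling$mnet_depth,
                         cfg$sampling$chip_signal, cfg$sampling$chip_background,
                         c(cfg$sampling$fragment_min, cfg$sampling$fragment_max),
                         cfg$sampling$spike_leakage),
    spikes = spikein_set(cfg$spikes$copies, cfg$spikes$length_bp))
}

.provenance <- function(cfg, outdir) {
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  md5 <- unname(tools::md5sum(cfg_path))
  c(sprintf("velocitt %s", as.character(utils::packageVersion("velocitt"))),
    sprintf("config_md5=%s", md5),
    sprintf("seed=%d", as.integer(cfg$seed)))
}

#' Simulate a dataset to disk
#'
#' Runs [emit_dataset()] under the configuration and writes one BED6 file
#' per sample (spike-in fragments included for TT-seq/mNET-seq), the gene
#' and non-transcribed-region annotation, the spike-in table, the sample
#' sheet and the simulation ground truth, each TSV carrying a provenance
#' header (package version, config hash, seed). Byte-identical given the
#' same configuration and seed.
#'
#' @param cfg A configuration list from [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
run_simulate <- function(cfg, outdir) {
  cfg <- pipeline_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- .provenance(cfg, outdir)
  ob <- .cfg_objects(cfg)
  ds <- emit_dataset(ob$genome, ob$kin, ob$conds, ob$samp, spikes = ob$spikes,
                     replicates = cfg$replicates, assays = cfg$assays,
                     library_scales = cfg$library_scales, seed = cfg$seed)
  g <- ob$genome$genes
  write_bed6(tibble::tibble(chrom = g$chrom, start = g$start, end = g$end,
                            name = g$gene_id, score = 0L, strand = g$strand),
             file.path(outdir, "genes.bed"))
  nt <- ob$genome$nt_regions
  write_bed6(tibble::tibble(chrom = nt$chrom, start = nt$start, end = nt$end,
                            name = nt$region_id, score = 0L, strand = "."),
             file.path(outdir, "nt_regions.bed"))
  write_tsv_prov(ds$spikes, file.path(outdir, "spikes.tsv"), prov)
  write_tsv_prov(ds$samples, file.path(outdir, "samples.tsv"), prov)
  write_tsv_prov(ds$truth, file.path(outdir, "truth_genes.tsv"), prov)
  for (a in names(ds$records)) {
    rec <- ds$records[[a]]
    for (s in unique(ds$samples$sample[ds$samples$assay == a])) {
      write_bed6(rec[rec$sample == s, ], file.path(outdir, paste0(s, ".bed")))
    }
  }
  invisible(outdir)
}

.read_dataset <- function(datadir) {
  samples <- readr::read_tsv(file.path(datadir, "samples.tsv"), comment = "#",
                             col_types = readr::cols(), progress = FALSE)
  genes <- read_gene_bed(file.path(datadir, "genes.bed"))
  nt_raw <- read_bed6(file.path(datadir, "nt_regions.bed"))
  nt <- tibble::tibble(region_id = nt_raw$name, chrom = nt_raw$chrom,
                       start = nt_raw$start, end = nt_raw$end)
  spikes <- readr::read_tsv(file.path(datadir, "spikes.tsv"), comment = "#",
                            col_types = readr::cols(), progress = FALSE)
  truth_path <- file.path(datadir, "truth_genes.tsv")
  truth <- if (file.exists(truth_path)) {
    readr::read_tsv(truth_path, comment = "#", col_types = readr::cols(),
                    progress = FALSE)
  } else NULL
  records <- lapply(split(samples$sample, samples$assay), function(ss) {
    dplyr::bind_rows(lapply(ss, function(s) {
      read_bed6(file.path(datadir, paste0(s, ".bed")), sample = s)
    }))
  })
  list(samples = samples, genes = genes, nt_regions = nt, spikes = spikes,
       truth = truth, records = records)
}

# features for counting: genes plus one full-length feature per spike
.count_features_with_spikes <- function(genes, spikes) {
  dplyr::bind_rows(
    genes[, c("gene_id", "chrom", "start", "end", "strand")],
    tibble::tibble(gene_id = spikes$spike_id, chrom = spikes$spike_id,
                   start = 0L, end = as.integer(spikes$length), strand = "+"))
}

#' Analyze a simulated (or imported) dataset
#'
#' Full downstream pass: strand-specific gene + spike counting
#' (IntersectionNotEmpty; TT-seq as whole fragments, mNET-seq as
#' last-incorporated-base tags), spike-in / background median-of-ratios
#' size factors, RPK expression filtering, per-gene velocity ratios and
#' their treated-vs-control log2 changes with a one-sample Wilcoxon test
#' and notched-boxplot summary, MA values, bootstrap metagene profiles per
#' condition, gene-length-quartile tilt statistics, the TSS-aligned TT-seq
#' change matrix, the gene-center-aligned ChIP matrix, and (when ground
#' truth is present) a velocity-recovery report. All tables are written to
#' `outdir` with provenance headers.
#'
#' @param cfg Configuration list (analysis parameters are read from it).
#' @param datadir Directory produced by [run_simulate()] (or arranged the
#'   same way from real data).
#' @param outdir Output directory.
#' @return Invisibly, a named list of the computed tables.
#' @export
run_analyze <- function(cfg, datadir, outdir) {
  cfg <- pipeline_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- .provenance(cfg, outdir)
  ds <- .read_dataset(datadir)
  an <- cfg$analysis
  conds <- vapply(cfg$conditions, `[[`, character(1), "name")
  ctrl <- conds[1]
  res <- list()

  feats <- .count_features_with_spikes(ds$genes, ds$spikes)
  have <- names(ds$records)

  # --- counting + size factors ------------------------------------------
  sf <- list()
  counts <- list()
  for (a in intersect(c("ttseq", "mnet"), have)) {
    rec <- ds$records[[a]]
    counts[[a]] <- count_features(rec, feats, ignore_strand = FALSE)
    sf[[a]] <- spikein_size_factors(counts[[a]], ds$spikes)
    write_count_tsv(counts[[a]], file.path(outdir, paste0("counts_", a, ".tsv")),
                    prov)
  }
  if ("chip" %in% have) {
    nt <- nontranscribed_regions(ds$nt_regions, ds$genes)
    chip_nt <- count_features(ds$records$chip, nt, ignore_strand = TRUE)
    sf$chip <- background_size_factors(chip_nt)
    write_count_tsv(chip_nt, file.path(outdir, "counts_chip_background.tsv"),
                    prov)
  }
  sf_tbl <- dplyr::bind_rows(sf, .id = "assay")
  write_tsv_prov(sf_tbl, file.path(outdir, "size_factors.tsv"), prov)
  res$size_factors <- sf_tbl

  # --- expression filter -------------------------------------------------
  if ("ttseq" %in% have) {
    gene_rows <- counts$ttseq$feature_id %in% ds$genes$gene_id
    expr <- rpk_filter(counts$ttseq[gene_rows, ], ds$genes,
                       threshold = an$rpk_threshold)
    write_tsv_prov(expr, file.path(outdir, "expressed_genes.tsv"), prov)
    res$expressed <- expr
    egenes <- ds$genes[ds$genes$gene_id %in% expr$gene_id[expr$expressed], ]
  } else {
    egenes <- ds$genes
  }

  # --- per-gene velocity and change -------------------------------------
  if (all(c("ttseq", "mnet") %in% have) && nrow(egenes) > 0) {
    by_cond <- function(a, cond) {
      ss <- ds$samples$sample[ds$samples$assay == a & ds$samples$condition == cond]
      ds$records[[a]][ds$records[[a]]$sample %in% ss, ]
    }
    vel <- lapply(stats::setNames(conds, conds), function(cd) {
      velocity_per_gene(by_cond("ttseq", cd), by_cond("mnet", cd), egenes,
                        sf$ttseq, sf$mnet, exclude_first = an$exclude_first)
    })
    vel_tbl <- dplyr::bind_rows(vel, .id = "condition")
    write_tsv_prov(vel_tbl, file.path(outdir, "velocity_per_gene.tsv"), prov)
    res$velocity <- vel_tbl
    if (length(conds) > 1) {
      chg <- velocity_log2_change(vel[[conds[2]]], vel[[ctrl]])
      write_tsv_prov(chg, file.path(outdir, "velocity_log2_change.tsv"), prov)
      res$velocity_change <- chg
      ok <- chg$log2_change[!is.na(chg$log2_change)]
      if (length(ok) > 0 && any(ok != 0)) {
        wt <- wilcoxon_signed_rank(ok)
        bs <- boxplot_summary(ok)
        report <- dplyr::bind_cols(
          tibble::tibble(quantity = "log2_velocity_change",
                         median = stats::median(ok)), wt,
          bs[, c("hinge_lo", "hinge_hi", "notch_lo", "notch_hi")])
        write_tsv_prov(report, file.path(outdir, "stats_report.tsv"), prov)
        res$stats_report <- report
      }
      if (!is.null(ds$truth)) {
        tw <- tidyr::pivot_wider(
          ds$truth[, c("gene_id", "condition", "mean_velocity_kb_min")],
          names_from = "condition", values_from = "mean_velocity_kb_min")
        tw$true_log2_change <- log2(tw[[conds[2]]] / tw[[ctrl]])
        rec <- dplyr::inner_join(chg, tw[, c("gene_id", "true_log2_change")],
                                 by = "gene_id")
        rec$error <- rec$log2_change - rec$true_log2_change
        write_tsv_prov(rec, file.path(outdir, "recovery_report.tsv"), prov)
        res$recovery <- rec
      }
    }
  }

  # --- MA values ---------------------------------------------------------
  if ("ttseq" %in% have && length(conds) > 1) {
    ma <- ma_table(counts$ttseq[counts$ttseq$feature_id %in% egenes$gene_id, ],
                   sf$ttseq, ds$samples, control = ctrl, treated = conds[2],
                   pseudo = an$pseudo_count)
    write_tsv_prov(ma, file.path(outdir, "ma_values.tsv"), prov)
    res$ma <- ma
  }

  # --- metagene profiles, tilt, heatmap matrices ------------------------
  if ("ttseq" %in% have && nrow(egenes) > 0) {
    seeds <- substream_seeds(cfg$seed, length(conds) + 1)
    tracks <- lapply(stats::setNames(conds, conds), function(cd) {
      ss <- ds$samples$sample[ds$samples$assay == "ttseq" &
                                ds$samples$condition == cd]
      rec <- ds$records$ttseq[ds$records$ttseq$sample %in% ss, ]
      coverage_track(rec, sf$ttseq[sf$ttseq$sample %in% ss, ])
    })
    mats <- lapply(tracks, function(tr) {
      metagene_matrix(tr, egenes, an$n_body_bins, an$flank_bp, an$flank_bins)
    })
    for (i in seq_along(conds)) {
      prof <- bootstrap_mean_ci(log2_pseudo(mats[[conds[i]]], an$pseudo_count),
                                iters = an$bootstrap_iters, seed = seeds[i])
      write_tsv_prov(prof, file.path(outdir,
        paste0("metagene_ttseq_", conds[i], ".tsv")), prov)
      res[[paste0("metagene_", conds[i])]] <- prof
    }
    if (length(conds) > 1) {
      common <- intersect(rownames(mats[[1]]), rownames(mats[[2]]))
      chmat <- log2_pseudo(mats[[conds[2]]][common, , drop = FALSE],
                           an$pseudo_count) -
        log2_pseudo(mats[[ctrl]][common, , drop = FALSE], an$pseudo_count)
      body <- chmat[, attr(mats[[1]], "region") == "body", drop = FALSE]
      quart <- length_quartile_groups(egenes[egenes$gene_id %in% common, ])
      tilts <- tibble::tibble(
        gene_id = rownames(body),
        tilt = apply(body, 1, tilt_statistic))
      tilts <- dplyr::left_join(tilts,
        quart[, c("gene_id", "length_bp", "quartile")], by = "gene_id")
      write_tsv_prov(tilts, file.path(outdir, "gene_tilts.tsv"), prov)
      res$tilts <- tilts
      tq <- dplyr::summarise(dplyr::group_by(tilts, .data$quartile),
                             n = dplyr::n(),
                             mean_tilt = mean(.data$tilt, na.rm = TRUE),
                             .groups = "drop")
      write_tsv_prov(tq, file.path(outdir, "tilt_by_quartile.tsv"), prov)
      res$tilt_by_quartile <- tq
      aligned <- tss_aligned_change_matrix(tracks[[ctrl]], tracks[[conds[2]]],
                                           egenes, bin_width = an$velocity_bin,
                                           window_bp = an$tss_window_bp,
                                           pseudo = an$pseudo_count)
      write_tsv_prov(aligned, file.path(outdir, "tss_change_matrix.tsv"), prov)
      res$tss_matrix <- aligned
    }
  }
  if ("chip" %in% have && nrow(egenes) > 0) {
    chip_samples <- ds$samples$sample[ds$samples$assay == "chip"]
    chip_track <- coverage_track(ds$records$chip,
                                 sf$chip[sf$chip$sample %in% chip_samples, ])
    cmat <- center_aligned_matrix(chip_track, egenes, bin_width = an$chip_bin,
                                  window_bins = an$chip_window_bins)
    write_tsv_prov(cmat, file.path(outdir, "chip_center_matrix.tsv"), prov)
    res$chip_matrix <- cmat
  }
  invisible(res)
}

#' Simulate and analyze in one call
#'
#' @param cfg Configuration list.
#' @param outdir Output directory; simulated data goes to
#'   `<outdir>/simulated`, analysis tables to `<outdir>/analysis`.
#' @return Invisibly, the analysis result list.
#' @export
run_all <- function(cfg, outdir) {
  simdir <- file.path(outdir, "simulated")
  run_simulate(cfg, simdir)
  run_analyze(cfg, simdir, file.path(outdir, "analysis"))
}
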