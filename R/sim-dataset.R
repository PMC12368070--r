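#' Sample sequencing fragments from labeled intervals
#'
#' Fragment counts per interval are Poisson with mean
#' `width/1000 * depth_per_kb * library_scale`; fragment start positions are
#' uniform within the interval and lengths uniform in
#' `[fragment_length[1], fragment_length[2]]`, truncated at the interval end.
#' Strand is inherited from the source interval.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`, `strand`.
#' @param fragment_length Two integers, min/max fragment length (bp).
#' @param depth_per_kb Expected fragments per kb of interval.
#' @param library_scale Per-sample depth multiplier.
#' @param seed Integer seed (NULL to use the current RNG stream).
#' @param sample Sample label.
#' @return A fragment-record tibble (BED6-style columns plus `sample`).
#' @export
fragment_records <- function(intervals, fragment_length = c(150L, 300L),
                             depth_per_kb = 1, library_scale = 1, seed = NULL,
                             sample = "S1") {
  if (length(fragment_length) != 2 || fragment_length[1] > fragment_length[2]) {
    abort_velo("`fragment_length` must be c(min, max) with min <= max")
  }
  assert_scalar_number(depth_per_kb, "depth_per_kb", nonneg = TRUE)
  assert_scalar_number(library_scale, "library_scale", positive = TRUE)
  if (nrow(intervals) == 0) return(empty_records())
  with_seed(seed, {
    w <- intervals$end - intervals$start
    n <- stats::rpois(nrow(intervals), w / 1000 * depth_per_kb * library_scale)
    tot <- sum(n)
    if (tot == 0) return(empty_records())
    idx <- rep(seq_len(nrow(intervals)), n)
    fs <- intervals$start[idx] + floor(stats::runif(tot) * w[idx])
    fl <- fragment_length[1] +
      floor(stats::runif(tot) * (fragment_length[2] - fragment_length[1] + 1))
    fe <- pmin(fs + fl, intervals$end[idx])
    as_record_tibble(intervals$chrom[idx], fs, fe,
                     sprintf("frag%06d", seq_len(tot)),
                     intervals$strand[idx], sample)
  })
}

#' Construct the default spike-in set
#'
#' Three 4sU-labeled and three unlabeled synthetic spike-in RNAs of constant
#' abundance per sample; labeled spikes survive 4sU selection and anchor the
#' cross-sample normalization.
#'
#' @param copies Expected sequenced fragments per labeled spike at library
#'   scale 1.
#' @param length_bp Spike RNA length.
#' @return Tibble with `spike_id`, `length`, `copies`, `labeled`.
#' @export
spikein_set <- function(copies = 10000, length_bp = 1500L) {
  tibble::tibble(
    spike_id = sprintf("spike%s%d", rep(c("L", "U"), each = 3), rep(1:3, 2)),
    length = as.integer(length_bp),
    copies = copies,
    labeled = rep(c(TRUE, FALSE), each = 3))
}

#' Emit spike-in fragments for one sample
#'
#' Labeled spike-ins yield Poisson(`copies * library_scale`) fragments on
#' their own "chromosome"; unlabeled spikes yield the `leakage` fraction of
#' that (default 0, i.e. perfect 4sU selection). Because copies are constant
#' across conditions, these counts are the normalization anchor.
#'
#' @param spikes Spike-in tibble (see [spikein_set()]).
#' @param library_scale Per-sample depth multiplier, > 0.
#' @param seed Integer seed (NULL to use the current RNG stream).
#' @param leakage Fraction in `[0, 1]`.
#' @param fragment_length Min/max fragment length.
#' @param sample Sample label.
#' @return Fragment-record tibble on spike chromosomes.
#' @export
emit_spikeins <- function(spikes, library_scale = 1, seed = NULL, leakage = 0,
                          fragment_length = c(150L, 300L), sample = "S1") {
  assert_columns(spikes, c("spike_id", "length", "copies", "labeled"), "spike table")
  assert_scalar_number(library_scale, "library_scale", positive = TRUE)
  if (any(spikes$length <= 0) || any(spikes$copies <= 0)) {
    abort_velo("spike-in lengths and copies must be > 0")
  }
  with_seed(seed, {
    mu <- spikes$copies * library_scale * ifelse(spikes$labeled, 1, leakage)
    n <- stats::rpois(nrow(spikes), mu)
    tot <- sum(n)
    if (tot == 0) return(empty_records())
    idx <- rep(seq_len(nrow(spikes)), n)
    fs <- floor(stats::runif(tot) * spikes$length[idx])
    fl <- fragment_length[1] +
      floor(stats::runif(tot) * (fragment_length[2] - fragment_length[1] + 1))
    fe <- pmin(fs + fl, spikes$length[idx])
    fe <- pmax(fe, fs + 1L)
    as_record_tibble(spikes$spike_id[idx], fs, fe,
                     sprintf("spike_frag%06d", seq_len(tot)), "+", sample)
  })
}

#' Emit ChIP-seq fragments: gene-body signal plus genome-wide background
#'
#' Signal fragments are drawn over gene bodies (a block occupancy profile,
#' optionally weighted per gene via a `weight` column, as for an
#' H3K36me3-like gene-body mark); background fragments are uniform over the
#' whole chromosome, so non-transcribed regions receive background coverage
#' proportional to library scale. ChIP fragments are unstranded.
#'
#' @param genes Gene tibble (optional `weight` column, default 1).
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @param signal_rate Expected signal fragments per kb of gene body (at
#'   weight 1, scale 1).
#' @param background_rate Expected background fragments per kb of genome.
#' @param library_scale Per-sample depth multiplier.
#' @param seed Integer seed.
#' @param fragment_length Min/max fragment length.
#' @param sample Sample label.
#' @return Fragment-record tibble with strand ".".
#' @export
emit_chip <- function(genes, chrom_sizes, signal_rate = 2, background_rate = 1,
                      library_scale = 1, seed = NULL,
                      fragment_length = c(150L, 300L), sample = "S1") {
  if (nrow(chrom_sizes) == 0) abort_velo("empty genome: no chromosomes")
  assert_scalar_number(background_rate, "background_rate", nonneg = TRUE)
  assert_scalar_number(signal_rate, "signal_rate", nonneg = TRUE)
  with_seed(seed, {
    sig <- if (nrow(genes) > 0 && signal_rate > 0) {
      g <- gene_models(genes)
      w <- if ("weight" %in% names(genes)) genes$weight else rep(1, nrow(g))
      iv <- tibble::tibble(chrom = g$chrom, start = g$start, end = g$end,
                           strand = ".")
      # per-gene weighting via per-interval depth: emit gene by gene groups
      n <- stats::rpois(nrow(iv),
        (iv$end - iv$start) / 1000 * signal_rate * w * library_scale)
      tot <- sum(n)
      if (tot > 0) {
        idx <- rep(seq_len(nrow(iv)), n)
        wd <- iv$end - iv$start
        fs <- iv$start[idx] + floor(stats::runif(tot) * wd[idx])
        fl <- fragment_length[1] +
          floor(stats::runif(tot) * (fragment_length[2] - fragment_length[1] + 1))
        as_record_tibble(iv$chrom[idx], fs, fs + fl,
                         sprintf("chip_sig%06d", seq_len(tot)), ".", sample)
      } else empty_records()
    } else empty_records()
    bg <- {
      n <- stats::rpois(nrow(chrom_sizes),
        chrom_sizes$size / 1000 * background_rate * library_scale)
      tot <- sum(n)
      if (tot > 0) {
        idx <- rep(seq_len(nrow(chrom_sizes)), n)
        fs <- floor(stats::runif(tot) * chrom_sizes$size[idx])
        fl <- fragment_length[1] +
          floor(stats::runif(tot) * (fragment_length[2] - fragment_length[1] + 1))
        fe <- pmin(fs + fl, chrom_sizes$size[idx])
        as_record_tibble(chrom_sizes$chrom[idx], fs, fe,
                         sprintf("chip_bg%06d", seq_len(tot)), ".", sample)
      } else empty_records()
    }
    dplyr::bind_rows(sig, bg)
  })
}

# default warm-up: twice the slowest full-gene transit time across the genome
.default_warmup <- function(genes, kin_list, conditions) {
  maxL <- max(genes$end - genes$start) / 1000
  minv <- min(vapply(kin_list, function(k) min(k$velocity), numeric(1)))
  minf <- min(vapply(conditions, function(cd) cd$velocity_factor, numeric(1)))
  2 * maxL / (minv * minf)
}

#' Simulate a complete multi-assay dataset with known truth
#'
#' For every condition, replicate and assay an independent pool of polymerase
#' trajectories is simulated per gene (fresh cells per library), then
#' sequenced: TT-seq fragments from 4sU-labeled segments, mNET-seq width-1
#' tags at engaged active sites, ChIP fragments with genome-wide background,
#' and spike-in fragments appended to TT-seq and mNET-seq libraries. One
#' master seed expands into per-sample substreams in a fixed order, so the
#' bundle is fully reproducible.
#'
#' @param genome A list from [synthetic_genome()] (or with the same shape).
#' @param kinetics A single [kinetics_spec()] applied to all genes, or a list
#'   of specs named by `gene_id`.
#' @param conditions List of [condition_spec()]; the first is conventionally
#'   the control.
#' @param sampling A [sampling_spec()].
#' @param spikes Spike-in tibble (see [spikein_set()]); NULL for none.
#' @param replicates Replicates per condition.
#' @param assays Character subset of `c("ttseq", "mnet", "chip")`.
#' @param library_scales Optional numeric vector of per-sample scales,
#'   recycled over samples in emission order; default all 1.
#' @param seed Master integer seed.
#' @param warmup Minutes of pre-sampling initiation; `NULL` (default) uses
#'   twice the slowest full-gene transit time, reaching steady state.
#' @return A list: `records` (named list of per-assay record tibbles, spike
#'   fragments included), `truth` (per gene x condition initiation rate and
#'   effective mean velocity), `samples` (per-sample metadata incl. library
#'   scale), `genome`, `spikes`.
#' @export
emit_dataset <- function(genome, kinetics, conditions, sampling,
                         spikes = spikein_set(), replicates = 2,
                         assays = c("ttseq", "mnet", "chip"),
                         library_scales = NULL, seed = 1, warmup = NULL) {
  genes <- gene_models(genome$genes)
  if (!inherits(sampling, "sampling_spec")) abort_velo("`sampling` must be a sampling_spec")
  if (inherits(conditions, "condition_spec")) conditions <- list(conditions)
  kin_for <- function(gid) {
    if (inherits(kinetics, "kinetics_spec")) kinetics else kinetics[[gid]]
  }
  kin_list <- if (inherits(kinetics, "kinetics_spec")) list(kinetics) else kinetics
  assays <- match.arg(assays, several.ok = TRUE)
  horizon <- sampling$sample_time
  if (is.null(warmup) && nrow(genes) > 0) {
    warmup <- .default_warmup(genes, kin_list, conditions)
  }
  warmup <- warmup %||% 0

  samples <- tidyr::expand_grid(
    condition = vapply(conditions, `[[`, character(1), "name"),
    replicate = seq_len(replicates),
    assay = assays)
  samples$sample <- sprintf("%s_%s_rep%d", samples$assay, samples$condition,
                            samples$replicate)
  ns <- nrow(samples)
  samples$library_scale <- rep(library_scales %||% 1, length.out = ns)
  samples$seed <- substream_seeds(seed, ns)

  cond_by_name <- stats::setNames(conditions,
    vapply(conditions, `[[`, character(1), "name"))
  window <- c(sampling$label_start, sampling$sample_time)

  recs <- lapply(seq_len(ns), function(i) {
    s <- samples[i, ]
    cond <- cond_by_name[[s$condition]]
    with_seed(s$seed, {
      if (s$assay == "chip") {
        out <- emit_chip(genes, genome$chrom_sizes,
                         signal_rate = sampling$chip_signal,
                         background_rate = sampling$chip_background,
                         library_scale = s$library_scale,
                         fragment_length = sampling$fragment_length,
                         sample = s$sample)
      } else {
        per_gene <- lapply(seq_len(nrow(genes)), function(j) {
          gene <- genes[j, ]
          traj <- simulate_trajectories(gene, kin_for(gene$gene_id), cond,
                                        horizon = horizon, warmup = warmup)
          if (s$assay == "mnet") {
            tags <- engaged_positions(traj, sampling$sample_time, sample = s$sample)
            if (nrow(tags) == 0) return(tags)
            copies <- stats::rpois(nrow(tags), sampling$mnet_depth * s$library_scale)
            tags[rep(seq_len(nrow(tags)), copies), ]
          } else {
            iv <- labeled_intervals(traj, window)
            fragment_records(iv, fragment_length = sampling$fragment_length,
                             depth_per_kb = sampling$ttseq_depth,
                             library_scale = s$library_scale, sample = s$sample)
          }
        })
        out <- dplyr::bind_rows(per_gene)
        if (nrow(out) == 0) out <- empty_records()
        if (!is.null(spikes) && nrow(spikes) > 0) {
          out <- dplyr::bind_rows(out,
            emit_spikeins(spikes, library_scale = s$library_scale,
                          leakage = sampling$spike_leakage,
                          fragment_length = sampling$fragment_length,
                          sample = s$sample))
        }
      }
      if (nrow(out) > 0) out$name <- sprintf("%s_r%07d", s$sample, seq_len(nrow(out)))
      out
    })
  })

  records <- lapply(stats::setNames(assays, assays), function(a) {
    dplyr::bind_rows(recs[samples$assay == a])
  })

  grid <- tidyr::expand_grid(gene_id = genes$gene_id,
                             condition = names(cond_by_name))
  truth <- purrr::pmap_dfr(grid, function(gene_id, condition) {
    kin <- kin_for(gene_id)
    g <- genes[genes$gene_id == gene_id, ]
    pieces <- .velocity_pieces(kin, g$end - g$start)
    wmean <- sum(kin$velocity * 1000 * diff(pieces$bounds)) / (g$end - g$start) / 1000
    f <- cond_by_name[[condition]]$velocity_factor
    tibble::tibble(gene_id = gene_id, condition = condition,
                   initiation_rate = kin$initiation_rate,
                   mean_velocity_kb_min = wmean * f)
  })

  list(records = records, truth = truth,
       samples = dplyr::select(samples, "sample", "assay", "condition",
                               "replicate", "library_scale", "seed"),
       genome = genome, spikes = spikes)
}
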