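#' Per-bin elongation-velocity ratio matrix
#'
#' The velocity proxy: mNET-seq occupancy scales with initiation/velocity
#' while TT-seq synthesis scales with initiation, so the normalized
#' TT-seq(midpoint)/mNET-seq ratio tracks velocity up to a global constant.
#' Tracks must be binned on the same absolute 50-bp grid; replicates of a
#' condition are normalized per sample and summed before the ratio is taken.
#' Bins with zero mNET-seq signal are NA (shown gray in heatmaps).
#'
#' @param tt_binned,mnet_binned Binned run-length tracks from [bin_track()]
#'   of TT-seq midpoint and mNET-seq last-base coverage. If they carry a
#'   `sample` column the per-sample tracks are summed after normalization;
#'   otherwise they are taken as already-combined raw tracks.
#' @param sf_tt,sf_mnet Size-factor tibbles (or single numbers for combined
#'   tracks).
#' @param genes Gene-model tibble; bins are reported TSS-anchored per gene.
#' @param bin_width Bin width (must match both tracks' grids).
#' @return A `velocity_matrix` tibble: `gene_id`, `bin_index` (1 = TSS-most
#'   bin), `tt`, `mnet`, `ratio` (NA where `mnet` is 0), plus `n_bins` per
#'   gene.
#' @export
velocity_bins <- function(tt_binned, mnet_binned, sf_tt, sf_mnet, genes,
                          bin_width = 50) {
  bw_tt <- attr(tt_binned, "bin_width") %||% bin_width
  bw_mn <- attr(mnet_binned, "bin_width") %||% bin_width
  if (bw_tt != bin_width || bw_mn != bin_width) {
    abort_velo("bin grids mismatch: tracks were binned at a different width")
  }
  norm_combine <- function(track, sf) {
    if (is.numeric(sf)) return(apply_size_factors(track, sf))
    # track value columns are per-bin sums of per-sample coverage; the
    # caller passes one track per sample via the `sample` column
    assert_columns(track, "sample", "binned track")
    tr <- dplyr::left_join(track, sf, by = "sample")
    if (anyNA(tr$size_factor)) abort_velo("missing size factor for a sample")
    tr$value <- tr$value / tr$size_factor
    dplyr::summarise(dplyr::group_by(tr, .data$chrom, .data$strand,
                                     .data$start, .data$end),
                     value = sum(.data$value), .groups = "drop")
  }
  tt <- norm_combine(tt_binned, sf_tt)
  mn <- norm_combine(mnet_binned, sf_mnet)
  genes <- gene_anchors(genes)
  per_gene <- purrr::pmap_dfr(
    genes[, c("gene_id", "chrom", "start", "end", "strand")],
    function(gene_id, chrom, start, end, strand) {
      b0 <- start %/% bin_width
      b1 <- (end - 1L) %/% bin_width
      starts <- (b0:b1) * bin_width
      sel_tt <- tt[tt$chrom == chrom & tt$strand == strand, ]
      sel_mn <- mn[mn$chrom == chrom & mn$strand == strand, ]
      v_tt <- sel_tt$value[match(starts, sel_tt$start)]
      v_mn <- sel_mn$value[match(starts, sel_mn$start)]
      v_tt[is.na(v_tt)] <- 0
      v_mn[is.na(v_mn)] <- 0
      if (strand == "-") { v_tt <- rev(v_tt); v_mn <- rev(v_mn) }
      tibble::tibble(gene_id = gene_id, bin_index = seq_along(starts),
                     tt = v_tt, mnet = v_mn,
                     ratio = ifelse(v_mn == 0, NA_real_, v_tt / v_mn),
                     n_bins = length(starts))
    })
  structure(per_gene, bin_width = bin_width,
            class = c("velocity_matrix", class(per_gene)))
}

#' Per-gene elongation-velocity ratio
#'
#' Counts are restricted to the gene body excluding the first 1 kb in the
#' direction of transcription, counted strand-specifically
#' (IntersectionNotEmpty), normalized per sample, summed across replicates,
#' and the TT-seq/mNET-seq ratio of the sums is reported. Genes no longer
#' than the excluded prefix get `NA` with a warning.
#'
#' @param tt_records TT-seq fragment records (a condition's replicates).
#' @param mnet_records mNET-seq tag records (same condition).
#' @param genes Gene-model tibble.
#' @param sf_tt,sf_mnet Size-factor tibbles covering the samples present.
#' @param exclude_first Bp excluded downstream of the TSS (default 1000).
#' @return Tibble `gene_id`, `tt_norm`, `mnet_norm`, `velocity_ratio`.
#' @export
velocity_per_gene <- function(tt_records, mnet_records, genes, sf_tt, sf_mnet,
                              exclude_first = 1000) {
  genes <- gene_models(genes)
  short <- genes$end - genes$start <= exclude_first
  if (any(short)) {
    warning(sprintf("%d gene(s) shorter than %d bp: velocity set to NA",
                    sum(short), exclude_first), call. = FALSE)
  }
  body <- genes[!short, ]
  trimmed <- dplyr::mutate(body,
    start = ifelse(.data$strand == "+", .data$start + exclude_first, .data$start),
    end = ifelse(.data$strand == "+", .data$end, .data$end - exclude_first))
  norm_total <- function(records, sf) {
    cnt <- count_features(records, trimmed, ignore_strand = FALSE)
    cnt <- apply_size_factors(cnt, sf)
    vals <- as.matrix(cnt[, setdiff(names(cnt), "feature_id"), drop = FALSE])
    stats::setNames(rowSums(vals), cnt$feature_id)
  }
  tt <- norm_total(tt_records, sf_tt)
  mn <- norm_total(mnet_records, sf_mnet)
  out <- tibble::tibble(gene_id = genes$gene_id,
                        tt_norm = as.numeric(tt[genes$gene_id]),
                        mnet_norm = as.numeric(mn[genes$gene_id]))
  out$velocity_ratio <- ifelse(is.na(out$mnet_norm) | out$mnet_norm == 0,
                               NA_real_, out$tt_norm / out$mnet_norm)
  out
}

#' Log2 change of the velocity statistic between conditions
#'
#' Joins two per-gene velocity tables (or two `velocity_matrix` objects, by
#' gene and bin) and returns `log2(treated / control)`; NA in either input
#' propagates.
#'
#' @param treated,control Outputs of [velocity_per_gene()] or
#'   [velocity_bins()], both of the same kind.
#' @return Tibble with the join keys and `log2_change`.
#' @export
velocity_log2_change <- function(treated, control) {
  if (inherits(treated, "velocity_matrix")) {
    keys <- c("gene_id", "bin_index")
    val <- "ratio"
  } else {
    keys <- "gene_id"
    val <- "velocity_ratio"
  }
  j <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(treated), dplyr::all_of(c(keys, val))),
    dplyr::select(tibble::as_tibble(control), dplyr::all_of(c(keys, val))),
    by = keys, suffix = c("_treated", "_control"))
  t_v <- j[[paste0(val, "_treated")]]
  c_v <- j[[paste0(val, "_control")]]
  j$log2_change <- ifelse(is.na(t_v) | is.na(c_v) | t_v <= 0 | c_v <= 0,
                          NA_real_, log2(t_v / c_v))
  dplyr::select(j, dplyr::all_of(keys), "log2_change")
}

#' Tilt of a gene-body profile
#'
#' Mean of the last quartile of positions minus mean of the first quartile:
#' negative values mean signal is depleted toward the gene end relative to
#' the start (the downward tilt expected when elongation slows and distal
#' regions are supplied at the old, lower polymerase flux).
#'
#' @param profile Numeric vector over gene-body positions (e.g. per-gene
#'   log2 change of normalized TT-seq coverage). NAs ignored.
#' @return A single number; NA if either quartile window is all-NA.
#' @export
tilt_statistic <- function(profile) {
  n <- length(profile)
  if (n < 1) return(NA_real_)
  m <- max(1L, n %/% 4L)
  head_q <- profile[seq_len(m)]
  tail_q <- profile[seq.int(n - m + 1L, n)]
  if (all(is.na(head_q)) || all(is.na(tail_q))) return(NA_real_)
  mean(tail_q, na.rm = TRUE) - mean(head_q, na.rm = TRUE)
}
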