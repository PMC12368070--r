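# decode a genomic window of a run track into a per-base numeric vector,
# zero-padded outside [0, available length)
.track_window <- function(track_sub, start, end) {
  v <- numeric(end - start)
  if (nrow(track_sub) == 0) return(v)
  s <- pmax(track_sub$start, start)
  e <- pmin(track_sub$end, end)
  keep <- which(e > s)
  for (i in keep) {
    v[(s[i] - start + 1):(e[i] - start)] <- track_sub$value[i]
  }
  v
}

#' Scaled metagene profile of one gene
#'
#' The gene body is divided into `n_body_bins` equal spans (per-span mean of
#' the per-base signal) and flanked by `flank_bins` fixed-width bins covering
#' `flank_bp` on each side. Minus-strand genes are reversed, so index 1 is
#' the upstream flank and the body runs TSS to TES.
#'
#' @param track Run-length track tibble (per-base values).
#' @param gene One-row gene tibble.
#' @param n_body_bins Number of scaled body bins (default 100).
#' @param flank_bp Flank width in bp on each side (default 2500).
#' @param flank_bins Number of fixed-width bins per flank (default 50;
#'   `flank_bp` must be divisible by it).
#' @return Numeric vector of length `2 * flank_bins + n_body_bins`, or NULL
#'   (with a warning) when the gene is shorter than `n_body_bins` bases.
#' @export
scaled_profile <- function(track, gene, n_body_bins = 100, flank_bp = 2500,
                           flank_bins = 50) {
  if (flank_bp %% flank_bins != 0) {
    abort_velo("`flank_bp` must be divisible by `flank_bins`")
  }
  L <- gene$end - gene$start
  if (L < n_body_bins) {
    warning(sprintf("gene %s shorter than %d bp: skipped", gene$gene_id,
                    n_body_bins), call. = FALSE)
    return(NULL)
  }
  sub <- track[track$chrom == gene$chrom & track$strand == gene$strand, ]
  v <- .track_window(sub, gene$start - flank_bp, gene$end + flank_bp)
  if (gene$strand == "-") v <- rev(v)
  fw <- flank_bp %/% flank_bins
  cs <- c(0, cumsum(v))
  # max(0, .) guards against floating-point jitter in the cumulative sums
  span_mean <- function(s, e) max(0, cs[e + 1] - cs[s + 1]) / (e - s)  # 0-based [s,e)
  up <- vapply(seq_len(flank_bins) - 1L,
               function(k) span_mean(k * fw, (k + 1) * fw), numeric(1))
  bbounds <- flank_bp + round(seq(0, L, length.out = n_body_bins + 1))
  body <- vapply(seq_len(n_body_bins),
                 function(k) span_mean(bbounds[k], bbounds[k + 1]), numeric(1))
  down_off <- flank_bp + L
  down <- vapply(seq_len(flank_bins) - 1L,
                 function(k) span_mean(down_off + k * fw, down_off + (k + 1) * fw),
                 numeric(1))
  c(up, body, down)
}

#' Scaled metagene matrix over a gene set
#'
#' Applies [scaled_profile()] to every gene; genes shorter than
#' `n_body_bins` bases are skipped with one consolidated warning.
#'
#' @inheritParams scaled_profile
#' @param genes Gene-model tibble.
#' @return A genes x positions matrix (rownames = gene ids) with a `region`
#'   attribute labelling positions as upstream/body/downstream.
#' @export
metagene_matrix <- function(track, genes, n_body_bins = 100, flank_bp = 2500,
                            flank_bins = 50) {
  genes <- gene_models(genes)
  keep <- genes$end - genes$start >= n_body_bins
  if (any(!keep)) {
    warning(sprintf("%d gene(s) shorter than %d bp: skipped", sum(!keep),
                    n_body_bins), call. = FALSE)
  }
  genes <- genes[keep, ]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    scaled_profile(track, genes[i, ], n_body_bins, flank_bp, flank_bins)
  })
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(0), 0, 2 * flank_bins + n_body_bins)
  rownames(m) <- genes$gene_id
  structure(m, region = rep(c("upstream", "body", "downstream"),
                            c(flank_bins, n_body_bins, flank_bins)))
}

#' Log2 transform with pseudo-count
#'
#' `log2(x + pseudo)`; with the default pseudo-count of 1 a zero maps to 0.
#'
#' @param x Numeric vector or matrix of non-negative values.
#' @param pseudo Pseudo-count added before the log (default 1).
#' @return Transformed object of the same shape (attributes preserved).
#' @export
log2_pseudo <- function(x, pseudo = 1) {
  if (any(x < 0, na.rm = TRUE)) abort_velo("values must be non-negative")
  out <- log2(x + pseudo)
  attributes(out) <- attributes(x)
  out
}

#' Bootstrap mean profile with percentile confidence band
#'
#' Gene rows are resampled with replacement `iters` times; the reported mean
#' is the observed column mean and the confidence band the percentile
#' interval of the bootstrap column means. Deterministic given `seed`.
#'
#' @param m Genes x positions matrix (e.g. from [metagene_matrix()] after
#'   [log2_pseudo()]).
#' @param iters Bootstrap iterations (default 10000).
#' @param seed Integer seed (NULL to use the current RNG stream).
#' @param level Confidence level (default 0.95).
#' @return A `metagene_profile` tibble: `position`, `region` (if present on
#'   `m`), `mean`, `ci_lo`, `ci_hi`; attributes `n_genes`, `iters`, `level`.
#' @export
bootstrap_mean_ci <- function(m, iters = 10000, seed = NULL, level = 0.95) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (iters <= 0) abort_velo("`iters` must be > 0")
  n <- nrow(m)
  if (n < 1) abort_velo("need at least one gene row")
  obs <- colMeans(m)
  boot <- with_seed(seed, {
    # resampling n rows with replacement == multinomial row weights
    w <- stats::rmultinom(iters, n, rep.int(1, n)) / n
    crossprod(w, m)  # iters x positions matrix of bootstrap means
  })
  a <- (1 - level) / 2
  qs <- apply(boot, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  out <- tibble::tibble(position = seq_along(obs))
  reg <- attr(m, "region")
  if (!is.null(reg)) out$region <- reg
  out$mean <- as.numeric(obs)
  out$ci_lo <- pmin(qs[1, ], obs)
  out$ci_hi <- pmax(qs[2, ], obs)
  structure(out, n_genes = n, iters = iters, level = level,
            class = c("metagene_profile", class(out)))
}

#' Metagene profile of a coverage track with bootstrap confidence band
#'
#' Convenience composition: scaled per-gene profiles, `log2(x + pseudo)`
#' transform, then bootstrap of the gene means.
#'
#' @inheritParams metagene_matrix
#' @inheritParams bootstrap_mean_ci
#' @param pseudo Pseudo-count (default 1).
#' @return A `metagene_profile` tibble (see [bootstrap_mean_ci()]).
#' @export
metagene_profile <- function(track, genes, n_body_bins = 100, flank_bp = 2500,
                             flank_bins = 50, pseudo = 1, iters = 10000,
                             seed = NULL, level = 0.95) {
  m <- metagene_matrix(track, genes, n_body_bins, flank_bp, flank_bins)
  bootstrap_mean_ci(log2_pseudo(m, pseudo), iters = iters, seed = seed,
                    level = level)
}

#' Split genes into length quartiles
#'
#' Genes are ranked by body length (ties broken by gene id) and split into
#' four near-equal groups, remainders going to the earlier (shorter) groups.
#'
#' @param genes Gene-model tibble.
#' @return The genes with `length_bp` and a `quartile` factor
#'   (shortest/short/long/longest) appended; groups partition the input.
#' @export
length_quartile_groups <- function(genes) {
  genes <- gene_models(genes)
  genes$length_bp <- genes$end - genes$start
  ord <- order(genes$length_bp, genes$gene_id)
  n <- nrow(genes)
  base <- n %/% 4L
  sizes <- base + as.integer(seq_len(4) <= n %% 4L)
  labels <- c("shortest", "short", "long", "longest")
  q <- rep(labels, sizes)
  genes$quartile <- factor(NA_character_, levels = labels)
  genes$quartile[ord] <- factor(q, levels = labels)
  genes
}

#' TSS-aligned log2-change matrix (heatmap input)
#'
#' Fixed-width bins anchored at each gene's TSS and oriented in the
#' direction of transcription. Per bin the change is
#' `log2(treated + 1) - log2(control + 1)` of normalized coverage sums; bins
#' with zero signal in both conditions are NA (gray in the heatmap). The
#' bin index of the gene end is recorded so heatmaps can trace gene ends.
#'
#' @param ctrl_track,treated_track Normalized, replicate-combined run-length
#'   tracks.
#' @param genes Gene-model tibble.
#' @param bin_width Bin width in bp (default 50).
#' @param window_bp Window downstream of the TSS in bp (default 10000;
#'   must be a multiple of `bin_width`).
#' @param pseudo Pseudo-count (default 1).
#' @return An `aligned_matrix` tibble: `gene_id`, `bin_index`, `control`,
#'   `treated`, `change`, `end_bin`; attribute `anchor = "TSS"`.
#' @export
tss_aligned_change_matrix <- function(ctrl_track, treated_track, genes,
                                      bin_width = 50, window_bp = 10000,
                                      pseudo = 1) {
  if (window_bp %% bin_width != 0) {
    abort_velo("`window_bp` must be a multiple of `bin_width`")
  }
  nb <- window_bp %/% bin_width
  genes <- gene_anchors(genes)
  one_gene <- function(track, gene) {
    sub <- track[track$chrom == gene$chrom & track$strand == gene$strand, ]
    if (gene$strand == "+") {
      v <- .track_window(sub, gene$start, gene$start + window_bp)
    } else {
      v <- rev(.track_window(sub, gene$end - window_bp, gene$end))
    }
    colSums(matrix(v, nrow = bin_width))
  }
  out <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    cv <- one_gene(ctrl_track, g)
    tv <- one_gene(treated_track, g)
    tibble::tibble(gene_id = g$gene_id, bin_index = seq_len(nb),
                   control = cv, treated = tv,
                   change = ifelse(cv == 0 & tv == 0, NA_real_,
                                   log2(tv + pseudo) - log2(cv + pseudo)),
                   end_bin = as.integer(ceiling(g$length_bp / bin_width)))
  })
  structure(out, anchor = "TSS", bin_width = bin_width,
            class = c("aligned_matrix", class(out)))
}

#' Gene-center-aligned signal matrix with body masking
#'
#' The genome is tiled into fixed bins on the absolute grid (origin 0); per
#' gene, `window_bins` bins centered on the bin containing the gene midpoint
#' are reported, oriented in the direction of transcription. Bins not fully
#' inside the gene body are NA, so neighbouring genes cannot contribute.
#'
#' @param track Normalized, replicate-combined run-length track (use strand
#'   "." tracks for unstranded ChIP coverage).
#' @param genes Gene-model tibble.
#' @param bin_width Bin width in bp (default 500).
#' @param window_bins Number of bins reported per gene (default 40).
#' @return An `aligned_matrix` tibble: `gene_id`, `bin_index` (1-based along
#'   the window), `value` (NA outside the gene body); attribute
#'   `anchor = "gene_center"`.
#' @export
center_aligned_matrix <- function(track, genes, bin_width = 500,
                                  window_bins = 40) {
  genes <- gene_anchors(genes)
  half <- window_bins %/% 2L
  out <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    center_bin <- ((g$start + g$end) %/% 2L) %/% bin_width
    bins <- (center_bin - half):(center_bin + (window_bins - half) - 1L)
    bs <- bins * bin_width
    be <- bs + bin_width
    sub <- track[track$chrom == g$chrom &
                   track$strand %in% c(g$strand, "."), ]
    vals <- vapply(seq_along(bs), function(k) {
      sum(.track_window(sub, bs[k], be[k]))
    }, numeric(1))
    inside <- bs >= g$start & be <= g$end
    vals[!inside] <- NA_real_
    if (g$strand == "-") vals <- rev(vals)
    tibble::tibble(gene_id = g$gene_id, bin_index = seq_len(window_bins),
                   value = vals)
  })
  structure(out, anchor = "gene_center", bin_width = bin_width,
            class = c("aligned_matrix", class(out)))
}
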