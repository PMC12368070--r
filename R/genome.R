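#' Construct and validate a gene-model table
#'
#' Genes are the unit of every per-gene statistic in the package. Coordinates
#' follow BED conventions: 0-based, half-open. The transcript start site (TSS)
#' is `start` for `+` genes and `end - 1` for `-` genes; the transcript end
#' site (TES) is the opposite terminus.
#'
#' @param df A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `biotype`.
#' @return A tibble of validated gene models with a `biotype` column.
#' @examples
#' gene_models(data.frame(gene_id = "g1", chrom = "chr1", start = 100,
#'                        end = 5100, strand = "+"))
#' @export
gene_models <- function(df) {
  assert_columns(df, c("gene_id", "chrom", "start", "end", "strand"), "gene table")
  out <- tibble::as_tibble(df)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$gene_id <- as.character(out$gene_id)
  out$chrom <- as.character(out$chrom)
  out$strand <- as.character(out$strand)
  if (!"biotype" %in% names(out)) out$biotype <- "protein_coding"
  if (anyDuplicated(out$gene_id)) {
    abort_velo(sprintf("duplicate gene_id: %s",
                       paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", ")))
  }
  bad <- which(!(out$strand %in% c("+", "-")))
  if (length(bad) > 0) {
    abort_velo(sprintf("gene %s: strand must be '+' or '-'", out$gene_id[bad[1]]))
  }
  bad <- which(out$start >= out$end)
  if (length(bad) > 0) {
    abort_velo(sprintf("gene %s: start must be < end", out$gene_id[bad[1]]))
  }
  dplyr::select(out, "gene_id", "chrom", "start", "end", "strand", "biotype")
}

#' Add TSS/TES anchor coordinates to a gene table
#'
#' @param genes A gene-model tibble (see [gene_models()]).
#' @return The input with `tss`, `tes` (0-based base positions) and
#'   `length_bp` columns appended.
#' @export
gene_anchors <- function(genes) {
  genes <- gene_models(genes)
  dplyr::mutate(genes,
    tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
    tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start),
    length_bp = .data$end - .data$start)
}

#' Generate a synthetic genome annotation for simulation
#'
#' Places `n_genes` non-overlapping genes of random length on one synthetic
#' chromosome, separated by fixed intergenic gaps, with alternating strands.
#' The central half of every intergenic gap is recorded as a non-transcribed
#' region, the anchor used for ChIP-seq background normalization.
#'
#' @param n_genes Number of genes.
#' @param length_range Two integers, min/max gene length in bp (sampled
#'   uniformly).
#' @param spacing Intergenic gap in bp between consecutive genes.
#' @param seed Integer seed; the annotation is deterministic given the seed.
#' @param chrom Chromosome name.
#' @return A list with elements `genes` (gene tibble), `nt_regions`
#'   (non-transcribed regions, tibble with `region_id`, `chrom`, `start`,
#'   `end`) and `chrom_sizes` (tibble with `chrom`, `size`).
#' @examples
#' gn <- synthetic_genome(5, c(2e3, 8e3), spacing = 4e3, seed = 1)
#' gn$genes
#' @export
synthetic_genome <- function(n_genes, length_range = c(10e3, 100e3),
                             spacing = 20e3, seed = 1, chrom = "chrSim") {
  if (n_genes < 0) abort_velo("`n_genes` must be >= 0")
  assert_scalar_number(spacing, "spacing", positive = TRUE)
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] <= 0) {
    abort_velo("`length_range` must be c(min, max) with 0 < min <= max")
  }
  lens <- with_seed(seed, {
    if (n_genes == 0) integer() else
      as.integer(round(stats::runif(n_genes, length_range[1], length_range[2])))
  })
  spacing <- as.integer(spacing)
  starts <- integer(n_genes)
  pos <- spacing
  for (i in seq_len(n_genes)) {
    starts[i] <- pos
    pos <- pos + lens[i] + spacing
  }
  genes <- tibble::tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = chrom,
    start = starts,
    end = starts + lens,
    strand = rep(c("+", "-"), length.out = n_genes),
    biotype = "protein_coding")
  # gaps: [0, first start) plus between genes plus trailing gap
  gap_starts <- c(0L, genes$end)
  gap_ends <- c(genes$start, pos)
  if (n_genes == 0) { gap_starts <- 0L; gap_ends <- spacing }
  q <- as.integer((gap_ends - gap_starts) / 4)
  nt <- tibble::tibble(
    region_id = sprintf("nt%04d", seq_along(gap_starts)),
    chrom = chrom,
    start = gap_starts + q,
    end = gap_ends - q)
  list(genes = gene_models(genes),
       nt_regions = nt,
       chrom_sizes = tibble::tibble(chrom = chrom, size = as.integer(pos)))
}

#' Validate non-transcribed regions against a gene annotation
#'
#' Background-normalization anchors must not overlap any gene; overlapping
#' regions are rejected here, at construction time.
#'
#' @param regions Tibble with `region_id`, `chrom`, `start`, `end`.
#' @param genes Gene-model tibble.
#' @return The validated `regions` tibble, invisibly unchanged.
#' @export
nontranscribed_regions <- function(regions, genes) {
  assert_columns(regions, c("region_id", "chrom", "start", "end"), "region table")
  genes <- gene_models(genes)
  rg <- GenomicRanges::GRanges(regions$chrom,
          IRanges::IRanges(regions$start + 1L, regions$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
          IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(rg, gg, ignore.strand = TRUE)
  if (length(hits) > 0) {
    bad <- regions$region_id[S4Vectors::queryHits(hits)[1]]
    abort_velo(sprintf("non-transcribed region %s overlaps a gene", bad))
  }
  tibble::as_tibble(regions)
}
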