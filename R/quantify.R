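#' Reduce fragments to the last incorporated base (mNET-seq convention)
#'
#' The 3'-most base of the nascent RNA marks the polymerase active site: a
#' `+` fragment `[s, e)` maps to base `e - 1`, a `-` fragment to base `s`.
#' Unstranded fragments are rejected.
#'
#' @param fragments Record tibble with `+`/`-` strands.
#' @return Width-1 tag-record tibble.
#' @export
last_base_positions <- function(fragments) {
  assert_columns(fragments, c("chrom", "start", "end", "strand"), "fragments")
  if (any(fragments$strand == ".")) {
    abort_velo("last-base reduction requires stranded fragments")
  }
  pos <- ifelse(fragments$strand == "+", fragments$end - 1L, fragments$start)
  out <- fragments
  out$start <- as.integer(pos)
  out$end <- as.integer(pos + 1L)
  out
}

#' Reduce fragments to their midpoints (TT-seq velocity convention)
#'
#' Midpoint is `(start + end) %/% 2` (right-of-center for even widths);
#' strand and record count are preserved.
#'
#' @param fragments Record tibble.
#' @return Width-1 tag-record tibble, one per input fragment.
#' @export
fragment_midpoints <- function(fragments) {
  assert_columns(fragments, c("chrom", "start", "end", "strand"), "fragments")
  pos <- (fragments$start + fragments$end) %/% 2L
  out <- fragments
  out$start <- as.integer(pos)
  out$end <- as.integer(pos + 1L)
  out
}

.records_to_granges <- function(records, star_dot = TRUE) {
  s <- records$strand
  if (star_dot) s[s == "."] <- "*"
  GenomicRanges::GRanges(records$chrom,
    IRanges::IRanges(records$start + 1L, records$end), strand = s)
}

#' Per-base coverage of tags or fragments as a run-length track
#'
#' Each record adds 1 (or `1/size factor` when `sf` is given, yielding
#' normalized coverage summed across samples) over its interval `[start, end)`
#' on its own strand; unstranded records are tracked under strand ".".
#'
#' @param records Record tibble (may mix samples; see `sf`).
#' @param sf Optional size-factor tibble (`sample`, `size_factor`): each
#'   record is weighted by the reciprocal of its sample's factor.
#' @return A run-length track tibble (`chrom`, `strand`, `start`, `end`,
#'   `value`), zero runs omitted.
#' @export
coverage_track <- function(records, sf = NULL) {
  empty <- tibble::tibble(chrom = character(), strand = character(),
                          start = integer(), end = integer(), value = numeric())
  if (nrow(records) == 0) return(empty)
  w <- rep(1, nrow(records))
  if (!is.null(sf)) {
    assert_columns(records, "sample", "records")
    m <- match(records$sample, sf$sample)
    if (anyNA(m)) abort_velo("records contain samples missing from `sf`")
    if (any(sf$size_factor <= 0)) abort_velo("size factors must be > 0")
    w <- 1 / sf$size_factor[m]
  }
  out <- lapply(split(seq_len(nrow(records)), records$strand), function(idx) {
    gr <- GenomicRanges::GRanges(records$chrom[idx],
            IRanges::IRanges(records$start[idx] + 1L, records$end[idx]))
    cov <- GenomicRanges::coverage(gr, weight = w[idx])
    per_chrom <- lapply(names(cov), function(ch) {
      r <- cov[[ch]]
      v <- S4Vectors::runValue(r)
      len <- S4Vectors::runLength(r)
      ends <- cumsum(len)
      keep <- v != 0
      tibble::tibble(chrom = ch,
                     start = as.integer(ends[keep] - len[keep]),
                     end = as.integer(ends[keep]),
                     value = as.numeric(v[keep]))
    })
    dplyr::bind_rows(per_chrom)
  })
  strands <- names(out)
  out <- dplyr::bind_rows(out, .id = "strand")
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(tibble::as_tibble(out[, c("chrom", "strand", "start", "end", "value")]),
                 .data$chrom, .data$strand, .data$start)
}

# materialize one (chrom, strand) of a run track as an Rle of given length
.track_rle <- function(track, chrom, strand, len) {
  tr <- track[track$chrom == chrom & track$strand == strand, ]
  r <- S4Vectors::Rle(0, len)
  if (nrow(tr) > 0) {
    tr <- tr[tr$start < len, ]
    s <- pmax(tr$start, 0L) + 1L
    e <- pmin(tr$end, len)
    keep <- e >= s
    if (any(keep)) {
      ir <- IRanges::IRanges(s[keep], e[keep])
      r <- r + S4Vectors::Rle(
        GenomicRanges::coverage(ir, weight = tr$value[keep], width = len))
    }
  }
  r
}

#' Aggregate a per-base track into fixed-width genomic bins
#'
#' Bin `b` covers `[b*w, (b+1)*w)` on the absolute genome grid (origin 0);
#' the bin value is the sum of per-base values. Total mass is conserved.
#'
#' @param track Run-length track tibble.
#' @param bin_width Bin width in bp, > 0.
#' @return A run-length track tibble whose runs are bins (start multiple of
#'   `bin_width`); zero bins omitted. Carries attribute `bin_width`.
#' @export
bin_track <- function(track, bin_width = 50) {
  assert_scalar_number(bin_width, "bin_width", positive = TRUE)
  bin_width <- as.integer(bin_width)
  assert_columns(track, c("chrom", "strand", "start", "end", "value"), "track")
  groups <- unique(track[, c("chrom", "strand")])
  out <- purrr::pmap_dfr(groups, function(chrom, strand) {
    tr <- track[track$chrom == chrom & track$strand == strand, ]
    len <- max(tr$end)
    nbin <- ceiling(len / bin_width)
    r <- .track_rle(tr, chrom, strand, nbin * bin_width)
    v <- IRanges::viewSums(IRanges::Views(r,
      IRanges::successiveIRanges(rep(bin_width, nbin))))
    keep <- which(v != 0)
    tibble::tibble(chrom = chrom, strand = strand,
                   start = (keep - 1L) * bin_width,
                   end = keep * bin_width,
                   value = as.numeric(v[keep]))
  })
  structure(tibble::as_tibble(out), bin_width = bin_width)
}

#' Count records per feature (strand-specific, IntersectionNotEmpty)
#'
#' A record is assigned to a feature if, after discarding bases shared by two
#' or more features, its remaining overlap is with exactly one feature (the
#' IntersectionNotEmpty mode). Records overlapping features but resolvable to
#' no single one are tallied as ambiguous; records overlapping nothing as
#' unassigned. With `ignore_strand = FALSE`, only same-strand overlaps count.
#'
#' @param records Record tibble with a `sample` column.
#' @param features Feature tibble (`gene_id` or `region_id` identifies rows)
#'   with `chrom`, `start`, `end` and, unless `ignore_strand`, `strand`.
#' @param ignore_strand Ignore strands (for unstranded ChIP data).
#' @return A wide count tibble (`feature_id` x samples) with a
#'   `counting_summary` attribute holding per-sample assigned / ambiguous /
#'   unassigned tallies (retrievable with [counting_summary()]).
#' @export
count_features <- function(records, features, ignore_strand = FALSE) {
  id_col <- intersect(c("gene_id", "region_id", "feature_id"), names(features))[1]
  if (is.na(id_col)) abort_velo("features need a gene_id/region_id/feature_id column")
  assert_columns(features, c("chrom", "start", "end"), "features")
  if (anyDuplicated(features[[id_col]])) abort_velo("feature ids must be unique")
  if (!"sample" %in% names(records)) records$sample <- "S1"
  samples <- unique(records$sample)
  ids <- features[[id_col]]

  fstrand <- if (ignore_strand || !"strand" %in% names(features)) {
    rep("*", nrow(features))
  } else features$strand
  fstrand[fstrand == "."] <- "*"
  fgr <- GenomicRanges::GRanges(features$chrom,
           IRanges::IRanges(features$start + 1L, features$end),
           strand = fstrand)

  if (nrow(records) == 0) {
    out <- tibble::tibble(feature_id = ids)
    return(structure(out, counting_summary = tibble::tibble(
      sample = character(), assigned = integer(), ambiguous = integer(),
      unassigned = integer())))
  }

  # disjoint feature pieces; pieces contributed by exactly one feature are
  # that feature's unique bases (shared bases are discarded by the mode)
  dj <- GenomicRanges::disjoin(fgr, with.revmap = TRUE,
                               ignore.strand = ignore_strand)
  rv <- S4Vectors::mcols(dj)$revmap
  n_owner <- S4Vectors::elementNROWS(rv)
  uniq_flat <- dj[n_owner == 1L]
  uniq_feature <- unlist(rv[n_owner == 1L])

  rgr <- .records_to_granges(records)
  if (ignore_strand) GenomicRanges::strand(rgr) <- "*"

  any_hit <- IRanges::overlapsAny(rgr, fgr, ignore.strand = ignore_strand)
  hits <- GenomicRanges::findOverlaps(rgr, uniq_flat,
                                      ignore.strand = ignore_strand)
  pair <- unique(tibble::tibble(rec = S4Vectors::queryHits(hits),
                                feat = uniq_feature[S4Vectors::subjectHits(hits)]))
  nfeat <- tabulate(pair$rec, nbins = nrow(records))
  assigned <- nfeat == 1L
  feat_of <- rep(NA_integer_, nrow(records))
  one <- pair[pair$rec %in% which(assigned), ]
  feat_of[one$rec] <- one$feat

  tab <- table(factor(ids[feat_of], levels = ids),
               factor(records$sample, levels = samples))
  counts <- tibble::as_tibble(as.data.frame.matrix(tab), .name_repair = "minimal")
  out <- tibble::tibble(feature_id = ids)
  for (s in samples) out[[s]] <- as.integer(counts[[s]])

  is_assigned <- assigned
  summ <- tibble::tibble(
    sample = samples,
    assigned = vapply(samples, function(s)
      sum(is_assigned & records$sample == s), 0L, USE.NAMES = FALSE),
    ambiguous = vapply(samples, function(s)
      sum(any_hit & !is_assigned & records$sample == s), 0L, USE.NAMES = FALSE),
    unassigned = vapply(samples, function(s)
      sum(!any_hit & records$sample == s), 0L, USE.NAMES = FALSE))
  structure(out, counting_summary = summ)
}

#' Per-sample assigned/ambiguous/unassigned tallies of a count table
#'
#' @param counts A count tibble from [count_features()].
#' @return Tibble with `sample`, `assigned`, `ambiguous`, `unassigned`.
#' @export
counting_summary <- function(counts) {
  attr(counts, "counting_summary")
}

#' Expression filter: median reads-per-kilobase over TT-seq samples
#'
#' RPK = count / (gene length / 1000). A gene is expressed when its median
#' RPK across the supplied TT-seq samples is strictly greater than the
#' threshold and it overlaps no other gene in the annotation (any strand).
#'
#' @param counts Wide count tibble (TT-seq samples; spike rows ignored).
#' @param genes Gene-model tibble.
#' @param threshold RPK threshold (default 10, strict `>`).
#' @return Tibble with `gene_id`, `length_bp`, `median_rpk`, `overlapping`,
#'   `expressed`.
#' @export
rpk_filter <- function(counts, genes, threshold = 10) {
  genes <- gene_models(genes)
  if (any(genes$end - genes$start <= 0)) abort_velo("zero-length gene")
  m <- match(genes$gene_id, counts$feature_id)
  if (anyNA(m)) abort_velo("counts are missing some genes")
  vals <- as.matrix(counts[m, setdiff(names(counts), "feature_id")])
  len <- genes$end - genes$start
  rpk <- vals / (len / 1000)
  med <- apply(rpk, 1, stats::median)
  gg <- GenomicRanges::GRanges(genes$chrom,
          IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::countOverlaps(gg, gg, ignore.strand = TRUE) > 1L
  tibble::tibble(gene_id = genes$gene_id, length_bp = len, median_rpk = med,
                 overlapping = ov, expressed = med > threshold & !ov)
}
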