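BED6_COLS <- c("chrom", "start", "end", "name", "score", "strand")

#' Read a BED6 file of fragment or tag records
#'
#' All coordinates are 0-based half-open (BED native). Malformed lines are
#' rejected with the offending line number.
#'
#' @param path File path.
#' @param sample Sample label attached to the records (default: file stem).
#' @return A record tibble with BED6 columns plus `sample`.
#' @export
read_bed6 <- function(path, sample = NULL) {
  sample <- sample %||% sub("\\.bed$", "", basename(path))
  df <- suppressWarnings(readr::read_tsv(
    path, col_names = BED6_COLS, comment = "#",
    col_types = readr::cols(chrom = "c", start = "d", end = "d",
                            name = "c", score = "d", strand = "c"),
    progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort_velo(sprintf("%s: malformed BED line %d (%s)", path, probs$row[1],
                       probs$expected[1]))
  }
  if (nrow(df) == 0) {
    out <- empty_records()
    out$sample <- character(0)
    return(out)
  }
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$chrom))
  if (length(bad) > 0) {
    abort_velo(sprintf("%s: malformed BED line %d (missing field)", path, bad[1]))
  }
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad) > 0) {
    abort_velo(sprintf("%s: line %d: start must satisfy 0 <= start < end",
                       path, bad[1]))
  }
  bad <- which(!(df$strand %in% c("+", "-", ".")))
  if (length(bad) > 0) {
    abort_velo(sprintf("%s: line %d: strand must be '+', '-' or '.'", path, bad[1]))
  }
  as_record_tibble(df$chrom, df$start, df$end, df$name, df$strand, sample)
}

#' Write records to a BED6 file
#'
#' @param records Record tibble (BED6 columns; extra columns ignored).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(records, path) {
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  assert_columns(records, BED6_COLS, "record table")
  readr::write_tsv(records[, BED6_COLS], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read a gene annotation from BED6
#'
#' Gene name is taken from the BED name field. Strand "." is rejected: genes
#' must be stranded for TSS/TES anchoring.
#'
#' @param path File path.
#' @return A validated gene-model tibble.
#' @export
read_gene_bed <- function(path) {
  rec <- read_bed6(path)
  bad <- which(rec$strand == ".")
  if (length(bad) > 0) {
    abort_velo(sprintf("%s: line %d: genes must have strand '+' or '-'",
                       path, bad[1]))
  }
  gene_models(tibble::tibble(gene_id = rec$name, chrom = rec$chrom,
                             start = rec$start, end = rec$end,
                             strand = rec$strand))
}

#' Write a stranded coverage track as a bedGraph file pair
#'
#' One file per strand (the two assays are strand specific). Zero-valued runs
#' are omitted and adjacent runs with equal value are merged. Negative values
#' are rejected.
#'
#' @param track A run-length track tibble (`chrom`, `strand`, `start`, `end`,
#'   `value`).
#' @param path_plus,path_minus Output paths for the two strands.
#' @return Invisibly, the two paths.
#' @export
write_bedgraph <- function(track, path_plus, path_minus) {
  assert_columns(track, c("chrom", "strand", "start", "end", "value"), "track")
  if (any(track$value < 0)) abort_velo("track values must be non-negative")
  for (s in c("+", "-")) {
    p <- if (s == "+") path_plus else path_minus
    tr <- dplyr::arrange(track[track$strand == s & track$value != 0, ],
                         .data$chrom, .data$start)
    # merge adjacent runs with identical value
    if (nrow(tr) > 1) {
      new_run <- c(TRUE, !(tr$chrom[-1] == tr$chrom[-nrow(tr)] &
                           tr$start[-1] == tr$end[-nrow(tr)] &
                           tr$value[-1] == tr$value[-nrow(tr)]))
      tr$grp <- cumsum(new_run)
      tr <- dplyr::summarise(dplyr::group_by(tr, .data$grp),
                             chrom = dplyr::first(.data$chrom),
                             start = min(.data$start), end = max(.data$end),
                             value = dplyr::first(.data$value), .groups = "drop")
      tr <- dplyr::arrange(tr[, c("chrom", "start", "end", "value")],
                           .data$chrom, .data$start)
    } else {
      tr <- tr[, c("chrom", "start", "end", "value")]
    }
    readr::write_tsv(tr, p, col_names = FALSE, progress = FALSE)
  }
  invisible(c(path_plus, path_minus))
}

#' Read a bedGraph file pair back into a stranded track
#'
#' @param path_plus,path_minus bedGraph paths written by [write_bedgraph()].
#' @return A run-length track tibble.
#' @export
read_bedgraph <- function(path_plus, path_minus) {
  one <- function(path, s) {
    df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                          col_types = "ciid", progress = FALSE)
    df$strand <- s
    df
  }
  out <- dplyr::bind_rows(one(path_plus, "+"), one(path_minus, "-"))
  tibble::as_tibble(out[, c("chrom", "strand", "start", "end", "value")])
}

#' Write a genes-x-samples count table to TSV
#'
#' @param counts Wide count tibble: `feature_id` column plus one column per
#'   sample.
#' @param path Output path.
#' @param header_lines Optional provenance comment lines (prefixed `#`).
#' @return `path`, invisibly.
#' @export
write_count_tsv <- function(counts, path, header_lines = NULL) {
  assert_columns(counts, "feature_id", "count table")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes-x-samples count table from TSV
#'
#' @param path File path.
#' @param integer_counts Require all counts to be non-negative integers
#'   (TRUE for raw TT-seq/mNET-seq tables).
#' @return Wide count tibble.
#' @export
read_count_tsv <- function(path, integer_counts = TRUE) {
  df <- suppressWarnings(readr::read_tsv(path, comment = "#",
    col_types = readr::cols(feature_id = "c", .default = "d"),
    progress = FALSE))
  if (!"feature_id" %in% names(df)) {
    abort_velo(sprintf("%s: missing feature_id column", path))
  }
  if (ncol(df) < 2) abort_velo(sprintf("%s: no sample columns", path))
  vals <- as.matrix(df[, -1])
  if (anyNA(vals)) abort_velo(sprintf("%s: missing count values", path))
  if (integer_counts && any(vals != round(vals) | vals < 0)) {
    abort_velo(sprintf("%s: counts must be non-negative integers", path))
  }
  tibble::as_tibble(df)
}

# write a tibble as TSV preceded by provenance comment lines
write_tsv_prov <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
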