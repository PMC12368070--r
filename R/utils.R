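# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code with a temporary RNG state seeded by `seed`, restoring the caller's
# stream afterwards so exported operations are deterministic without clobbering
# the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Expand one master seed into n reproducible substream seeds (fixed order).
# Kept strictly below .Machine$integer.max so derived seeds are valid inputs
# to set.seed() on 32-bit integer platforms.
substream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

abort_velo <- function(msg, class = "velocitt_error") {
  rlang::abort(msg, class = class)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_velo(sprintf("%s is missing required column(s): %s",
                       what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_velo(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort_velo(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) abort_velo(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

empty_records <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 name = character(), score = integer(), strand = character(),
                 sample = character())
}

as_record_tibble <- function(chrom, start, end, name, strand, sample) {
  tibble::tibble(chrom = as.character(chrom),
                 start = as.integer(start),
                 end = as.integer(end),
                 name = as.character(name),
                 score = 0L,
                 strand = as.character(strand),
                 sample = as.character(sample))
}
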