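#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metagene profile
#'
#' @param x A `metagene_profile` tibble.
#' @param ... Ignored.
#' @return A plain tibble, one row per metagene position.
#' @export
tidy.metagene_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a metagene profile
#'
#' @param x A `metagene_profile` tibble.
#' @param ... Ignored.
#' @return Tibble with `n_genes`, `iters`, `level`, `n_positions`.
#' @export
glance.metagene_profile <- function(x, ...) {
  tibble::tibble(n_genes = attr(x, "n_genes"), iters = attr(x, "iters"),
                 level = attr(x, "level"), n_positions = nrow(x))
}

#' Tidy a velocity or aligned matrix
#'
#' @param x A `velocity_matrix` or `aligned_matrix` tibble.
#' @param ... Ignored.
#' @return A plain long tibble (gene x bin).
#' @export
tidy.velocity_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.velocity_matrix
#' @export
tidy.aligned_matrix <- tidy.velocity_matrix

#' One-row summary of a velocity matrix
#'
#' @param x A `velocity_matrix` tibble.
#' @param ... Ignored.
#' @return Tibble with gene count, bin width and NA fraction.
#' @export
glance.velocity_matrix <- function(x, ...) {
  val <- intersect(c("ratio", "change", "value"), names(x))[1]
  tibble::tibble(n_genes = length(unique(x$gene_id)),
                 bin_width = attr(x, "bin_width"),
                 na_fraction = mean(is.na(x[[val]])))
}

#' @rdname glance.velocity_matrix
#' @export
glance.aligned_matrix <- glance.velocity_matrix
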