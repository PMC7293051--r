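# broom-style tidiers for the package's fitted/derived objects.

#' Tidy a cluster assignment
#' @param x A `sed_clusters` object.
#' @param ... Unused.
#' @return Tibble `entity_id`, `cluster`.
#' @export
tidy.sed_clusters <- function(x, ...) {
  as_tibble(x$assignment)
}

#' One-row summary of a cluster assignment
#' @param x A `sed_clusters` object.
#' @param ... Unused.
#' @return Tibble with `n_entities`, `n_clusters`, `largest_cluster`,
#'   `metric`, `linkage`, `cut`, `cut_value`.
#' @export
glance.sed_clusters <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  tibble(
    n_entities = nrow(x$assignment),
    n_clusters = length(sizes),
    largest_cluster = if (length(sizes)) max(sizes) else 0L,
    metric = x$params$metric,
    linkage = x$params$linkage,
    cut = x$params$cut,
    cut_value = x$params$cut_value
  )
}

#' Tidy a weighted-count comparison
#' @param x A `sed_comparison` object.
#' @param ... Unused.
#' @return Tibble `entity_id`, `x`, `y`, `residual`.
#' @export
tidy.sed_comparison <- function(x, ...) x$data

#' One-row summary of a weighted-count comparison
#' @param x A `sed_comparison` object.
#' @param ... Unused.
#' @return Tibble with `r`, `n_shared`, `log2_transform`.
#' @export
glance.sed_comparison <- function(x, ...) {
  tibble(r = x$r, n_shared = x$n_shared, log2_transform = x$log2_transform)
}

#' Tidy a shuffled-assignment permutation null
#' @param x A `sed_perm_null` object.
#' @param ... Unused.
#' @return Tibble with `cluster`, `median_r`, `origin` (`observed`/`null`),
#'   `perm` (NA for observed rows).
#' @export
tidy.sed_perm_null <- function(x, ...) {
  bind_rows(
    x$observed |> mutate(origin = "observed", perm = NA_integer_),
    x$null |> mutate(origin = "null") |> select(-"n_proteins")
  )
}

#' One-row summary of a permutation null
#' @param x A `sed_perm_null` object.
#' @param ... Unused.
#' @return Tibble with observed/null medians, the one-sided rank-sum p, and
#'   the permutation count and seed.
#' @export
glance.sed_perm_null <- function(x, ...) {
  tt <- perm_null_test(x)
  tibble(
    observed_median = median(x$observed$median_r),
    null_median = median(x$null$median_r),
    p_value = tt$p_value,
    n_clusters = nrow(x$observed),
    n_perm = x$n_perm,
    seed = x$seed
  )
}

#' One-row summary of an RBP-RNA correlation screen
#' @param x An `rbp_correlation` tibble.
#' @param ... Unused.
#' @return Tibble with `rbp_id`, `threshold`, `n_rna`, `n_correlated`,
#'   `n_fractions`.
#' @export
glance.rbp_correlation <- function(x, ...) {
  tibble(
    rbp_id = attr(x, "rbp_id"),
    threshold = attr(x, "threshold"),
    n_rna = nrow(x),
    n_correlated = sum(x$correlated),
    n_fractions = attr(x, "n_fractions")
  )
}
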