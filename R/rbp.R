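# RBP-target prediction by co-fractionation: correlate an RNA-binding
# protein's peptide profile with RNA profiles (or RNA cluster means) and call
# RNAs exceeding a correlation threshold as candidate targets.

#' Correlate one RBP peptide profile with all RNA profiles
#'
#' @param rna A normalized RNA `sed_profile` tibble.
#' @param rbp A one-row `sed_profile` (or tibble with `entity_id` +
#'   `frac<i>` columns) holding the RBP's normalized peptide profile.
#' @param threshold Correlation cutoff for target calls; RNAs with
#'   `r > threshold` (strictly) form the correlated set. Default 0.85.
#' @return An `rbp_correlation` object: tibble `entity_id`, `r`, `correlated`,
#'   with attributes `rbp_id`, `threshold`, `n_fractions` (shared fractions
#'   used; peptide fractions are intersected with RNA fractions).
#' @export
correlate_rbp_to_rnas <- function(rna, rbp, threshold = 0.85) {
  stopifnot(inherits(rna, "sed_profile"))
  assert_scalar_number(threshold, "threshold", min = -1, max = 1)
  rbp <- as_tibble(rbp)
  if (nrow(rbp) != 1L) {
    stop_cosedim("`rbp` must be a single profile row.", "cosedim_validation_error")
  }
  rbp_id <- as.character(rbp$entity_id)
  rbp_idx <- as.integer(sub("^frac", "", setdiff(names(rbp), "entity_id")))
  shared <- intersect(fraction_indices(rna), rbp_idx)
  if (length(shared) < 3L) {
    stop_cosedim("Fewer than 3 shared fractions.", "cosedim_validation_error")
  }
  pv <- as.numeric(rbp[paste0("frac", sort(shared))])
  if (sd(pv) == 0) {
    stop_cosedim("RBP profile is constant over the shared fractions.",
                 "cosedim_constant_error")
  }
  rm <- profile_values(restrict_fractions(rna, shared))
  rs <- apply(rm, 1, sd)
  r <- rep(NA_real_, nrow(rm))
  r[rs > 0] <- as.vector(cor(t(rm[rs > 0, , drop = FALSE]), pv))
  out <- tibble(entity_id = rownames(rm), r = r,
                correlated = !is.na(r) & r > threshold)
  structure(out,
            rbp_id = rbp_id, threshold = threshold, n_fractions = length(shared),
            class = c("rbp_correlation", class(out)))
}

#' Correlate RBP peptide profiles with RNA cluster mean profiles
#'
#' Each RBP is correlated against every cluster's mean normalized RNA profile
#' over the shared fractions; pairs exceeding the threshold are reported and
#' each RBP's best pair is flagged.
#'
#' @param rbps A protein `sed_profile` tibble of RBP peptide profiles.
#' @param cluster_means Cluster mean profiles from [cluster_mean_profiles()].
#' @param threshold Correlation cutoff (strict `>`), default 0.85.
#' @return Tibble `rbp_id`, `cluster`, `r`, `best` with only above-threshold
#'   pairs; attribute `full_r` holds the complete RBP-by-cluster correlation
#'   matrix.
#' @export
correlate_rbps_to_clusters <- function(rbps, cluster_means, threshold = 0.85) {
  stopifnot(inherits(rbps, "sed_profile"))
  assert_scalar_number(threshold, "threshold", min = -1, max = 1)
  cm <- mean_profiles_as_sed(as_tibble(cluster_means))
  shared <- shared_fractions(rbps, cm)
  if (length(shared) < 3L) {
    stop_cosedim("Fewer than 3 shared fractions.", "cosedim_validation_error")
  }
  rm <- profile_values(restrict_fractions(rbps, shared))
  km <- profile_values(restrict_fractions(cm, shared))
  full <- suppressWarnings(cor(t(rm), t(km)))
  rownames(full) <- rownames(rm)
  colnames(full) <- as.character(as_tibble(cluster_means)$cluster)
  pairs <- as_tibble(as.table(full), .name_repair = "minimal")
  names(pairs) <- c("rbp_id", "cluster", "r")
  pairs$cluster <- as.integer(as.character(pairs$cluster))
  out <- pairs |>
    filter(!is.na(.data$r), .data$r > threshold)
  out <- if (nrow(out)) {
    out |>
      group_by(.data$rbp_id) |>
      mutate(best = .data$r == max(.data$r)) |>
      ungroup() |>
      arrange(.data$rbp_id, desc(.data$r))
  } else {
    out |> mutate(best = logical(0))
  }
  attr(out, "full_r") <- full
  attr(out, "threshold") <- threshold
  out
}

#' CLIP binding-site density stratified by profile correlation
#'
#' Bins genes by their correlation to an RBP's peptide profile and compares
#' the distribution of CLIP site density (binding sites per unit expression)
#' between bins. If correlation to the RBP reflects genuine binding, density
#' should rise across bins.
#'
#' @param clip Tibble `entity_id`, `sites` (nonnegative counts).
#' @param expression Tibble `entity_id`, `tpm` (positive expression summary,
#'   e.g. mean TPM across the gradient).
#' @param correlations Tibble `entity_id`, `r` (e.g. an [correlate_rbp_to_rnas()]
#'   result).
#' @param bin_edges Increasing numeric vector covering `[-1, 1]`; genes are
#'   binned into left-open intervals (lowest edge closed). Default
#'   `c(-1, 0, 0.85, 1)`: anti/uncorrelated, intermediate, strongly correlated.
#' @return A `clip_bins` object: list with `densities` (tibble `entity_id`,
#'   `r`, `density`, `bin`), `medians` (per-bin median density), and `tests`
#'   (pairwise rank-sum p with BH `q` across bin pairs; empty bins are
#'   excluded with a warning).
#' @export
clip_density_by_bin <- function(clip, expression, correlations,
                                bin_edges = c(-1, 0, 0.85, 1)) {
  stopifnot(is.numeric(bin_edges), length(bin_edges) >= 3L,
            !is.unsorted(bin_edges, strictly = TRUE))
  if (bin_edges[1L] > -1 || bin_edges[length(bin_edges)] < 1) {
    stop_cosedim("`bin_edges` must cover [-1, 1].", "cosedim_validation_error")
  }
  d <- as_tibble(correlations)["entity_id"] |>
    mutate(r = as_tibble(correlations)$r) |>
    inner_join(as_tibble(clip), by = "entity_id") |>
    inner_join(as_tibble(expression), by = "entity_id")
  if (any(d$tpm <= 0)) {
    stop_cosedim("Expression summary must be positive for all included genes.",
                 "cosedim_validation_error")
  }
  d <- d |>
    mutate(density = .data$sites / .data$tpm,
           bin = cut(.data$r, breaks = bin_edges, include.lowest = TRUE))
  counts <- table(d$bin)
  empty <- names(counts)[counts == 0L]
  if (length(empty)) {
    warn(sprintf("Empty correlation bin(s) excluded from tests: %s.",
                 paste(empty, collapse = ", ")))
  }
  used <- names(counts)[counts > 0L]
  medians <- d |>
    group_by(.data$bin) |>
    summarise(n = n(), median_density = median(.data$density), .groups = "drop")
  tests <- if (length(used) >= 2L) {
    purrr::map_dfr(utils::combn(used, 2L, simplify = FALSE), function(pr) {
      xa <- d$density[d$bin == pr[1L]]
      xb <- d$density[d$bin == pr[2L]]
      tibble(bin_a = pr[1L], bin_b = pr[2L],
             p = rank_sum_test(xa, xb)$p_value)
    }) |>
      mutate(q = p.adjust(.data$p, method = "BH"))
  } else {
    tibble(bin_a = character(), bin_b = character(), p = numeric(), q = numeric())
  }
  structure(list(densities = d, medians = medians, tests = tests,
                 bin_edges = bin_edges),
            class = "clip_bins")
}

#' @export
print.clip_bins <- function(x, ...) {
  cat("<clip_bins> median CLIP density by correlation bin:\n")
  print(as.data.frame(x$medians), row.names = FALSE)
  invisible(x)
}
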