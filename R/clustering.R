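# Co-sedimentation clustering: group entities whose normalized gradient
# profiles share a shape, using agglomerative hierarchical clustering.

#' Hierarchically cluster normalized sedimentation profiles
#'
#' Groups entities by profile-shape similarity. The default metric is
#' correlation distance (1 - Pearson between row profiles), matching the idea
#' that co-sedimenting RNAs have highly correlated relative profiles
#' regardless of absolute abundance; the default cut at distance 0.3 keeps
#' within-cluster profile correlations roughly above 0.7.
#'
#' @param x A normalized `sed_profile` tibble (see [normalize_profiles()]).
#' @param metric `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"`, or `"ward"` (Ward.D2).
#' @param cut Cut criterion: `"distance"` (tree height) or `"n_clusters"`.
#' @param cut_value Height for `"distance"` cuts (default 0.3) or the desired
#'   cluster count for `"n_clusters"`.
#' @return A `sed_clusters` object: list with `assignment` (tibble
#'   `entity_id`, `cluster`; cluster ids contiguous from 1, ranked by
#'   decreasing size with ties broken by first occurrence), `params`, and the
#'   underlying `hclust` tree. Clustering is deterministic for fixed input;
#'   merge ties are resolved by `stats::hclust`'s fixed ordering.
#' @export
cluster_profiles <- function(x,
                             metric = c("correlation", "euclidean"),
                             linkage = c("average", "complete", "ward"),
                             cut = c("distance", "n_clusters"),
                             cut_value = 0.3) {
  stopifnot(inherits(x, "sed_profile"))
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  cut <- match.arg(cut)
  assert_scalar_number(cut_value, "cut_value", min = 0)
  m <- profile_values(x)
  if (nrow(m) < 2L) {
    stop_cosedim("Clustering needs at least 2 entities.", "cosedim_validation_error")
  }
  if (metric == "correlation") {
    rs <- apply(m, 1, sd)
    if (any(rs == 0)) {
      stop_cosedim(
        sprintf("Constant profile(s) under correlation metric: %s.",
                paste(head(rownames(m)[rs == 0], 10), collapse = ", ")),
        "cosedim_constant_error"
      )
    }
    d <- as.dist(1 - cor(t(m)))
  } else {
    d <- dist(m)
  }
  method <- c(average = "average", complete = "complete", ward = "ward.D2")[[linkage]]
  tree <- hclust(d, method = method)
  raw <- if (cut == "distance") {
    cutree(tree, h = cut_value)
  } else {
    if (cut_value < 1 || cut_value > nrow(m)) {
      stop_cosedim("`cut_value` for n_clusters must be in [1, n_entities].",
                   "cosedim_validation_error")
    }
    cutree(tree, k = as.integer(cut_value))
  }
  relabeled <- relabel_by_size(raw)
  structure(
    list(
      assignment = tibble(entity_id = rownames(m), cluster = relabeled),
      params = list(metric = metric, linkage = linkage, cut = cut,
                    cut_value = cut_value),
      tree = tree
    ),
    class = "sed_clusters"
  )
}

# Rank cluster labels by decreasing member count (ties: smaller first member
# index wins) so cluster 1 is always the largest -- stable reporting.
relabel_by_size <- function(labels) {
  sizes <- table(labels)
  first_seen <- tapply(seq_along(labels), labels, min)
  ord <- order(-as.integer(sizes), first_seen[names(sizes)])
  map <- setNames(seq_along(ord), names(sizes)[ord])
  unname(map[as.character(labels)])
}

#' @export
print.sed_clusters <- function(x, ...) {
  k <- max(x$assignment$cluster)
  cat(sprintf("<sed_clusters> %d entities in %d cluster(s); metric=%s, linkage=%s, cut=%s@%g\n",
              nrow(x$assignment), k, x$params$metric, x$params$linkage,
              x$params$cut, x$params$cut_value))
  invisible(x)
}

#' Drop small co-sedimentation clusters
#'
#' Retains clusters with at least `min_size` members; the default of 20 keeps
#' only groups large enough for downstream set enrichment. Retained clusters
#' are relabeled contiguously from 1 (still ranked by size).
#'
#' @param clusters A `sed_clusters` object.
#' @param min_size Minimum member count (default 20).
#' @return A `sed_clusters` object containing only the retained entities, with
#'   `params$retained` / `params$dropped` cluster counts recorded.
#' @export
filter_clusters_by_size <- function(clusters, min_size = 20) {
  stopifnot(inherits(clusters, "sed_clusters"))
  assert_scalar_number(min_size, "min_size", min = 1)
  a <- clusters$assignment
  sizes <- dplyr::count(a, .data$cluster)
  keep <- sizes$cluster[sizes$n >= min_size]
  inform(sprintf("filter_clusters_by_size: retained %d of %d clusters (min_size %d).",
                 length(keep), nrow(sizes), as.integer(min_size)))
  kept <- dplyr::filter(a, .data$cluster %in% keep)
  if (nrow(kept)) kept$cluster <- relabel_by_size(kept$cluster)
  out <- clusters
  out$assignment <- kept
  out$params$min_size <- min_size
  out$params$retained <- length(keep)
  out$params$dropped <- nrow(sizes) - length(keep)
  out
}

#' Mean normalized profile of each cluster
#'
#' @param clusters A `sed_clusters` object.
#' @param x The normalized `sed_profile` tibble the clusters were derived from
#'   (every clustered entity must be present).
#' @return A tibble with `cluster`, `n_members`, and one `frac<i>` column per
#'   fraction holding the arithmetic mean of member rows (each mean profile
#'   sums to 1 when the input rows do).
#' @export
cluster_mean_profiles <- function(clusters, x) {
  stopifnot(inherits(clusters, "sed_clusters"), inherits(x, "sed_profile"))
  a <- clusters$assignment
  missing <- setdiff(a$entity_id, x$entity_id)
  if (length(missing)) {
    stop_cosedim(sprintf("Clustered entities missing from profile table: %s.",
                         paste(head(missing, 5), collapse = ", ")),
                 "cosedim_validation_error")
  }
  m <- profile_values(x)[a$entity_id, , drop = FALSE]
  means <- rowsum(m, group = a$cluster) / as.vector(table(a$cluster))
  dplyr::bind_cols(
    tibble(cluster = as.integer(rownames(means)),
           n_members = as.vector(table(a$cluster))),
    as_tibble(means)
  ) |>
    arrange(.data$cluster)
}

# Coerce a cluster-mean tibble into a sed_profile so profile machinery
# (correlation, plotting) applies to cluster means directly.
mean_profiles_as_sed <- function(means, kind = "rna") {
  tbl <- dplyr::bind_cols(
    tibble(entity_id = paste0("cluster_", means$cluster)),
    means[setdiff(names(means), c("cluster", "n_members"))]
  )
  new_sed_profile(tbl, kind, normalized = TRUE)
}
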