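# Gradient-level statistics: the fraction-weighted count summary, comparisons
# against reference per-gene scalars (e.g. ribosome-footprint TPM), RNA-protein
# co-sedimentation correlations, and the shuffled-assignment permutation null.

#' Fraction-weighted counts
#'
#' Collapses each entity's raw gradient distribution to a single scalar,
#' `sum over fractions i in [first, last] of i * n_i`, where `n_i` is the raw
#' abundance (TPM) in physical fraction i. Heavier-sedimenting entities score
#' higher. Raw, unnormalized values are used: the statistic is meant to be
#' compared against total-abundance references.
#'
#' @param x A raw `sed_profile` tibble.
#' @param first,last Inclusive physical fraction range. Defaults 3 and 24, the
#'   usable range of a 24-fraction gradient; use 1 and 7 for a 7-peak polysome
#'   profile.
#' @return Tibble `entity_id`, `weighted_count`.
#' @export
weighted_counts <- function(x, first = 3, last = 24) {
  stopifnot(inherits(x, "sed_profile"))
  assert_scalar_number(first, "first", min = 1)
  assert_scalar_number(last, "last", min = first)
  idx <- fraction_indices(x)
  wanted <- seq.int(first, last)
  missing <- setdiff(wanted, idx)
  if (length(missing)) {
    stop_cosedim(sprintf("Requested fractions absent from the table: %s.",
                         paste(missing, collapse = ", ")),
                 "cosedim_validation_error")
  }
  m <- profile_values(x)[, paste0("frac", wanted), drop = FALSE]
  tibble(entity_id = rownames(m),
         weighted_count = as.vector(m %*% wanted))
}

#' Compare weighted counts to a per-gene reference scalar
#'
#' Correlates the gradient's weighted counts against an external per-gene
#' scalar (e.g. ribosome-footprint TPM) over the shared gene set, and flags
#' off-diagonal structure via signed orthogonal (total least squares)
#' residuals from the principal axis. A gene group sedimenting lighter than
#' its ribosome load predicts shows systematically negative residuals.
#'
#' @param weighted Tibble `entity_id`, `weighted_count` (see [weighted_counts()]).
#' @param reference Tibble with `entity_id` and one numeric value column
#'   (second column used).
#' @param log2_transform Compare on `log2(v + 1)` (default; both axes span
#'   orders of magnitude).
#' @return A `sed_comparison` object: list with `r` (Pearson over shared
#'   genes), `data` (tibble `entity_id`, `x` = transformed weighted count,
#'   `y` = transformed reference, `residual` = signed orthogonal deviation,
#'   positive when the weighted count exceeds the principal-axis prediction),
#'   `n_shared`, `log2_transform`.
#' @export
compare_weighted_to_reference <- function(weighted, reference,
                                          log2_transform = TRUE) {
  w <- as_tibble(weighted)
  r <- as_tibble(reference)
  stopifnot("entity_id" %in% names(w), "entity_id" %in% names(r))
  ref_col <- setdiff(names(r), "entity_id")[1L]
  shared <- inner_join(
    w |> select("entity_id", wc = "weighted_count"),
    r |> select("entity_id", ref = all_of(ref_col)),
    by = "entity_id"
  )
  if (nrow(shared) < 10L) {
    stop_cosedim(sprintf("Only %d shared genes; at least 10 required.", nrow(shared)),
                 "cosedim_validation_error")
  }
  xv <- shared$wc
  yv <- shared$ref
  if (log2_transform) {
    xv <- log2(xv + 1)
    yv <- log2(yv + 1)
  }
  rho <- pearson_cor(xv, yv)
  cx <- xv - mean(xv)
  cy <- yv - mean(yv)
  v <- prcomp(cbind(cx, cy), center = FALSE, scale. = FALSE)$rotation[, 1L]
  if (v[1L] < 0) v <- -v  # principal axis points along increasing x
  # Signed perpendicular distance; normal chosen so residual > 0 means the
  # point lies on the large-x (heavier weighted count) side of the axis.
  normal <- c(v[2L], -v[1L])
  if (normal[1L] < 0) normal <- -normal
  resid <- cx * normal[1L] + cy * normal[2L]
  structure(
    list(
      r = rho,
      data = tibble(entity_id = shared$entity_id, x = xv, y = yv, residual = resid),
      n_shared = nrow(shared),
      log2_transform = log2_transform
    ),
    class = "sed_comparison"
  )
}

#' @export
print.sed_comparison <- function(x, ...) {
  cat(sprintf("<sed_comparison> %d shared genes, Pearson r = %.3f (log2: %s)\n",
              x$n_shared, x$r, x$log2_transform))
  invisible(x)
}

#' Correlate each RNA's profile with its encoded protein's profile
#'
#' Pearson correlation between normalized RNA and protein profiles over the
#' fractions shared by the two tables (typically protein fractions form a
#' subset of RNA fractions). A positive correlation means the transcript
#' co-sediments with its protein product.
#'
#' @param rna,protein Normalized `sed_profile` tibbles.
#' @param id_map Tibble `rna_id`, `protein_id` pairing transcripts to encoded
#'   proteins. Pairs referencing absent ids are skipped with a warning.
#' @return Tibble `rna_id`, `protein_id`, `r`, `n_fractions`.
#' @export
rna_protein_correlations <- function(rna, protein, id_map) {
  stopifnot(inherits(rna, "sed_profile"), inherits(protein, "sed_profile"))
  map <- as_tibble(id_map)
  stopifnot(all(c("rna_id", "protein_id") %in% names(map)))
  shared <- shared_fractions(rna, protein)
  if (length(shared) < 3L) {
    stop_cosedim("Fewer than 3 shared fractions between RNA and protein tables.",
                 "cosedim_validation_error")
  }
  rm <- profile_values(restrict_fractions(rna, shared))
  pm <- profile_values(restrict_fractions(protein, shared))
  ok <- map$rna_id %in% rownames(rm) & map$protein_id %in% rownames(pm)
  if (any(!ok)) {
    warn(sprintf("%d pairing(s) reference absent ids; skipped.", sum(!ok)))
    map <- map[ok, ]
  }
  if (!nrow(map)) {
    stop_cosedim("No usable RNA-protein pairs.", "cosedim_empty_error")
  }
  map |>
    mutate(
      r = purrr::map2_dbl(.data$rna_id, .data$protein_id,
                          function(g, p) pearson_cor(rm[g, ], pm[p, ])),
      n_fractions = length(shared)
    )
}

#' Annotation rate in the tails of a correlation distribution
#'
#' Proportion of genes carrying an annotation (e.g. a predicted signal
#' sequence) among the most positively and most negatively RNA-protein
#' correlated genes. Ties at the percentile boundary are broken by
#' lexicographic gene id so the selection is deterministic.
#'
#' @param correlations Tibble with an id column (`rna_id` or `entity_id`) and
#'   column `r`.
#' @param annotation Tibble `entity_id`, `flag` (logical); missing genes count
#'   as `FALSE`.
#' @param pct Tail width in percent (0 < pct < 50), default 20.
#' @return A list with `top_rate`, `bottom_rate`, `n_tail`.
#' @export
percentile_annotation_rate <- function(correlations, annotation, pct = 20) {
  assert_scalar_number(pct, "pct", min = 1e-9, max = 50 - 1e-9)
  cc <- as_tibble(correlations)
  idcol <- intersect(c("rna_id", "entity_id"), names(cc))[1L]
  stopifnot(!is.na(idcol), "r" %in% names(cc))
  if (nrow(cc) < 10L) {
    stop_cosedim("At least 10 genes are required.", "cosedim_validation_error")
  }
  ann <- as_tibble(annotation)
  flags <- setNames(as.logical(ann$flag), ann$entity_id)
  ids <- cc[[idcol]]
  fl <- flags[ids]
  fl[is.na(fl)] <- FALSE
  n_tail <- max(1L, floor(nrow(cc) * pct / 100))
  ord_top <- order(-cc$r, ids)
  ord_bot <- order(cc$r, ids)
  list(
    top_rate = mean(fl[ord_top[seq_len(n_tail)]]),
    bottom_rate = mean(fl[ord_bot[seq_len(n_tail)]]),
    n_tail = n_tail
  )
}

#' Median pairwise profile correlation within a member set
#'
#' Median Pearson correlation over all member pairs, the within-cluster
#' coherence statistic. Exact over all `choose(k, 2)` pairs for up to 200
#' members; larger sets are first down-sampled to 200 members (deterministic
#' under `seed`) and the median is computed on that subset's pairs.
#'
#' @param x A `sed_profile` tibble.
#' @param members Character vector of at least 2 entity ids present in `x`.
#' @param seed Seed used only when down-sampling kicks in.
#' @return Single numeric median pairwise correlation.
#' @export
cluster_median_pairwise <- function(x, members, seed = 1L) {
  stopifnot(inherits(x, "sed_profile"))
  members <- unique(as.character(members))
  missing <- setdiff(members, x$entity_id)
  if (length(missing)) {
    stop_cosedim(sprintf("Members missing from profile table: %s.",
                         paste(head(missing, 5), collapse = ", ")),
                 "cosedim_validation_error")
  }
  if (length(members) < 2L) {
    stop_cosedim("At least 2 members are required.", "cosedim_validation_error")
  }
  if (length(members) > 200L) {
    members <- withr::with_seed(seed, sample(members, 200L))
  }
  m <- profile_values(x)[members, , drop = FALSE]
  cc <- suppressWarnings(cor(t(m)))
  median(cc[upper.tri(cc)])
}

#' Permutation null for per-cluster protein coherence
#'
#' Tests whether proteins encoded by co-clustered RNAs co-sediment more than
#' chance predicts. Observed statistic: for every cluster with at least 2
#' proteins measured, the median pairwise correlation of member protein
#' profiles. Null: protein profiles are reassigned to clusters by a uniform
#' random permutation of protein ids and the medians recomputed, `n_perm`
#' times.
#'
#' @param clusters A `sed_clusters` object (RNA cluster assignment; entity ids
#'   are gene ids).
#' @param protein A normalized protein `sed_profile` tibble whose entity ids
#'   are the gene ids of the encoded proteins.
#' @param n_perm Number of permutations (default 100).
#' @param seed RNG seed recorded in the result.
#' @param perm_fun Permutation generator taking the protein id vector and
#'   returning a permuted vector; the default draws a uniform permutation.
#'   (Passing `identity` reproduces the observed medians, useful for checks.)
#' @return A `sed_perm_null` object: list with `observed` (tibble `cluster`,
#'   `n_proteins`, `median_r`), `null` (tibble `perm`, `cluster`, `median_r`),
#'   `n_perm`, `seed`, `n_skipped` (cluster-permutation combinations with < 2
#'   proteins, skipped).
#' @export
shuffled_assignment_null <- function(clusters, protein, n_perm = 100, seed = 1L,
                                     perm_fun = NULL) {
  stopifnot(inherits(clusters, "sed_clusters"), inherits(protein, "sed_profile"))
  assert_scalar_number(n_perm, "n_perm", min = 1)
  a <- clusters$assignment |> filter(.data$entity_id %in% protein$entity_id)
  if (!nrow(a)) {
    stop_cosedim("No clustered gene has a measured protein profile.",
                 "cosedim_empty_error")
  }
  pm <- profile_values(protein)[a$entity_id, , drop = FALSE]
  medians_for <- function(ids) {
    # ids: protein row ids assigned, in order, to a$cluster
    split_idx <- split(ids, a$cluster)
    purrr::imap_dfr(split_idx, function(mem, cl) {
      if (length(mem) < 2L) return(tibble())
      cc <- suppressWarnings(cor(t(pm[mem, , drop = FALSE])))
      tibble(cluster = as.integer(cl), n_proteins = length(mem),
             median_r = median(cc[upper.tri(cc)]))
    })
  }
  observed <- medians_for(a$entity_id)
  n_skipped <- 0L
  null <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_perm), function(p) {
      ids <- if (is.null(perm_fun)) sample(a$entity_id) else perm_fun(a$entity_id)
      med <- medians_for(ids)
      n_skipped <<- n_skipped + (length(unique(a$cluster)) - nrow(med))
      if (nrow(med)) med$perm <- p
      med
    })
  })
  structure(
    list(observed = observed, null = null, n_perm = n_perm, seed = seed,
         n_skipped = n_skipped),
    class = "sed_perm_null"
  )
}

#' @export
print.sed_perm_null <- function(x, ...) {
  cat(sprintf("<sed_perm_null> %d clusters, %d permutations (seed %d); observed median of medians %.3f vs null %.3f\n",
              nrow(x$observed), x$n_perm, x$seed,
              median(x$observed$median_r), median(x$null$median_r)))
  invisible(x)
}

#' Test observed cluster coherence against its permutation null
#'
#' One-sided rank-sum test that the observed per-cluster protein medians
#' exceed the pooled shuffled-assignment null.
#'
#' @param x A `sed_perm_null` object.
#' @return List with `statistic` and `p_value` (see [rank_sum_test()]).
#' @export
perm_null_test <- function(x) {
  stopifnot(inherits(x, "sed_perm_null"))
  rank_sum_test(x$observed$median_r, x$null$median_r, alternative = "greater")
}
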