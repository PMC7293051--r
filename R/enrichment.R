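# Gene-set enrichment over co-sedimentation clusters: Fisher's exact test
# with Bonferroni correction for cluster queries, and a ranked-list minimum
# hypergeometric (min-HG) scan with BH FDR for correlation-ordered lists.

#' Build a gene-set collection over a universe
#'
#' @param sets Named list of character vectors (set name -> member gene ids).
#' @param universe Character vector of gene ids defining the background; here
#'   this is typically the genes that survived the expression floor and
#'   entered clustering, not the whole genome.
#' @return A `gene_set_collection`: list with `sets` (members intersected with
#'   the universe; empty sets dropped with a warning) and `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (!length(universe)) {
    stop_cosedim("Universe must be non-empty.", "cosedim_validation_error")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop_cosedim("All sets must be named.", "cosedim_validation_error")
  }
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    warn(sprintf("Dropping %d set(s) with no members in the universe: %s.",
                 length(empty), paste(head(empty, 5), collapse = ", ")))
    sets <- sets[lengths(sets) > 0L]
  }
  structure(list(sets = sets, universe = universe), class = "gene_set_collection")
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member ids, tab-separated.
#'
#' @param path Path to a GMT file.
#' @param universe Gene universe; defaults to the union of all members.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop_cosedim(sprintf("GMT line(s) with fewer than 3 fields: %s.",
                         paste(head(which(bad), 5), collapse = ", ")),
                 "cosedim_parse_error")
  }
  sets <- setNames(lapply(parts, function(p) p[-(1:2)]),
                   vapply(parts, `[[`, "", 1L))
  gene_set_collection(sets, universe %||% unique(unlist(sets)))
}

#' Write gene sets in GMT format
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @param description Description field written for every set (second column).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "na") {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, description, collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# One-sided (over-representation) hypergeometric tail P(X >= k).
hyper_tail <- function(k, n, K, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher's exact over-representation of gene sets in a query
#'
#' For each set, tests whether the query (e.g. one co-sedimentation cluster)
#' contains more set members than expected under random draws from the
#' universe. The one-sided Fisher p equals the hypergeometric tail
#' `P(X >= k)`; Bonferroni correction multiplies by the number of sets tested.
#' Fold enrichment is observed over expected membership, `k / (n K / N)`.
#'
#' @param query Character vector of gene ids (ids outside the universe are
#'   dropped with a warning).
#' @param collection A [gene_set_collection()].
#' @param alpha Significance level applied to the Bonferroni-adjusted p.
#' @return A tibble sorted by `p_raw` with columns `set`, `k` (overlap), `n`
#'   (query size), `K` (set size), `N` (universe size), `fold_enrichment`,
#'   `p_raw`, `p_adjusted`, `significant`, `method`.
#' @export
fisher_enrichment <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  assert_scalar_number(alpha, "alpha", min = 0, max = 1)
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warn(sprintf("%d query id(s) outside the universe dropped.", length(outside)))
    query <- setdiff(query, outside)
  }
  if (!length(query)) {
    stop_cosedim("Query is empty after intersection with the universe.",
                 "cosedim_empty_error")
  }
  N <- length(collection$universe)
  n <- length(query)
  m <- length(collection$sets)
  res <- purrr::map_dfr(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    K <- length(members)
    k <- length(intersect(query, members))
    tibble(
      set = nm, k = k, n = n, K = K, N = N,
      fold_enrichment = if (k == 0) 0 else k / (n * K / N),
      p_raw = if (k == 0) 1 else hyper_tail(k, n, K, N)
    )
  })
  res |>
    mutate(
      p_adjusted = pmin(1, m * .data$p_raw),
      significant = .data$p_adjusted < alpha,
      method = "fisher_bonferroni"
    ) |>
    arrange(.data$p_raw, .data$set)
}

#' Ranked-list minimum-hypergeometric enrichment
#'
#' Threshold-free enrichment for a gene list ordered by some score (here,
#' usually Pearson correlation to an RBP or protein profile, highest first).
#' For each set, every prefix of the list is treated as a candidate query and
#' the minimal hypergeometric tail p over prefixes is reported (min-HG), with
#' the optimizing prefix length. The min-HG score is anti-conservative across
#' prefixes (no exact multiple-testing correction over thresholds is applied);
#' BH q-values are computed across sets.
#'
#' @param ranked Character vector: an ordered permutation of a subset of the
#'   universe, best-ranked first.
#' @param collection A [gene_set_collection()].
#' @return A tibble sorted by `p_raw`: `set`, `k` (members at the optimizing
#'   prefix), `n` (optimizing prefix length), `K`, `N` (ranked-list length),
#'   `fold_enrichment` at the optimizing prefix, `p_raw` (min-HG), `q_value`
#'   (BH across sets), `method`. Sets with no member in the list are skipped
#'   with a warning.
#' @export
ranked_enrichment <- function(ranked, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ranked <- as.character(ranked)
  if (any(duplicated(ranked))) {
    stop_cosedim("Ranked list contains duplicates.", "cosedim_validation_error")
  }
  if (length(setdiff(ranked, collection$universe))) {
    stop_cosedim("Ranked list contains ids outside the universe.",
                 "cosedim_validation_error")
  }
  N <- length(ranked)
  res <- purrr::map_dfr(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    K <- sum(ranked %in% members)
    if (K == 0L) {
      warn(sprintf("Set '%s' has no members in the ranked list; skipped.", nm))
      return(tibble())
    }
    hits <- cumsum(ranked %in% members)
    prefix <- seq_len(N)
    p <- hyper_tail(hits, prefix, K, N)
    best <- which.min(p)
    tibble(
      set = nm, k = hits[best], n = best, K = K, N = N,
      fold_enrichment = hits[best] / (best * K / N),
      p_raw = p[best]
    )
  })
  if (!nrow(res)) {
    stop_cosedim("No set had members in the ranked list.", "cosedim_empty_error")
  }
  res |>
    mutate(q_value = p.adjust(.data$p_raw, method = "BH"),
           method = "min_hg_bh") |>
    arrange(.data$p_raw, .data$set)
}

#' Per-cluster annotation proportions for compartment scatter plots
#'
#' For each cluster, the proportion of member genes carrying each of two
#' orthogonal annotations (e.g. membership in an ER proximity-labeling set and
#' a predicted signal sequence), plus an optional enrichment flag for
#' coloring. Genes without an annotation entry count as unannotated, with a
#' warning.
#'
#' @param clusters A `sed_clusters` object.
#' @param annotations Tibble with columns `entity_id`, `in_apex`, `has_signal`
#'   (logical).
#' @param enriched_flags Optional tibble `cluster`, `flag` with flag values
#'   `"target_go"`, `"other_go"`, `"none"`; missing clusters get `"none"`.
#' @return Tibble: `cluster`, `n_members`, `prop_apex`, `prop_signal`, `flag`.
#' @export
cluster_annotation_scatter <- function(clusters, annotations,
                                       enriched_flags = NULL) {
  stopifnot(inherits(clusters, "sed_clusters"))
  a <- clusters$assignment
  ann <- as_tibble(annotations)
  stopifnot(all(c("entity_id", "in_apex", "has_signal") %in% names(ann)))
  joined <- left_join(a, ann, by = "entity_id")
  n_missing <- sum(is.na(joined$in_apex) | is.na(joined$has_signal))
  if (n_missing) {
    warn(sprintf("%d gene(s) lacked annotations; counted as unannotated.", n_missing))
  }
  joined$in_apex[is.na(joined$in_apex)] <- FALSE
  joined$has_signal[is.na(joined$has_signal)] <- FALSE
  out <- joined |>
    group_by(.data$cluster) |>
    summarise(n_members = n(),
              prop_apex = mean(.data$in_apex),
              prop_signal = mean(.data$has_signal),
              .groups = "drop")
  if (is.null(enriched_flags)) {
    out$flag <- "none"
  } else {
    out <- left_join(out, as_tibble(enriched_flags), by = "cluster")
    out$flag[is.na(out$flag)] <- "none"
  }
  out
}
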