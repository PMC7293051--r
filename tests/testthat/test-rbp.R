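# RBP-target prediction, hexamer statistics, CLIP density bins.

test_that("RBP-RNA correlation hits the exact limits and respects the threshold", {
  prof <- c(0.4, 0.3, 0.2, 0.1)
  rna <- make_profile(c(prof, rev(prof)), 3:6, ids = c("same", "flip"),
                      normalized = TRUE)
  rbp <- make_profile(prof, 3:6, ids = "rbp1", kind = "protein",
                      normalized = TRUE)
  rc <- correlate_rbp_to_rnas(rna, rbp, threshold = 0.85)
  expect_equal(rc$r[rc$entity_id == "same"], 1)
  expect_true(rc$correlated[rc$entity_id == "same"])
  expect_false(rc$correlated[rc$entity_id == "flip"])
  # threshold 1.0 excludes everything except exact equality (strict >)
  rc1 <- correlate_rbp_to_rnas(rna, rbp, threshold = 1.0)
  expect_equal(sum(rc1$correlated), 0L)
  flat <- make_profile(rep(0.25, 4), 3:6, ids = "flat", kind = "protein")
  expect_error(correlate_rbp_to_rnas(rna, flat),
               class = "cosedim_constant_error")
})

test_that("raising the threshold never grows the correlated set", {
  sim <- small_sim()
  norm <- suppressMessages(normalize_profiles(sim$rna))
  rbp_norm <- suppressMessages(normalize_profiles(sim$rbp, 0))
  rbp <- rbp_norm[rbp_norm$entity_id == sim$truth$planted_rbp, ]
  sizes <- vapply(seq(0.5, 0.95, by = 0.05), function(th) {
    sum(correlate_rbp_to_rnas(norm, rbp, threshold = th)$correlated)
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("a planted RBP recovers its compartment with high sensitivity/specificity", {
  sim <- default_sim()
  norm <- suppressMessages(normalize_profiles(sim$rna))
  rbp_norm <- suppressMessages(normalize_profiles(sim$rbp, 0))
  rbp <- rbp_norm[rbp_norm$entity_id == sim$truth$planted_rbp, ]
  rc <- correlate_rbp_to_rnas(norm, rbp, threshold = 0.85)
  tm <- truth_metrics(sim, rbp_result = rc)
  expect_gte(tm$rbp_recall, 0.8)
  expect_lte(tm$rbp_fpr, 0.05)
})

test_that("RBP-to-cluster matching flags the best cluster and recovers truth", {
  means <- tibble::tibble(cluster = 1:2, n_members = c(3L, 3L),
                          frac3 = c(0.5, 0.1), frac4 = c(0.3, 0.2),
                          frac5 = c(0.15, 0.3), frac6 = c(0.05, 0.4))
  rbp <- make_profile(c(0.5, 0.3, 0.15, 0.05), 3:6, ids = "rbpX",
                      kind = "protein", normalized = TRUE)
  res <- correlate_rbps_to_clusters(rbp, means, threshold = 0.85)
  expect_equal(res$cluster[res$best], 1L)
  expect_equal(res$r[res$best], 1)
  # nothing above an unreachable threshold
  res_hi <- correlate_rbps_to_clusters(rbp, means, threshold = 1)
  expect_equal(nrow(res_hi), 0L)
  # simulated RBPs map to the clusters holding their compartments
  sim <- default_sim()
  norm <- suppressMessages(normalize_profiles(sim$rna))
  cl <- cluster_profiles(norm)
  cm <- cluster_mean_profiles(cl, norm)
  rbp_norm <- suppressMessages(normalize_profiles(sim$rbp, 0))
  matches <- correlate_rbps_to_clusters(rbp_norm, cm, threshold = 0.85)
  truth <- dplyr::inner_join(cl$assignment, sim$truth$compartments,
                             by = "entity_id")
  majority <- truth |>
    dplyr::filter(!is.na(.data$compartment)) |>
    dplyr::count(.data$compartment, .data$cluster) |>
    dplyr::group_by(.data$compartment) |>
    dplyr::slice_max(.data$n, n = 1) |>
    dplyr::ungroup()
  best <- matches |> dplyr::filter(.data$best)
  joined <- dplyr::inner_join(best, sim$truth$rbps, by = "rbp_id") |>
    dplyr::inner_join(majority, by = "compartment", suffix = c("_hit", "_true"))
  expect_gte(sum(joined$cluster_hit == joined$cluster_true), 4L)
})

test_that("hexamer counts follow the overlapping-window convention", {
  hx <- hexamer_enrichment("AAAAAAA", "ACGTACGTACGT")
  expect_equal(hx$fg_count[hx$hexamer == "AAAAAA"],
               oracle_count_motif("AAAAAAA", "AAAAAA"))
  expect_equal(hx$fg_count[hx$hexamer == "AAAAAA"], 2L)
  # identical composition means every log2 ratio is exactly zero
  s <- "ACGTTGCAACGTGGCATCA"
  hx0 <- hexamer_enrichment(s, s)
  expect_true(all(hx0$log2_ratio == 0))
})

test_that("total hexamer count equals L - 5 for N-free sequences", {
  withr::with_seed(17, {
    for (i in 1:10) {
      L <- sample(6:300, 1)
      s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      hx <- hexamer_enrichment(s, "ACGTAC")
      expect_equal(sum(hx$fg_count), L - 5L)
    }
  })
  # windows containing N are skipped: every 6-window of this sequence spans the N
  hxn <- hexamer_enrichment("AAANAAAAA", "ACGTAC")
  expect_equal(sum(hxn$fg_count), 0L)
})

test_that("log2 ratios negate under foreground/background swap", {
  a <- c("ACGTACGTGGCA", "TTTTGCATGCAT")
  b <- c("GGGGCCCCAAAA", "ACACACACACAC")
  h1 <- hexamer_enrichment(a, b, pseudocount = 1)
  h2 <- hexamer_enrichment(b, a, pseudocount = 1)
  j <- dplyr::inner_join(as.data.frame(h1), as.data.frame(h2), by = "hexamer")
  expect_equal(j$log2_ratio.x, -j$log2_ratio.y, tolerance = 1e-12)
})

test_that("conservation rates match all-true, all-false, and Bernoulli masks", {
  seqs <- c(a = "ACGTACGTACGT")
  all_true <- list(a = rep(TRUE, 12))
  r1 <- hexamer_conservation_rate(seqs, all_true)
  expect_true(all(r1$conservation_rate == 1))
  all_false <- list(a = rep(FALSE, 12))
  r0 <- hexamer_conservation_rate(seqs, all_false)
  expect_true(all(r0$conservation_rate == 0))
  # Bernoulli(0.5) masks: overall conservation rate ~ 0.5^6
  withr::with_seed(23, {
    L <- 20000
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    mask <- runif(L) < 0.5
    rr <- hexamer_conservation_rate(setNames(s, "x"), list(x = mask))
    pooled <- sum(rr$n_conserved) / sum(rr$n_instances)
    expect_lt(abs(pooled - 0.5^6), 0.002)
  })
  expect_error(hexamer_conservation_rate(seqs, list(a = rep(TRUE, 5))),
               class = "cosedim_validation_error")
})

test_that("the planted hexamer ranks at the top of the enrichment", {
  sim <- default_sim()
  norm <- suppressMessages(normalize_profiles(sim$rna))
  rbp_norm <- suppressMessages(normalize_profiles(sim$rbp, 0))
  rc <- correlate_rbp_to_rnas(norm,
                              rbp_norm[rbp_norm$entity_id == sim$truth$planted_rbp, ])
  fg <- sim$utrs[sim$utrs$entity_id %in% rc$entity_id[rc$correlated], ]
  bg <- sim$utrs[sim$utrs$entity_id %in%
                   setdiff(rc$entity_id, fg$entity_id), ]
  hx <- hexamer_enrichment(fg, bg)
  expect_lte(truth_metrics(sim, hexamer_stats = hx)$motif_rank, 10L)
})

test_that("CLIP density tests are exact in the constructed extreme", {
  # top-bin densities all strictly above bottom-bin (6 vs 6): exact two-sided
  # rank-sum p = 2 / C(12, 6)
  clip <- tibble::tibble(entity_id = sprintf("g%02d", 1:12),
                         sites = c(1:6, 101:106))
  expr <- tibble::tibble(entity_id = clip$entity_id, tpm = rep(1, 12))
  corrs <- tibble::tibble(entity_id = clip$entity_id,
                          r = c(rep(-0.5, 6), rep(0.95, 6)))
  cb <- suppressWarnings(clip_density_by_bin(clip, expr, corrs))
  p_top_bottom <- cb$tests$p[cb$tests$bin_a == "[-1,0]" &
                               cb$tests$bin_b == "(0.85,1]"]
  expect_equal(p_top_bottom, 2 / choose(12, 6), tolerance = 1e-12)
  expect_equal(p_top_bottom,
               oracle_rank_sum_p(1:6 / 1, 101:106 / 1, "two.sided"),
               tolerance = 1e-12)
  # identical densities everywhere: all p = 1
  clip_same <- tibble::tibble(entity_id = clip$entity_id, sites = rep(5L, 12))
  cb_same <- suppressWarnings(clip_density_by_bin(clip_same, expr, corrs))
  expect_true(all(cb_same$tests$p == 1))
})

test_that("CLIP density medians rise across correlation bins on simulated targets", {
  sim <- default_sim()
  norm <- suppressMessages(normalize_profiles(sim$rna))
  rbp_norm <- suppressMessages(normalize_profiles(sim$rbp, 0))
  rc <- correlate_rbp_to_rnas(norm,
                              rbp_norm[rbp_norm$entity_id == sim$truth$planted_rbp, ])
  cb <- suppressWarnings(clip_density_by_bin(sim$clip, sim$expression, rc))
  med <- cb$medians$median_density
  expect_false(is.unsorted(med))
  expect_gt(med[length(med)], med[1])
})
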