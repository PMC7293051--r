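# Weighted counts, reference comparisons, RNA-protein correlation structure,
# and the shuffled-assignment permutation null.

test_that("weighted counts reduce correctly and match the brute-force sum", {
  nf <- length(3:24)
  single <- rep(0, nf); single[5 - 2] <- 10  # abundance 10 in fraction 5 only
  p <- make_profile(c(single, rep(0, nf), rep(1, nf)), 3:24,
                    ids = c("one", "zero", "unif"))
  wc <- weighted_counts(p, 3, 24)
  expect_equal(wc$weighted_count[wc$entity_id == "one"], 50)
  expect_equal(wc$weighted_count[wc$entity_id == "zero"], 0)
  brute <- 0; for (i in 3:24) brute <- brute + i * 1.0
  expect_equal(wc$weighted_count[wc$entity_id == "unif"], brute)
  expect_equal(brute, 297)
  expect_error(weighted_counts(p, 1, 24), class = "cosedim_validation_error")
})

test_that("weighted counts are linear and single-fraction ranges reduce to i * column", {
  m1 <- withr::with_seed(4, matrix(rexp(3 * 5), 3, 5))
  m2 <- withr::with_seed(5, matrix(rexp(3 * 5), 3, 5))
  p1 <- make_profile(as.vector(t(m1)), 3:7)
  p2 <- make_profile(as.vector(t(m2)), 3:7)
  p12 <- make_profile(as.vector(t(m1 + m2)), 3:7)
  expect_equal(weighted_counts(p12, 3, 7)$weighted_count,
               weighted_counts(p1, 3, 7)$weighted_count +
                 weighted_counts(p2, 3, 7)$weighted_count,
               tolerance = 1e-12)
  expect_equal(weighted_counts(p1, 5, 5)$weighted_count,
               5 * unname(profile_values(p1)[, "frac5"]), tolerance = 1e-12)
})

test_that("comparison against an identical reference gives r = 1 and zero residuals", {
  wc <- tibble::tibble(entity_id = sprintf("g%02d", 1:12),
                       weighted_count = (1:12) * 10)
  ref <- tibble::tibble(entity_id = wc$entity_id, tpm = wc$weighted_count)
  cmp <- compare_weighted_to_reference(wc, ref)
  expect_equal(cmp$r, 1)
  expect_true(all(abs(cmp$data$residual) < 1e-9))
  expect_error(compare_weighted_to_reference(wc[1:5, ], ref),
               class = "cosedim_validation_error")
})

test_that("ribosome-driven gradients track a total-abundance reference closely", {
  # compartment structure off: sedimentation reflects only per-gene scale
  cfg <- simulation_config(alpha = 0, n_background = 0, seed = 2)
  sim <- simulate_gradient(cfg)
  wc <- weighted_counts(sim$rna, 3, 24)
  totals <- tibble::tibble(entity_id = sim$rna$entity_id,
                           tpm = rowSums(profile_values(sim$rna)))
  cmp <- compare_weighted_to_reference(wc, totals)
  expect_gte(cmp$r, 0.95)
})

test_that("a light-shifted compartment shows negative orthogonal residuals", {
  sim <- default_sim()
  wc <- weighted_counts(sim$rna, 3, 24)
  # reference: expression-level scalar blind to position in the gradient
  totals <- tibble::tibble(entity_id = sim$rna$entity_id,
                           tpm = rowSums(profile_values(sim$rna)))
  cmp <- compare_weighted_to_reference(wc, totals)
  truth <- sim$truth$compartments
  d <- dplyr::inner_join(cmp$data, truth, by = "entity_id")
  light <- d$residual[d$compartment %in% "secretory_er"]
  rest <- d$residual[!(d$compartment %in% "secretory_er")]
  expect_lt(median(light), 0)
  expect_lt(rank_sum_test(light, rest, alternative = "less")$p_value, 0.01)
})

test_that("RNA-protein correlations hit the exact limits on shared fractions", {
  prof <- c(0.4, 0.3, 0.2, 0.1)  # linear, so its reversal is exactly anti-correlated
  rna <- make_profile(c(prof, prof), 3:6, ids = c("same", "flip"),
                      normalized = TRUE)
  prot <- make_profile(c(prof, rev(prof)), 3:6, ids = c("same", "flip"),
                       normalized = TRUE)
  res <- rna_protein_correlations(rna, prot,
                                  tibble::tibble(rna_id = c("same", "flip"),
                                                 protein_id = c("same", "flip")))
  expect_equal(res$r[res$rna_id == "same"], 1)
  expect_equal(res$r[res$rna_id == "flip"], -1)
  expect_equal(unique(res$n_fractions), 4L)
  expect_warning(
    rna_protein_correlations(rna, prot,
                             tibble::tibble(rna_id = c("same", "ghost"),
                                            protein_id = c("same", "ghost"))),
    "absent"
  )
})

test_that("simulated coupling yields a negative-median correlation histogram", {
  sim <- default_sim()
  norm <- suppressMessages(normalize_profiles(sim$rna))
  pnorm <- suppressMessages(normalize_profiles(sim$protein, 0))
  corrs <- rna_protein_correlations(norm, pnorm, sim$id_map)
  expect_equal(nrow(corrs), nrow(sim$id_map))
  expect_lt(median(corrs$r), 0)
})

test_that("percentile annotation rates use deterministic tie-breaks", {
  cc <- tibble::tibble(entity_id = sprintf("g%02d", 1:10),
                       r = c(0.9, 0.8, 0.7, 0.6, 0.5, -0.5, -0.6, -0.7, -0.8, -0.9))
  ann_all <- tibble::tibble(entity_id = cc$entity_id, flag = TRUE)
  rates <- percentile_annotation_rate(cc, ann_all, pct = 20)
  expect_equal(rates$top_rate, 1)
  expect_equal(rates$bottom_rate, 1)
  ann_half <- tibble::tibble(entity_id = cc$entity_id, flag = c(rep(TRUE, 5), rep(FALSE, 5)))
  rates2 <- percentile_annotation_rate(cc, ann_half, pct = 20)
  expect_equal(rates2$top_rate, 1)
  expect_equal(rates2$bottom_rate, 0)
  # ties at the boundary resolve by lexicographic id
  tied <- tibble::tibble(entity_id = c("b", "a", "c", "d", "e", "f", "g", "h", "i", "j"),
                         r = c(1, 1, rep(0, 8)))
  ann_a <- tibble::tibble(entity_id = "a", flag = TRUE)
  expect_equal(percentile_annotation_rate(tied, ann_a, pct = 10)$top_rate, 1)
})

test_that("median pairwise correlation handles exact and simulated cases", {
  p <- make_profile(rep(c(0.5, 0.3, 0.2), 3), 1:3, ids = c("a", "b", "c"),
                    normalized = TRUE)
  expect_equal(cluster_median_pairwise(p, c("a", "b", "c")), 1)
  mono <- c(0.1, 0.2, 0.3, 0.4)
  p2 <- make_profile(c(mono, rev(mono), mono), 1:4, ids = c("p", "q", "p2"))
  # pairwise correlations {1, -1, -1}: median -1
  expect_equal(cluster_median_pairwise(p2, c("p", "q", "p2")), -1)
  expect_error(cluster_median_pairwise(p, "a"), class = "cosedim_validation_error")
  sim <- default_sim()
  norm <- suppressMessages(normalize_profiles(sim$rna))
  truth <- sim$truth$compartments
  members <- intersect(truth$entity_id[truth$compartment %in% "golgi_vesicle"],
                       norm$entity_id)
  expect_gte(cluster_median_pairwise(norm, members), 0.85)
})

test_that("identity permutation reproduces observed medians exactly", {
  sim <- small_sim()
  norm <- suppressMessages(normalize_profiles(sim$rna))
  pnorm <- suppressMessages(normalize_profiles(sim$protein, 0))
  cl <- cluster_profiles(norm)
  null <- shuffled_assignment_null(cl, pnorm, n_perm = 1, seed = 1,
                                   perm_fun = identity)
  expect_equal(null$null$median_r, null$observed$median_r)
})

test_that("independent random protein profiles give a null centered near zero", {
  m <- withr::with_seed(13, matrix(rexp(50 * 17), 50, 17))
  prot <- make_profile(as.vector(t(m)), 3:19, ids = sprintf("p%02d", 1:50))
  cl <- structure(list(
    assignment = tibble::tibble(entity_id = sprintf("p%02d", 1:50),
                                cluster = rep(1:5, each = 10L)),
    params = list()
  ), class = "sed_clusters")
  null <- shuffled_assignment_null(cl, prot, n_perm = 100, seed = 2)
  expect_lt(abs(mean(null$null$median_r)), 0.05)
})

test_that("permutation null is exchangeable across seeds", {
  sim <- small_sim()
  norm <- suppressMessages(normalize_profiles(sim$rna))
  pnorm <- suppressMessages(normalize_profiles(sim$protein, 0))
  cl <- cluster_profiles(norm)
  n1 <- shuffled_assignment_null(cl, pnorm, n_perm = 60, seed = 101)
  n2 <- shuffled_assignment_null(cl, pnorm, n_perm = 60, seed = 202)
  se <- sqrt(stats::var(n1$null$median_r) / nrow(n1$null) +
               stats::var(n2$null$median_r) / nrow(n2$null))
  expect_lt(abs(mean(n1$null$median_r) - mean(n2$null$median_r)), 3 * se)
})

test_that("observed protein coherence beats the shuffled null on coupled data", {
  sim <- default_sim()
  norm <- suppressMessages(normalize_profiles(sim$rna))
  pnorm <- suppressMessages(normalize_profiles(sim$protein, 0))
  cl <- suppressMessages(filter_clusters_by_size(cluster_profiles(norm), 20))
  null <- shuffled_assignment_null(cl, pnorm, n_perm = 100, seed = 1)
  expect_lt(perm_null_test(null)$p_value, 0.01)
})

test_that("rank_sum_test matches exact enumeration for small groups", {
  withr::with_seed(31, {
    for (i in 1:12) {
      n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
      x <- rnorm(n1); y <- rnorm(n2, 0.5)
      for (alt in c("two.sided", "greater", "less")) {
        expect_equal(rank_sum_test(x, y, alt)$p_value,
                     oracle_rank_sum_p(x, y, alt), tolerance = 1e-12,
                     info = sprintf("rep %d alt %s", i, alt))
      }
    }
  })
  # all-tied degenerate case: no rank information, p = 1 by convention
  expect_equal(rank_sum_test(rep(1, 4), rep(1, 5))$p_value, 1)
})
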