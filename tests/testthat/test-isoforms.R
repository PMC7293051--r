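# Delta-PSI screen: confidence filtering, span computation, classification,
# and conservation comparisons.

toy_psi <- function() {
  read_psi_table(system.file("extdata", "psi_toy.tsv", package = "cosedim"))
}

test_that("the PSI reader validates structure and bounds", {
  t <- toy_psi()
  expect_s3_class(t, "psi_table")
  expect_equal(nrow(t), 30L)
  bad <- as.data.frame(t)
  bad$ci_low[1] <- 0.5  # above psi
  expect_error(psi_table(bad), class = "cosedim_validation_error")
  expect_error(psi_table(data.frame(event_id = "e")),
               class = "cosedim_validation_error")
  off <- as.data.frame(t)
  sel <- off$isoform_id == "ev5.2"
  off$psi[sel] <- 0.5  # sums become 0.9 != 1
  off$ci_low[sel] <- 0.45
  off$ci_high[sel] <- 0.55
  expect_warning(psi_table(off), "sums off")
})

test_that("confidence filter applies the strict all-fractions rule", {
  t <- toy_psi()
  f <- suppressMessages(filter_confident(t, 0.2))
  # ev4.1 has one fraction at width 0.25 -> isoform out; ev4 left with one
  # isoform -> whole event out. Hand count: 4 events x 2 isoforms x 3 fractions.
  expect_equal(nrow(f), 24L)
  expect_setequal(unique(f$event_id), c("ev1", "ev2", "ev3", "ev5"))
  expect_false("ev4" %in% f$event_id)
  # widths all zero are retained
  zero <- psi_table(data.frame(event_id = "e", event_type = "AFE",
                               isoform_id = c("i1", "i1", "i2", "i2"),
                               fraction = c(3L, 4L, 3L, 4L),
                               psi = c(0.4, 0.6, 0.6, 0.4),
                               ci_low = c(0.4, 0.6, 0.6, 0.4),
                               ci_high = c(0.4, 0.6, 0.6, 0.4)))
  expect_equal(nrow(suppressMessages(filter_confident(zero, 0.2))), 4L)
  # idempotence
  f2 <- suppressMessages(filter_confident(f, 0.2))
  expect_equal(as.data.frame(f2), as.data.frame(f))
})

test_that("delta-PSI is the brute-force max minus min and is order invariant", {
  psi_vals <- c(0.1, 0.3, 0.9, 0.2)
  t <- psi_table(data.frame(
    event_id = "e", event_type = "ALE",
    isoform_id = rep(c("i1", "i2"), each = 4),
    fraction = rep(3:6, 2),
    psi = c(psi_vals, 1 - psi_vals),
    ci_low = c(psi_vals, 1 - psi_vals) - 0.01,
    ci_high = c(psi_vals, 1 - psi_vals) + 0.01
  ))
  dp <- max_delta_psi(t)
  brute <- -Inf
  for (i in seq_along(psi_vals)) for (j in seq_along(psi_vals)) {
    brute <- max(brute, psi_vals[i] - psi_vals[j])
  }
  expect_equal(dp$delta_psi, brute)
  expect_equal(dp$delta_psi, 0.8)
  # reordering fractions changes nothing
  t2 <- t[order(-t$fraction), ]
  class(t2) <- class(t)
  expect_equal(max_delta_psi(t2)$delta_psi, 0.8)
  # relabeling psi -> 1 - psi leaves the span unchanged (two-isoform symmetry)
  t3 <- t
  t3$psi <- 1 - t3$psi
  tmp <- t3$ci_low; t3$ci_low <- 1 - t3$ci_high; t3$ci_high <- 1 - tmp
  class(t3) <- class(t)
  expect_equal(max_delta_psi(t3)$delta_psi, 0.8)
  # constant psi has zero span; single-fraction events error
  const <- psi_table(data.frame(event_id = "c", event_type = "AFE",
                                isoform_id = rep(c("i1", "i2"), each = 3),
                                fraction = rep(3:5, 2),
                                psi = rep(c(0.4, 0.6), each = 3),
                                ci_low = rep(c(0.35, 0.55), each = 3),
                                ci_high = rep(c(0.45, 0.65), each = 3)))
  expect_equal(max_delta_psi(const)$delta_psi, 0)
  single <- const[const$fraction == 3, ]
  class(single) <- class(const)
  expect_error(max_delta_psi(single), class = "cosedim_validation_error")
})

test_that("classification respects the boundary-down convention", {
  ev <- tibble::tibble(event_id = paste0("e", 1:5),
                       delta_psi = c(0.96, 0.25, 0.1, 0.3, 0.6))
  lab <- classify_events(ev)
  expect_equal(as.character(lab$class),
               c("strong", "non_regulated", "non_regulated", "moderate", "strong"))
  expect_equal(as.vector(table(lab$class)), c(2L, 1L, 2L))
  # delta exactly at the strong cut is moderate
  expect_equal(as.character(classify_events(tibble::tibble(delta_psi = 0.5))$class),
               "moderate")
  expect_error(classify_events(ev, strong_cut = 0.2, moderate_cut = 0.4),
               class = "cosedim_validation_error")
})

test_that("the toy fixture screens end-to-end exactly as hand-computed", {
  t <- toy_psi()
  ev <- classify_events(max_delta_psi(suppressMessages(filter_confident(t))))
  expect_equal(nrow(ev), 4L)
  got <- setNames(as.character(ev$class), ev$event_id)
  expect_equal(got[["ev1"]], "strong")      # span 0.9 - 0.1 = 0.8
  expect_equal(got[["ev2"]], "moderate")    # span 0.8 - 0.5 = 0.3
  expect_equal(got[["ev3"]], "non_regulated")  # span 0.1
  expect_equal(got[["ev5"]], "non_regulated")  # span 0
  expect_equal(ev$delta_psi[ev$event_id == "ev1"], 0.8)
  expect_equal(ev$delta_psi[ev$event_id == "ev2"], 0.3)
})

test_that("conservation tests are exact in the separable case and flat under ties", {
  labels <- tibble::tibble(
    event_id = paste0("e", 1:10),
    class = factor(rep(c("strong", "non_regulated"), each = 5),
                   levels = c("strong", "moderate", "non_regulated"))
  )
  scores <- tibble::tibble(event_id = labels$event_id,
                           score = c(11:15, 1:5))
  res <- suppressWarnings(conservation_group_test(labels, scores))
  expect_equal(res$tests$p, 1 / choose(10, 5), tolerance = 1e-12)
  # identical scores: p = 1
  flat <- tibble::tibble(event_id = labels$event_id, score = rep(2, 10))
  res_flat <- suppressWarnings(conservation_group_test(labels, flat))
  expect_equal(res_flat$tests$p, 1)
  # ECDF reaches 1 within each class
  tops <- res$ecdf |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(top = max(.data$ecdf), .groups = "drop")
  expect_true(all(tops$top == 1))
})

test_that("classes planted in the simulator are recovered without confusion", {
  sim <- default_sim()
  conf <- suppressMessages(filter_confident(sim$psi))
  ev <- classify_events(max_delta_psi(conf))
  cm <- truth_metrics(sim, psi_classes = ev)$psi_confusion
  expect_equal(sum(diag(cm)), sum(cm))
})
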