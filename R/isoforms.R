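# Alternative first/last exon screening: which isoform events shift their
# isoform usage (PSI) across the gradient, and are shifting events more
# conserved than static ones?

psi_required_cols <- c("event_id", "event_type", "isoform_id", "fraction",
                       "psi", "ci_low", "ci_high")

#' Validate a per-fraction isoform PSI table
#'
#' @param df Data frame with columns `event_id`, `event_type` (`"AFE"` or
#'   `"ALE"`), `isoform_id`, `fraction` (physical fraction number), `psi`,
#'   `ci_low`, `ci_high` (all PSI values and bounds in `[0, 1]` with
#'   `ci_low <= psi <= ci_high`).
#' @return A `psi_table` tibble. Within each event and fraction the isoform
#'   PSI values should sum to 1; deviations beyond 0.05 (estimation slop) are
#'   warned about, not rejected.
#' @export
psi_table <- function(df) {
  t <- as_tibble(df)
  missing <- setdiff(psi_required_cols, names(t))
  if (length(missing)) {
    stop_cosedim(sprintf("PSI table missing column(s): %s.",
                         paste(missing, collapse = ", ")),
                 "cosedim_validation_error")
  }
  if (!all(t$event_type %in% c("AFE", "ALE"))) {
    stop_cosedim("`event_type` must be 'AFE' or 'ALE'.", "cosedim_validation_error")
  }
  num_ok <- with(t, all(psi >= 0 & psi <= 1 & ci_low >= 0 & ci_high <= 1 &
                          ci_low <= psi & psi <= ci_high))
  if (is.na(num_ok) || !num_ok) {
    stop_cosedim("Require 0 <= ci_low <= psi <= ci_high <= 1 for every row.",
                 "cosedim_validation_error")
  }
  sums <- t |>
    group_by(.data$event_id, .data$fraction) |>
    summarise(s = sum(.data$psi), .groups = "drop")
  off <- sums |> filter(abs(.data$s - 1) > 0.05)
  if (nrow(off)) {
    warn(sprintf("%d event-fraction combination(s) have isoform PSI sums off 1 by > 0.05.",
                 nrow(off)))
  }
  class(t) <- c("psi_table", class(tibble()))
  t
}

#' Read a PSI summary TSV
#' @param path TSV with the columns documented in [psi_table()].
#' @return A `psi_table` tibble.
#' @export
read_psi_table <- function(path) {
  psi_table(readr::read_tsv(path, comment = "#",
                            col_types = readr::cols(
                              event_id = "c", event_type = "c", isoform_id = "c",
                              fraction = "i", psi = "d", ci_low = "d", ci_high = "d"
                            ), progress = FALSE))
}

#' Keep only confidently estimated isoforms
#'
#' An isoform is retained only if its confidence-interval width
#' (`ci_high - ci_low`) is strictly below `max_ci_width` in every fraction;
#' one wide fraction disqualifies the isoform. Events left with fewer than two
#' isoforms are dropped entirely (a one-isoform event has no usage contrast).
#'
#' @param t A `psi_table` tibble.
#' @param max_ci_width Strict upper bound on CI width, default 0.2.
#' @return A filtered `psi_table`; drop counts per reason are reported.
#' @export
filter_confident <- function(t, max_ci_width = 0.2) {
  stopifnot(inherits(t, "psi_table"))
  assert_scalar_number(max_ci_width, "max_ci_width", min = 1e-12, max = 1)
  iso_ok <- t |>
    group_by(.data$event_id, .data$isoform_id) |>
    summarise(ok = all((.data$ci_high - .data$ci_low) < max_ci_width),
              .groups = "drop")
  n_iso_dropped <- sum(!iso_ok$ok)
  kept <- t |>
    semi_join(iso_ok |> filter(.data$ok), by = c("event_id", "isoform_id"))
  ev_ok <- kept |>
    group_by(.data$event_id) |>
    summarise(n_iso = dplyr::n_distinct(.data$isoform_id), .groups = "drop")
  n_ev_dropped <- sum(ev_ok$n_iso < 2L)
  kept <- kept |>
    semi_join(ev_ok |> filter(.data$n_iso >= 2L), by = "event_id")
  inform(sprintf(
    "filter_confident: dropped %d isoform(s) with CI width >= %g; dropped %d event(s) left with < 2 isoforms.",
    n_iso_dropped, max_ci_width, n_ev_dropped))
  class(kept) <- c("psi_table", class(tibble()))
  kept
}

#' Maximum PSI span per event across the gradient
#'
#' For each isoform, the span `max(psi) - min(psi)` over fractions; the
#' event's delta-PSI is the largest isoform span. For two-isoform events the
#' two isoform spans coincide (PSI values are complementary), so this equals
#' any pairwise reading of the maximal usage difference across the gradient.
#'
#' @param t A `psi_table` tibble (typically after [filter_confident()]).
#' @return Tibble `event_id`, `event_type`, `delta_psi`, `n_fractions`.
#'   Events observed in fewer than 2 fractions are an error.
#' @export
max_delta_psi <- function(t) {
  stopifnot(inherits(t, "psi_table"))
  nf <- t |>
    group_by(.data$event_id) |>
    summarise(n_fractions = dplyr::n_distinct(.data$fraction), .groups = "drop")
  single <- nf$event_id[nf$n_fractions < 2L]
  if (length(single)) {
    stop_cosedim(sprintf("Event(s) with a single fraction: %s.",
                         paste(head(single, 5), collapse = ", ")),
                 "cosedim_validation_error")
  }
  t |>
    group_by(.data$event_id, .data$event_type, .data$isoform_id) |>
    summarise(span = max(.data$psi) - min(.data$psi),
              nf = dplyr::n_distinct(.data$fraction), .groups = "drop") |>
    group_by(.data$event_id, .data$event_type) |>
    summarise(delta_psi = max(.data$span), n_fractions = max(.data$nf),
              .groups = "drop")
}

#' Classify events by delta-PSI magnitude
#'
#' Three-way classification: `strong` for `delta_psi > strong_cut`, `moderate`
#' for `moderate_cut < delta_psi <= strong_cut`, else `non_regulated`. A value
#' sitting exactly on a cut falls to the lower class (the boundary convention;
#' strict inequalities leave the cut points themselves unassigned otherwise).
#'
#' @param events Tibble with `delta_psi` (e.g. from [max_delta_psi()]).
#' @param strong_cut,moderate_cut Class boundaries, defaults 0.5 and 0.25,
#'   with `0 < moderate_cut < strong_cut < 1`.
#' @return The input with a `class` factor column
#'   (`strong`/`moderate`/`non_regulated`).
#' @export
classify_events <- function(events, strong_cut = 0.5, moderate_cut = 0.25) {
  assert_scalar_number(strong_cut, "strong_cut", min = 1e-12, max = 1 - 1e-12)
  assert_scalar_number(moderate_cut, "moderate_cut", min = 1e-12, max = 1 - 1e-12)
  if (moderate_cut >= strong_cut) {
    stop_cosedim("`moderate_cut` must be below `strong_cut`.",
                 "cosedim_validation_error")
  }
  ev <- as_tibble(events)
  stopifnot("delta_psi" %in% names(ev))
  ev |>
    mutate(class = factor(
      dplyr::case_when(
        .data$delta_psi > strong_cut ~ "strong",
        .data$delta_psi > moderate_cut ~ "moderate",
        TRUE ~ "non_regulated"
      ),
      levels = c("strong", "moderate", "non_regulated")
    ))
}

#' Conservation comparison of regulated versus non-regulated events
#'
#' Compares per-event conservation scores (e.g. PhyloP) of each regulated
#' class against the non-regulated class by rank-sum test, with BH adjustment
#' across the comparisons, and returns ECDF tables for plotting cumulative
#' distributions.
#'
#' @param events Classified events (see [classify_events()]).
#' @param scores Tibble `event_id`, `score`.
#' @param alternative `"greater"` (default; regulated events more conserved)
#'   or `"two.sided"`.
#' @return A `psi_conservation` object: list with `ecdf` (tibble `class`,
#'   `score`, `ecdf`), `tests` (tibble `comparison`, `n_regulated`,
#'   `n_reference`, `p`, `q`). Empty classes are skipped with a warning.
#' @export
conservation_group_test <- function(events, scores,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  ev <- as_tibble(events)
  stopifnot(all(c("event_id", "class") %in% names(ev)))
  sc <- as_tibble(scores)
  stopifnot(all(c("event_id", "score") %in% names(sc)))
  d <- inner_join(ev |> select("event_id", "class"), sc, by = "event_id")
  ref <- d$score[d$class == "non_regulated"]
  if (!length(ref)) {
    stop_cosedim("Non-regulated reference class is empty.", "cosedim_empty_error")
  }
  ecdf_tbl <- d |>
    group_by(.data$class) |>
    arrange(.data$score, .by_group = TRUE) |>
    mutate(ecdf = row_number() / n()) |>
    ungroup() |>
    select("class", "score", "ecdf")
  tests <- purrr::map_dfr(c("strong", "moderate"), function(cl) {
    grp <- d$score[d$class == cl]
    if (!length(grp)) {
      warn(sprintf("Class '%s' is empty; comparison skipped.", cl))
      return(tibble())
    }
    tibble(comparison = paste0(cl, "_vs_non_regulated"),
           n_regulated = length(grp), n_reference = length(ref),
           p = rank_sum_test(grp, ref, alternative = alternative)$p_value)
  })
  if (nrow(tests)) tests$q <- p.adjust(tests$p, method = "BH")
  structure(list(ecdf = ecdf_tbl, tests = tests, alternative = alternative),
            class = "psi_conservation")
}

#' @export
print.psi_conservation <- function(x, ...) {
  cat("<psi_conservation> rank-sum comparisons vs non-regulated:\n")
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}

#' Write a PSI table as TSV
#' @param t A `psi_table` tibble.
#' @param path Output path.
#' @param comment Optional header comment lines.
#' @return `path`, invisibly.
#' @export
write_psi_table <- function(t, path, comment = NULL) {
  stopifnot(inherits(t, "psi_table"))
  out <- as_tibble(t)
  for (cl in c("psi", "ci_low", "ci_high")) out[[cl]] <- format_num(out[[cl]])
  lines <- c(
    if (length(comment)) paste0("# ", comment),
    paste(names(out), collapse = "\t"),
    do.call(paste, c(unname(as.list(out)), sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}
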