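# Entity-by-fraction abundance profiles: the universal carrier.
#
# A profile table is a tibble whose first column is `entity_id` and whose
# remaining columns are named `frac<i>` for strictly increasing physical
# fraction numbers i (e.g. frac3..frac24 for an RNA gradient where the first
# two collected fractions lacked usable material). Values are nonnegative
# abundances: TPM for RNA, normalized peptide quantity for protein.

new_sed_profile <- function(tbl, entity_kind, normalized = FALSE) {
  structure(
    tbl,
    entity_kind = entity_kind,
    normalized = normalized,
    class = c("sed_profile", class(tibble()))
  )
}

#' Build a sedimentation profile table from a data frame
#'
#' Validates and standardizes an entity-by-fraction abundance table. The first
#' column is taken as the entity identifier; every other column name must
#' contain a parseable fraction number (`frac3`, `F3` and `3` all map to
#' fraction 3). Columns are reordered by increasing fraction number.
#'
#' @param df A data frame: identifier column plus one numeric column per fraction.
#' @param entity_kind One of `"rna"`, `"protein"`, `"isoform"`.
#' @return A `sed_profile` tibble with columns `entity_id`, `frac<i>`, ....
#' @details Missing cells are imputed as 0 with a warning (an absent
#'   measurement in a fraction is taken as below detection); negative values
#'   are a hard error. Duplicate entity identifiers are rejected.
#' @export
profile_tbl <- function(df, entity_kind = c("rna", "protein", "isoform")) {
  entity_kind <- match.arg(entity_kind)
  if (!is.data.frame(df) || ncol(df) < 3L) {
    stop_cosedim("A profile table needs an id column and at least 2 fraction columns.",
                 "cosedim_validation_error")
  }
  ids <- as.character(df[[1L]])
  if (anyNA(ids) || any(duplicated(ids))) {
    dup <- unique(ids[duplicated(ids)])
    stop_cosedim(
      sprintf("Entity ids must be unique and non-missing (duplicated: %s).",
              paste(head(dup, 5), collapse = ", ")),
      "cosedim_validation_error"
    )
  }
  frac_names <- names(df)[-1L]
  idx <- suppressWarnings(as.integer(stringr::str_extract(frac_names, "[0-9]+")))
  if (anyNA(idx)) {
    stop_cosedim(
      sprintf("Column names not parseable as fraction numbers: %s.",
              paste(frac_names[is.na(idx)], collapse = ", ")),
      "cosedim_parse_error"
    )
  }
  if (any(duplicated(idx)) || any(idx <= 0L)) {
    stop_cosedim("Fraction numbers must be distinct positive integers.",
                 "cosedim_validation_error")
  }
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "")
      if (length(bad)) {
        stop_cosedim(
          sprintf("Non-numeric value '%s' at row %d (entity '%s'), column '%s'.",
                  v[bad[1L]], bad[1L], ids[bad[1L]], frac_names[j]),
          "cosedim_parse_error"
        )
      }
      v <- vn
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  if (anyNA(m)) {
    warn(sprintf("%d missing cell(s) imputed as 0.", sum(is.na(m))))
    m[is.na(m)] <- 0
  }
  if (any(m < 0)) {
    stop_cosedim("Negative abundances are not allowed.", "cosedim_validation_error")
  }
  ord <- order(idx)
  m <- m[, ord, drop = FALSE]
  colnames(m) <- paste0("frac", idx[ord])
  out <- dplyr::bind_cols(tibble(entity_id = ids), as_tibble(m))
  new_sed_profile(out, entity_kind)
}

#' Read a tab-separated profile table
#'
#' @param path Path to a TSV whose first column holds entity ids and whose
#'   remaining headers carry fraction numbers (lines starting `#` are skipped).
#' @inheritParams profile_tbl
#' @return A `sed_profile` tibble; see [profile_tbl()].
#' @export
read_profile_tsv <- function(path, entity_kind = c("rna", "protein", "isoform")) {
  entity_kind <- match.arg(entity_kind)
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  profile_tbl(df, entity_kind)
}

#' Write a profile table as TSV
#'
#' Mirrors the reader dialect; an optional comment header records provenance
#' (parameters, seed) in `# key: value` lines.
#'
#' @param x A `sed_profile` tibble.
#' @param path Output path.
#' @param comment Optional character vector of header comment lines (written
#'   with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path, comment = NULL) {
  stopifnot(inherits(x, "sed_profile"))
  out <- as_tibble(x)
  for (cl in names(out)[-1L]) out[[cl]] <- format_num(out[[cl]])
  lines <- c(
    if (length(comment)) paste0("# ", comment),
    paste(names(out), collapse = "\t"),
    do.call(paste, c(unname(as.list(out)), sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Fraction numbers of a profile table
#' @param x A `sed_profile` tibble.
#' @return Integer vector of physical fraction numbers, increasing.
#' @export
fraction_indices <- function(x) {
  as.integer(sub("^frac", "", setdiff(names(x), "entity_id")))
}

#' Extract the numeric abundance matrix
#' @param x A `sed_profile` tibble.
#' @return Numeric matrix, entities in rows (rownames = entity ids), fractions
#'   in columns.
#' @export
profile_values <- function(x) {
  m <- as.matrix(as_tibble(x)[setdiff(names(x), "entity_id")])
  rownames(m) <- x$entity_id
  m
}

entity_kind <- function(x) attr(x, "entity_kind") %||% "rna"

is_normalized <- function(x) isTRUE(attr(x, "normalized"))

# Restrict a profile table to a subset of fraction numbers (used for
# cross-kind operations on the intersection of RNA and protein fractions).
restrict_fractions <- function(x, fractions) {
  keep <- paste0("frac", sort(fractions))
  missing <- setdiff(keep, names(x))
  if (length(missing)) {
    stop_cosedim(sprintf("Fractions not present: %s.",
                         paste(sub("^frac", "", missing), collapse = ", ")),
                 "cosedim_validation_error")
  }
  new_sed_profile(as_tibble(x)[c("entity_id", keep)], entity_kind(x),
                  normalized = FALSE)
}

shared_fractions <- function(a, b) {
  intersect(fraction_indices(a), fraction_indices(b))
}

#' Row-normalize profiles to relative abundance
#'
#' Divides each entity's profile by its raw row sum so profiles become
#' comparable distributions over the gradient (each row sums to 1); a
#' compartment-enriched gene then reads directly as fold deviation from the
#' uniform 1/n_fractions baseline. Rows whose raw total falls below an
#' expression floor are dropped, never zero-padded.
#'
#' @param x A `sed_profile` tibble of raw abundances.
#' @param min_total Expression floor on the raw row sum; rows below it are
#'   dropped and reported. Default 1 (summed TPM) for RNA, 0 for protein
#'   tables, which arrive already curated.
#' @param method `"sum"` (default, sum-to-one) or `"max"` (peak-scaled, each
#'   row divided by its maximum).
#' @return A `sed_profile` tibble flagged as normalized, with attribute
#'   `dropped_entities` listing excluded ids.
#' @export
normalize_profiles <- function(x, min_total = NULL,
                               method = c("sum", "max")) {
  stopifnot(inherits(x, "sed_profile"))
  method <- match.arg(method)
  if (is.null(min_total)) {
    min_total <- if (identical(entity_kind(x), "rna")) 1 else 0
  }
  assert_scalar_number(min_total, "min_total", min = 0)
  m <- profile_values(x)
  totals <- rowSums(m)
  keep <- totals >= min_total & totals > 0
  dropped <- rownames(m)[!keep]
  if (length(dropped)) {
    inform(sprintf("normalize_profiles: dropped %d of %d entities below floor %g.",
                   length(dropped), nrow(m), min_total))
  }
  if (!any(keep)) {
    stop_cosedim("All rows fell below the expression floor.", "cosedim_empty_error")
  }
  m <- m[keep, , drop = FALSE]
  denom <- if (method == "sum") rowSums(m) else apply(m, 1, max)
  m <- m / denom
  out <- dplyr::bind_cols(tibble(entity_id = rownames(m)), as_tibble(m))
  res <- new_sed_profile(out, entity_kind(x), normalized = (method == "sum"))
  attr(res, "dropped_entities") <- dropped
  res
}

#' Fraction-by-fraction correlation matrix
#'
#' Pearson correlation of expression between every pair of gradient fractions,
#' across entities. In a well-behaved gradient, fractions of similar density
#' correlate more strongly than distant ones, so correlation decays away from
#' the diagonal.
#'
#' @param x A `sed_profile` tibble with at least 3 entities.
#' @param log2_transform Correlate `log2(value + 1)` rather than raw values.
#'   Defaults to `TRUE` for raw abundance tables (which span orders of
#'   magnitude) and is forced off for normalized input.
#' @return Symmetric numeric matrix with unit diagonal; dimnames are fraction
#'   numbers.
#' @export
fraction_correlation_matrix <- function(x, log2_transform = !is_normalized(x)) {
  stopifnot(inherits(x, "sed_profile"))
  m <- profile_values(x)
  if (nrow(m) < 3L) {
    stop_cosedim("At least 3 entities are required.", "cosedim_validation_error")
  }
  if (log2_transform) m <- log2(m + 1)
  csd <- apply(m, 2, sd)
  if (any(csd == 0)) {
    stop_cosedim(sprintf("Constant fraction column(s): %s.",
                         paste(sub("^frac", "", colnames(m)[csd == 0]), collapse = ", ")),
                 "cosedim_constant_error")
  }
  cc <- cor(m)
  dimnames(cc) <- list(fraction_indices(x), fraction_indices(x))
  diag(cc) <- 1
  cc
}
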