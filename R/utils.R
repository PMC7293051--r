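# Internal validation and small statistical helpers shared across modules.

stop_cosedim <- function(msg, class) {
  abort(msg, class = c(class, "cosedim_error"))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_cosedim(
      sprintf("`%s` must be a single number in [%s, %s].", name, min, max),
      "cosedim_validation_error"
    )
  }
  invisible(x)
}

#' Pearson correlation with explicit degeneracy handling
#'
#' Product-moment correlation between two equal-length numeric vectors. Unlike
#' [stats::cor()], constant input is a hard error rather than a silent `NA`:
#' a flat sedimentation profile has no defined shape to correlate.
#'
#' @param a,b Numeric vectors of equal length (at least 3), neither constant.
#' @return A single correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_cor(c(1, 2, 3, 5), c(2, 2, 4, 6))
#' @export
pearson_cor <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b)) {
    stop_cosedim("`a` and `b` must be numeric vectors of equal length.",
                 "cosedim_validation_error")
  }
  if (length(a) < 3L) {
    stop_cosedim("Correlation requires at least 3 paired observations.",
                 "cosedim_validation_error")
  }
  if (anyNA(a) || anyNA(b)) {
    stop_cosedim("Missing values are not allowed in correlation input.",
                 "cosedim_validation_error")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop_cosedim("Correlation is undefined for a constant vector.",
                 "cosedim_constant_error")
  }
  cor(a, b)
}

#' Wilcoxon rank-sum test wrapper
#'
#' Thin wrapper around [stats::wilcox.test()] used by all group comparisons in
#' the package. Exact p-values are used whenever the sample permits (no ties,
#' both groups < 50); ties fall back to the mid-rank normal approximation. The
#' fully degenerate case in which every value in both groups is identical has
#' no rank information at all and returns p = 1 by convention.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param alternative One of "two.sided", "greater", "less" (`x` relative to `y`).
#' @return A list with elements `statistic` (rank-sum W) and `p_value`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L) {
    stop_cosedim("Both groups must be non-empty.", "cosedim_validation_error")
  }
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  res <- suppressWarnings(wilcox.test(x, y, alternative = alternative))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

# Derive an independent sub-seed per purpose so adding one simulated output
# never perturbs the RNG stream of another. Kept below 2^31 - 1.
derive_seed <- function(seed, purpose) {
  stopifnot(is.character(purpose), length(purpose) == 1L)
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Format a numeric matrix/tibble cell for TSV output; 17 significant digits
# round-trip any double bit-exactly through the readers.
format_num <- function(x) {
  sprintf("%.17g", x)
}
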