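# Independent brute-force oracles. These re-derive expected values from first
# principles (explicit enumeration, closed forms) and deliberately share no
# code with the implementation paths they check.

# Hypergeometric upper tail P(X >= k) by explicit summation of 2x2 table
# probabilities C(K, x) C(N-K, n-x) / C(N, n).
oracle_hyper_tail <- function(k, n, K, N) {
  xs <- seq.int(max(k, max(0, n - (N - K))), min(n, K))
  if (!length(xs) || k > min(n, K)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# Exact Wilcoxon rank-sum p by full enumeration of all C(n1+n2, n1) group
# assignments (tie-free data only).
oracle_rank_sum_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U for x
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  total <- ncol(combos)
  switch(alternative,
    greater = sum(us >= obs) / total,
    less = sum(us <= obs) / total,
    two.sided = min(1, 2 * min(sum(us >= obs), sum(us <= obs)) / total)
  )
}

# Exhaustive min-HG prefix scan: for every prefix length b of the ranked
# membership indicator, the enumerated hypergeometric tail; returns the
# minimum and its optimizing prefix.
oracle_min_hg <- function(is_member) {
  N <- length(is_member)
  K <- sum(is_member)
  hits <- cumsum(is_member)
  ps <- vapply(seq_len(N), function(b) oracle_hyper_tail(hits[b], b, K, N), 0)
  list(p = min(ps), prefix = which.min(ps), k = hits[which.min(ps)])
}

# Position-by-position overlapping hexamer count of one motif in one sequence.
oracle_count_motif <- function(seq, motif) {
  L <- nchar(seq)
  w <- nchar(motif)
  if (L < w) return(0L)
  sum(vapply(seq_len(L - w + 1L),
             function(i) substring(seq, i, i + w - 1L) == motif, TRUE))
}

# Pearson correlation from the raw covariance / sigma sums, written out.
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# Small deterministic profile fixture: `n` entities over the given fractions.
make_profile <- function(values, fractions, ids = NULL,
                         kind = "rna", normalized = FALSE) {
  m <- matrix(values, ncol = length(fractions), byrow = TRUE)
  df <- data.frame(entity_id = ids %||% sprintf("g%02d", seq_len(nrow(m))), m)
  names(df)[-1] <- paste0("frac", fractions)
  p <- profile_tbl(df, kind)
  attr(p, "normalized") <- normalized
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared simulation fixtures, built once per test run.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_gradient(simulation_config(seed = 1))
    cache
  }
})

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_gradient(simulation_config(
        n_compartments = 4, genes_per_compartment = 40, n_background = 10,
        n_proteins = 100, n_rbps = 3, seed = 7
      ))
    }
    cache
  }
})
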