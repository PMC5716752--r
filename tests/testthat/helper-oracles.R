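# Independent oracles. These deliberately avoid the package's code paths:
# brute-force enumeration and textbook closed forms only.

# Pearson r by the direct covariance formula.
oracle_pearson_r <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Exact two-sided permutation p for Pearson r at small n: fraction of all
# n! permutations of y whose |r| >= |r_observed| (observed included).
oracle_permutation_p <- function(x, y) {
  n <- length(y)
  stopifnot(n <= 7)  # n! enumeration
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  r_obs <- abs(oracle_pearson_r(x, y))
  rs <- vapply(perms(y), function(p) abs(oracle_pearson_r(x, p)), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# Per-gene signature enumeration for Venn regions: for every gene in the
# union, record exactly which sets contain it; count genes per signature.
oracle_venn <- function(sets) {
  labels <- names(sets)
  universe <- unique(unlist(sets))
  combos <- list()
  for (size in seq_along(labels))
    combos <- c(combos, utils::combn(labels, size, simplify = FALSE))
  counts <- stats::setNames(integer(length(combos)),
                            vapply(combos, paste, "", collapse = "&"))
  for (g in universe) {
    sig <- labels[vapply(labels, function(l) g %in% sets[[l]], logical(1))]
    counts[[paste(sig, collapse = "&")]] <-
      counts[[paste(sig, collapse = "&")]] + 1L
  }
  counts
}

# Brute-force recurrence: per gene, count member cohorts listing it.
oracle_recurrent <- function(gene_lists, cutoff) {
  universe <- unique(unlist(gene_lists))
  keep <- vapply(universe, function(g)
    sum(vapply(gene_lists, function(l) g %in% l, logical(1))) >= cutoff,
    logical(1))
  sort(universe[keep])
}

# Textbook pooled two-sample t (x vs y), returning c(t, p).
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# BH step-up by its definition: q_(i) = min_{j >= i} ( m * p_(j) / j ).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
# of the query from the background (N <= 12).
oracle_hyper_p <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  term <- seq_len(K)  # wlog the first K background genes form the term
  hits <- apply(draws, 2, function(d) sum(d %in% term))
  mean(hits >= k)
}
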