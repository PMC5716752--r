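#' Fold enrichment of a gene list against a gene-set collection
#'
#' For each term, counts the overlap of the query list with the term inside
#' a background universe and reports the fold enrichment
#' `FE = (k/n) / (K/N)` — the query hit proportion over the background
#' proportion — together with the one-sided (over-representation)
#' hypergeometric tail p-value
#' `p = sum_{i = k}^{min(n, K)} P(X = i; N, K, n)`, i.e. Fisher's exact
#' test, alternative "greater". Here `N` is the background size, `K` the
#' term's genes within the background, `n` the query genes within the
#' background and `k` the query genes in the term. `k = 0` yields
#' `FE = 0`, `p = 1`.
#'
#' The background should be the universe actually screened (e.g. all genes
#' tested in the correlation screen), not the whole genome. Query genes
#' outside the background are dropped with a message; terms with no gene in
#' the background are skipped.
#'
#' @param query Character vector of query genes (e.g. a consensus list).
#' @param collection A `gene_set_collection` from [read_gmt()], or a named
#'   list of character vectors.
#' @param background Character vector: the gene universe (size >= 2).
#' @param adjust If `TRUE` (default), add a BH-adjusted `q` column across
#'   the reported terms.
#' @return A data frame with one row per term: `term_id`, `description`,
#'   `k`, `n`, `K`, `N`, `fold_enrichment`, `p`, `q`, sorted by `p`.
#' @export
fold_enrichment <- function(query, collection, background, adjust = TRUE) {
  background <- unique(as.character(background))
  if (length(background) < 2L) stop("background must contain >= 2 genes")
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside))
    message("fold_enrichment: dropping ", length(outside),
            " query gene(s) outside the background")
  query <- intersect(query, background)
  if (!length(query)) stop("empty query after restriction to background")
  if (!inherits(collection, "gene_set_collection")) {
    if (is.null(names(collection))) stop("`collection` must be named")
    collection <- lapply(collection, function(g)
      list(description = "", genes = unique(as.character(g))))
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(collection[[id]]$genes, background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    fe <- (k / n) / (K / N)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, description = collection[[id]]$description,
               k = k, n = n, K = K, N = N, fold_enrichment = fe, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term overlaps the background")
  out$q <- if (adjust) bh_adjust(out$p) else NA_real_
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
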