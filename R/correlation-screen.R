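#' Correlate every gene with a seed gene within one cohort
#'
#' Computes, for every gene other than the seed, the correlation of its
#' expression with the seed gene's expression across the cohort's samples.
#' Missing values are handled pairwise-complete, and the number of samples
#' actually used per gene is recorded. The two-sided p-value is obtained
#' from the t transform `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t
#' distribution with `n - 2` degrees of freedom (for Spearman this is the
#' usual large-sample approximation on the rank correlation).
#'
#' Genes with zero variance on the pairwise-complete samples are reported
#' with status `excluded_constant`; genes with fewer than 5 usable sample
#' pairs with status `excluded_low_n`. Neither gets an r or p.
#'
#' @param cohort An [expression_cohort()] (gene-level).
#' @param seed_gene Gene symbol of the seed; must be present and
#'   non-constant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_n Minimum pairwise-complete sample count to report a
#'   correlation (default 5).
#' @return A data frame of class `correlation_table` with columns `gene`,
#'   `r`, `p`, `n_used`, `status` and attributes `cohort_id`, `seed_gene`,
#'   `method`.
#' @export
correlate_with_seed <- function(cohort, seed_gene,
                                method = c("pearson", "spearman"),
                                min_n = 5L) {
  method <- match.arg(method)
  vals <- cohort$values
  if (!seed_gene %in% rownames(vals))
    stop("seed gene '", seed_gene, "' absent from cohort ", cohort$cohort_id)
  if (ncol(vals) < 5L)
    stop("cohort ", cohort$cohort_id, " has fewer than 5 samples")
  seed <- vals[seed_gene, ]
  if (sum(!is.na(seed)) < 2L || stats::sd(seed, na.rm = TRUE) == 0)
    stop("seed gene '", seed_gene, "' is constant in cohort ",
         cohort$cohort_id, "; screen undefined")
  genes <- setdiff(rownames(vals), seed_gene)
  M <- vals[genes, , drop = FALSE]

  seed_ok <- !is.na(seed)
  n_used <- as.integer((!is.na(M)) %*% seed_ok)

  # pairwise variance of each gene restricted to samples where the seed is
  # present (and the gene itself): zero-variance genes are excluded
  pair_sd <- vapply(seq_len(nrow(M)), function(i) {
    x <- M[i, seed_ok]
    x <- x[!is.na(x)]
    if (length(x) < 2L) 0 else stats::sd(x)
  }, numeric(1L))

  r <- suppressWarnings(
    as.vector(stats::cor(t(M), seed, use = "pairwise.complete.obs",
                         method = method))
  )
  r <- pmin(1, pmax(-1, r))

  status <- rep("ok", length(genes))
  status[n_used < min_n] <- "excluded_low_n"
  status[n_used >= min_n & (is.na(r) | pair_sd == 0)] <- "excluded_constant"
  r[status != "ok"] <- NA_real_

  p <- rep(NA_real_, length(genes))
  ok <- status == "ok"
  if (any(ok)) {
    df <- n_used[ok] - 2L
    tt <- r[ok] * sqrt(df / pmax(1 - r[ok]^2, 0))
    tt[abs(r[ok]) == 1] <- Inf * sign(r[ok][abs(r[ok]) == 1])
    p[ok] <- 2 * stats::pt(-abs(tt), df)
  }

  out <- data.frame(gene = genes, r = r, p = p, n_used = n_used,
                    status = status, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out,
            class = c("correlation_table", "data.frame"),
            cohort_id = cohort$cohort_id,
            group_id = cohort$group_id,
            seed_gene = seed_gene,
            method = method)
}

#' Split a correlation table into positive and negative significant lists
#'
#' Produces the cohort's two signed gene lists: genes significantly
#' positively correlated with the seed and genes significantly negatively
#' correlated. A gene is listed iff its status is `ok`, its (optionally
#' BH-adjusted) p-value is below `alpha`, its correlation has the matching
#' sign and `|r| >= min_abs_r`. Excluded genes are never listed.
#'
#' @param table A `correlation_table` from [correlate_with_seed()].
#' @param alpha Significance threshold on the p-value, in (0, 1);
#'   default 0.05.
#' @param min_abs_r Optional floor on `|r|` (default 0); lets users emulate
#'   a threshold on the correlation magnitude instead of the p-value.
#' @param adjust `"none"` (default, raw p as in single-cohort screens) or
#'   `"BH"` to apply Benjamini-Hochberg across the cohort's ok genes before
#'   thresholding.
#' @return A `signed_gene_lists` object: list with `cohort_id`, `group_id`,
#'   `positive`, `negative` (character vectors), `alpha`, `min_abs_r`.
#' @export
split_by_sign <- function(table, alpha = 0.05, min_abs_r = 0,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single number in (0, 1)")
  ok <- table$status == "ok"
  p <- table$p
  if (adjust == "BH") p[ok] <- bh_adjust(p[ok])
  hit <- ok & !is.na(p) & p < alpha & abs(table$r) >= min_abs_r
  structure(
    list(cohort_id = attr(table, "cohort_id"),
         group_id = attr(table, "group_id"),
         positive = table$gene[hit & table$r > 0],
         negative = table$gene[hit & table$r < 0],
         alpha = alpha, min_abs_r = min_abs_r),
    class = "signed_gene_lists"
  )
}

#' @export
print.signed_gene_lists <- function(x, ...) {
  cat(sprintf("<signed_gene_lists> %s: %d positive, %d negative (alpha %g)\n",
              x$cohort_id, length(x$positive), length(x$negative), x$alpha))
  invisible(x)
}

#' Write a correlation table to TSV
#'
#' Columns `gene`, `r`, `p`, `n_used`, `status`.
#'
#' @param table A `correlation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
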