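# Two-sample t statistic, pooled ("student") or unpooled ("welch").
# Returns c(t, df, p); degenerate zero-variance, zero-difference input
# yields t = 0, p = 1.
.two_sample_t <- function(x, y, variant = "student") {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- if (n1 > 1L) stats::var(x) else NA_real_
  v2 <- if (n2 > 1L) stats::var(y) else NA_real_
  if (variant == "student") {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2L
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  d <- m1 - m2
  if (se == 0) {
    tt <- if (d == 0) 0 else Inf * sign(d)
    if (d == 0) df <- n1 + n2 - 2L
  } else {
    tt <- d / se
  }
  p <- if (is.finite(tt)) 2 * stats::pt(-abs(tt), df) else 0
  if (tt == 0) p <- 1
  c(t = tt, df = df, p = p)
}

#' Dichotomize a cohort's samples by seed-gene expression
#'
#' Splits samples into a seed-low and a seed-high stratum: a sample is
#' `high` iff its seed expression is strictly greater than the cohort median
#' of seed expression, `low` otherwise. The strictly-greater-than-median
#' rule is the least-parameterized convention; with an odd sample count the
#' median sample lands in `low`.
#'
#' @param cohort An [expression_cohort()].
#' @param seed_gene Seed gene symbol; must be present, non-constant, with
#'   at least 4 non-missing samples.
#' @param rule Splitting rule; only `"median"` is implemented.
#' @return Named character vector `sample_id -> "low"/"high"` over samples
#'   with non-missing seed expression.
#' @export
dichotomize_by_seed <- function(cohort, seed_gene, rule = "median") {
  rule <- match.arg(rule, "median")
  if (!seed_gene %in% rownames(cohort$values))
    stop("seed gene '", seed_gene, "' absent from cohort ", cohort$cohort_id)
  seed <- cohort$values[seed_gene, ]
  seed <- seed[!is.na(seed)]
  if (length(seed) < 4L) stop("need >= 4 samples with seed expression")
  if (stats::sd(seed) == 0)
    stop("seed gene '", seed_gene, "' is constant; cannot dichotomize")
  med <- stats::median(seed)
  labels <- ifelse(seed > med, "high", "low")
  if (!all(c("low", "high") %in% labels))
    stop("median split left a stratum empty")
  labels
}

#' Test genes between seed-low and seed-high strata
#'
#' Per-gene two-sample t-test of expression between the two strata, the
#' standard follow-up after [dichotomize_by_seed()]: which markers differ
#' between seed-high and seed-low samples? `"student"` uses the pooled
#' variance (the classical Student t-test); `"welch"` the unpooled variant,
#' preferable under unequal stratum variances. A gene with fewer than 2
#' usable values in either stratum is reported with status `not_testable`
#' rather than raising an error.
#'
#' @param cohort An [expression_cohort()].
#' @param labels Named `"low"/"high"` vector as from [dichotomize_by_seed()].
#' @param genes Genes to test (default: all genes in the cohort).
#' @param variant `"student"` (default) or `"welch"`.
#' @param adjust If `TRUE`, add a BH-adjusted `q` column across testable
#'   genes.
#' @return A `stratified_result` data frame: `gene`, `mean_low`,
#'   `mean_high`, `t`, `p`, `q` (NA unless `adjust`), `direction`
#'   (`up_in_high` / `down_in_high` / `flat`), `status`.
#' @export
two_group_test <- function(cohort, labels, genes = rownames(cohort$values),
                           variant = c("student", "welch"), adjust = FALSE) {
  variant <- match.arg(variant)
  if (is.null(names(labels)) || !all(labels %in% c("low", "high")))
    stop("`labels` must be a named vector of 'low'/'high'")
  unknown <- setdiff(names(labels), colnames(cohort$values))
  if (length(unknown))
    stop("label(s) for unknown sample(s): ", paste(unknown, collapse = ", "))
  missing_genes <- setdiff(genes, rownames(cohort$values))
  if (length(missing_genes))
    stop("gene(s) absent from cohort: ", paste(missing_genes, collapse = ", "))
  lo_ids <- names(labels)[labels == "low"]
  hi_ids <- names(labels)[labels == "high"]
  rows <- lapply(genes, function(g) {
    lo <- cohort$values[g, lo_ids]; lo <- lo[!is.na(lo)]
    hi <- cohort$values[g, hi_ids]; hi <- hi[!is.na(hi)]
    if (length(lo) < 2L || length(hi) < 2L) {
      return(data.frame(gene = g, mean_low = NA_real_, mean_high = NA_real_,
                        t = NA_real_, p = NA_real_,
                        direction = NA_character_, status = "not_testable",
                        stringsAsFactors = FALSE))
    }
    tv <- .two_sample_t(hi, lo, variant)
    diff <- mean(hi) - mean(lo)
    data.frame(gene = g, mean_low = mean(lo), mean_high = mean(hi),
               t = unname(tv["t"]), p = unname(tv["p"]),
               direction = if (diff > 0) "up_in_high"
                           else if (diff < 0) "down_in_high" else "flat",
               status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  if (adjust) {
    ok <- out$status == "ok"
    out$q[ok] <- bh_adjust(out$p[ok])
  }
  out <- out[, c("gene", "mean_low", "mean_high", "t", "p", "q",
                 "direction", "status")]
  structure(out, class = c("stratified_result", "data.frame"),
            variant = variant)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (q-values), order-preserving with the
#' input: sort p ascending, multiply `p_(i)` by `m/i`, enforce monotonicity
#' from the largest down, cap at 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must be in [0, 1] and non-missing")
  m <- length(pvals)
  o <- order(pvals)
  scaled <- pvals[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Association of an ordinal marker score with infiltration status
#'
#' Tests whether an ordinal expression score (0 = no expression, 1-3 =
#' increasing expression, as scored on immunohistochemistry) differs
#' between samples with and without immune infiltration. The ordinal score
#' is treated as interval and compared with a two-sample Student t-test.
#'
#' @param scores Integer scores in `{0, 1, 2, 3}`, one per sample.
#' @param infiltrated Logical, one per sample; `TRUE` = infiltration
#'   positive. Both classes need at least 2 samples.
#' @return A `marker_association` list: `mean_pos`, `mean_neg`, `t`, `p`,
#'   `n_pos`, `n_neg`.
#' @export
score_infiltration_association <- function(scores, infiltrated) {
  if (length(scores) != length(infiltrated))
    stop("`scores` and `infiltrated` lengths differ")
  if (any(is.na(scores)) || !all(scores %in% 0:3))
    stop("scores must be integers in {0, 1, 2, 3}")
  if (any(is.na(infiltrated)) || !is.logical(infiltrated))
    stop("`infiltrated` must be logical without NA")
  n_pos <- sum(infiltrated); n_neg <- sum(!infiltrated)
  if (n_pos < 2L || n_neg < 2L)
    stop("need >= 2 samples in each infiltration class (have ",
         n_pos, " positive, ", n_neg, " negative)")
  tv <- .two_sample_t(scores[infiltrated], scores[!infiltrated], "student")
  structure(list(mean_pos = mean(scores[infiltrated]),
                 mean_neg = mean(scores[!infiltrated]),
                 t = unname(tv["t"]), p = unname(tv["p"]),
                 n_pos = n_pos, n_neg = n_neg),
            class = "marker_association")
}

#' @export
print.marker_association <- function(x, ...) {
  cat(sprintf(
    "<marker_association> mean score %0.2f (n=%d infiltrated) vs %0.2f (n=%d), t = %0.3f, p = %0.4g\n",
    x$mean_pos, x$n_pos, x$mean_neg, x$n_neg, x$t, x$p))
  invisible(x)
}

#' Order samples by seed expression for heatmap export
#'
#' Classifier-style heatmaps of a small marker panel are drawn with samples
#' sorted by the seed gene's expression. This returns that ordering
#' (ascending seed expression, ties broken lexicographically by sample id)
#' and the gene-ordered sub-matrix, optionally written as TSV for external
#' plotting.
#'
#' @param cohort An [expression_cohort()].
#' @param genes Ordered marker genes for the rows; all must be present.
#' @param seed_gene Seed gene driving the sample order; must be present.
#' @param path Optional output TSV path for the sub-matrix.
#' @return List with `sample_order` (character) and `matrix`
#'   (genes x ordered samples).
#' @export
order_for_heatmap <- function(cohort, genes, seed_gene, path = NULL) {
  missing_genes <- setdiff(c(seed_gene, genes), rownames(cohort$values))
  if (length(missing_genes))
    stop("gene(s) absent from cohort: ", paste(missing_genes, collapse = ", "))
  seed <- cohort$values[seed_gene, ]
  ord <- order(seed, colnames(cohort$values))
  sub <- cohort$values[genes, ord, drop = FALSE]
  if (!is.null(path)) {
    df <- data.frame(gene = rownames(sub), sub, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(sample_order = colnames(cohort$values)[ord], matrix = sub)
}
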