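# Shared fixture builders. Everything is generated in code at test time.

make_cohort <- function(values, cohort_id = "c1", group_id = "g1") {
  expression_cohort(values, cohort_id = cohort_id, group_id = group_id)
}

# Small cohort with named genes; rows given as a named list of numeric
# vectors, all the same length.
cohort_from_rows <- function(rows, cohort_id = "c1", group_id = "g1",
                             sample_ids = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- sample_ids %||% paste0("s", seq_len(ncol(m)))
  make_cohort(m, cohort_id, group_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A signed_gene_lists object built directly (bypassing the correlation
# stage) for consensus-layer tests.
make_sign_lists <- function(cohort_id, positive, negative,
                            group_id = "g1", alpha = 0.05) {
  structure(list(cohort_id = cohort_id, group_id = group_id,
                 positive = positive, negative = negative,
                 alpha = alpha, min_abs_r = 0),
            class = "signed_gene_lists")
}

# Synthetic stand-in for the published supplementary per-tumor recurrent
# lists (which are not redistributable here): four labeled gene sets per
# sign constructed region by region so that the planted Venn decomposition
# is exact by construction. Defaults reproduce the published screen's
# headline geometry: per-tumor list sizes 1473/1292/1653/1246 (+) and
# 845/1209/1704/1084 (-) for lung/breast/colon/cervix, 105 (+) / 17 (-)
# genes in all four lists, and 449 (+) / 168 (-) in at least three.
synthetic_sd1_standin <- function() {
  build_sign <- function(prefix, all4, triples, totals) {
    groups <- names(totals)
    counter <- 0L
    gene_block <- function(n) {
      ids <- sprintf("%s%05d", prefix, counter + seq_len(n))
      counter <<- counter + n
      ids
    }
    sets <- stats::setNames(vector("list", length(groups)), groups)
    core <- gene_block(all4)
    for (g in groups) sets[[g]] <- core
    # one exactly-3 region per excluded group
    for (i in seq_along(groups)) {
      block <- gene_block(triples[[i]])
      for (g in groups[-i]) sets[[g]] <- c(sets[[g]], block)
    }
    # pad each set with exclusive genes up to its published size
    for (g in groups) {
      pad <- totals[[g]] - length(sets[[g]])
      stopifnot(pad >= 0)
      sets[[g]] <- c(sets[[g]], gene_block(pad))
    }
    sets
  }
  list(
    positive = build_sign(
      "P", all4 = 105L, triples = c(86L, 86L, 86L, 86L),
      totals = c(lung = 1473L, breast = 1292L, colon = 1653L,
                 cervix = 1246L)),
    negative = build_sign(
      "N", all4 = 17L, triples = c(38L, 38L, 38L, 37L),
      totals = c(lung = 845L, breast = 1209L, colon = 1704L,
                 cervix = 1084L))
  )
}
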