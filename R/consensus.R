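#' Specify a recurrence cutoff for one condition group
#'
#' A condition group (e.g. one tumor type) contains `m_g` cohorts; a gene is
#' called recurrent for the group, within one correlation sign, when it is
#' significant with that sign in at least `cutoff` of the member cohorts.
#' Typical screens use cutoffs well below `m_g` (e.g. 2 of 5 cervical, 3 of
#' 6 lung, 5 of 19 breast, 5 of 10 colon cohorts) because platform and
#' cohort heterogeneity prevents any gene from replicating everywhere.
#'
#' @param group_id Group label.
#' @param cohort_ids Character vector of member cohort ids.
#' @param cutoff Integer in `[1, length(cohort_ids)]`.
#' @return A `group_recurrence_spec`.
#' @export
group_recurrence_spec <- function(group_id, cohort_ids, cutoff) {
  cohort_ids <- as.character(cohort_ids)
  .check_unique(cohort_ids, "cohort")
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 1L || cutoff > length(cohort_ids))
    stop("cutoff must be in [1, ", length(cohort_ids), "] for group ",
         group_id)
  structure(list(group_id = group_id, cohort_ids = cohort_ids,
                 cutoff = cutoff),
            class = "group_recurrence_spec")
}

#' @rdname group_recurrence_spec
#' @param fraction Fraction of member cohorts; the cutoff is
#'   `ceiling(fraction * m_g)`, handy for scaled-down designs.
#' @export
fraction_cutoff <- function(fraction, cohort_ids) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  max(1L, as.integer(ceiling(fraction * length(cohort_ids))))
}

#' Filter per-cohort sign lists down to a group's recurrent genes
#'
#' Counts, per sign independently, in how many of the group's cohorts each
#' gene appears, and keeps genes meeting the group's cutoff.
#'
#' @param lists List of `signed_gene_lists` (one per cohort, from
#'   [split_by_sign()]); matched to the spec by their `cohort_id`.
#' @param spec A [group_recurrence_spec()]. Every `cohort_id` in the spec
#'   must have a supplied list.
#' @return A `recurrence_result`: list with `group_id`, `cutoff`, `m`, and
#'   per sign (`positive`, `negative`) a data frame `gene`, `n_cohorts`
#'   (only genes meeting the cutoff, sorted by gene).
#' @export
recurrence_filter <- function(lists, spec) {
  ids <- vapply(lists, function(l) l$cohort_id, character(1L))
  missing <- setdiff(spec$cohort_ids, ids)
  if (length(missing))
    stop("no sign list supplied for cohort(s): ",
         paste(missing, collapse = ", "))
  members <- lists[match(spec$cohort_ids, ids)]
  one_sign <- function(sign) {
    tab <- table(unlist(lapply(members, `[[`, sign), use.names = FALSE))
    keep <- tab[tab >= spec$cutoff]
    df <- data.frame(gene = as.character(names(keep) %||% character(0)),
                     n_cohorts = as.integer(keep),
                     stringsAsFactors = FALSE)
    df[order(df$gene), , drop = FALSE]
  }
  structure(list(group_id = spec$group_id, cutoff = spec$cutoff,
                 m = length(spec$cohort_ids),
                 positive = one_sign("positive"),
                 negative = one_sign("negative")),
            class = "recurrence_result")
}

#' @export
print.recurrence_result <- function(x, ...) {
  cat(sprintf("<recurrence_result> %s (cutoff %d of %d): %d positive, %d negative\n",
              x$group_id, x$cutoff, x$m,
              nrow(x$positive), nrow(x$negative)))
  invisible(x)
}

.recurrent_genes <- function(x, sign) {
  # accept a recurrence_result, a data.frame with a gene column, or a
  # plain character vector
  el <- if (inherits(x, "recurrence_result") || is.list(x) && !is.null(x[[sign]]))
    x[[sign]] else x
  if (is.data.frame(el)) as.character(el$gene) else as.character(el)
}

#' Venn region counts for 2-4 labeled gene sets
#'
#' Decomposes the union of the sets into its exclusive regions: each gene is
#' assigned to the unique combination of sets containing it, and genes per
#' combination are counted. Region names join the member labels with `&`.
#'
#' @param sets Named list of 2-4 character vectors.
#' @return Named integer vector over all `2^k - 1` nonempty combinations
#'   (zero counts included).
#' @export
venn_counts <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("`sets` must be a named list")
  k <- length(sets)
  if (k < 2L || k > 4L)
    stop("Venn region decomposition supports 2-4 sets, got ", k)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  combos <- .venn_combos(names(sets))
  counts <- vapply(combos, function(cmb) {
    inside <- names(sets) %in% cmb
    sum(apply(member, 1L, function(row) all(row == inside)))
  }, integer(1L))
  names(counts) <- vapply(combos, paste, character(1L), collapse = "&")
  counts
}

.venn_combos <- function(labels) {
  k <- length(labels)
  out <- list()
  for (size in seq_len(k))
    out <- c(out, utils::combn(labels, size, simplify = FALSE))
  out
}

#' Intersect per-group recurrent lists across condition groups
#'
#' Builds the cross-group consensus per sign: counts in how many groups each
#' gene is recurrent, extracts the genes recurrent in at least `min_groups`
#' groups, and (for up to 4 groups) decomposes the union into Venn regions.
#' Genes recurrent positively in one group and negatively in another are
#' kept in both sign outputs and flagged in `conflict_genes`.
#'
#' @param recurrent Named list `group_id -> recurrence_result` (or
#'   `group_id -> list(positive =, negative =)` with character vectors or
#'   `gene`-column data frames).
#' @param min_groups Consensus level G: minimum number of groups (default:
#'   all groups supplied).
#' @return A `consensus_result`: per sign a list with `recurrent_by_group`,
#'   `group_count` (named integer), `consensus` (genes with
#'   `group_count >= min_groups`, sorted), `venn_regions` (NULL above 4
#'   groups); plus `conflict_genes`, `min_groups`, `groups`.
#' @export
consensus_intersect <- function(recurrent, min_groups = length(recurrent)) {
  if (is.null(names(recurrent)) || any(!nzchar(names(recurrent))))
    stop("`recurrent` must be a named list keyed by group_id")
  if (length(recurrent) < 2L) stop("need at least 2 groups")
  if (min_groups < 1L || min_groups > length(recurrent))
    stop("min_groups must be in [1, ", length(recurrent), "]")
  one_sign <- function(sign) {
    by_group <- lapply(recurrent, .recurrent_genes, sign = sign)
    tab <- table(unlist(by_group, use.names = FALSE))
    group_count <- stats::setNames(as.integer(tab), names(tab))
    consensus <- sort(names(group_count)[group_count >= min_groups])
    venn <- if (length(by_group) <= 4L) venn_counts(by_group) else NULL
    list(recurrent_by_group = by_group, group_count = group_count,
         consensus = consensus, venn_regions = venn)
  }
  pos <- one_sign("positive")
  neg <- one_sign("negative")
  conflicts <- sort(intersect(
    unlist(pos$recurrent_by_group, use.names = FALSE),
    unlist(neg$recurrent_by_group, use.names = FALSE)))
  structure(list(positive = pos, negative = neg,
                 conflict_genes = conflicts,
                 min_groups = min_groups, groups = names(recurrent)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result> %d groups, G = %d: %d positive, %d negative consensus gene(s), %d conflict(s)\n",
    length(x$groups), x$min_groups,
    length(x$positive$consensus), length(x$negative$consensus),
    length(x$conflict_genes)))
  invisible(x)
}

#' Extract the consensus gene set at a given level
#'
#' @param result A `consensus_result`.
#' @param G Minimum number of groups.
#' @param sign `"positive"` or `"negative"`.
#' @return Sorted character vector of genes recurrent in at least `G`
#'   groups with the given sign.
#' @export
consensus_at <- function(result, G, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  gc <- result[[sign]]$group_count
  if (G < 1L || G > length(result$groups))
    stop("G must be in [1, ", length(result$groups), "]")
  sort(names(gc)[gc >= G])
}
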