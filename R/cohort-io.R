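#' Construct an expression cohort
#'
#' An expression cohort bundles one dataset's log2-scale expression matrix
#' (features in rows, samples in columns) with its cohort identity and the
#' condition group (e.g. tumor type) it belongs to. All downstream screening
#' operations consume this container.
#'
#' @param values Numeric matrix, features x samples, log2 scale. Row and
#'   column names are required and must be unique; `NA` marks missing values.
#' @param cohort_id Single string identifying the dataset.
#' @param group_id Single string identifying the condition group the cohort
#'   belongs to (recurrence is counted within groups).
#' @return An object of class `expression_cohort`.
#' @export
expression_cohort <- function(values, cohort_id, group_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty expression matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row (feature) and column (sample) names")
  .check_unique(rownames(values), "feature")
  .check_unique(colnames(values), "sample")
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad))
    stop("non-finite expression values at ", sum(bad), " cell(s)")
  if (!is.character(cohort_id) || length(cohort_id) != 1L || is.na(cohort_id))
    stop("`cohort_id` must be a single string")
  if (!is.character(group_id) || length(group_id) != 1L || is.na(group_id))
    stop("`group_id` must be a single string")
  structure(
    list(cohort_id = cohort_id, group_id = group_id, values = values),
    class = "expression_cohort"
  )
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " identifier(s): ",
         paste(utils::head(dup, 5L), collapse = ", "))
  invisible(ids)
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("<expression_cohort> %s (group %s): %d features x %d samples\n",
              x$cohort_id, x$group_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname expression_cohort
#' @param x An `expression_cohort`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expression_cohort
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a header line and an identifier in the first column. With
#' `orientation = "features_in_rows"` (the default, matching common
#' microarray exports) the header holds sample ids and the first column
#' feature ids; `"samples_in_rows"` reads the transpose. The literal token
#' `NA` (or an empty cell) is treated as missing. Values are assumed to be
#' on the log2 scale; a matrix maximum above 30 triggers a warning because
#' log2 microarray intensities rarely exceed ~16.
#'
#' @param path Path to a tab-separated file.
#' @param cohort_id,group_id Identity of the cohort (default: file basename
#'   and `"unknown"`).
#' @param orientation `"features_in_rows"` or `"samples_in_rows"`.
#' @return An [expression_cohort()].
#' @export
read_expression_tsv <- function(path,
                                cohort_id = sub("\\.[^.]*$", "", basename(path)),
                                group_id = "unknown",
                                orientation = c("features_in_rows",
                                                "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty expression matrix in ", path)
  ids <- raw[[1L]]
  .check_unique(ids, if (orientation == "features_in_rows") "feature" else "sample")
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at row %d (id '%s'), column '%s'",
                 cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], ids[bad[1L, 1L]],
                 colnames(cells)[bad[1L, 2L]]))
  }
  dimnames(num) <- list(ids, colnames(cells))
  if (orientation == "samples_in_rows") num <- t(num)
  if (any(!is.na(num)) && max(num, na.rm = TRUE) > 30)
    warning("matrix maximum ", format(max(num, na.rm = TRUE)),
            " exceeds 30: input may not be log2-transformed")
  expression_cohort(num, cohort_id = cohort_id, group_id = group_id)
}

#' Write an expression cohort to TSV
#'
#' Features in rows, header row of sample ids, first column `feature` —
#' the same dialect [read_expression_tsv()] reads, so write/read round-trips.
#'
#' @param cohort An [expression_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(cohort, path) {
  df <- data.frame(feature = rownames(cohort$values),
                   cohort$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two tab-separated columns (with header): `probe_id`, `gene_symbol`.
#' Probe ids must be unique and gene symbols nonempty.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `probe_id` and `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("probe map needs two columns: probe_id, gene_symbol")
  names(df)[1:2] <- c("probe_id", "gene_symbol")
  probe_map(df$probe_id, df$gene_symbol)
}

#' @rdname read_probe_map
#' @param probe_id,gene_symbol Character vectors of equal length.
#' @export
probe_map <- function(probe_id, gene_symbol) {
  probe_id <- as.character(probe_id)
  gene_symbol <- as.character(gene_symbol)
  if (length(probe_id) != length(gene_symbol))
    stop("probe_id and gene_symbol lengths differ")
  .check_unique(probe_id, "probe")
  if (any(is.na(gene_symbol) | !nzchar(gene_symbol)))
    stop("empty gene_symbol in probe map")
  data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
             stringsAsFactors = FALSE)
}

#' Collapse probe-level features to gene level
#'
#' Microarray platforms carry several probes per gene; cross-platform set
#' logic downstream needs one row per gene symbol. Two rules are provided:
#' `"named_probe"` keeps an explicitly designated probe per gene (the
#' convention for well-characterised seed genes, e.g. 219630_at for MAP17
#' on Affymetrix arrays) and falls back to `"max_mean"` for other genes;
#' `"max_mean"` keeps, per gene, the probe with the highest mean expression
#' across samples. Probes absent from the map are dropped with a message.
#'
#' @param cohort An [expression_cohort()] with probe-level features.
#' @param map A probe map as returned by [read_probe_map()] / [probe_map()].
#' @param method `"max_mean"` (default) or `"named_probe"`.
#' @param designated For `"named_probe"`: named character vector,
#'   `gene_symbol -> probe_id`. A designated probe missing from the cohort
#'   is a hard error.
#' @return A gene-level [expression_cohort()].
#' @export
collapse_probes <- function(cohort, map,
                            method = c("max_mean", "named_probe"),
                            designated = NULL) {
  method <- match.arg(method)
  vals <- cohort$values
  keep <- rownames(vals) %in% map$probe_id
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message("collapse_probes: dropping ", n_drop, " unmapped feature(s)")
  vals <- vals[keep, , drop = FALSE]
  if (nrow(vals) == 0L) stop("no mapped features remain after dropping")
  gene <- map$gene_symbol[match(rownames(vals), map$probe_id)]

  pick <- vapply(split(seq_len(nrow(vals)), gene), function(idx) {
    if (length(idx) == 1L) return(idx)
    idx[which.max(rowMeans(vals[idx, , drop = FALSE], na.rm = TRUE))]
  }, integer(1L))

  if (method == "named_probe") {
    if (is.null(designated) || is.null(names(designated)))
      stop("`designated` (gene -> probe) is required for method = 'named_probe'")
    for (g in names(designated)) {
      p <- designated[[g]]
      if (!p %in% rownames(vals))
        stop("designated probe '", p, "' for gene '", g,
             "' absent from cohort ", cohort$cohort_id)
      pick[[g]] <- match(p, rownames(vals))
    }
  }

  out <- vals[pick, , drop = FALSE]
  rownames(out) <- names(pick)
  expression_cohort(out, cohort_id = cohort$cohort_id,
                    group_id = cohort$group_id)
}

#' Write / read a gene list with annotations
#'
#' Tab-separated with a header; first column `gene`, any further columns are
#' per-gene annotations. Write then read returns identical content.
#'
#' @param genes Character vector of gene symbols, or a data frame whose
#'   first column is `gene`.
#' @param path File path.
#' @param annotations Optional data frame of per-gene annotation columns.
#' @return `write_gene_list_tsv`: `path`, invisibly. `read_gene_list_tsv`:
#'   a data frame with a `gene` column.
#' @export
write_gene_list_tsv <- function(genes, path, annotations = NULL) {
  df <- if (is.data.frame(genes)) {
    names(genes)[1L] <- "gene"
    genes
  } else {
    data.frame(gene = as.character(genes), stringsAsFactors = FALSE)
  }
  if (!is.null(annotations)) df <- cbind(df, annotations)
  .check_unique(df$gene, "gene")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_list_tsv
#' @export
read_gene_list_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- "gene"
  df$gene <- as.character(df$gene)
  .check_unique(df$gene, "gene")
  df
}

#' Read a gene-set collection in GMT format
#'
#' One term per line: term id, description, then one or more member genes,
#' all tab-separated. Lines with fewer than three fields are a hard error.
#'
#' @param path Path to a `.gmt` file.
#' @return A `gene_set_collection`: named list of
#'   `list(description =, genes =)` keyed by term id.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields")
    ids[[i]] <- f[[1L]]
    sets[[i]] <- list(description = f[[2L]], genes = unique(f[-(1:2)]))
  }
  .check_unique(ids, "term")
  names(sets) <- ids
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d term(s)\n", length(x)))
  invisible(x)
}
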