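#' Read a run configuration (JSON or YAML)
#'
#' A run configuration describes an end-to-end screen: the cohort manifest,
#' the seed gene, correlation settings, per-group recurrence cutoffs and
#' the consensus level. Fields:
#'
#' * `cohorts`: list of `{path, cohort_id, group_id}` entries (paths are
#'   resolved relative to the config file's directory when not absolute);
#' * `seed_gene`; `method` (`"pearson"`/`"spearman"`, default pearson);
#'   `alpha` (default 0.05); `min_abs_r` (default 0);
#' * `cutoffs`: mapping `group_id -> integer` recurrence cutoff, or a
#'   string like `"cervix:2/5,lung:3/6,breast:5/19,colon:5/10"` (the `/m`
#'   part is checked against the manifest);
#' * `min_groups`: consensus level G (default: number of groups);
#' * optional `stratify`: `{genes: [...], variant: "student"}`;
#' * optional `enrichment`: `{gmt: path, background: "screen" or path}`;
#' * `seed`: master seed recorded in the summary.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return The configuration as a list, with `base_dir` attached.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  cfg$base_dir <- dirname(normalizePath(path))
  cfg
}

#' Parse a cutoff string like "cervix:2/5,lung:3/6"
#'
#' @param s Comma-separated `group:cutoff` or `group:cutoff/m` entries.
#' @return Named integer vector of cutoffs, with attribute `m` (named
#'   integer, NA where no `/m` was given).
#' @export
parse_cutoffs <- function(s) {
  parts <- strsplit(trimws(strsplit(s, ",", fixed = TRUE)[[1L]]), ":",
                    fixed = TRUE)
  bad <- vapply(parts, length, integer(1L)) != 2L
  if (any(bad)) stop("malformed cutoff entry: ",
                     paste(sapply(parts[bad], paste, collapse = ":"),
                           collapse = ", "))
  ids <- vapply(parts, `[[`, character(1L), 1L)
  rhs <- strsplit(vapply(parts, `[[`, character(1L), 2L), "/", fixed = TRUE)
  k <- as.integer(vapply(rhs, `[[`, character(1L), 1L))
  m <- vapply(rhs, function(x)
    if (length(x) > 1L) as.integer(x[[2L]]) else NA_integer_, integer(1L))
  if (any(is.na(k))) stop("non-integer cutoff in: ", s)
  structure(stats::setNames(k, ids), m = stats::setNames(m, ids))
}

.resolve_path <- function(p, base) {
  if (grepl("^(/|[A-Za-z]:)", p) || is.null(base)) p else file.path(base, p)
}

#' Run the full co-expression consensus screen
#'
#' Orchestrates correlate -> split-by-sign -> per-group recurrence ->
#' cross-group consensus (plus stratified testing and gene-set enrichment
#' when configured) from a single configuration, writing per-stage TSVs, a
#' machine-readable `summary.json` and a run log. Identical configuration
#' and inputs produce byte-identical summaries (the log carries the
#' timestamps; the summary does not).
#'
#' @param config A configuration list (see [read_run_config()]) or a path
#'   to a config file. Cohorts may be supplied in-memory as a list of
#'   [expression_cohort()] under `config$cohort_objects` instead of the
#'   `cohorts` manifest.
#' @param outdir Output directory (created if needed); overrides
#'   `config$outdir`.
#' @return The summary, invisibly, as a list (also written to
#'   `<outdir>/summary.json`).
#' @export
run_screen <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    message(msg)
  }
  stage <- "setup"
  on_error <- function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  tryCatch({
    seed_gene <- config$seed_gene %||% stop("config lacks `seed_gene`")
    method <- config$method %||% "pearson"
    alpha <- config$alpha %||% 0.05
    min_abs_r <- config$min_abs_r %||% 0

    stage <- "load"
    cohorts <- if (!is.null(config$cohort_objects)) {
      config$cohort_objects
    } else {
      if (is.null(config$cohorts)) stop("config lacks a `cohorts` manifest")
      lapply(config$cohorts, function(entry) {
        p <- .resolve_path(entry$path, config$base_dir)
        if (!file.exists(p)) stop("cohort file not found: ", p)
        read_expression_tsv(p, cohort_id = entry$cohort_id,
                            group_id = entry$group_id)
      })
    }
    names(cohorts) <- vapply(cohorts, `[[`, character(1L), "cohort_id")
    group_of <- vapply(cohorts, `[[`, character(1L), "group_id")
    log_line("loaded ", length(cohorts), " cohort(s) in ",
             length(unique(group_of)), " group(s)")

    cutoffs <- config$cutoffs
    if (is.character(cutoffs) && length(cutoffs) == 1L)
      cutoffs <- parse_cutoffs(cutoffs)
    cutoffs <- unlist(cutoffs)
    groups <- unique(group_of)
    missing_spec <- setdiff(groups, names(cutoffs))
    if (length(missing_spec))
      stop("no cutoff specified for group(s): ",
           paste(missing_spec, collapse = ", "))

    stage <- "correlate"
    sign_lists <- lapply(cohorts, function(co) {
      tab <- correlate_with_seed(co, seed_gene, method = method)
      write_correlation_tsv(
        tab, file.path(outdir, paste0("correlation_", co$cohort_id, ".tsv")))
      split_by_sign(tab, alpha = alpha, min_abs_r = min_abs_r)
    })
    for (sl in sign_lists)
      log_line("cohort ", sl$cohort_id, ": ", length(sl$positive),
               " positive, ", length(sl$negative), " negative")

    stage <- "recurrence"
    recurrent <- lapply(groups, function(g) {
      spec <- group_recurrence_spec(g, names(cohorts)[group_of == g],
                                    cutoffs[[g]])
      res <- recurrence_filter(sign_lists[group_of == g], spec)
      for (s in c("positive", "negative"))
        write_gene_list_tsv(res[[s]],
                            file.path(outdir,
                                      sprintf("recurrent_%s_%s.tsv", g, s)))
      res
    })
    names(recurrent) <- groups

    stage <- "consensus"
    G <- config$min_groups %||% length(groups)
    cons <- consensus_intersect(recurrent, min_groups = G)
    for (s in c("positive", "negative")) {
      gc <- cons[[s]]$group_count
      write_gene_list_tsv(
        data.frame(gene = names(gc)[order(names(gc))],
                   group_count = gc[order(names(gc))]),
        file.path(outdir, sprintf("consensus_%s.tsv", s)))
      if (!is.null(cons[[s]]$venn_regions))
        utils::write.table(
          data.frame(region = names(cons[[s]]$venn_regions),
                     count = as.integer(cons[[s]]$venn_regions)),
          file.path(outdir, sprintf("venn_%s.tsv", s)),
          sep = "\t", quote = FALSE, row.names = FALSE)
    }
    log_line("consensus at G = ", G, ": ",
             length(cons$positive$consensus), " positive, ",
             length(cons$negative$consensus), " negative")

    summary <- list(
      seed_gene = seed_gene, method = method, alpha = alpha,
      min_abs_r = min_abs_r, min_groups = G,
      master_seed = config$seed %||% NA,
      cohort_list_sizes = lapply(sign_lists, function(sl)
        list(positive = length(sl$positive), negative = length(sl$negative))),
      recurrent_sizes = lapply(recurrent, function(r)
        list(cutoff = r$cutoff, m = r$m,
             positive = nrow(r$positive), negative = nrow(r$negative))),
      consensus_sizes = list(positive = length(cons$positive$consensus),
                             negative = length(cons$negative$consensus)),
      conflict_genes = length(cons$conflict_genes))

    stage <- "stratify"
    if (!is.null(config$stratify)) {
      strat <- lapply(cohorts, function(co) {
        labels <- dichotomize_by_seed(co, seed_gene)
        res <- two_group_test(co, labels,
                              genes = unlist(config$stratify$genes),
                              variant = config$stratify$variant %||% "student",
                              adjust = isTRUE(config$stratify$adjust))
        utils::write.table(as.data.frame(res),
                           file.path(outdir, paste0("stratified_",
                                                    co$cohort_id, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        sum(res$status == "ok" & !is.na(res$p) & res$p < alpha)
      })
      summary$stratified_significant <- strat
    }

    stage <- "enrich"
    if (!is.null(config$enrichment)) {
      collection <- read_gmt(.resolve_path(config$enrichment$gmt,
                                           config$base_dir))
      bg_spec <- config$enrichment$background %||% "screen"
      background <- if (identical(bg_spec, "screen")) {
        unique(unlist(lapply(cohorts, function(co) rownames(co$values))))
      } else {
        read_gene_list_tsv(.resolve_path(bg_spec, config$base_dir))$gene
      }
      enr <- fold_enrichment(cons$positive$consensus, collection, background)
      utils::write.table(enr, file.path(outdir, "enrichment_positive.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$enrichment_terms_tested <- nrow(enr)
    }

    stage <- "summary"
    cfg_for_hash <- config[setdiff(names(config),
                                   c("base_dir", "cohort_objects", "outdir"))]
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(cfg_for_hash, tmp, auto_unbox = TRUE, digits = NA)
    summary$config_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line("R ", getRversion(), ", coexscreen ",
             as.character(utils::packageVersion("coexscreen")),
             ", config hash ", summary$config_hash,
             ", seed ", summary$master_seed)
    invisible(summary)
  }, error = on_error)
}

#' Simulate cohorts to disk
#'
#' Writes every cohort of a synthetic design as an expression TSV plus the
#' planted truth as JSON, and returns a manifest usable in a run config.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory.
#' @return Data frame manifest (`path`, `cohort_id`, `group_id`),
#'   invisibly; `truth.json` is written alongside.
#' @export
simulate_to_dir <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_cohorts(config)
  manifest <- do.call(rbind, lapply(sim$cohorts, function(co) {
    p <- file.path(outdir, paste0(co$cohort_id, ".tsv"))
    write_expression_tsv(co, p)
    data.frame(path = p, cohort_id = co$cohort_id, group_id = co$group_id,
               stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL
  write_truth_json(sim$truth, file.path(outdir, "truth.json"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
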