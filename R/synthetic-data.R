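#' Configuration for the synthetic multi-cohort generator
#'
#' Describes a world with the structure the screen assumes: several
#' condition groups, each with a number of cohorts; one seed gene; a
#' planted module of genes positively co-expressed with the seed and a
#' planted module negatively co-expressed, both driven by a shared latent
#' factor; and independent background genes. Defaults mirror a full
#' four-tumor screen (5 cervical, 6 lung, 19 breast and 10 colon cohorts).
#'
#' Per cohort of `n` samples, a latent factor `f ~ N(0, 1)` is drawn per
#' sample. The seed gene is `baseline + f + sigma * noise`; a
#' positive-module gene, when active in the cohort (probability `pi` per
#' cohort per gene), is `baseline + beta * f + sigma * noise`; the negative
#' module uses `-beta`. Inactive module genes and background genes are
#' `baseline + sigma * noise`. Per-gene, per-cohort baselines are
#' `N(baseline_mean, baseline_sd)`, giving log2-intensity-like levels. The
#' implied population correlation of an active module gene with the latent
#' factor is `beta / sqrt(beta^2 + sigma^2)`.
#'
#' @param groups Data frame with columns `group_id`, `n_cohorts`, `n_min`,
#'   `n_max` (per-cohort sample-size range, drawn uniformly).
#' @param genes_total Total genes including the seed (default 2000).
#' @param module_size_pos,module_size_neg Planted module sizes (default 50
#'   each).
#' @param beta Latent-factor loading of module genes, >= 0 (default 0.8).
#' @param sigma Residual noise SD, > 0 (default 1).
#' @param pi Per-cohort, per-gene module membership probability in (0, 1]
#'   (default 1); values below 1 emulate cohorts in which a module gene is
#'   not co-regulated, the reason recurrence cutoffs below the cohort count
#'   are needed.
#' @param baseline_mean,baseline_sd Background log2 level distribution
#'   (defaults 8 and 1.5, typical of MAS5.0 log2 intensities).
#' @param seed_gene Name to give the seed gene (default `"SEED1"`).
#' @param seed Master random seed (integer).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(groups = default_groups(),
                             genes_total = 2000L,
                             module_size_pos = 50L,
                             module_size_neg = 50L,
                             beta = 0.8, sigma = 1, pi = 1,
                             baseline_mean = 8, baseline_sd = 1.5,
                             seed_gene = "SEED1", seed = 1L) {
  need <- c("group_id", "n_cohorts", "n_min", "n_max")
  if (!is.data.frame(groups) || !all(need %in% names(groups)))
    stop("`groups` must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (any(groups$n_min < 5L) || any(groups$n_max < groups$n_min))
    stop("per-cohort sample-size range must satisfy 5 <= n_min <= n_max")
  if (module_size_pos + module_size_neg + 1L > genes_total)
    stop("module sizes + seed gene exceed genes_total")
  if (beta < 0) stop("beta must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (pi <= 0 || pi > 1) stop("pi must be in (0, 1]")
  if (baseline_sd < 0) stop("baseline_sd must be >= 0")
  structure(list(groups = groups, genes_total = as.integer(genes_total),
                 module_size_pos = as.integer(module_size_pos),
                 module_size_neg = as.integer(module_size_neg),
                 beta = beta, sigma = sigma, pi = pi,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed_gene = seed_gene, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_groups <- function() {
  data.frame(group_id = c("cervix", "lung", "breast", "colon"),
             n_cohorts = c(5L, 6L, 19L, 10L),
             n_min = 50L, n_max = 250L,
             stringsAsFactors = FALSE)
}

#' @rdname synthetic_config
#' @param n_cohorts,n Scaled-down design: cohorts per group and fixed
#'   per-cohort sample size.
#' @param ... Passed on to [synthetic_config()].
#' @export
scaled_down_config <- function(seed = 1L, n_cohorts = 3L, n = 100L, ...) {
  synthetic_config(
    groups = data.frame(group_id = c("cervix", "lung", "breast", "colon"),
                        n_cohorts = as.integer(n_cohorts),
                        n_min = as.integer(n), n_max = as.integer(n),
                        stringsAsFactors = FALSE),
    seed = seed, ...)
}

# Fixed master-seed -> per-cohort substream map: cohorts are numbered in
# manifest order (groups in row order, cohorts within group in order) and
# cohort i uses seed (master * 7919 + i * 104729) mod (2^31 - 1). This
# makes each cohort reproducible independently of generation order.
.cohort_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483647 * 7919 + i * 104729) %%
               2147483647)
}

#' Generate synthetic multi-cohort expression data with planted modules
#'
#' Draws every cohort described by the configuration (see
#' [synthetic_config()] for the generative model) and returns the cohorts
#' together with the planted ground truth for recovery scoring. Fully
#' reproducible: the same configuration (including its master seed) yields
#' bit-identical matrices, and each cohort is drawn from its own
#' deterministic substream of the master seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `cohorts` (list of [expression_cohort()]) and `truth`
#'   (a `synthetic_truth`: `positive_module`, `negative_module`,
#'   `realized_membership` — per cohort, named logical over module genes —
#'   and the `config`).
#' @export
generate_cohorts <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("`config` must be a synthetic_config")
  n_pos <- config$module_size_pos
  n_neg <- config$module_size_neg
  n_bg <- config$genes_total - n_pos - n_neg - 1L
  pos_genes <- sprintf("PM%04d", seq_len(n_pos))
  neg_genes <- sprintf("NM%04d", seq_len(n_neg))
  bg_genes <- if (n_bg > 0L) sprintf("BG%05d", seq_len(n_bg)) else character(0)
  gene_ids <- c(config$seed_gene, pos_genes, neg_genes, bg_genes)
  module_genes <- c(pos_genes, neg_genes)
  loadings <- c(rep(config$beta, n_pos), rep(-config$beta, n_neg))

  cohorts <- list()
  membership <- list()
  idx <- 0L
  for (g in seq_len(nrow(config$groups))) {
    grp <- config$groups[g, ]
    for (j in seq_len(grp$n_cohorts)) {
      idx <- idx + 1L
      cid <- sprintf("%s_c%02d", grp$group_id, j)
      rng <- .cohort_seed(config$seed, idx)
      set.seed(rng)
      n <- if (grp$n_min == grp$n_max) grp$n_min
           else sample(grp$n_min:grp$n_max, 1L)
      active <- stats::runif(length(module_genes)) <= config$pi
      names(active) <- module_genes
      f <- stats::rnorm(n)
      baseline <- stats::rnorm(length(gene_ids), config$baseline_mean,
                               config$baseline_sd)
      noise <- matrix(stats::rnorm(length(gene_ids) * n, sd = config$sigma),
                      nrow = length(gene_ids))
      signal <- matrix(0, nrow = length(gene_ids), ncol = n)
      signal[1L, ] <- f
      act_load <- loadings * active
      signal[1L + seq_along(module_genes), ] <- outer(act_load, f)
      vals <- baseline + signal + noise
      dimnames(vals) <- list(gene_ids,
                             sprintf("%s_s%03d", cid, seq_len(n)))
      cohorts[[cid]] <- expression_cohort(vals, cohort_id = cid,
                                          group_id = grp$group_id)
      membership[[cid]] <- active
    }
  }
  truth <- structure(list(positive_module = pos_genes,
                          negative_module = neg_genes,
                          realized_membership = membership,
                          config = config),
                     class = "synthetic_truth")
  list(cohorts = cohorts, truth = truth)
}

#' Score recovery of the planted modules
#'
#' Compares a consensus result (or explicit found gene sets) against the
#' planted truth: per sign, `precision = |found ∩ planted| / |found|` and
#' `recall = |found ∩ planted| / |planted|`; `F1` is their harmonic mean,
#' defined as 0 when precision + recall = 0. An empty found set gives
#' precision 0 with a degenerate flag.
#'
#' @param consensus A `consensus_result` from [consensus_intersect()], or a
#'   list `list(positive =, negative =)` of character vectors.
#' @param truth A `synthetic_truth` from [generate_cohorts()].
#' @param G Consensus level at which to extract the found sets (default:
#'   the result's `min_groups`); ignored for plain lists.
#' @return A `recovery_metrics` data frame: one row per sign with
#'   `precision`, `recall`, `F1`, `n_found`, `n_planted`, `degenerate`.
#' @export
evaluate_recovery <- function(consensus, truth, G = NULL) {
  found <- if (inherits(consensus, "consensus_result")) {
    if (is.null(G)) G <- consensus$min_groups
    list(positive = consensus_at(consensus, G, "positive"),
         negative = consensus_at(consensus, G, "negative"))
  } else {
    list(positive = as.character(consensus$positive),
         negative = as.character(consensus$negative))
  }
  planted <- list(positive = truth$positive_module,
                  negative = truth$negative_module)
  rows <- lapply(c("positive", "negative"), function(s) {
    f <- unique(found[[s]]); pl <- unique(planted[[s]])
    hit <- length(intersect(f, pl))
    precision <- if (length(f)) hit / length(f) else 0
    recall <- if (length(pl)) hit / length(pl) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(sign = s, precision = precision, recall = recall, F1 = f1,
               n_found = length(f), n_planted = length(pl),
               degenerate = length(f) == 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("recovery_metrics", "data.frame"))
}

#' Write / read the planted-truth JSON
#'
#' The simulate stage writes the cohorts as expression TSVs plus this truth
#' file; recovery scoring reads it back.
#'
#' @param truth A `synthetic_truth`.
#' @param path JSON path.
#' @return `write_truth_json`: `path`, invisibly; `read_truth_json`: a
#'   `synthetic_truth` (without the full config echo's class).
#' @export
write_truth_json <- function(truth, path) {
  cfg <- unclass(truth$config)
  cfg$groups <- as.list(cfg$groups)
  jsonlite::write_json(
    list(positive_module = truth$positive_module,
         negative_module = truth$negative_module,
         realized_membership = lapply(truth$realized_membership, function(a)
           as.list(a)),
         config = cfg),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(positive_module = as.character(x$positive_module),
                 negative_module = as.character(x$negative_module),
                 realized_membership = lapply(x$realized_membership, unlist),
                 config = x$config),
            class = "synthetic_truth")
}
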