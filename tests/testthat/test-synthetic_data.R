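test_that("generation is reproducible and cohort substreams are order-independent", {
  cfg <- scaled_down_config(seed = 3, n_cohorts = 2L, n = 20L,
                            genes_total = 100L, module_size_pos = 10L,
                            module_size_neg = 10L)
  a <- generate_cohorts(cfg)
  b <- generate_cohorts(cfg)
  expect_identical(lapply(a$cohorts, `[[`, "values"),
                   lapply(b$cohorts, `[[`, "values"))
  expect_identical(a$truth$realized_membership, b$truth$realized_membership)
  # different master seed changes the data
  c2 <- generate_cohorts(scaled_down_config(seed = 4, n_cohorts = 2L,
                                            n = 20L, genes_total = 100L,
                                            module_size_pos = 10L,
                                            module_size_neg = 10L))
  expect_false(identical(a$cohorts[[1]]$values, c2$cohorts[[1]]$values))
})

test_that("generated cohorts have the configured shape and identities", {
  cfg <- synthetic_config(
    groups = data.frame(group_id = c("ga", "gb"), n_cohorts = c(2L, 1L),
                        n_min = c(10L, 15L), n_max = c(12L, 15L)),
    genes_total = 50L, module_size_pos = 5L, module_size_neg = 5L, seed = 8)
  sim <- generate_cohorts(cfg)
  expect_length(sim$cohorts, 3L)
  expect_identical(vapply(sim$cohorts, `[[`, "", "group_id"),
                   c(ga_c01 = "ga", ga_c02 = "ga", gb_c01 = "gb"))
  for (co in sim$cohorts) {
    expect_equal(nrow(co$values), 50L)
    expect_true("SEED1" %in% rownames(co$values))
  }
  n <- vapply(sim$cohorts, function(co) ncol(co$values), integer(1))
  expect_true(all(n[1:2] >= 10L & n[1:2] <= 12L))
  expect_equal(unname(n[3]), 15L)
  expect_length(intersect(sim$truth$positive_module,
                          sim$truth$negative_module), 0L)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(genes_total = 90L), "exceed")
  expect_error(synthetic_config(pi = 0), "pi")
  expect_error(synthetic_config(sigma = 0), "sigma")
  expect_error(synthetic_config(beta = -1), "beta")
})

test_that("pi < 1 drops module genes per cohort at the configured rate", {
  cfg <- scaled_down_config(seed = 17, n_cohorts = 5L, n = 10L,
                            genes_total = 500L, module_size_pos = 100L,
                            module_size_neg = 100L, pi = 0.5)
  sim <- generate_cohorts(cfg)
  act <- unlist(sim$truth$realized_membership)
  frac <- mean(act)
  se <- sqrt(0.5 * 0.5 / length(act))
  expect_lt(abs(frac - 0.5), 4 * se)
  # membership recorded for module genes only
  expect_setequal(unique(unlist(lapply(sim$truth$realized_membership, names))),
                  c(sim$truth$positive_module, sim$truth$negative_module))
})

test_that("active module genes carry the planted correlation; beta = 0 removes it", {
  cfg <- scaled_down_config(seed = 23, n_cohorts = 1L, n = 100L)
  co <- generate_cohorts(cfg)$cohorts[[1]]
  tab <- correlate_with_seed(co, "SEED1")
  pos_r <- tab$r[grepl("^PM", tab$gene)]
  neg_r <- tab$r[grepl("^NM", tab$gene)]
  # population rho between an active module gene and the (noisy) seed is
  # beta / sqrt((beta^2 + sigma^2) * (1 + sigma^2)) ~= 0.44
  expect_gt(mean(pos_r), 0.35)
  expect_lt(mean(neg_r), -0.35)
  # per-cohort detection power at alpha 0.05 is high at n = 100
  sl <- split_by_sign(tab, alpha = 0.05)
  detected <- (sum(sl$positive %in% tab$gene[grepl("^PM", tab$gene)]) +
               sum(sl$negative %in% tab$gene[grepl("^NM", tab$gene)])) /
    (cfg$module_size_pos + cfg$module_size_neg)
  expect_gte(detected, 0.9)
})

test_that("evaluate_recovery computes set-arithmetic metrics with degenerate flags", {
  truth <- structure(list(positive_module = sprintf("PM%04d", 1:50),
                          negative_module = sprintf("NM%04d", 1:50),
                          realized_membership = list(), config = NULL),
                     class = "synthetic_truth")
  exact <- evaluate_recovery(list(positive = truth$positive_module,
                                  negative = truth$negative_module), truth)
  expect_equal(exact$precision, c(1, 1))
  expect_equal(exact$recall, c(1, 1))
  expect_equal(exact$F1, c(1, 1))

  extra <- evaluate_recovery(
    list(positive = c(truth$positive_module, "IMPOSTOR"),
         negative = character(0)), truth)
  pos <- extra[extra$sign == "positive", ]
  expect_equal(pos$precision, 50 / 51, tolerance = 1e-12)
  expect_equal(pos$recall, 1)
  neg <- extra[extra$sign == "negative", ]
  expect_equal(neg$precision, 0)
  expect_equal(neg$recall, 0)
  expect_equal(neg$F1, 0)
  expect_true(neg$degenerate)
})

test_that("truth JSON round-trips", {
  cfg <- scaled_down_config(seed = 2, n_cohorts = 1L, n = 10L,
                            genes_total = 30L, module_size_pos = 5L,
                            module_size_neg = 5L, pi = 0.6)
  sim <- generate_cohorts(cfg)
  p <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, p)
  back <- read_truth_json(p)
  expect_identical(back$positive_module, sim$truth$positive_module)
  expect_identical(back$negative_module, sim$truth$negative_module)
  expect_equal(back$realized_membership[["cervix_c01"]],
               sim$truth$realized_membership[["cervix_c01"]])
})

test_that("recall degrades as membership probability pi decreases", {
  recall_at <- function(pi, seed) {
    sim <- generate_cohorts(scaled_down_config(seed = seed, pi = pi))
    met <- evaluate_recovery(screen_sim(sim$cohorts, cutoff = 2L,
                                        min_groups = 4L), sim$truth)
    mean(met$recall)
  }
  r <- vapply(c(1.0, 0.8, 0.5), recall_at, numeric(1), seed = 51L)
  expect_gte(r[1], r[2] - 0.05)  # non-increasing within noise
  expect_gte(r[2], r[3] - 0.05)
  expect_gt(r[1] - r[3], 0.2)    # and the drop is real, not flat
})
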