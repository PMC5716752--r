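test_that("dichotomize_by_seed applies the strict-median rule", {
  co <- cohort_from_rows(list(SEED = c(1, 2, 3, 4), G = c(0, 0, 0, 0)),
                         sample_ids = paste0("s", 1:4))
  lab <- dichotomize_by_seed(co, "SEED")
  expect_identical(lab[c("s1", "s2")], c(s1 = "low", s2 = "low"))
  expect_identical(lab[c("s3", "s4")], c(s3 = "high", s4 = "high"))

  # ties at the median fall into "low" (strict inequality)
  co2 <- cohort_from_rows(list(SEED = c(1, 2, 2, 3), G = rep(0, 4)),
                          sample_ids = paste0("s", 1:4))
  lab2 <- dichotomize_by_seed(co2, "SEED")
  expect_identical(names(lab2)[lab2 == "high"], "s4")
  expect_setequal(names(lab2)[lab2 == "low"], c("s1", "s2", "s3"))

  co3 <- cohort_from_rows(list(SEED = rep(5, 4), G = rep(0, 4)))
  expect_error(dichotomize_by_seed(co3, "SEED"), "constant")
})

test_that("two_group_test matches the pooled closed form and handles edge cases", {
  co <- cohort_from_rows(
    list(SEED = c(1, 1, 1, 8, 8, 8),
         ORA = c(1, 2, 3, 2, 3, 4),
         SAME = c(5, 6, 7, 5, 6, 7),
         THIN = c(1, 2, NA, 3, NA, NA)),
    sample_ids = paste0("s", 1:6))
  labels <- stats::setNames(c("low", "low", "low", "high", "high", "high"),
                            paste0("s", 1:6))
  res <- two_group_test(co, labels, genes = c("ORA", "SAME", "THIN"))
  ora <- res[res$gene == "ORA", ]
  want <- oracle_pooled_t(c(2, 3, 4), c(1, 2, 3))  # high vs low
  expect_equal(ora$t, unname(want["t"]), tolerance = 1e-10)
  expect_equal(ora$p, unname(want["p"]), tolerance = 1e-10)
  # hand-computed values for the same case: t = 1/sqrt(2/3), df = 4
  expect_equal(ora$t, sqrt(1.5), tolerance = 1e-10)
  expect_equal(ora$p, 2 * pt(-sqrt(1.5), 4), tolerance = 1e-10)
  expect_identical(ora$direction, "up_in_high")
  expect_equal(ora$mean_low, 2)
  expect_equal(ora$mean_high, 3)

  same <- res[res$gene == "SAME", ]
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_identical(same$direction, "flat")

  expect_identical(res$status[res$gene == "THIN"], "not_testable")
  expect_true(is.na(res$p[res$gene == "THIN"]))
})

test_that("swapping strata negates t and preserves p; welch differs under heteroscedasticity", {
  set.seed(5)
  vals <- list(SEED = c(rep(0, 6), rep(9, 6)),
               G = c(rnorm(6, sd = 0.2), rnorm(6, sd = 3)))
  co <- cohort_from_rows(vals, sample_ids = paste0("s", 1:12))
  labels <- stats::setNames(rep(c("low", "high"), each = 6), paste0("s", 1:12))
  flipped <- stats::setNames(rep(c("high", "low"), each = 6), paste0("s", 1:12))
  for (variant in c("student", "welch")) {
    a <- two_group_test(co, labels, genes = "G", variant = variant)
    b <- two_group_test(co, flipped, genes = "G", variant = variant)
    expect_equal(a$t, -b$t, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
  s <- two_group_test(co, labels, genes = "G", variant = "student")
  w <- two_group_test(co, labels, genes = "G", variant = "welch")
  expect_false(isTRUE(all.equal(s$p, w$p)))
  # welch agrees with R's reference implementation
  ref <- t.test(vals$G[7:12], vals$G[1:6])
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$p, ref$p.value, tolerance = 1e-10)
})

test_that("bh_adjust matches the step-up definition", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.05, 6)), rep(0.05, 6))
  set.seed(99)
  for (rep in 1:10) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= 0 & q <= 1))
    expect_gte(min(q), min(p))
    # monotone nondecreasing in sorted-p order
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("score_infiltration_association runs the pooled t on ordinal scores", {
  flat <- score_infiltration_association(c(2, 2, 2, 2),
                                         c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)

  res <- score_infiltration_association(c(3, 3, 2, 0, 1),
                                        c(TRUE, TRUE, TRUE, FALSE, FALSE))
  want <- oracle_pooled_t(c(3, 3, 2), c(0, 1))
  expect_equal(res$t, unname(want["t"]), tolerance = 1e-10)
  expect_equal(res$p, unname(want["p"]), tolerance = 1e-10)
  expect_equal(res$n_pos, 3L)
  expect_equal(res$n_neg, 2L)
  expect_equal(res$mean_pos, 8 / 3)

  expect_error(score_infiltration_association(c(1, 2, 3), rep(TRUE, 3)),
               "class")
  expect_error(score_infiltration_association(c(1, 5), c(TRUE, FALSE)),
               "scores")
})

test_that("order_for_heatmap sorts by seed with lexicographic ties and round-trips", {
  co <- cohort_from_rows(list(SEED = c(3, 1, 2), M1 = c(9, 8, 7),
                              M2 = c(1, 2, 3)),
                         sample_ids = c("a", "b", "c"))
  out <- order_for_heatmap(co, genes = c("M1", "M2"), seed_gene = "SEED")
  expect_identical(out$sample_order, c("b", "c", "a"))
  expect_identical(rownames(out$matrix), c("M1", "M2"))
  expect_equal(unname(out$matrix["M1", ]), c(8, 7, 9))

  tie <- cohort_from_rows(list(SEED = c(1, 1), M = c(5, 6)),
                          sample_ids = c("z", "a"))
  expect_identical(order_for_heatmap(tie, "M", "SEED")$sample_order,
                   c("a", "z"))

  p <- tempfile(fileext = ".tsv")
  order_for_heatmap(co, c("M1", "M2"), "SEED", path = p)
  back <- read_expression_tsv(p, cohort_id = "hm", group_id = "g")
  expect_equal(back$values, out$matrix)

  expect_error(order_for_heatmap(co, c("M1", "NOPE"), "SEED"), "NOPE")
})

test_that("stratified direction agrees with the planted sign almost always", {
  agree <- 0L; total <- 0L
  for (s in 1:10) {
    cfg <- scaled_down_config(seed = 300L + s, n_cohorts = 1L,
                              genes_total = 150L, module_size_pos = 25L,
                              module_size_neg = 25L)
    co <- generate_cohorts(cfg)$cohorts[[1]]
    labels <- dichotomize_by_seed(co, "SEED1")
    module <- grep("^(PM|NM)", rownames(co$values), value = TRUE)
    res <- two_group_test(co, labels, genes = module)
    planted <- ifelse(grepl("^PM", res$gene), "up_in_high", "down_in_high")
    agree <- agree + sum(res$direction == planted)
    total <- total + nrow(res)
  }
  expect_gte(agree / total, 0.95)
})
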