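# coexscreen

Cross-cohort seed-gene co-expression consensus screening in R.

## The problem

A recurring question in transcriptomics is: *which genes track the
expression of one gene of interest across many independent patient
cohorts?* A single-cohort correlation screen is noisy — every microarray
or RNA-seq dataset has its own platform, composition and batch structure —
so hits are only believable when they recur across cohorts and across
conditions. The canonical design (used, e.g., to map the inflammatory
program co-expressed with the membrane protein MAP17/PDZK1IP1 across
cervical, lung, breast and colon tumors) is:

1. **Per-cohort screen.** Correlate every gene with the seed gene inside
   each cohort; call a gene significant at a two-sided p < α (default
   α = 0.05, from `t = r·sqrt((n−2)/(1−r²))` on n−2 degrees of freedom)
   and split hits into a *positive* and a *negative* list by the sign
   of r.
2. **Per-group recurrence.** Within each condition group (e.g. one tumor
   type with m_g cohorts), keep genes appearing — same sign — in at least
   k_g of the group's cohorts (published defaults: 2 of 5 cervical, 3 of
   6 lung, 5 of 19 breast, 5 of 10 colon cohorts).
3. **Cross-group consensus.** Intersect the recurrent lists across groups
   (Venn-style, with the full region decomposition) and keep genes
   recurrent in at least G groups.
4. **Interpretation.** Score the consensus list against gene-set
   collections with fold enrichment `FE = (k/n)/(K/N)` and a one-sided
   hypergeometric test; split samples into seed-high/seed-low strata at
   the median and t-test marker genes between strata.

Because the real inputs are dozens of public datasets, the package ships
a synthetic multi-cohort generator with *planted* positively and
negatively co-expressed modules (a shared latent factor per cohort, gene
loadings ±β, residual noise σ, per-cohort module membership probability
π), so the entire pipeline is testable offline and recovery of the
planted truth is measurable as precision/recall.

## Worked example

Simulate the scaled-down design (4 groups × 3 cohorts, n = 100 samples,
2,000 genes, 50-gene positive and negative planted modules, β = 0.8,
σ = 1, π = 1), screen it, and score recovery:

```r
library(coexscreen)

sim <- generate_cohorts(scaled_down_config(seed = 42))
sim$cohorts[[1]]
#> <expression_cohort> cervix_c01 (group cervix): 2000 features x 100 samples

tab <- correlate_with_seed(sim$cohorts[[1]], "SEED1")
head(tab[order(tab$p), ], 3)
#>      gene          r            p n_used status
#> 33 PM0033  0.6233455 4.317711e-12    100     ok
#> 16 PM0016  0.5869557 1.381064e-10    100     ok
#> 55 NM0005 -0.5778348 3.081703e-10    100     ok

split_by_sign(tab, alpha = 0.05)
#> <signed_gene_lists> cervix_c01: 92 positive, 88 negative (alpha 0.05)

sign_lists <- lapply(sim$cohorts, function(co)
  split_by_sign(correlate_with_seed(co, "SEED1"), alpha = 0.05))
groups <- unique(vapply(sim$cohorts, `[[`, "", "group_id"))
recurrent <- lapply(groups, function(g) {
  members <- Filter(function(s) s$group_id == g, sign_lists)
  recurrence_filter(members, group_recurrence_spec(
    g, vapply(members, `[[`, "", "cohort_id"), cutoff = 2L))
})
names(recurrent) <- groups
recurrent$cervix
#> <recurrence_result> cervix (cutoff 2 of 3): 56 positive, 57 negative

cons <- consensus_intersect(recurrent, min_groups = 4)
cons
#> <consensus_result> 4 groups, G = 4: 50 positive, 50 negative consensus gene(s), 0 conflict(s)

as.data.frame(evaluate_recovery(cons, sim$truth))
#>       sign precision recall F1 n_found n_planted degenerate
#> 1 positive         1      1  1      50        50      FALSE
#> 2 negative         1      1  1      50        50      FALSE
```

Reading: each single cohort's list carries ~40 false positives (α/2 per
sign on ~1,900 background genes), the 2-of-3 recurrence filter cuts those
to a handful per group, and the all-four-groups consensus recovers the
planted 50+50 modules exactly — precision and recall 1.0 for both signs.

`run_screen()` drives the same stages from a JSON/YAML config with
per-stage TSV outputs, a deterministic `summary.json` and a run log;
`inst/cli/coexscreen.R` exposes `simulate`, `run-all`/`screen` and
`recover` subcommands.

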