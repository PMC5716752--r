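# Run the in-memory screen (correlate -> split -> recurrence -> consensus)
# on a simulated cohort set, without touching disk.
screen_sim <- function(cohorts, seed_gene = "SEED1", alpha = 0.05,
                       cutoff = 2L, min_groups = 4L) {
  sign_lists <- lapply(cohorts, function(co)
    split_by_sign(correlate_with_seed(co, seed_gene), alpha = alpha))
  groups <- unique(vapply(cohorts, `[[`, "", "group_id"))
  recurrent <- lapply(groups, function(g) {
    members <- Filter(function(sl) sl$group_id == g, sign_lists)
    spec <- group_recurrence_spec(
      g, vapply(members, `[[`, "", "cohort_id"), cutoff)
    recurrence_filter(members, spec)
  })
  names(recurrent) <- groups
  consensus_intersect(recurrent, min_groups = min_groups)
}
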