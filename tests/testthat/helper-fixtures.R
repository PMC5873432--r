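# Shared fixture builders (all generated in code; nothing on disk).

small_regions <- function(n_pairs = 3, n_midline = 0) {
  synthetic_region_table(n_pairs = n_pairs, n_midline = n_midline)
}

# A tiny deterministic correlation matrix with all-distinct |Cij|.
fixed_corr <- function(n = 5, seed = 42) {
  set.seed(seed)
  C <- rand_corr(n)
  C
}

# A quick detrended cohort -> correlation matrix.
quick_corr <- function(n_subjects = 60, regions = small_regions(10),
                       h = 0.4, seed = 11) {
  coh <- generate_cohort(cohort_config(
    n_subjects, age_range = c(20, 31), region_table = regions,
    homologous_coupling = h, seed = seed))
  pearson_matrix(regress_out_confounds(coh$myelin, coh$subjects))
}

expect_curve_invariants <- function(curve) {
  expect_s3_class(curve, "property_curve")
  expect_length(curve$values, length(curve$sparsity))
  expect_equal(curve$auc, auc_trapezoid(curve$sparsity, curve$values))
}
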