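test_that("windows slide one subject at a time over the age order", {
  s5 <- subject_table(paste0("s", 1:5), c(3, 1, 5, 2, 4), rep(c("F", "M"), c(3, 2)))
  w <- build_windows(s5, 3)
  ages <- lapply(w$indices, function(i) sort(s5$age[i]))
  expect_equal(ages, list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(w$window_ages, c(2, 3, 4))

  w1 <- build_windows(s5, 5)
  expect_length(w1$indices, 1)
  expect_equal(w1$window_ages, median(s5$age))
  expect_error(build_windows(s5, 6), "exceeds")

  # study-scale window arithmetic: M - w + 1 windows, one-subject turnover
  set.seed(28)
  s437 <- subject_table(sprintf("t%03d", 1:437), runif(437, 48, 87),
                        sample(c("F", "M"), 437, TRUE))
  w73 <- build_windows(s437, 73)
  expect_length(w73$indices, 365)
  expect_true(all(w73$window_ages >= 48 & w73$window_ages <= 87))
  for (t in sample(364, 20)) {
    expect_length(setdiff(w73$indices[[t]], w73$indices[[t + 1]]), 1)
    expect_length(setdiff(w73$indices[[t + 1]], w73$indices[[t]]), 1)
  }
  expect_false(is.unsorted(w73$window_ages))
})

test_that("duplicated subjects produce identical consecutive window values", {
  # consecutive windows swap the departing subject for an identical twin
  # (same age, sex and MT row), so the window data -- and hence the
  # property values -- are identical. Tied ages make the age columns
  # constant within the window; the reduced design handles that.
  rt <- small_regions(4)
  set.seed(29)
  M <- 11; w_size <- 10
  s2 <- subject_table(sprintf("s%02d", 1:M), rep(50, M),
                      c("F", sample(c("F", "M"), M - 2, TRUE), "F"))
  m2 <- matrix(rnorm(M * nrow(rt), 1.8, 0.1), M, nrow(rt),
               dimnames = list(s2$subject_id, rt$region_id))
  m2[M, ] <- m2[1, ]                      # s11 is a twin of s01
  w <- build_windows(s2, w_size)
  series <- window_property_series(m2, s2, w, "global_connectivity",
                                   regions = rt, grid = sparsity_grid(0.5, 0.9, 0.1))
  expect_length(series$values, 2)
  expect_equal(series$values[1], series$values[2], tolerance = 1e-12)
  expect_equal(series$n_reduced_design, 2)
})

test_that("an age-invariant cohort yields a flat homologous series", {
  rt <- small_regions(10)
  coh <- generate_cohort(cohort_config(140, age_range = c(48, 87),
                                       region_table = rt,
                                       homologous_coupling = 0.5, seed = 32))
  w <- build_windows(coh$subjects, 73)
  series <- window_property_series(coh$myelin, coh$subjects, w,
                                   "homologous_connectivity", regions = rt)
  fit <- fit_trajectory(series, max_order = 1)
  expect_lt(abs(fit$coefficients[2]), 0.008)   # ~flat in r units per year
})

test_that("a planted rising homologous coupling is recovered as a trend", {
  rt <- small_regions(10)
  coh <- generate_cohort(cohort_config(150, age_range = c(48, 87),
                                       region_table = rt,
                                       homologous_coupling = 0.45,
                                       homologous_coupling_slope = 0.012,
                                       seed = 33))
  w <- build_windows(coh$subjects, 73)
  series <- window_property_series(coh$myelin, coh$subjects, w,
                                   "homologous_connectivity", regions = rt)
  fit <- fit_trajectory(series, max_order = 1)
  expect_gt(fit$coefficients[2], 0)            # positive slope
  expect_lt(fit$coef_pvalues[2], 0.05)
})

test_that("AIC order selection recovers exact fits and simple models", {
  x <- seq(48, 75, length.out = 40)
  cubic <- 2 - 0.05 * x + 0.002 * x^2 - 1.2e-5 * x^3
  s <- list(window_ages = x, values = cubic)
  fit <- fit_trajectory(s, max_order = 6)
  expect_equal(fit$order, 3)
  expect_equal(unname(fit$coefficients),
               c(2, -0.05, 0.002, -1.2e-5), tolerance = 1e-6)
  expect_true(all(fit$coef_pvalues < 0.05))

  line <- list(window_ages = x, values = 0.3 + 0.01 * x)
  expect_equal(fit_trajectory(line, max_order = 6)$order, 1)

  expect_error(fit_trajectory(list(window_ages = x[1:5], values = cubic[1:5]),
                              max_order = 6), "more windows")
})

test_that("order selection is invariant to affine rescaling of the values", {
  set.seed(34)
  x <- seq(48, 75, length.out = 100)
  for (i in 1:10) {
    y <- 0.5 + 0.01 * x - 3e-4 * (x - 60)^2 + rnorm(100, 0, 0.01)
    s1 <- list(window_ages = x, values = y)
    s2 <- list(window_ages = x, values = 40 * y - 7)
    expect_equal(fit_trajectory(s1)$order, fit_trajectory(s2)$order)
  }
})

test_that("NBC window series resolve a named region", {
  rt <- small_regions(5)
  coh <- generate_cohort(cohort_config(40, age_range = c(48, 60),
                                       region_table = rt,
                                       homologous_coupling = 0.4, seed = 35))
  w <- build_windows(coh$subjects, 36)
  series <- window_property_series(coh$myelin, coh$subjects, w, "nbc",
                                   regions = rt, grid = sparsity_grid(0.5, 0.9, 0.1),
                                   region = rt$region_id[1])
  expect_length(series$values, 5)
  expect_true(all(is.finite(series$values)))
  expect_error(window_property_series(coh$myelin, coh$subjects, w, "nbc",
                                      regions = rt, region = "nope"),
               "unknown region")
})
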