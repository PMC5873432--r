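test_that("pearson_matrix matches the textbook formula and flags degeneracy", {
  set.seed(8)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("r", 1:4)))
  C <- pearson_matrix(x)
  # independent oracle: explicit covariance / sigma sigma
  for (i in 1:3) for (j in (i + 1):4) {
    xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
    r <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    expect_equal(C[i, j], r, tolerance = 1e-12)
  }
  expect_equal(diag(C), setNames(rep(0, 4), paste0("r", 1:4)))
  expect_identical(C, t(C))

  y <- cbind(a = x[, 1], b = x[, 1], c = -x[, 2], d = x[, 2])
  Cy <- pearson_matrix(y)
  expect_equal(Cy["a", "b"], 1)
  expect_equal(Cy["c", "d"], -1)

  z <- cbind(x, flat = rep(2, 10))
  expect_error(pearson_matrix(z), "flat")
})

test_that("fisher_mean_abs implements the r-to-z pooling exactly", {
  expect_equal(as.numeric(fisher_mean_abs(c(0.4, 0.4))), 0.4, tolerance = 1e-12)
  expect_equal(as.numeric(fisher_mean_abs(c(0.5, -0.5))), 0.5, tolerance = 1e-12)
  # direct evaluation of the closed form via logs (independent arithmetic)
  z <- function(r) 0.5 * log((1 + r) / (1 - r))
  zm <- (z(0.2) + z(0.8)) / 2
  expected <- (exp(2 * zm) - 1) / (exp(2 * zm) + 1)
  expect_equal(as.numeric(fisher_mean_abs(c(0.2, 0.8))), expected,
               tolerance = 1e-12)
  expect_equal(expected, 0.57215, tolerance = 1e-4)

  # pooled value lies between min and max magnitude
  set.seed(9)
  for (i in 1:20) {
    v <- runif(sample(2:10, 1), -0.95, 0.95)
    fm <- as.numeric(fisher_mean_abs(v))
    expect_gte(fm, min(abs(v)) - 1e-12)
    expect_lte(fm, max(abs(v)) + 1e-12)
  }
  # first-order equality with the arithmetic mean for small |r|
  small <- c(0.01, 0.02, 0.015)
  expect_equal(as.numeric(fisher_mean_abs(small)), mean(small), tolerance = 1e-4)
  expect_error(fisher_mean_abs(numeric(0)), "empty")
  expect_equal(attr(fisher_mean_abs(c(0.5, 1)), "n_clamped"), 1)
})

test_that("connectivity summaries resolve every scope", {
  rt <- region_table(c("a.L", "a.R", "m"), c("x", "y", "z"),
                     c("L", "R", "midline"),
                     c("parietal", "parietal", "limbic"),
                     c("a.R", "a.L", ""))
  C <- matrix(0.4, 3, 3, dimnames = list(rt$region_id, rt$region_id))
  diag(C) <- 0
  g <- connectivity_summary(C, rt, "global")
  expect_equal(g$mean_abs_corr, 0.4, tolerance = 1e-12)
  expect_equal(g$n_pairs, 3)

  C2 <- C; C2["a.L", "a.R"] <- C2["a.R", "a.L"] <- -0.3
  lob <- connectivity_summary(C2, rt, "lobe:parietal")
  expect_equal(lob$mean_abs_corr, 0.3, tolerance = 1e-12)
  expect_equal(lob$n_pairs, 1)
  hom <- connectivity_summary(C2, rt, "homologous")
  expect_equal(hom$mean_abs_corr, 0.3, tolerance = 1e-12)

  reg <- connectivity_summary(C2, rt, "region:m")
  expect_equal(reg$n_pairs, 2)
  expect_error(connectivity_summary(C, rt, "lobe:occipital"), "unresolvable|fewer")
  expect_error(connectivity_summary(C, rt, "region:zz"), "unresolvable")
})

test_that("top_connected_regions agrees with a brute-force ranking", {
  set.seed(10)
  rt <- small_regions(3)
  C <- fixed_corr(6, seed = 10)
  dimnames(C) <- list(rt$region_id, rt$region_id)
  diag(C) <- 0
  top <- top_connected_regions(C, rt, k = 6)
  brute <- vapply(1:6, function(i) {
    v <- pmin(abs(C[i, -i]), 1 - 1e-7)
    tanh(mean(atanh(v)))
  }, numeric(1))
  expect_identical(top$region_id, rt$region_id[order(-brute, rt$region_id)])
  expect_equal(top$mean_abs_corr, sort(brute, decreasing = TRUE),
               tolerance = 1e-12)

  # a region correlated 0.9 with all others ranks first
  C2 <- matrix(0.05, 6, 6, dimnames = dimnames(C))
  C2[1, ] <- C2[, 1] <- 0.9
  diag(C2) <- 0
  expect_identical(top_connected_regions(C2, rt, 1)$region_id, rt$region_id[1])
  expect_error(top_connected_regions(C2, rt, 0), ">= 1")
})

test_that("summaries are equivariant under region relabeling", {
  set.seed(11)
  rt <- small_regions(4)
  C <- quick_corr(50, rt, h = 0.3, seed = 11)
  perm <- sample(nrow(rt))
  rtp <- rt[perm, ]
  Cp <- C[perm, perm]
  for (scope in c("global", "homologous", "lobe:frontal"))
    expect_equal(connectivity_summary(Cp, rtp, scope)$mean_abs_corr,
                 connectivity_summary(C, rt, scope)$mean_abs_corr,
                 tolerance = 1e-12)
})
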