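#' Regress confounds out of the regional MT values
#'
#' Removes, within the analysis group, the modelled mean effects of age,
#' age^2, sex and the age-by-sex interaction from every region by ordinary
#' least squares on the shared 5-column design (intercept, age, age^2,
#' sex, age x sex). The residuals replace the raw values: only
#' fluctuations around the mean aging trajectory enter the covariance
#' analysis. Age is mean-centered within the group before squaring — a
#' purely numerical measure that leaves residuals unchanged. Sex is coded
#' F = 0, M = 1. A rank-deficient design (e.g. a single-sex group) drops
#' the collinear columns with a warning; the dropped set is recorded in
#' the result.
#'
#' @param myelin M x N MT matrix.
#' @param subjects aligned subject table.
#' @return An M x N residual matrix (class `residual_matrix`) with
#'   attributes `coefficients` (design coefficients per region) and
#'   `dropped_columns`.
#' @export
regress_out_confounds <- function(myelin, subjects) {
  validate_subject_table(subjects)
  stopifnot(is.matrix(myelin), nrow(myelin) == nrow(subjects))
  age_c <- subjects$age - mean(subjects$age)
  male <- as.numeric(subjects$sex == "M")
  X <- cbind(intercept = 1, age = age_c, age2 = age_c^2,
             sex = male, age_sex = age_c * male)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[-keep]
    warning("rank-deficient confound design; dropping column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (nrow(X) <= ncol(X))
    stop("need more subjects (", nrow(X), ") than design columns (", ncol(X), ")")
  fit <- lm.fit(X, myelin)
  res <- fit$residuals
  dimnames(res) <- dimnames(myelin)
  structure(res, class = c("residual_matrix", class(res)),
            coefficients = fit$coefficients, dropped_columns = dropped)
}

#' Polynomial fit of mean gray-matter MT versus age
#'
#' Fits the cohort's global MT — the unweighted mean over the N regional
#' means — against age with a polynomial of the given order (default 2,
#' the inverted-U model of lifespan myelination). Returns the coefficients
#' on the raw age scale (ascending powers), their t-test p-values, RSS and
#' the Gaussian-OLS AIC.
#'
#' @param myelin M x N MT matrix.
#' @param subjects aligned subject table.
#' @param order polynomial order (>= 1).
#' @return A `poly_fit` object; see [fit_trajectory()] for the fields.
#' @export
fit_global_age_model <- function(myelin, subjects, order = 2) {
  validate_subject_table(subjects)
  stopifnot(is.matrix(myelin), nrow(myelin) == nrow(subjects), order >= 1)
  global_mt <- rowMeans(myelin)
  poly_fit_xy(subjects$age, global_mt, order)
}

# Polynomial OLS on centered x; coefficients returned on the raw x scale.
poly_fit_xy <- function(x, y, order) {
  n <- length(x)
  if (n <= order + 1) stop("need more observations than coefficients")
  if (sd(x) == 0) stop("predictor is constant")
  m <- mean(x)
  xc <- x - m
  X <- outer(xc, 0:order, `^`)
  colnames(X) <- paste0("x", 0:order)
  fit <- stats::lm(y ~ 0 + X)
  cf <- unname(stats::coef(fit))
  if (anyNA(cf)) stop("collinear polynomial design (too few distinct x)")
  rss <- sum(stats::residuals(fit)^2)
  pval <- suppressWarnings(summary(fit)$coefficients[, "Pr(>|t|)"])
  structure(list(
    order = order,
    coefficients = shift_poly(cf, m),    # ascending powers of raw x
    coefficients_centered = cf,
    center = m,
    coef_pvalues = unname(pval),
    rss = rss,
    aic = aic_gaussian(n, rss, order, sd(y)),
    n = n
  ), class = "poly_fit")
}

# AIC for a Gaussian OLS polynomial fit: n ln(RSS/n) + 2 (k + 1), with
# k = order + 1 regression parameters. RSS is floored at the square of a
# relative residual of 1e-8 (times the response scale): fits that agree
# with the data to within double-precision rounding are treated as
# equally exact, so order selection on noise-free data cannot be driven
# by floating-point noise in the residuals.
aic_gaussian <- function(n, rss, order, scale = 1) {
  floor_rss <- n * (1e-8 * max(scale, .Machine$double.xmin))^2
  n * log(max(rss, floor_rss, .Machine$double.xmin) / n) + 2 * (order + 2)
}

# Re-express sum c_k (x - m)^k as ascending powers of x.
shift_poly <- function(cf, m) {
  ord <- length(cf) - 1
  out <- numeric(ord + 1)
  for (k in 0:ord) {
    j <- 0:k
    out[j + 1] <- out[j + 1] + cf[k + 1] * choose(k, j) * (-m)^(k - j)
  }
  names(out) <- paste0("x", 0:ord)
  out
}

#' Age at the vertex of a quadratic (or higher) polynomial fit
#'
#' For an order-2 fit returns `-b / (2c)`, the fitted myelination peak.
#'
#' @param fit a `poly_fit`.
#' @return Peak age in years.
#' @export
peak_age <- function(fit) {
  stopifnot(inherits(fit, "poly_fit"), fit$order >= 2)
  cf <- fit$coefficients
  -cf[2] / (2 * cf[3])
}

#' @export
print.poly_fit <- function(x, ...) {
  cat("Polynomial fit, order", x$order, "\n")
  cat("  coefficients (raw scale):", signif(x$coefficients, 5), "\n")
  cat("  RSS:", signif(x$rss, 5), " AIC:", signif(x$aic, 6), "\n")
  invisible(x)
}
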