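#' Bootstrap a network statistic over subjects
#'
#' Classical Efron bootstrap of the correlation matrix: each draw
#' resamples the M subjects with replacement (resample size = M),
#' recomputes the Pearson matrix from the resampled residual rows and
#' evaluates the statistic. The statistic may return a single scalar or a
#' named numeric vector (one resampling pass then serves every compared
#' attribute). A draw whose resample leaves some region with zero
#' variance is redrawn (at most 10 retries) and the event counted. The
#' stream is fully determined by `seed`.
#'
#' @param residuals M x N residual matrix from [regress_out_confounds()].
#' @param statistic `function(corr)` returning a scalar or named vector.
#' @param n_boot number of bootstrap samples (study default 2000).
#' @param seed integer seed for this statistic's stream.
#' @return A `boot_set`: `statistics` (n_boot x n_stat matrix),
#'   `n_boot`, `seed`, `n_redrawn`, `n_nonfinite`.
#' @export
bootstrap_statistics <- function(residuals, statistic, n_boot = 2000, seed = 1L) {
  stopifnot(is.matrix(residuals), nrow(residuals) >= 10, is.function(statistic),
            n_boot >= 1)
  M <- nrow(residuals)
  set.seed(seed)
  n_redrawn <- 0L
  draws <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    for (try in seq_len(11L)) {
      idx <- sample.int(M, M, replace = TRUE)
      x <- residuals[idx, , drop = FALSE]
      ok <- tryCatch({ corr <- pearson_matrix(x); TRUE },
                     error = function(e) FALSE)
      if (ok) break
      n_redrawn <- n_redrawn + 1L
      if (try == 11L) stop("zero-variance resample persisted after 10 retries")
    }
    draws[[b]] <- statistic(corr)
  }
  stats_mat <- do.call(rbind, draws)
  if (is.null(colnames(stats_mat)) && ncol(stats_mat) == 1)
    colnames(stats_mat) <- "statistic"
  structure(list(
    statistics = stats_mat,
    n_boot = n_boot,
    seed = seed,
    n_redrawn = n_redrawn,
    n_nonfinite = colSums(!is.finite(stats_mat))
  ), class = "boot_set")
}

boot_values <- function(boot, statistic = NULL) {
  stopifnot(inherits(boot, "boot_set"))
  m <- boot$statistics
  if (is.null(statistic)) {
    if (ncol(m) != 1)
      stop("boot_set holds several statistics; name one of: ",
           paste(colnames(m), collapse = ", "))
    statistic <- colnames(m)[1]
  }
  if (!statistic %in% colnames(m)) stop("unknown statistic: ", statistic)
  m[, statistic]
}

#' Bootstrap group difference with a bias-corrected percentile CI
#'
#' Builds the empirical distribution of group differences by subtracting
#' bootstrap samples of the two groups pairwise by bootstrap index
#' (statistically equivalent to independent pairing, as the groups are
#' resampled independently), then computes the 95% (or `1 - alpha`)
#' bias-corrected percentile interval: the bias term
#' `z0 = qnorm(P(diff < point estimate))` shifts the percentile bounds to
#' `pnorm(2 z0 + z_{alpha/2})` and `pnorm(2 z0 + z_{1-alpha/2})`. The
#' difference is significant when 0 lies outside the interval.
#'
#' @param bootA,bootB `boot_set`s of equal `n_boot`.
#' @param pointA,pointB full-sample statistic values (A minus B is the
#'   point estimate).
#' @param alpha significance level.
#' @param statistic column name when the boot sets hold several
#'   statistics.
#' @return A `group_diff`: `statistic`, `point_estimate`,
#'   `ci_low`, `ci_high`, `significant`, `z0`, `alpha`, `n_boot`,
#'   `n_dropped`, `diff_distribution`.
#' @export
group_difference <- function(bootA, bootB, pointA, pointB,
                             alpha = 0.05, statistic = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  a <- boot_values(bootA, statistic)
  b <- boot_values(bootB, statistic)
  if (length(a) != length(b))
    stop("bootstrap sets must have equal n_boot")
  diffs <- a - b
  keep <- is.finite(diffs)
  n_dropped <- sum(!keep)
  diffs <- diffs[keep]
  if (!length(diffs)) stop("no finite bootstrap differences")
  point <- pointA - pointB
  if (diff(range(diffs)) == 0)
    stop("degenerate difference distribution: all bootstrap differences equal")
  p0 <- mean(diffs < point)
  nb <- length(diffs)
  if (p0 <= 0 || p0 >= 1) {
    warning("bias-correction proportion at boundary; clamping z0")
    p0 <- min(max(p0, 1 / (2 * nb)), 1 - 1 / (2 * nb))
  }
  z0 <- qnorm(p0)
  probs <- pnorm(2 * z0 + qnorm(c(alpha / 2, 1 - alpha / 2)))
  # empirical quantiles by the (B+1)p order-statistic convention of the
  # bootstrap literature (quantile type 6); the default type 7 is
  # anti-conservative in the tails at moderate B
  ci <- unname(quantile(diffs, probs, type = 6))
  structure(list(
    statistic = statistic %||% colnames(bootA$statistics)[1],
    point_estimate = point,
    ci_low = ci[1],
    ci_high = ci[2],
    significant = ci[1] > 0 || ci[2] < 0,
    z0 = z0,
    alpha = alpha,
    n_boot = length(a),
    n_dropped = n_dropped,
    diff_distribution = diffs
  ), class = "group_diff")
}

#' @export
print.group_diff <- function(x, ...) {
  cat(sprintf("Group difference [%s]: %.4g, %d%% BC CI [%.4g, %.4g] %s\n",
              x$statistic, x$point_estimate, round(100 * (1 - x$alpha)),
              x$ci_low, x$ci_high,
              if (x$significant) "(significant)" else "(n.s.)"))
  invisible(x)
}
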