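#' Interregional Pearson correlation matrix
#'
#' Computes the N x N matrix of Pearson correlations between region
#' columns across subjects — the myelin covariance network in its weighted
#' form. Self-connections are excluded: the diagonal is forced to exactly
#' 0. A region with (numerically) zero variance makes the coefficient
#' undefined and raises an error naming the region.
#'
#' @param residuals M x N residual (or raw) matrix with region column
#'   names; typically the output of [regress_out_confounds()].
#' @return Symmetric N x N correlation matrix, zero diagonal.
#' @export
pearson_matrix <- function(residuals) {
  stopifnot(is.matrix(residuals), nrow(residuals) >= 3)
  sds <- apply(residuals, 2, sd)
  scale <- apply(abs(residuals), 2, max)
  bad <- sds <= 1e-12 * (scale + 1)
  if (any(bad))
    stop("zero-variance region(s): ",
         paste(colnames(residuals)[bad] %||% which(bad), collapse = ", "))
  C <- cor(residuals)
  C <- (C + t(C)) / 2
  diag(C) <- 0
  C
}

#' Fisher-pooled mean of absolute correlations
#'
#' Pools correlation magnitudes by transforming `|r|` to z with Fisher's
#' r-to-z (atanh), averaging, and transforming back (tanh). Magnitudes at
#' or above `1 - 1e-7` are clamped to that value before atanh to avoid
#' infinities; the number of clamped entries is attached as attribute
#' `n_clamped`.
#'
#' @param values correlations in `[-1, 1]`; signs are discarded.
#' @return The pooled mean magnitude, in `[0, 1]`.
#' @examples
#' fisher_mean_abs(c(0.5, -0.5))  # 0.5
#' @export
fisher_mean_abs <- function(values) {
  if (!length(values)) stop("empty correlation list")
  if (any(!is.finite(values)) || any(abs(values) > 1 + 1e-12))
    stop("correlations must be finite and in [-1, 1]")
  a <- abs(values)
  n_clamped <- sum(a >= 1 - 1e-7)
  a <- pmin(a, 1 - 1e-7)
  structure(tanh(mean(atanh(a))), n_clamped = n_clamped)
}

#' Connectivity summary over a pair scope
#'
#' Summarizes the magnitude of myelin covariance over a chosen set of
#' region pairs: `"global"` (all N(N-1)/2 pairs), `"homologous"` (the
#' left-right mirror-pair diagonal), `"lobe:<name>"` (all within-lobe
#' pairs, both hemispheres pooled) or `"region:<id>"` (that region's
#' N-1 pairs). The primary estimate is the Fisher-pooled mean of `|r|`;
#' the raw arithmetic mean is reported alongside.
#'
#' @param corr correlation matrix from [pearson_matrix()].
#' @param regions region table aligned with `corr`.
#' @param scope scope selector string.
#' @return A `connectivity_summary` list: `scope`, `mean_abs_corr`
#'   (Fisher-pooled), `mean_abs_corr_raw`, `n_pairs`.
#' @export
connectivity_summary <- function(corr, regions, scope = "global") {
  validate_correlation_matrix(corr)
  validate_region_table(regions)
  stopifnot(nrow(corr) == nrow(regions))
  vals <- scope_values(corr, regions, scope)
  structure(list(
    scope = scope,
    mean_abs_corr = as.numeric(fisher_mean_abs(vals)),
    mean_abs_corr_raw = mean(abs(vals)),
    n_pairs = length(vals)
  ), class = "connectivity_summary")
}

scope_values <- function(corr, regions, scope) {
  if (scope == "global")
    return(corr[upper.tri(corr)])
  if (scope == "homologous") {
    pairs <- homologous_pairs(regions)
    if (!nrow(pairs)) stop("no homologous pairs in region table")
    return(corr[pairs])
  }
  if (startsWith(scope, "lobe:")) {
    lobe <- sub("^lobe:", "", scope)
    if (!lobe %in% regions$lobe) stop("unresolvable scope: ", scope)
    idx <- which(regions$lobe == lobe)
    if (length(idx) < 2) stop("lobe '", lobe, "' has fewer than 2 regions")
    sub <- corr[idx, idx, drop = FALSE]
    return(sub[upper.tri(sub)])
  }
  if (startsWith(scope, "region:")) {
    id <- sub("^region:", "", scope)
    i <- match(id, regions$region_id)
    if (is.na(i)) stop("unresolvable scope: ", scope)
    return(corr[i, -i])
  }
  stop("unresolvable scope: ", scope)
}

#' Regions with the strongest mean interregional covariance
#'
#' Ranks regions by the Fisher-pooled mean `|r|` of their N-1 pairs,
#' descending; ties are broken by region id. The top rows of the ranking
#' are the "most connected" structures of the network.
#'
#' @param corr correlation matrix.
#' @param regions aligned region table.
#' @param k number of regions to return (`1..N`).
#' @return `data.frame` with `region_id`, `name`, `mean_abs_corr`.
#' @export
top_connected_regions <- function(corr, regions, k = 15) {
  validate_correlation_matrix(corr)
  stopifnot(nrow(corr) == nrow(regions))
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(regions)) stop("k exceeds the number of regions")
  per <- vapply(seq_len(nrow(corr)), function(i)
    as.numeric(fisher_mean_abs(corr[i, -i])), numeric(1))
  o <- order(-per, regions$region_id)[seq_len(k)]
  data.frame(region_id = regions$region_id[o],
             name = regions$name[o],
             mean_abs_corr = per[o],
             stringsAsFactors = FALSE)
}
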