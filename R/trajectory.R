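#' Fixed-size sliding windows over the age-ordered cohort
#'
#' Subjects are sorted by age (ties by subject id) and grouped into
#' overlapping windows of constant size: window t holds age ranks
#' `t .. t + window_size - 1`, so contiguous windows differ by exactly
#' one subject (the youngest is replaced by the nearest older
#' participant). The window "age" is the median age of its members.
#' Keeping the subject count constant keeps the correlation matrices
#' across windows unbiased by sample size; the default 73 matches the
#' young-group size of the two-group design.
#'
#' @param subjects subject table.
#' @param window_size subjects per window.
#' @return A `window_set`: `indices` (list of row-index vectors into
#'   `subjects`), `window_ages` (median ages), `window_size`.
#' @export
build_windows <- function(subjects, window_size = 73) {
  validate_subject_table(subjects)
  M <- nrow(subjects)
  if (window_size > M) stop("window_size (", window_size,
                            ") exceeds the cohort size (", M, ")")
  stopifnot(window_size >= 2)
  o <- order(subjects$age, subjects$subject_id)
  n_win <- M - window_size + 1
  idx <- lapply(seq_len(n_win), function(t) o[t:(t + window_size - 1)])
  ages <- vapply(idx, function(i) median(subjects$age[i]), numeric(1))
  structure(list(indices = idx, window_ages = ages,
                 window_size = as.integer(window_size)),
            class = "window_set")
}

#' Property series over sliding windows
#'
#' For every window the analysis of the two-group design is repeated
#' without bootstrapping: confounds are regressed out within the window,
#' the Pearson matrix computed, and the requested property evaluated.
#' Properties `"clustering"`, `"path_length"`, `"global_efficiency"`,
#' `"local_efficiency"` and `"robustness"` are AUCs over the sparsity
#' grid; `"global_connectivity"` and `"homologous_connectivity"` are
#' Fisher-pooled mean `|r|`; `"nbc"` is the NBC of `region` (AUC over the
#' grid, or the value at `nbc_sparsity` if given). Windows with a
#' rank-deficient confound design fall back on the reduced design
#' (see [regress_out_confounds()]); their count is recorded.
#'
#' @param myelin M x N MT matrix.
#' @param subjects aligned subject table.
#' @param windows a `window_set` from [build_windows()].
#' @param property property selector (see above).
#' @param regions region table (needed for connectivity and nbc).
#' @param grid sparsity grid.
#' @param region region id for `property = "nbc"`.
#' @param nbc_sparsity single sparsity for `"nbc"`; `NULL` = AUC.
#' @return A `window_series`: `window_ages`, `values`, `property`,
#'   `window_size`, `n_reduced_design`.
#' @export
window_property_series <- function(myelin, subjects, windows, property,
                                   regions = NULL, grid = sparsity_grid(),
                                   region = NULL, nbc_sparsity = NULL) {
  stopifnot(inherits(windows, "window_set"), is.matrix(myelin),
            nrow(myelin) == nrow(subjects))
  auc_props <- c(clustering = "C", path_length = "L",
                 global_efficiency = "Eglob", local_efficiency = "Eloc")
  known <- c(names(auc_props), "robustness", "global_connectivity",
             "homologous_connectivity", "nbc")
  if (!property %in% known)
    stop("unknown property: ", property)
  if (property %in% c("global_connectivity", "homologous_connectivity", "nbc") &&
      is.null(regions))
    stop("property '", property, "' needs the region table")
  if (property == "nbc") {
    if (is.null(region)) stop("property 'nbc' needs a region id")
    ri <- match(region, regions$region_id)
    if (is.na(ri)) stop("unknown region: ", region)
  }

  n_reduced <- 0L
  values <- vapply(windows$indices, function(ix) {
    res <- withCallingHandlers(
      regress_out_confounds(myelin[ix, , drop = FALSE], subjects[ix, , drop = FALSE]),
      warning = function(w) {
        if (grepl("rank-deficient", conditionMessage(w))) {
          n_reduced <<- n_reduced + 1L
          invokeRestart("muffleWarning")
        }
      })
    corr <- pearson_matrix(res)
    if (property %in% names(auc_props)) {
      key <- auc_props[[property]]
      property_curves(corr, grid)[[key]]$auc
    } else if (property == "robustness") {
      robustness_over_grid(corr, grid)$auc
    } else if (property == "global_connectivity") {
      connectivity_summary(corr, regions, "global")$mean_abs_corr
    } else if (property == "homologous_connectivity") {
      connectivity_summary(corr, regions, "homologous")$mean_abs_corr
    } else {
      if (is.null(nbc_sparsity)) {
        nbc <- vapply(threshold_series(corr, grid),
                      function(g) betweenness_centrality(g)$nbc[ri], numeric(1))
        auc_trapezoid(grid, nbc)
      } else {
        betweenness_centrality(threshold_at_sparsity(corr, nbc_sparsity))$nbc[ri]
      }
    }
  }, numeric(1))

  structure(list(window_ages = windows$window_ages, values = values,
                 property = property, window_size = windows$window_size,
                 n_reduced_design = n_reduced),
            class = "window_series")
}

#' Polynomial fit of an aging trajectory with AIC order selection
#'
#' Fits OLS polynomials of order 1..`max_order` to the property values
#' versus window age and selects the order by AIC
#' (`n ln(RSS/n) + 2(k+1)`, `k = order + 1` coefficients). The default
#' `"parsimony"` rule returns the lowest order whose AIC lies within 2
#' units of the minimum — the conventional margin within which models are
#' considered equivalently supported — which protects against the
#' well-known tendency of the raw AIC minimum to prefer spuriously
#' complex polynomials; `"min"` returns the exact argmin. Coefficient
#' significance is assessed by the usual t-tests.
#'
#' @param series a `window_series` (or any list with `window_ages` and
#'   `values`).
#' @param max_order largest candidate order (default 6).
#' @param select `"parsimony"` (lowest order with AIC within 2 of the
#'   minimum) or `"min"` (argmin AIC).
#' @return The selected `poly_fit`, with an extra field `aic_table`
#'   (order, rss, aic for every candidate).
#' @export
fit_trajectory <- function(series, max_order = 6, select = c("parsimony", "min")) {
  select <- match.arg(select)
  x <- series$window_ages
  y <- series$values
  stopifnot(length(x) == length(y))
  if (length(x) <= max_order + 1)
    stop("need more windows (", length(x), ") than max_order + 1")
  fits <- lapply(seq_len(max_order), function(k) poly_fit_xy(x, y, k))
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  pick <- if (select == "min") which.min(aics)
          else min(which(aics - min(aics) <= 2))
  fit <- fits[[pick]]
  fit$aic_table <- data.frame(order = seq_len(max_order),
                              rss = vapply(fits, `[[`, numeric(1), "rss"),
                              aic = aics)
  fit$selection <- select
  fit
}
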