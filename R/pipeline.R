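#' Pipeline configuration
#'
#' Bundles and validates every tunable of the two headline experiments
#' (two-group comparison, aging trajectory). Data enter either as file
#' paths to the three canonical tables (`data`) or as synthetic cohort
#' configurations (`simulate`).
#'
#' @param simulate for [run_group_comparison()]: a named list of two
#'   [cohort_config()]s sharing a region table; for [run_trajectory()]: a
#'   single [cohort_config()]. `NULL` when reading from files.
#' @param data `list(matrix, subjects, regions)` of file paths, or `NULL`.
#' @param groups for file input to the group comparison: a named list of
#'   two inclusive age bands, e.g. `list(young = c(20, 31), old = c(60, 71))`.
#' @param grid sparsity grid (>= 2 points).
#' @param n_boot bootstrap samples per group (>= 50; study default 2000).
#' @param alpha significance level of the BC percentile test.
#' @param hub_threshold NBC cutoff defining hubs.
#' @param top_k size of the most-connected-regions table.
#' @param include_nbc also bootstrap per-region NBC AUCs in the group
#'   comparison (adds N statistics).
#' @param window_size sliding-window size for the trajectory study.
#' @param max_poly_order largest candidate polynomial order.
#' @param properties trajectory properties to trace.
#' @param nbc_regions region ids whose NBC trajectory is traced.
#' @param seed master seed; all resampling streams are derived from it.
#' @param output_dir directory for reports and matrices, or `NULL` to
#'   only return the report.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, data = NULL, groups = NULL,
                            grid = sparsity_grid(), n_boot = 2000,
                            alpha = 0.05, hub_threshold = 1.5, top_k = 15,
                            include_nbc = FALSE,
                            window_size = 73, max_poly_order = 6,
                            properties = c("clustering", "path_length",
                                           "global_efficiency", "local_efficiency",
                                           "global_connectivity",
                                           "homologous_connectivity"),
                            nbc_regions = character(0),
                            seed = 1L, output_dir = NULL) {
  validate_sparsity_grid(grid)
  if (length(grid) < 2) stop("sparsity grid must have at least 2 points")
  stopifnot(n_boot >= 50, alpha > 0, alpha < 1, hub_threshold > 0,
            top_k >= 1, window_size >= 2, max_poly_order >= 1)
  if (is.null(simulate) && is.null(data))
    stop("provide either `simulate` configs or `data` paths")
  structure(list(simulate = simulate, data = data, groups = groups,
                 grid = grid, n_boot = as.integer(n_boot), alpha = alpha,
                 hub_threshold = hub_threshold, top_k = as.integer(top_k),
                 include_nbc = isTRUE(include_nbc),
                 window_size = as.integer(window_size),
                 max_poly_order = as.integer(max_poly_order),
                 properties = properties, nbc_regions = nbc_regions,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' sparsity grid is given as `grid: {lo, hi, step}` and simulated cohorts
#' as named lists of [cohort_config()] arguments (their shared region
#' table is built with [synthetic_region_table()] unless a `regions`
#' path is given).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(raw$grid) && is.list(raw$grid))
    raw$grid <- sparsity_grid(raw$grid$lo %||% 0.5, raw$grid$hi %||% 0.9,
                              raw$grid$step %||% 0.02)
  if (!is.null(raw$simulate)) {
    rt <- if (!is.null(raw$regions)) {
      df <- read.delim(raw$regions, colClasses = "character", na.strings = NULL)
      df$homologue_id[is.na(df$homologue_id)] <- ""
      validate_region_table(df)
      df
    } else synthetic_region_table()
    build <- function(args) {
      args$region_table <- rt
      args$age_range <- as.numeric(args$age_range)
      do.call(cohort_config, args)
    }
    raw$simulate <- if (!is.null(raw$simulate$n_subjects)) build(raw$simulate)
                    else lapply(raw$simulate, build)
    raw$regions <- NULL
  }
  if (!is.null(raw$groups)) raw$groups <- lapply(raw$groups, as.numeric)
  do.call(pipeline_config, raw)
}

# Resolve the two (myelin, subjects) groups + shared region table.
resolve_groups <- function(config) {
  if (!is.null(config$simulate)) {
    stopifnot(length(config$simulate) == 2, !is.null(names(config$simulate)))
    fx <- make_two_group_fixture(config$simulate[[1]], config$simulate[[2]])
    gs <- list(fx[[1]][c("subjects", "myelin")], fx[[2]][c("subjects", "myelin")])
    names(gs) <- names(config$simulate)
    list(groups = gs, regions = fx$regions)
  } else {
    stopifnot(!is.null(config$groups), length(config$groups) == 2)
    ds <- read_myelin_dataset(config$data$matrix, config$data$subjects,
                              config$data$regions)
    gs <- lapply(config$groups, function(band) {
      keep <- ds$subjects$age >= band[1] & ds$subjects$age <= band[2]
      if (sum(keep) < 10) stop("age band [", band[1], ", ", band[2],
                               "] selects fewer than 10 subjects")
      list(subjects = ds$subjects[keep, , drop = FALSE],
           myelin = ds$myelin[keep, , drop = FALSE])
    })
    list(groups = gs, regions = ds$regions)
  }
}

detrend_logged <- function(myelin, subjects) {
  dropped <- character(0)
  res <- withCallingHandlers(
    regress_out_confounds(myelin, subjects),
    warning = function(w) {
      if (grepl("rank-deficient", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(residuals = res, dropped = attr(res, "dropped_columns"))
}

#' Two-group myelin covariance network comparison
#'
#' The first headline experiment: for each group, confounds are regressed
#' out, the Pearson matrix built, the network attributes (AUCs over the
#' sparsity grid), connectivity summaries, targeted-attack robustness and
#' (optionally) per-region NBC AUCs are bootstrapped over subjects, and
#' every statistic is compared between groups with the bias-corrected
#' percentile test. Per-group hub tables (grid-mean NBC above the hub
#' threshold) and most-connected-region tables are included.
#'
#' @param config a [pipeline_config()] with two groups.
#' @return The report (a nested list, also written to
#'   `config$output_dir` when set): `config` echo, per-`groups` summaries
#'   and tables, `comparisons` (one [group_difference()] record per
#'   statistic).
#' @export
run_group_comparison <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rg <- resolve_groups(config)
  regions <- rg$regions
  grid <- config$grid
  include <- c("auc", "robustness", "connectivity",
               if (config$include_nbc) "nbc")
  stat_fun <- function(corr) network_statistics(corr, regions, grid, include)
  width <- max(grid) - min(grid)

  per_group <- lapply(names(rg$groups), function(gname) {
    g <- rg$groups[[gname]]
    det <- detrend_logged(g$myelin, g$subjects)
    corr <- pearson_matrix(det$residuals)
    point <- stat_fun(corr)
    nbc_auc <- network_statistics(corr, regions, grid, "nbc")
    mean_nbc <- data.frame(region_id = regions$region_id,
                           name = regions$name,
                           nbc = unname(nbc_auc) / width,
                           stringsAsFactors = FALSE)
    hubs <- identify_hubs(mean_nbc, config$hub_threshold)
    boot <- bootstrap_statistics(det$residuals, stat_fun, config$n_boot,
                                 derive_seed(config$seed, paste0("group:", gname)))
    list(name = gname, n_subjects = nrow(g$subjects),
         dropped_design_columns = det$dropped,
         corr = corr, point = point, boot = boot,
         top_connected = top_connected_regions(corr, regions,
                                               min(config$top_k, nrow(regions))),
         hubs = hubs)
  })
  names(per_group) <- names(rg$groups)

  stat_names <- colnames(per_group[[1]]$boot$statistics)
  comparisons <- lapply(stat_names, function(s) {
    gd <- group_difference(per_group[[1]]$boot, per_group[[2]]$boot,
                           per_group[[1]]$point[[s]], per_group[[2]]$point[[s]],
                           config$alpha, s)
    gd$diff_distribution <- NULL        # keep the report compact
    unclass(gd)
  })
  names(comparisons) <- stat_names

  report <- list(
    analysis = "group_comparison",
    config = config_echo(config),
    groups = lapply(per_group, function(g)
      list(name = g$name, n_subjects = g$n_subjects,
           dropped_design_columns = as.list(g$dropped_design_columns),
           statistics = as.list(g$point),
           bootstrap = list(n_boot = g$boot$n_boot, seed = g$boot$seed,
                            n_redrawn = g$boot$n_redrawn),
           top_connected = g$top_connected,
           hubs = g$hubs)),
    comparisons = comparisons
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (g in per_group)
      write_symmetric_matrix(g$corr, file.path(config$output_dir,
                                               paste0("corr_", g$name, ".tsv")))
    write_report(report, file.path(config$output_dir, "group_comparison.json"))
  }
  report
}

#' Sliding-window aging trajectory of network attributes
#'
#' The second headline experiment: windows of constant size slide one
#' subject at a time over the age-ordered cohort; within each window the
#' full (bootstrap-free) network analysis is repeated, and each property
#' series is fitted with an AIC-selected polynomial of the window age.
#'
#' @param config a [pipeline_config()] whose `simulate` is a single
#'   [cohort_config()] (or whose `data` paths hold the cohort).
#' @return The report: `config` echo, per-property `series`
#'   (window ages, values) and `fit` (selected order, raw-scale
#'   coefficients, p-values, AIC table).
#' @export
run_trajectory <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulate)) {
    stopifnot(inherits(config$simulate, "cohort_config"))
    coh <- generate_cohort(config$simulate)
    subjects <- coh$subjects; myelin <- coh$myelin
    regions <- config$simulate$region_table
  } else {
    ds <- read_myelin_dataset(config$data$matrix, config$data$subjects,
                              config$data$regions)
    subjects <- ds$subjects; myelin <- ds$myelin; regions <- ds$regions
  }
  if (nrow(subjects) <= config$window_size)
    stop("cohort (", nrow(subjects), ") not larger than window_size (",
         config$window_size, ")")
  windows <- build_windows(subjects, config$window_size)

  trace_one <- function(property, region = NULL) {
    series <- window_property_series(myelin, subjects, windows, property,
                                     regions = regions, grid = config$grid,
                                     region = region)
    fit <- fit_trajectory(series, config$max_poly_order)
    list(property = if (is.null(region)) property else paste0("nbc:", region),
         series = list(window_ages = series$window_ages,
                       values = series$values,
                       n_reduced_design = series$n_reduced_design),
         fit = list(order = fit$order,
                    coefficients = as.list(fit$coefficients),
                    coef_pvalues = fit$coef_pvalues,
                    rss = fit$rss, aic = fit$aic,
                    selection = fit$selection,
                    aic_table = fit$aic_table))
  }
  traces <- c(lapply(config$properties, trace_one),
              lapply(config$nbc_regions, function(r) trace_one("nbc", r)))
  names(traces) <- vapply(traces, `[[`, character(1), "property")

  report <- list(
    analysis = "trajectory",
    config = config_echo(config),
    n_subjects = nrow(subjects),
    n_windows = length(windows$indices),
    window_size = windows$window_size,
    properties = traces
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (tr in traces) {
      fn <- file.path(config$output_dir,
                      paste0("series_", gsub("[^A-Za-z0-9._-]", "_", tr$property), ".tsv"))
      write.table(data.frame(window_age = tr$series$window_ages,
                             value = tr$series$values),
                  fn, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_report(report, file.path(config$output_dir, "trajectory.json"))
  }
  report
}

config_echo <- function(config) {
  list(
    grid = list(lo = min(config$grid), hi = max(config$grid),
                n_points = length(config$grid)),
    n_boot = config$n_boot, alpha = config$alpha,
    hub_threshold = config$hub_threshold, top_k = config$top_k,
    include_nbc = config$include_nbc,
    window_size = config$window_size, max_poly_order = config$max_poly_order,
    seed = config$seed,
    sex_coding = "F=0, M=1",
    simulated = !is.null(config$simulate)
  )
}
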