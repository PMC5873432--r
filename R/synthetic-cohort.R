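#' Synthetic atlas-like region table
#'
#' Builds a parcellation metadata table with the dimensionality of a
#' whole-brain gray-matter atlas without shipping any atlas file: paired
#' left/right structures distributed over the seven lobe groups plus a few
#' midline structures. The default (56 homologous pairs + 2 midline = 114
#' regions) matches the dimensionality used throughout the package's
#' examples. All ids and names are synthetic.
#'
#' @param n_pairs number of homologous L/R pairs.
#' @param n_midline number of unpaired midline structures.
#' @return A validated region table of `2 * n_pairs + n_midline` rows.
#' @export
synthetic_region_table <- function(n_pairs = 56, n_midline = 2) {
  stopifnot(n_pairs >= 1, n_midline >= 0)
  # lobe sizes loosely proportional to a whole-brain parcellation,
  # scaled to n_pairs by largest-remainder allocation
  quota <- c(frontal = 16, parietal = 8, temporal = 10, occipital = 8,
             limbic = 6, insula = 2, subcortical = 6)
  share <- quota / sum(quota) * n_pairs
  counts <- floor(share)
  short <- n_pairs - sum(counts)
  if (short > 0) {
    bump <- order(share - counts, decreasing = TRUE)[seq_len(short)]
    counts[bump] <- counts[bump] + 1
  }
  lobes <- rep(names(quota), counts)
  base <- sprintf("roi%03d", seq_len(n_pairs))
  ids <- c(rbind(paste0(base, ".L"), paste0(base, ".R")))
  hom <- c(rbind(paste0(base, ".R"), paste0(base, ".L")))
  df <- data.frame(
    region_id = ids,
    name = paste(rep(lobes, each = 2), "structure", rep(seq_len(n_pairs), each = 2),
                 rep(c("left", "right"), n_pairs)),
    hemisphere = rep(c("L", "R"), n_pairs),
    lobe = rep(lobes, each = 2),
    homologue_id = hom,
    stringsAsFactors = FALSE
  )
  if (n_midline > 0) {
    df <- rbind(df, data.frame(
      region_id = sprintf("mid%02d", seq_len(n_midline)),
      name = paste("midline structure", seq_len(n_midline)),
      hemisphere = "midline",
      lobe = "limbic",
      homologue_id = "",
      stringsAsFactors = FALSE
    ))
  }
  validate_region_table(df)
  df
}

#' Configuration of a synthetic MT cohort
#'
#' Describes the generative model of [generate_cohort()]: uniform ages,
#' region-wise concave quadratic mean MT trajectories peaking in mid-life,
#' additive sex effects, and a latent-factor residual structure (one
#' shared factor per homologous pair and one per lobe, plus independent
#' noise) that plants a known correlation between every region pair. MT is
#' expressed in percent units (p.u.), the scale of semi-quantitative MT
#' saturation maps.
#'
#' @param n_subjects number of subjects.
#' @param age_range `c(lo, hi)` years; ages are drawn uniformly.
#' @param female_fraction fraction of female subjects (count rounded).
#' @param region_table region metadata (default [synthetic_region_table()]).
#' @param peak_age per-region myelination peak in years: a scalar, a
#'   vector of length N, or `NULL` to draw each peak uniformly in
#'   `peak_age_range`.
#' @param peak_age_range range from which unset peaks are drawn
#'   (default `c(40, 50)`, the mid-life myelination peak window).
#' @param baseline_mt mean MT at the peak, p.u.
#' @param region_baseline_sd between-region SD of baseline MT, p.u.
#' @param quadratic_curvature concavity of the age trajectory,
#'   p.u. / year^2 (the mean falls by `curvature * (age - peak)^2`).
#' @param sex_effect additive male-minus-female offset, p.u.
#' @param age_sex_effect age-by-sex interaction slope, p.u. / year.
#' @param homologous_coupling planted correlation between homologous
#'   pair members, in `[0, 1)`.
#' @param homologous_coupling_slope optional linear drift of the
#'   homologous coupling with age (per year, centered on the midpoint of
#'   `age_range`); lets trajectory tests plant an age-varying coupling.
#' @param lobe_coupling planted within-lobe correlation: a scalar or a
#'   named vector over lobes, in `[0, 1)`.
#' @param noise_sd SD of the total residual around the mean trajectory,
#'   p.u.; must be > 0.
#' @param seed integer RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects,
                          age_range = c(18, 87),
                          female_fraction = 0.5,
                          region_table = synthetic_region_table(),
                          peak_age = NULL,
                          peak_age_range = c(40, 50),
                          baseline_mt = 1.8,
                          region_baseline_sd = 0.05,
                          quadratic_curvature = 1e-4,
                          sex_effect = 0.02,
                          age_sex_effect = 0,
                          homologous_coupling = 0,
                          homologous_coupling_slope = 0,
                          lobe_coupling = 0,
                          noise_sd = 0.05,
                          seed = 1L) {
  validate_region_table(region_table)
  stopifnot(n_subjects >= 4, length(age_range) == 2, age_range[1] < age_range[2],
            female_fraction >= 0, female_fraction <= 1,
            quadratic_curvature >= 0)
  if (!is.null(peak_age))
    stopifnot(length(peak_age) %in% c(1L, nrow(region_table)))
  if (noise_sd <= 0)
    stop("degenerate config: noise_sd must be > 0 (otherwise detrended ",
         "residuals vanish and the correlation matrix is undefined)")
  lobe_l <- lobe_coupling_vector(lobe_coupling)
  # couplings at the extremes of the age range must leave non-negative
  # independent-noise variance, i.e. the implied covariance must be PSD
  h_ends <- homologous_coupling + homologous_coupling_slope *
    (age_range - mean(age_range))
  if (any(h_ends < 0) || any(h_ends >= 1))
    stop("homologous coupling leaves [0, 1) within age_range")
  lmax <- max(lobe_l)
  if (any(h_ends + lmax > 1) || lmax >= 1)
    stop("implied covariance is not positive semi-definite: ",
         "homologous + lobe coupling exceeds 1")
  structure(list(
    n_subjects = as.integer(n_subjects), age_range = age_range,
    female_fraction = female_fraction, region_table = region_table,
    peak_age = peak_age, peak_age_range = peak_age_range,
    baseline_mt = baseline_mt, region_baseline_sd = region_baseline_sd,
    quadratic_curvature = quadratic_curvature, sex_effect = sex_effect,
    age_sex_effect = age_sex_effect,
    homologous_coupling = homologous_coupling,
    homologous_coupling_slope = homologous_coupling_slope,
    lobe_coupling = lobe_l, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "cohort_config")
}

lobe_coupling_vector <- function(lobe_coupling) {
  if (length(lobe_coupling) == 1 && is.null(names(lobe_coupling)))
    lobe_coupling <- setNames(rep(as.numeric(lobe_coupling), length(.lobes)), .lobes)
  stopifnot(all(names(lobe_coupling) %in% .lobes),
            all(lobe_coupling >= 0), all(lobe_coupling < 1))
  full <- setNames(numeric(length(.lobes)), .lobes)
  full[names(lobe_coupling)] <- lobe_coupling
  full
}

#' Generate a synthetic MT cohort with planted covariance structure
#'
#' Draws subjects and an MT matrix from the model described in
#' [cohort_config()]. Each region's mean follows a concave quadratic in
#' age peaking at its `peak_age`; residuals share one unit-variance latent
#' factor per homologous pair (loading `sqrt(homologous_coupling)`) and
#' one per lobe (loading `sqrt(lobe_coupling)`), plus independent Gaussian
#' noise scaled so each region's residual variance is `noise_sd^2`. The
#' planted correlation between two regions is therefore the sum of their
#' shared squared loadings: `homologous + lobe` coupling for a homologous
#' pair, the lobe coupling for two same-lobe regions, 0 otherwise.
#'
#' @param config a [cohort_config()].
#' @return A list with `subjects`, `myelin` (M x N matrix) and
#'   `ground_truth` (planted correlation matrix, per-region peaks,
#'   per-subject homologous coupling, seed echo).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  regions <- config$region_table
  N <- nrow(regions)
  M <- config$n_subjects
  set.seed(config$seed)

  age <- runif(M, config$age_range[1], config$age_range[2])
  n_f <- round(config$female_fraction * M)
  sex <- sample(c(rep("F", n_f), rep("M", M - n_f)))
  subjects <- subject_table(sprintf("sub%04d", seq_len(M)), age, sex)

  peaks <- config$peak_age
  if (is.null(peaks))
    peaks <- runif(N, config$peak_age_range[1], config$peak_age_range[2])
  peaks <- rep_len(peaks, N)
  baseline <- config$baseline_mt + rnorm(N, 0, config$region_baseline_sd)

  male <- as.numeric(sex == "M")
  age_c <- age - mean(config$age_range)
  mean_mt <- outer(age, peaks, function(a, p) -config$quadratic_curvature * (a - p)^2)
  mean_mt <- sweep(mean_mt, 2, baseline, `+`) +
    config$sex_effect * male + config$age_sex_effect * age_c * male

  # latent-factor residual structure
  pairs <- homologous_pairs(regions)
  pair_of <- integer(N)                      # 0 = unpaired
  if (nrow(pairs)) {
    pair_of[pairs[, 1]] <- seq_len(nrow(pairs))
    pair_of[pairs[, 2]] <- seq_len(nrow(pairs))
  }
  lobe_of <- match(regions$lobe, .lobes)
  h_subj <- config$homologous_coupling +
    config$homologous_coupling_slope * age_c   # per-subject pair coupling
  l_reg <- config$lobe_coupling[lobe_of]       # per-region lobe coupling

  F_pair <- matrix(rnorm(M * max(1, nrow(pairs))), M)
  F_lobe <- matrix(rnorm(M * length(.lobes)), M)
  Z <- matrix(rnorm(M * N), M)

  E <- matrix(0, M, N)
  for (j in seq_len(N)) {
    h_j <- if (pair_of[j] > 0) h_subj else numeric(M)
    nl <- sqrt(pmax(0, 1 - h_j - l_reg[j]))
    E[, j] <- (if (pair_of[j] > 0) sqrt(h_j) * F_pair[, pair_of[j]] else 0) +
      sqrt(l_reg[j]) * F_lobe[, lobe_of[j]] + nl * Z[, j]
  }
  myelin <- mean_mt + config$noise_sd * E
  dimnames(myelin) <- list(subjects$subject_id, regions$region_id)

  # planted correlation between every region pair
  h_bar <- mean(h_subj)
  planted <- matrix(0, N, N, dimnames = list(regions$region_id, regions$region_id))
  same_lobe <- outer(lobe_of, lobe_of, `==`)
  lobe_load <- sqrt(config$lobe_coupling[lobe_of])
  planted[same_lobe] <- outer(lobe_load, lobe_load)[same_lobe]
  if (nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      planted[i, j] <- planted[j, i] <- planted[i, j] + h_bar
    }
  diag(planted) <- 0

  list(
    subjects = subjects,
    myelin = myelin,
    ground_truth = list(
      planted_correlation = planted,
      peak_age = setNames(peaks, regions$region_id),
      homologous_coupling = h_bar,
      homologous_coupling_by_subject = h_subj,
      lobe_coupling = config$lobe_coupling,
      seed = config$seed
    )
  )
}

#' Generate two aligned cohorts for a group comparison
#'
#' Convenience wrapper producing e.g. a young and an old cohort that share
#' the same region table, mirroring a two-age-band study design.
#'
#' @param config_young,config_old [cohort_config()]s with identical
#'   region tables.
#' @return A list with `young`, `old` (each a [generate_cohort()] result)
#'   and the shared `regions` table.
#' @export
make_two_group_fixture <- function(config_young, config_old) {
  stopifnot(inherits(config_young, "cohort_config"),
            inherits(config_old, "cohort_config"))
  if (!identical(config_young$region_table, config_old$region_table))
    stop("the two configs must share the same region table")
  list(
    young = generate_cohort(config_young),
    old = generate_cohort(config_old),
    regions = config_young$region_table
  )
}
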