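#' Subject covariate table
#'
#' Builds and validates the subject table used throughout the package:
#' one row per subject with an opaque unique id, age in years and sex
#' coded as `"F"` / `"M"`. Downstream regression designs encode sex
#' numerically with F = 0, M = 1; the coding is echoed in pipeline
#' reports.
#'
#' @param subject_id character vector of unique ids.
#' @param age numeric vector of ages in years (finite, > 0).
#' @param sex character or factor with levels `"F"` and `"M"`.
#' @return A validated `data.frame` with columns `subject_id`, `age`, `sex`.
#' @export
subject_table <- function(subject_id, age, sex) {
  df <- data.frame(
    subject_id = as.character(subject_id),
    age = as.numeric(age),
    sex = as.character(sex),
    stringsAsFactors = FALSE
  )
  validate_subject_table(df)
  df
}

validate_subject_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("subject_id", "age", "sex") %in% names(df)))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ", df$subject_id[duplicated(df$subject_id)][1])
  if (!all(is.finite(df$age)) || any(df$age <= 0))
    stop("age must be finite and positive")
  if (!all(df$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'")
  invisible(df)
}

#' Region metadata table
#'
#' One row per gray-matter region of the parcellation: id, free-text name,
#' hemisphere (`"L"`, `"R"` or `"midline"`), lobe, and the id of the
#' contralateral homologous region (empty string when the region has no
#' homologue). The row order of this table is authoritative: every matrix,
#' graph and output of the package indexes regions in this order.
#'
#' @param region_id character vector of unique ids.
#' @param name free-text structure names.
#' @param hemisphere `"L"`, `"R"` or `"midline"`.
#' @param lobe one of `"frontal"`, `"parietal"`, `"temporal"`,
#'   `"occipital"`, `"limbic"`, `"insula"`, `"subcortical"`.
#' @param homologue_id region_id of the mirror structure, or `""`.
#' @return A validated `data.frame`.
#' @export
region_table <- function(region_id, name, hemisphere, lobe, homologue_id = "") {
  df <- data.frame(
    region_id = as.character(region_id),
    name = as.character(name),
    hemisphere = as.character(hemisphere),
    lobe = as.character(lobe),
    homologue_id = as.character(homologue_id),
    stringsAsFactors = FALSE
  )
  validate_region_table(df)
  df
}

.lobes <- c("frontal", "parietal", "temporal", "occipital", "limbic",
            "insula", "subcortical")

validate_region_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("region_id", "name", "hemisphere", "lobe", "homologue_id") %in% names(df)))
  if (anyDuplicated(df$region_id))
    stop("duplicate region_id: ", df$region_id[duplicated(df$region_id)][1])
  if (!all(df$hemisphere %in% c("L", "R", "midline")))
    stop("hemisphere must be 'L', 'R' or 'midline'")
  if (!all(df$lobe %in% .lobes))
    stop("lobe must be one of: ", paste(.lobes, collapse = ", "))
  paired <- df$homologue_id != ""
  if (any(paired)) {
    idx <- match(df$homologue_id[paired], df$region_id)
    if (anyNA(idx))
      stop("homologue_id not in table: ", df$homologue_id[paired][is.na(idx)][1])
    back <- df$homologue_id[idx]
    if (!all(back == df$region_id[paired]))
      stop("homologue relation is not symmetric (",
           df$region_id[paired][back != df$region_id[paired]][1], ")")
    h1 <- df$hemisphere[paired]
    h2 <- df$hemisphere[idx]
    if (!all((h1 == "L" & h2 == "R") | (h1 == "R" & h2 == "L")))
      stop("homologous pairs must lie in opposite hemispheres")
  }
  invisible(df)
}

# Unordered homologous pairs as a 2-column index matrix into the region table.
homologous_pairs <- function(regions) {
  paired <- which(regions$homologue_id != "")
  if (!length(paired)) return(matrix(integer(), ncol = 2))
  j <- match(regions$homologue_id[paired], regions$region_id)
  keep <- paired < j
  cbind(paired[keep], j[keep])
}

validate_myelin_matrix <- function(values, subjects = NULL, regions = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite MT value at subject row ", rownames(values)[bad[1]] %||% bad[1],
         ", region column ", colnames(values)[bad[2]] %||% bad[2])
  }
  if (nrow(values) < 4) stop("need at least 4 subjects")
  if (!is.null(subjects) && !identical(rownames(values), subjects$subject_id))
    stop("matrix rows are not aligned with the subject table")
  if (!is.null(regions) && !identical(colnames(values), regions$region_id))
    stop("matrix columns are not aligned with the region table")
  invisible(values)
}

validate_correlation_matrix <- function(C) {
  stopifnot(is.matrix(C), is.numeric(C), nrow(C) == ncol(C))
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-10, check.attributes = FALSE)))
    stop("correlation matrix must be symmetric")
  if (any(diag(C) != 0))
    stop("correlation matrix diagonal must be exactly 0 (self-connections excluded)")
  off <- C[upper.tri(C)]
  if (any(abs(off) > 1 + 1e-12))
    stop("off-diagonal correlations must lie in [-1, 1]")
  invisible(C)
}

#' Read an aligned myelin dataset from plain-text tables
#'
#' Reads the three canonical TSV files (MT matrix, subject covariates,
#' region metadata) and aligns them: matrix rows are reordered to the
#' subject-table order and columns to the region-table order, so that any
#' permutation of file rows or columns yields identical downstream
#' statistics.
#'
#' @param matrix_path TSV whose first column is `subject_id` and remaining
#'   header names are region ids.
#' @param subjects_path subject table TSV (`subject_id`, `age`, `sex`).
#' @param regions_path region table TSV.
#' @return A list with elements `myelin` (M x N numeric matrix with
#'   subject/region dimnames), `subjects`, `regions`.
#' @export
read_myelin_dataset <- function(matrix_path, subjects_path, regions_path) {
  for (p in c(matrix_path, subjects_path, regions_path))
    if (!file.exists(p)) stop("file not found: ", p)

  subjects <- read.delim(subjects_path, colClasses = "character")
  subjects$age <- suppressWarnings(as.numeric(subjects$age))
  validate_subject_table(subjects)
  regions <- read.delim(regions_path, colClasses = "character", na.strings = NULL)
  regions$homologue_id[is.na(regions$homologue_id)] <- ""
  validate_region_table(regions)

  raw <- read.delim(matrix_path, check.names = FALSE, colClasses = "character")
  if (names(raw)[1] != "subject_id") stop("matrix first column must be 'subject_id'")
  ids <- raw$subject_id
  if (anyDuplicated(ids)) stop("duplicate subject_id in matrix: ", ids[duplicated(ids)][1])
  miss <- setdiff(subjects$subject_id, ids)
  if (length(miss)) stop("subject missing from matrix: ", miss[1])
  extra <- setdiff(ids, subjects$subject_id)
  if (length(extra)) stop("matrix subject not in subject table: ", extra[1])
  rcols <- names(raw)[-1]
  miss <- setdiff(regions$region_id, rcols)
  if (length(miss)) stop("region missing from matrix: ", miss[1])
  extra <- setdiff(rcols, regions$region_id)
  if (length(extra)) stop("matrix region not in region table: ", extra[1])

  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = list(ids, rcols)))
  if (anyNA(num) || !all(is.finite(num))) {
    bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)[1, ]
    stop("non-numeric MT value for subject ", rownames(num)[bad[1]],
         ", region ", colnames(num)[bad[2]])
  }
  num <- num[subjects$subject_id, regions$region_id, drop = FALSE]
  validate_myelin_matrix(num, subjects, regions)
  list(myelin = num, subjects = subjects, regions = regions)
}

#' Write a myelin dataset to plain-text tables
#'
#' Inverse of [read_myelin_dataset()]: writes the MT matrix, subject table
#' and region table as TSV (UTF-8, Unix newlines, decimal point), so that
#' read-back reproduces the dataset exactly up to numeric print precision.
#'
#' @param myelin M x N numeric matrix with subject/region dimnames.
#' @param subjects,regions validated tables.
#' @param matrix_path,subjects_path,regions_path output file paths.
#' @return Invisibly, the three paths.
#' @export
write_myelin_dataset <- function(myelin, subjects, regions,
                                 matrix_path, subjects_path, regions_path) {
  validate_myelin_matrix(myelin, subjects, regions)
  df <- data.frame(subject_id = rownames(myelin),
                   format(myelin, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(subjects, subjects_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(regions, regions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, subjects_path, regions_path))
}

#' Write a symmetric matrix (correlation matrix or adjacency) as TSV
#'
#' The file has a `region_id` header column and row, one line per region.
#' Binary graphs are written as 0/1 adjacency; see [write_edge_list()] for
#' the edge-list export.
#'
#' @param x a symmetric numeric matrix with region dimnames, or a
#'   `binary_graph`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_symmetric_matrix <- function(x, path) {
  if (inherits(x, "binary_graph")) x <- x$adjacency * 1L
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  if (!isTRUE(all.equal(x, t(x), tolerance = 1e-12, check.attributes = FALSE)))
    stop("matrix must be symmetric")
  ids <- colnames(x) %||% as.character(seq_len(ncol(x)))
  df <- data.frame(region_id = ids,
                   format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- ids
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a symmetric matrix written by [write_symmetric_matrix()]
#' @param path TSV path.
#' @return Numeric matrix with region dimnames.
#' @export
read_symmetric_matrix <- function(path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- raw$region_id
  m <- matrix(as.numeric(as.matrix(raw[, -1, drop = FALSE])),
              length(ids), length(ids), dimnames = list(ids, ids))
  m
}

#' Export a binary graph as an undirected edge list
#'
#' One unordered region-id pair per line, tab-separated; each edge appears
#' once with the lexicographically smaller id first.
#'
#' @param graph a `binary_graph`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "binary_graph"))
  A <- graph$adjacency
  ids <- colnames(A)
  e <- which(A & upper.tri(A), arr.ind = TRUE)
  a <- ids[e[, 1]]; b <- ids[e[, 2]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  o <- order(lo, hi)
  writeLines(paste(lo[o], hi[o], sep = "\t"), path)
  invisible(path)
}

#' Write a structured JSON report
#'
#' Serializes a result record (typically a named list containing a config
#' echo, seeds and statistics) as pretty-printed JSON with deterministic
#' key order, so that identical records produce byte-identical files.
#'
#' @param results a serializable (no functions/environments) named list.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path) {
  assert_serializable(results)
  json <- jsonlite::toJSON(results, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
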