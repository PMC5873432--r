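test_that("a written dataset reads back identically and in canonical order", {
  set.seed(1)
  regions <- small_regions(2)               # 4 regions
  subjects <- subject_table(sprintf("s%d", 1:5), c(25, 30, 41, 52, 63),
                            c("F", "M", "F", "M", "F"))
  m <- matrix(rnorm(20, 1.8, 0.1), 5, 4,
              dimnames = list(subjects$subject_id, regions$region_id))
  d <- withr::local_tempdir()
  paths <- file.path(d, c("mt.tsv", "subj.tsv", "reg.tsv"))
  write_myelin_dataset(m, subjects, regions, paths[1], paths[2], paths[3])
  back <- read_myelin_dataset(paths[1], paths[2], paths[3])
  expect_equal(back$myelin, m, tolerance = 1e-12)
  expect_identical(back$subjects$subject_id, subjects$subject_id)
  expect_identical(back$regions$region_id, regions$region_id)

  # shuffle matrix columns and rows on disk: read-back must canonicalize
  raw <- read.delim(paths[1], check.names = FALSE)
  shuf <- raw[c(3, 1, 5, 2, 4), c(1, 4, 2, 5, 3)]
  write.table(shuf, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_myelin_dataset(paths[1], paths[2], paths[3])
  expect_equal(back2$myelin, m, tolerance = 1e-12)
})

test_that("alignment and parse errors name the offending id or cell", {
  regions <- small_regions(2)
  subjects <- subject_table(sprintf("s%d", 1:5), 21:25, rep(c("F", "M"), c(3, 2)))
  m <- matrix(1:20 + 0.5, 5, 4,
              dimnames = list(subjects$subject_id, regions$region_id))
  d <- withr::local_tempdir()
  paths <- file.path(d, c("mt.tsv", "subj.tsv", "reg.tsv"))
  write_myelin_dataset(m, subjects, regions, paths[1], paths[2], paths[3])

  # corrupt one cell -> parse error naming subject row and region column
  raw <- readLines(paths[1])
  raw[4] <- sub("\t[0-9.]+$", "\tNaN", raw[4])
  writeLines(raw, paths[1])
  expect_error(read_myelin_dataset(paths[1], paths[2], paths[3]),
               "s3.*roi002\\.R")

  # missing subject
  write_myelin_dataset(m[-2, , drop = FALSE], subjects[-2, ], regions,
                       paths[1], paths[2], paths[3])
  write.table(subjects, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_myelin_dataset(paths[1], paths[2], paths[3]), "s2")
})

test_that("region table invariants are enforced", {
  expect_error(region_table("a", "x", "L", "frontal", homologue_id = "b"),
               "not in table")
  # asymmetric homologue mapping
  expect_error(region_table(c("a", "b", "c"), c("x", "y", "z"),
                            c("L", "R", "R"), "frontal",
                            homologue_id = c("b", "c", "b")),
               "not symmetric|opposite")
  # same-hemisphere pair
  expect_error(region_table(c("a", "b"), c("x", "y"), c("L", "L"),
                            "frontal", homologue_id = c("b", "a")),
               "opposite hemispheres")
  expect_silent(validate_region_table(synthetic_region_table()))
})

test_that("symmetric-matrix writer round-trips and rejects asymmetry", {
  C <- fixed_corr(3); diag(C) <- 0
  d <- withr::local_tempdir()
  p <- file.path(d, "corr.tsv")
  write_symmetric_matrix(C, p)
  expect_equal(read_symmetric_matrix(p), C, tolerance = 1e-12)

  bad <- C; bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(write_symmetric_matrix(bad, p), "symmetric")

  # triangle graph -> 3 unordered edge pairs
  g <- bg(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  pe <- file.path(d, "edges.tsv")
  write_edge_list(g, pe)
  expect_identical(readLines(pe), c("a\tb", "a\tc", "b\tc"))
})

test_that("reports serialize deterministically and reject bad fields", {
  rec <- list(config = list(seed = 7, sex_coding = "F=0, M=1"),
              ci_low = -0.1, ci_high = 0.2, significant = FALSE)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "r1.json"); p2 <- file.path(d, "r2.json")
  write_report(rec, p1)
  write_report(rec, p2)
  expect_identical(readLines(p1), readLines(p2))
  parsed <- jsonlite::read_json(p1)
  expect_named(parsed, c("config", "ci_low", "ci_high", "significant"))

  expect_error(write_report(list(a = 1, f = identity), p1), "results\\$f")
  expect_silent(write_report(list(config = list(seed = 1)), p1))
})

test_that("round-trip holds for random instances (property)", {
  set.seed(99)
  d <- withr::local_tempdir()
  for (rep in 1:5) {
    np <- sample(2:6, 1)
    regions <- small_regions(np, n_midline = rep %% 2)
    M <- sample(5:9, 1)
    subjects <- subject_table(sprintf("p%02d", 1:M),
                              runif(M, 20, 80),
                              sample(c("F", "M"), M, TRUE))
    m <- matrix(rnorm(M * nrow(regions), 1.5, 0.2), M, nrow(regions),
                dimnames = list(subjects$subject_id, regions$region_id))
    paths <- file.path(d, c("a.tsv", "b.tsv", "c.tsv"))
    write_myelin_dataset(m, subjects, regions, paths[1], paths[2], paths[3])
    back <- read_myelin_dataset(paths[1], paths[2], paths[3])
    expect_equal(back$myelin, m, tolerance = 1e-10)
    expect_equal(back$subjects$age, subjects$age, tolerance = 1e-10)
  }
})
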