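test_that("constructor validates ids, dimensions and group map", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("P1", "P2"), c("s1", "s2")))
  it <- intensity_table(m * 1.0, groups = c(s1 = "A", s2 = "B"))
  expect_s3_class(it, "intensity_table")
  expect_identical(sample_groups(it), c(s1 = "A", s2 = "B"))

  dup <- m * 1.0
  colnames(dup) <- c("s1", "s1")
  expect_error(intensity_table(dup, groups = c("A", "B")),
               class = "pmadbench_validation_error")
  rownames(dup) <- c("P1", "P1")
  colnames(dup) <- c("s1", "s2")
  expect_error(intensity_table(dup, groups = c("A", "B")),
               class = "pmadbench_validation_error")
  expect_error(intensity_table(m * 1.0, groups = c(s1 = "A", sX = "B")),
               class = "pmadbench_validation_error")
})

test_that("missing cells are tracked through the mask", {
  m <- matrix(c(5, NA, 2, 7), 2, 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  it <- intensity_table(m, groups = c("A", "A"))
  expect_identical(missing_mask(it),
                   matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2,
                          dimnames = dimnames(m)))
  td <- tidy(it)
  expect_identical(nrow(td), 4L)
  expect_identical(sum(td$missing), 1L)
})

test_that("reader parses matrices, missing tokens and inline groups", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ts1\ts2\ts3\ts4",
               "group\tA\tA\tB\tB",
               "P1\t1.5\tNA\t3\t4",
               "P2\t2\t5\t\t0"), f)
  it <- read_intensity_table(f, groups = "inline")
  expect_identical(dim(it), c(2L, 4L))
  expect_identical(unname(sample_groups(it)), c("A", "A", "B", "B"))
  expect_true(is.na(it["P1", "s2"]))  # "NA" token
  expect_true(is.na(it["P2", "s3"]))  # empty token
  expect_identical(it["P2", "s4"], 0)

  itz <- read_intensity_table(f, groups = "inline", zero_as_missing = TRUE)
  expect_true(is.na(itz["P2", "s4"]))
})

test_that("reader reports bad cells and duplicate headers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ts1\ts1", "group\tA\tB", "P1\t1\t2"), f)
  expect_error(read_intensity_table(f, groups = "inline"),
               class = "pmadbench_validation_error")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ts1\ts2", "group\tA\tB", "P1\t1\tabc"), f2)
  expect_error(read_intensity_table(f2, groups = "inline"),
               regexp = "abc", class = "pmadbench_parse_error")
})

test_that("side-file group annotation works", {
  f <- withr::local_tempfile(fileext = ".tsv")
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ts1\ts2", "P1\t1\t2"), f)
  writeLines(c("s1\tA", "s2\tB"), g)
  it <- read_intensity_table(f, groups = g)
  expect_identical(unname(sample_groups(it)), c("A", "B"))
})

test_that("write -> read round-trips values, mask and groups exactly", {
  it <- random_table(p = 20, s = 6, missing = 0.2, seed = 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_table(it, f)
  back <- read_intensity_table(f, groups = "inline")
  expect_equal(unclass(back)[, ], unclass(it)[, ], tolerance = 0)
  expect_identical(missing_mask(back), missing_mask(it))
  expect_identical(sample_groups(back), sample_groups(it))
})

test_that("result writer emits ranking rows for failed chains too", {
  assessments <- assess_chains(structure(
    tibble::tibble(
      dataset_id = "D1",
      chain = c("LOG-MED-NON", "LOG-QUA-NON", "LOG-NON-NON"),
      transformation = "LOG",
      normalization = c("MED", "QUA", "NON"),
      imputation = "NON",
      pmad = c(0.2, 0.5, NA),
      failure_stage = c(NA, NA, "normalization"),
      failure_class = c(NA, NA, "degenerate-scale")),
    class = c("chain_sweep", "tbl_df", "tbl", "data.frame")))
  out <- withr::local_tempdir()
  manifest <- write_results(assessments, out_dir = out)
  expect_true(file.exists(file.path(out, "ranking_D1.tsv")))
  expect_true(file.exists(file.path(out, "categories.tsv")))
  rk <- readr::read_tsv(file.path(out, "ranking_D1.tsv"),
                        show_col_types = FALSE)
  expect_identical(nrow(rk), 3L)
  expect_identical(rk$chain[1:2], c("LOG-MED-NON", "LOG-QUA-NON"))
  expect_true(is.na(rk$pmad[3]) && rk$failure_class[3] == "degenerate-scale")
})
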