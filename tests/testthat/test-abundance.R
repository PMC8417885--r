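test_that("abundance_matrix validates counts and computes depths", {
  m <- abundance_matrix(matrix(c(5, 1, 0, 0, 2, 3), nrow = 3),
                        subject_id = "S1")
  expect_equal(unname(colSums(m)), c(6, 5))
  expect_equal(nrow(m), 3L)
  expect_equal(attr(m, "subject_id"), "S1")

  expect_warning(
    m2 <- abundance_matrix(rbind(c(2, 1), c(0, 0), c(1, 4))),
    "all-zero")
  expect_equal(nrow(m2), 2L)

  expect_error(abundance_matrix(matrix(c(1, -1, 2, 3), 2)), "negative")
  expect_error(abundance_matrix(matrix(c(1, 1.5, 2, 3), 2)), "non-integer")
  expect_error(abundance_matrix(matrix(numeric(0), 0, 0)), "empty")
  expect_error(suppressWarnings(abundance_matrix(matrix(c(1, 0, 0, 0), 2))),
               ">= 1 read")
})

test_that("abundance tables round-trip through TSV in both orientations", {
  m <- abundance_matrix(matrix(c(5L, 1L, 0L, 0L, 2L, 3L), nrow = 3),
                        species_ids = c("a", "b", "c"),
                        sample_ids = c("t1", "t2"), subject_id = "S1")
  f <- tempfile(fileext = ".tsv")
  write_abundance_table(m, f)
  r <- read_abundance_table(f, subject_id = "S1")
  expect_equal(unclass(r), unclass(m))

  # transpose then read with samples as rows
  f2 <- tempfile(fileext = ".tsv")
  tm <- t(unclass(m))
  df <- data.frame(sample_id = rownames(tm), tm, check.names = FALSE)
  write.table(df, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  r2 <- read_abundance_table(f2, orientation = "samples_as_rows",
                             subject_id = "S1")
  expect_equal(unclass(r2), unclass(m))

  # non-numeric entry is reported with its location
  writeLines(c("sp\tt1\tt2", "a\t5\tx"), f2)
  expect_error(read_abundance_table(f2), "non-numeric")
})

test_that("metadata reader enforces schema, groups, and time ordering", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(subject_id = "s1", sample_id = c("a", "b"),
                   group = "ABV", time_index = c(1L, 2L))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- read_metadata(f)
  expect_s3_class(md$group, "factor")

  df$time_index <- c(2L, 1L)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_metadata(f), "strictly increasing")

  df$time_index <- c(1L, 2L); df$group <- "XXX"
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_metadata(f), "unknown group")
})

test_that("result tables render to fixed precision and round-trip", {
  row <- msn_result_row("S12", L_0 = -7164.578, theta = 17.818,
                        M_value = 11.849, L_M = -8855.097, N_M = 2437,
                        N = 2500, P_M = 2437 / 2500, L_L = -7387.665,
                        N_L = 2158, P_L = 2158 / 2500)
  f <- tempfile(fileext = ".tsv")
  write_result_table(row, f)
  txt <- readLines(f)
  expect_match(txt[2], "2437\t2500\t0\\.975", all = FALSE)
  back <- read_result_table(f)
  expect_equal(back$P_M, 0.975)
  expect_equal(back$theta, 17.818)

  # empty input gives a header-only file with the full schema
  write_result_table(row[0L, ], f, schema = "msn")
  expect_length(readLines(f), 1L)

  nrow_ <- nnh_result_row("S3", J = 164, S = 8.455, theta = 4.032,
                          m = 0.007, x = 0.803, gamma = 1.236,
                          R2 = 0.981, chi2 = 0.925, P = 0.996,
                          N_pass = 11, pct_pass = 100)
  write_result_table(nrow_, f)
  back2 <- read_result_table(f)
  expect_equal(back2$pct_pass, 100.0)
  expect_equal(back2$gamma, 1.236)
})
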