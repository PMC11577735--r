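test_that("expression matrices load from TSV and CSV with validation", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "expr.tsv")
  writeLines(c("feature_id\tS1\tS2\tS3",
               "GZMA\t1.5\t2.5\t3.5",
               "PRF1\t4\t5\t6"), tsv)
  em <- load_expression_matrix(tsv)
  expect_equal(dim(em), c(2L, 3L))
  expect_equal(rownames(em), c("GZMA", "PRF1"))
  expect_equal(colnames(em), c("S1", "S2", "S3"))
  expect_equal(unname(em["PRF1", "S2"]), 5)

  csv <- file.path(d, "expr.csv")
  writeLines(c("feature_id,S1,S2", "GZMA,1,2", "PRF1,3,4"), csv)
  expect_equal(dim(load_expression_matrix(csv)), c(2L, 2L))

  # round trip preserves values
  out <- file.path(d, "roundtrip.tsv")
  write_expression_matrix(em, out)
  expect_equal(unclass(load_expression_matrix(out)), unclass(em),
               ignore_attr = TRUE)
})

test_that("malformed expression cells and duplicate samples are named in errors", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "bad.tsv")
  writeLines(c("feature_id\tS1\tS2",
               "GZMA\t1.0\tn/a",
               "PRF1\t3\t4"), bad)
  expect_error(load_expression_matrix(bad), "GZMA.*S2")

  dup <- file.path(d, "dup.tsv")
  writeLines(c("feature_id\tS1\tS1", "GZMA\t1\t2"), dup)
  expect_error(load_expression_matrix(dup), "duplicate sample")
})

test_that("missing cells are rejected in strict mode and imputable per gene", {
  d <- withr::local_tempdir()
  f <- file.path(d, "na.tsv")
  writeLines(c("feature_id\tS1\tS2\tS3",
               "GZMA\t1\tNA\t3",
               "PRF1\t4\t5\t6"), f)
  expect_error(load_expression_matrix(f), "missing expression")
  em <- suppressMessages(load_expression_matrix(f, impute = "gene_mean"))
  expect_equal(unname(em["GZMA", "S2"]), 2)  # mean of 1 and 3
})

test_that("log2_offset transforms raw-scale input", {
  d <- withr::local_tempdir()
  f <- file.path(d, "raw.tsv")
  writeLines(c("feature_id\tS1\tS2", "GZMA\t3\t7", "PRF1\t15\t0"), f)
  em <- load_expression_matrix(f, log2_offset = 1)
  expect_equal(unname(em["GZMA", ]), c(2, 3), ignore_attr = TRUE)
  expect_equal(unname(em["PRF1", "S1"]), 4)
})

test_that("collapse_probes averages probes per gene and respects bounds", {
  vals <- rbind(p1 = c(2, 4), p2 = c(4, 6), p3 = c(9, 1), lone = c(5, 5))
  colnames(vals) <- c("S1", "S2")
  em <- expression_matrix(vals, "probe")
  map <- c(p1 = "GENEA", p2 = "GENEA", lone = "GENEB")
  out <- collapse_probes(em, map)
  expect_equal(unname(out["GENEA", ]), c(3, 5), ignore_attr = TRUE)
  expect_equal(unname(out["GENEB", ]), c(5, 5), ignore_attr = TRUE)
  expect_true("p3" %in% rownames(out))          # pass-through keeps probe id
  expect_equal(ncol(out), 2L)

  # three probes -> mean; collapsed value within per-sample probe range
  m3 <- rbind(a = c(1, 1), b = c(2, 5), c = c(6, 3))
  colnames(m3) <- c("S1", "S2")
  em3 <- expression_matrix(m3, "probe")
  out3 <- collapse_probes(em3, c(a = "G", b = "G", c = "G"))
  expect_equal(unname(out3["G", ]), c(3, 3), ignore_attr = TRUE)
  mins <- apply(unclass(em3), 2, min); maxs <- apply(unclass(em3), 2, max)
  expect_true(all(out3["G", ] >= mins & out3["G", ] <= maxs))

  expect_error(collapse_probes(em, character(0), passthrough = FALSE),
               "empty probe-to-gene mapping")
})

test_that("align_cohort intersects samples, drops incomplete records, is idempotent", {
  vals <- matrix(1:12 + 0, 2, 6,
                 dimnames = list(c("GZMA", "PRF1"), paste0("S", 1:6)))
  em <- expression_matrix(vals, "gene")
  cl <- clinical_table(data.frame(
    sample_id = c("S2", "S3", "S4", "S7"),
    os_time = c(5, NA, 3, 2),
    os_event = c(1, 1, NA, 0), stringsAsFactors = FALSE))
  co <- suppressMessages(align_cohort(em, cl, "t"))
  expect_equal(colnames(co$expr), "S2")
  expect_equal(co$clinical$sample_id, "S2")
  dropped <- attr(co, "dropped")
  expect_setequal(dropped$sample_id, c("S3", "S4"))

  co2 <- suppressMessages(align_cohort(co$expr, co$clinical, "t"))
  expect_identical(unclass(co2$expr), unclass(co$expr))
  expect_identical(co2$clinical, co$clinical)

  cl_disjoint <- clinical_table(data.frame(sample_id = "X1", os_time = 1,
                                           os_event = 1,
                                           stringsAsFactors = FALSE))
  expect_error(suppressMessages(align_cohort(em, cl_disjoint)), "no samples shared")
})

test_that("zero follow-up samples are dropped with a warning", {
  vals <- matrix(rnorm(12), 2, 6,
                 dimnames = list(c("A", "B"), paste0("S", 1:6)))
  cl <- clinical_table(data.frame(sample_id = paste0("S", 1:6),
                                  os_time = c(0, 1, 2, 3, 4, 5),
                                  os_event = rep(1, 6),
                                  stringsAsFactors = FALSE))
  expect_warning(
    co <- suppressMessages(align_cohort(expression_matrix(vals, "gene"), cl)),
    "os_time = 0")
  expect_equal(ncol(co$expr), 5L)
})

test_that("cap_followup censors beyond the horizon, inclusive boundary", {
  cl <- clinical_table(data.frame(
    sample_id = c("a", "b", "c", "d"),
    os_time = c(10, 5, 8, 8.001),
    os_event = c(1, 1, 1, 0), stringsAsFactors = FALSE))
  out <- cap_followup(cl, 8)
  expect_equal(out$os_time, c(8, 5, 8, 8))
  expect_equal(out$os_event, c(0, 1, 1, 0))
  # never increases time, never creates an event
  expect_true(all(out$os_time <= cl$os_time))
  expect_true(all(out$os_event <= cl$os_event))
  expect_error(cap_followup(cl, -1), "positive")
})

test_that("clinical tables validate codings and map FIGO numerals", {
  df <- data.frame(sample_id = c("a", "b"), os_time = c(1, 2),
                   os_event = c(0, 1), stage = c("II", "IV"),
                   debulking = c("optimal", NA), stringsAsFactors = FALSE)
  cl <- clinical_table(df)
  expect_equal(cl$stage, c("low", "high"))
  expect_error(clinical_table(transform(df, os_event = c(2, 1))), "os_event")
  expect_error(clinical_table(transform(df, stage = c("weird", "IV"))), "stage")
  expect_error(clinical_table(df[c(1, 1), ]), "duplicate sample_id")
})
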