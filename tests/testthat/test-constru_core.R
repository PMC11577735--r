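test_that("tertile_split follows the floor(3r/n) rule with stable ties", {
  t9 <- tertile_split(1:9)
  expect_equal(as.character(t9$labels),
               rep(c("T1", "T2", "T3"), each = 3))
  expect_equal(t9$boundaries, c(3, 6))

  # n = 10: enumerate the rule independently -> sizes (4, 3, 3)
  rule_sizes <- function(n) tabulate(floor(3 * (0:(n - 1)) / n) + 1L, 3L)
  t10 <- tertile_split(sort(rnorm(10)))
  expect_equal(unname(table(t10$labels)), rule_sizes(10), ignore_attr = TRUE)
  expect_equal(rule_sizes(10), c(4L, 3L, 3L))

  # all-equal values: assignment follows original input order
  teq <- tertile_split(rep(5, 9))
  expect_equal(as.character(teq$labels), rep(c("T1", "T2", "T3"), each = 3))

  expect_error(tertile_split(1:5), "at least 6")
})

test_that("tertile sizes differ by at most one and ties are deterministic", {
  rule_sizes <- function(n) tabulate(floor(3 * (0:(n - 1)) / n) + 1L, 3L)
  set.seed(31)
  for (n in c(6, 7, 8, 11, 100, 101, 500, 997)) {
    v <- sample(round(rnorm(n), 1))   # duplicates likely
    t1 <- tertile_split(v)
    expect_lte(diff(range(table(t1$labels))), 1)
    expect_equal(unname(table(t1$labels)), rule_sizes(n), ignore_attr = TRUE)
    expect_identical(tertile_split(v)$labels, t1$labels)
  }
})

test_that("parity_score computes the printed formula and is antisymmetric", {
  expect_equal(parity_score(1e-3, 0.5, 0.5, 1.0),
               3 / 0.5 - (-log10(0.5)) / 1.0, tolerance = 1e-12)
  expect_equal(parity_score(1, 1, 1e-4, 0.5), -8, tolerance = 1e-12)
  expect_equal(parity_score(0.3, 0.8, 0.3, 0.8), 0)
  # p at the clamp floor stays finite
  expect_true(is.finite(parity_score(1e-320, 0.5, 0.5, 1)))
  expect_error(parity_score(0, 1, 0.5, 1), "p-values")
  expect_error(parity_score(0.5, -1, 0.5, 1), "positive")
})

test_that("percentile ranks map 0-based average ranks onto [0, 100]", {
  expect_equal(percentile_rank(c(1, 2, 3, 4, 5)), c(0, 25, 50, 75, 100))
  expect_equal(percentile_rank(c(2, 2)), c(50, 50))
  expect_equal(percentile_rank(c(5, 1)), c(100, 0))
  expect_equal(percentile_rank(c(3, NA, 1)), c(100, NA, 0))
  expect_error(percentile_rank(c(NA_real_, NA_real_)), "missing")
  # monotone in the scores, full span
  set.seed(8)
  x <- rnorm(200)
  pr <- percentile_rank(x)
  expect_equal(order(pr), order(x))
  expect_equal(range(pr), c(0, 100))
})

scan_fixture <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$tab)) {
      spec <- simulation_spec(
        n_samples = 300, n_genes = 120, seed = 7,
        planted = list(list(gene = 10, active_tertile = "T3",
                            beta_score = -1)))
      cohort <- cap_followup(suppressMessages(simulate_cohort(spec)))
      score <- as.numeric(score_signature(cohort$expr,
                                          builtin_signature("CYTscore")))
      cache$cohort <- cohort
      cache$score <- score
      cache$tab <- suppressMessages(constru_scan(cohort, score))
    }
    as.list(cache)
  }
})

test_that("the scan recovers a planted upper-tertile conditional gene", {
  fx <- scan_fixture()
  rec <- fx$tab$records
  g <- rec[rec$gene == "G00008", ]   # row 10 of the simulated matrix
  expect_true(g$t1_p > g$t3_p)
  expect_lt(g$t3_hr, 1)
  expect_lt(g$parity, 0)             # UpperT-type gene: negative parity
  expect_lt(g$parity_percentile, 5)
})

test_that("scan output table is structurally sound", {
  fx <- scan_fixture()
  rec <- fx$tab$records
  expect_equal(nrow(rec), 120)
  expect_setequal(rec$gene, rownames(fx$cohort$expr))
  # tertile Ns partition the cohort
  ok <- !is.na(rec$t1_n)
  expect_true(all(rec$t1_n[ok] + rec$t2_n[ok] + rec$t3_n[ok] == 300))
  # parity present iff T1 and T3 stats both present
  expect_equal(is.na(rec$parity), is.na(rec$t1_p) | is.na(rec$t3_p))
  # percentiles computed over exactly the unfiltered estimable records
  ranked <- !is.na(rec$parity_percentile)
  expect_equal(ranked, is.na(rec$filtered_reason) & !is.na(rec$parity))
  expect_equal(order(rec$parity_percentile[ranked]), order(rec$parity[ranked]))
})

test_that("a constant gene is flagged, not fatal", {
  fx <- scan_fixture()
  cohort <- fx$cohort
  expr <- unclass(cohort$expr)
  expr[5, ] <- 3.14
  cohort$expr <- expression_matrix(expr, "gene")
  tab <- suppressMessages(constru_scan(cohort, fx$score))
  rec <- tab$records[5, ]
  expect_equal(rec$filtered_reason, "constant")
  expect_true(is.na(rec$t1_p) && is.na(rec$parity))
})

test_that("a fully missing age column is dropped from the models, logged", {
  fx <- scan_fixture()
  cohort <- fx$cohort
  cohort$clinical$age <- NA_real_
  expect_message(tab <- constru_scan(cohort, fx$score), "age")
  expect_false("age" %in% tab$covariates)
  expect_gt(sum(!is.na(tab$records$parity)), 0)
})

test_that("scan is deterministic: identical inputs give identical tables", {
  fx <- scan_fixture()
  tab2 <- suppressMessages(constru_scan(fx$cohort, fx$score))
  expect_identical(fx$tab$records, tab2$records)
})

test_that("correlation_filter excludes |r| > threshold and re-ranks survivors", {
  fx <- scan_fixture()
  tab <- correlation_filter(fx$tab, 0.15)
  rec <- tab$records
  # the two score genes are strongly correlated with the score by design
  expect_equal(rec$filtered_reason[rec$gene == "GZMA"], "score-correlated")
  hit <- !is.na(rec$cyt_r) & abs(rec$cyt_r) > 0.15 &
    rec$filtered_reason %in% "score-correlated"
  expect_true(all(is.na(rec$parity_percentile[hit])))
  retained <- is.na(rec$filtered_reason) & !is.na(rec$parity)
  expect_true(all(abs(rec$cyt_r[retained]) <= 0.15))
  expect_equal(sort(unique(stats::na.omit(
    c(rec$parity_percentile[retained][which.min(rec$parity[retained])],
      rec$parity_percentile[retained][which.max(rec$parity[retained])])))),
    c(0, 100))
  # boundary semantics: r = -0.16 filtered, r = 0.10 retained
  t2 <- fx$tab
  t2$records$cyt_r[3] <- -0.16
  t2$records$cyt_r[4] <- 0.10
  t2 <- correlation_filter(t2, 0.15)
  expect_equal(t2$records$filtered_reason[3], "score-correlated")
  expect_true(is.na(t2$records$filtered_reason[4]) ||
                t2$records$filtered_reason[4] != "score-correlated")
  expect_error(correlation_filter(fx$tab, 1.2), "threshold")
})

make_fake_table <- function(genes, percentiles, cohort = "fake") {
  rec <- data.frame(gene = genes, parity = percentiles,
                    parity_percentile = percentiles,
                    filtered_reason = NA_character_,
                    stringsAsFactors = FALSE)
  structure(list(records = rec, cohort = cohort, score_name = "CYTscore",
                 covariates = character(), corr_threshold = 0.15),
            class = "constru_table")
}

test_that("select_candidates intersects extremes across cohorts", {
  ta <- make_fake_table(c("X", "Y", "Z", "W"), c(1, 1, 99, 50), "A")
  tb <- make_fake_table(c("X", "Y", "Z", "W"), c(1, 50, 99, 97), "B")
  cand <- select_candidates(list(ta, tb), 4)
  expect_equal(cand$upperT_genes, "X")
  expect_equal(cand$lowerT_genes, "Z")

  # no gene extreme in both -> empty sets, not an error
  t0 <- make_fake_table(c("X", "Y"), c(50, 60), "A")
  t1 <- make_fake_table(c("X", "Y"), c(2, 99), "B")
  cand0 <- select_candidates(list(t0, t1), 4)
  expect_length(cand0$upperT_genes, 0)
  expect_length(cand0$lowerT_genes, 0)

  # a gene extreme on opposite ends is excluded from both sets
  tu <- make_fake_table("X", 1, "A")
  tl <- make_fake_table("X", 99, "B")
  both <- select_candidates(list(tu, tl), 4)
  expect_length(both$upperT_genes, 0)
  expect_length(both$lowerT_genes, 0)

  expect_error(select_candidates(list(ta), 4), "two scan tables")
})

test_that("candidate sets are nested in the cutoff and always disjoint", {
  set.seed(13)
  genes <- sprintf("G%03d", 1:200)
  ta <- make_fake_table(genes, percentile_rank(rnorm(200)), "A")
  tb <- make_fake_table(genes, percentile_rank(rnorm(200)), "B")
  prev_u <- character(); prev_l <- character()
  for (cut in c(2, 4, 6)) {
    cand <- select_candidates(list(ta, tb), cut)
    expect_length(intersect(cand$upperT_genes, cand$lowerT_genes), 0)
    expect_true(all(prev_u %in% cand$upperT_genes))
    expect_true(all(prev_l %in% cand$lowerT_genes))
    prev_u <- cand$upperT_genes; prev_l <- cand$lowerT_genes
  }
})

test_that("scan tables round-trip through TSV", {
  fx <- scan_fixture()
  d <- withr::local_tempdir()
  path <- file.path(d, "tab.tsv")
  write_constru_table(fx$tab, path)
  back <- read_constru_table(path)
  expect_equal(back$records$gene, fx$tab$records$gene)
  expect_equal(back$records$parity, fx$tab$records$parity, tolerance = 1e-10)
  expect_equal(back$records$t3_p, fx$tab$records$t3_p, tolerance = 1e-10)
})
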