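# The gene-stratified scan: for every gene, split samples into expression
# tertiles, fit the adjusted score-survival Cox model within each tertile,
# compute interaction statistics, parity scores, percentile ranks, the
# score-correlation filter, and cross-cohort candidate selection.

#' Split samples into expression tertiles
#'
#' Samples are sorted ascending by value, ties broken by original index
#' (stable sort), and the sample at 0-based sorted rank r of n receives
#' tertile `floor(3 r / n) + 1`.  T1 holds the lowest values.  Group sizes
#' therefore differ by at most one and the assignment is deterministic.
#'
#' @param values Numeric vector, length >= 6.
#' @param labels Three labels for the tertiles (low to high).
#' @return List with `labels` (factor over `labels`, one per sample, input
#'   order) and `boundaries` (highest value in T1 and in T2).
#' @export
tertile_split <- function(values, labels = c("T1", "T2", "T3")) {
  n <- length(values)
  if (n < 6) stop_constru("tertile split needs at least 6 samples, got %d", n)
  if (anyNA(values)) stop_constru("tertile split input contains NA")
  if (length(labels) != 3) stop_constru("exactly 3 tertile labels required")
  ord <- order(values)                      # radix sort: stable under ties
  tert_sorted <- (3L * (seq_len(n) - 1L)) %/% n + 1L
  lab <- integer(n)
  lab[ord] <- tert_sorted
  boundaries <- c(values[ord][max(which(tert_sorted == 1L))],
                  values[ord][max(which(tert_sorted == 2L))])
  list(labels = factor(labels[lab], levels = labels), boundaries = boundaries)
}

#' Parity score contrasting score-survival statistics between tertiles
#'
#' `(-log10 P / HR)[T1] - (-log10 P / HR)[T3]`, combining the significance
#' (-log10 P) and effect size (hazard ratio) of the score-survival
#' association in a gene's lower and upper expression tertiles.  High
#' values mark genes whose *low* expression is conditional for the
#' association (LowerT type); low values mark the UpperT type.  P-values
#' are clamped at 1e-300 before the log transform.
#'
#' @param p_t1,hr_t1 Score Wald p-value and hazard ratio in tertile T1.
#' @param p_t3,hr_t3 Same for tertile T3.
#' @return Numeric parity score (vectorized).
#' @export
parity_score <- function(p_t1, hr_t1, p_t3, hr_t3) {
  for (v in list(p_t1, p_t3))
    if (any(!is.na(v) & (v <= 0 | v > 1)))
      stop_constru("p-values must lie in (0, 1]")
  for (v in list(hr_t1, hr_t3))
    if (any(!is.na(v) & v <= 0))
      stop_constru("hazard ratios must be positive")
  (-log10(clamp_p(p_t1)) / hr_t1) - (-log10(clamp_p(p_t3)) / hr_t3)
}

#' Percentile ranks over a score vector
#'
#' 0-based ascending ranks (average rank for ties) mapped to `[0, 100]` by
#' `100 r / (n - 1)`.  Missing scores are excluded from ranking and return
#' `NA` in place.
#'
#' @param scores Numeric vector with at least 2 non-missing values.
#' @return Vector of percentile ranks in `[0, 100]`, `NA` where input is `NA`.
#' @export
percentile_rank <- function(scores) {
  ok <- !is.na(scores)
  n <- sum(ok)
  if (n == 0) stop_constru("all scores missing; cannot rank")
  if (n < 2) stop_constru("at least 2 non-missing scores required")
  out <- rep(NA_real_, length(scores))
  r <- rank(scores[ok], ties.method = "average") - 1
  out[ok] <- 100 * r / (n - 1)
  out
}

# Assemble the cohort-level adjustment covariate frame for the scan,
# applying the missing-data policy: partially missing age is mean-imputed
# within cohort, fully missing covariates are dropped with a logged warning,
# categorical NA becomes an explicit level at design time.
scan_covariates <- function(cohort, covariates = c("age", "stage", "debulking")) {
  cl <- cohort$clinical
  out <- list()
  for (nm in intersect(covariates, c("age", "stage", "debulking"))) {
    if (!nm %in% colnames(cl) || all(is.na(cl[[nm]]))) {
      constru_log("constru", "cohort '%s': covariate '%s' absent or fully missing; dropped from models",
                  cohort$name, nm)
      next
    }
    v <- cl[[nm]]
    if (nm == "age" && anyNA(v)) {
      constru_log("constru", "cohort '%s': %d missing age value(s) mean-imputed",
                  cohort$name, sum(is.na(v)))
      v[is.na(v)] <- mean(v, na.rm = TRUE)
    }
    out[[nm]] <- v
  }
  if (!length(out)) return(NULL)
  as.data.frame(out, stringsAsFactors = FALSE)
}

REFERENCE_LEVELS <- list(stage = "low", debulking = "optimal")

#' Genome-wide tertile-conditional score-survival scan
#'
#' For every gene of the cohort's expression matrix: split samples into the
#' gene's expression tertiles ([tertile_split()]); within each tertile fit
#' a multivariable Cox model of survival on the continuous score adjusted
#' for patient age (continuous), stage (categorical, reference `low`) and
#' debulking status (categorical, reference `optimal`), recording the
#' score's hazard ratio and Wald p-value; fit the whole-cohort interaction
#' model `score + gene + score:gene` and record the interaction term; and
#' record the Pearson correlation of the gene with the score.  Genes whose
#' T1 and T3 fits both converge receive a [parity_score()]; parity
#' percentile ranks are computed over all estimable, unfiltered genes.
#'
#' Per-gene failures are never fatal: constant genes are flagged
#' `filtered_reason = "constant"`, tertiles with fewer than 2 events or
#' non-converging fits are marked non-estimable and excluded from ranking.
#'
#' @param cohort An aligned `cohort` (see [align_cohort()]); cap follow-up
#'   first with [cap_followup()].
#' @param score Per-sample numeric score (e.g. the CYTscore), finite for
#'   every sample.
#' @param covariates Adjustment covariates to use when present (default
#'   age, stage, debulking).
#' @param score_name Label recorded in the output table.
#' @return A `constru_table`: list with `records` (one row per gene),
#'   `cohort`, `score_name`, `covariates`, `corr_threshold` (`NA` until
#'   [correlation_filter()] runs).
#' @export
constru_scan <- function(cohort, score,
                         covariates = c("age", "stage", "debulking"),
                         score_name = "CYTscore") {
  stopifnot(inherits(cohort, "cohort"))
  ns <- ncol(cohort$expr)
  if (length(score) != ns) stop_constru("score length must equal sample count")
  if (any(!is.finite(score))) stop_constru("score must be finite for all samples")
  time <- cohort$clinical$os_time
  event <- cohort$clinical$os_event
  covdf <- scan_covariates(cohort, covariates)
  base_design <- if (is.null(covdf)) NULL else
    build_cox_design(covdf, REFERENCE_LEVELS, drop_constant = TRUE)
  expr <- unclass(cohort$expr)
  genes <- rownames(expr)
  ng <- length(genes)
  ctrl <- survival::coxph.control()

  t_hr <- matrix(NA_real_, ng, 3)
  t_p <- matrix(NA_real_, ng, 3)
  t_n <- matrix(NA_integer_, ng, 3)
  t_ev <- matrix(NA_integer_, ng, 3)
  t_conv <- matrix(FALSE, ng, 3)
  inter_hr <- rep(NA_real_, ng)
  inter_p <- rep(NA_real_, ng)
  corr <- rep(NA_real_, ng)
  filt <- rep(NA_character_, ng)

  score_c <- score - mean(score)
  for (gi in seq_len(ng)) {
    x <- expr[gi, ]
    if (stats::sd(x) == 0) { filt[gi] <- "constant"; next }
    corr[gi] <- stats::cor(x, score)
    tert <- tertile_split(x)$labels
    for (ti in 1:3) {
      rows <- which(as.integer(tert) == ti)
      t_n[gi, ti] <- length(rows)
      t_ev[gi, ti] <- sum(event[rows])
      if (t_ev[gi, ti] < 2) next
      s <- score[rows]
      if (stats::sd(s) == 0) next
      X <- cbind(score = s)
      if (!is.null(base_design)) {
        B <- base_design[rows, , drop = FALSE]
        keep <- apply(B, 2, function(cc) stats::sd(cc) > 0)
        if (any(keep)) X <- cbind(X, B[, keep, drop = FALSE])
      }
      X <- drop_degenerate_indicators(X, event[rows])
      fit <- cox_fit_matrix(X, time[rows], event[rows], control = ctrl)
      if (fit$converged) {
        t_conv[gi, ti] <- TRUE
        t_hr[gi, ti] <- fit$terms$hazard_ratio[1L]
        t_p[gi, ti] <- fit$terms$wald_p[1L]
      }
    }
    # Whole-cohort interaction model, for comparative purposes only: it is
    # reported but never used for candidate selection.  Centered inputs
    # stabilize the product term without changing its coefficient.
    xc <- x - mean(x)
    Xi <- cbind(score = score_c, gene = xc, score_x_gene = score_c * xc)
    ifit <- cox_fit_matrix(Xi, time, event, control = ctrl)
    if (ifit$converged) {
      inter_hr[gi] <- ifit$terms$hazard_ratio[3L]
      inter_p[gi] <- ifit$terms$wald_p[3L]
    }
  }

  estimable <- t_conv[, 1] & t_conv[, 3]
  parity <- rep(NA_real_, ng)
  parity[estimable] <- parity_score(t_p[estimable, 1], t_hr[estimable, 1],
                                    t_p[estimable, 3], t_hr[estimable, 3])
  filt[is.na(filt) & !estimable] <- "non-estimable"

  records <- data.frame(
    gene = genes,
    t1_hr = t_hr[, 1], t1_p = t_p[, 1], t1_n = t_n[, 1], t1_events = t_ev[, 1],
    t2_hr = t_hr[, 2], t2_p = t_p[, 2], t2_n = t_n[, 2], t2_events = t_ev[, 2],
    t3_hr = t_hr[, 3], t3_p = t_p[, 3], t3_n = t_n[, 3], t3_events = t_ev[, 3],
    interaction_hr = inter_hr, interaction_p = inter_p,
    cyt_r = corr, parity = parity, parity_percentile = NA_real_,
    filtered_reason = filt,
    stringsAsFactors = FALSE)
  tab <- structure(list(records = records, cohort = cohort$name,
                        score_name = score_name,
                        covariates = if (is.null(covdf)) character() else colnames(covdf),
                        corr_threshold = NA_real_),
                   class = "constru_table")
  rerank(tab)
}

# Percentile ranks are always recomputed over exactly the unfiltered,
# estimable records.
rerank <- function(table) {
  rec <- table$records
  ok <- is.na(rec$filtered_reason) & !is.na(rec$parity)
  rec$parity_percentile <- NA_real_
  if (sum(ok) >= 2) rec$parity_percentile[ok] <- percentile_rank(rec$parity[ok])
  table$records <- rec
  table
}

#' @export
print.constru_table <- function(x, ...) {
  rec <- x$records
  cat(sprintf("<constru_table '%s', score %s: %d genes, %d ranked, %d filtered>\n",
              x$cohort, x$score_name, nrow(rec),
              sum(!is.na(rec$parity_percentile)),
              sum(!is.na(rec$filtered_reason))))
  invisible(x)
}

#' Filter scan records correlated with the score
#'
#' Genes whose expression correlates with the score beyond the threshold
#' (Pearson `|r| > threshold`) make poor stratifiers — their tertiles
#' compress the score's distribution — and are marked
#' `filtered_reason = "score-correlated"`.  Percentile ranks are recomputed
#' over the surviving records.
#'
#' @param table A `constru_table` from [constru_scan()].
#' @param threshold Absolute correlation threshold in (0, 1); default 0.15.
#' @return The filtered, re-ranked `constru_table`.
#' @export
correlation_filter <- function(table, threshold = 0.15) {
  stopifnot(inherits(table, "constru_table"))
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1)
    stop_constru("threshold must lie in (0, 1)")
  rec <- table$records
  hit <- is.na(rec$filtered_reason) & !is.na(rec$cyt_r) & abs(rec$cyt_r) > threshold
  rec$filtered_reason[hit] <- "score-correlated"
  table$records <- rec
  table$corr_threshold <- threshold
  rerank(table)
}

#' Select candidate genes shared across cohorts
#'
#' UpperT candidates are genes whose parity percentile is at most
#' `cutoff_percentile` in *every* table (score-survival association
#' concentrated in the gene's upper tertile); LowerT candidates sit at or
#' above `100 - cutoff_percentile` in every table.  A gene qualifying for
#' both sets (possible across discordant cohorts) is excluded from both.
#'
#' @param tables List of at least two `constru_table`s over a shared gene
#'   universe.
#' @param cutoff_percentile Percentile cutoff (the study design used 2, 4
#'   and 6; default 4).
#' @return A `candidate_sets`: list with `upperT_genes`, `lowerT_genes`,
#'   `cutoff_percentile`, `cohorts`.
#' @export
select_candidates <- function(tables, cutoff_percentile = 4) {
  if (!is.list(tables) || length(tables) < 2)
    stop_constru("at least two scan tables required")
  stopifnot(all(vapply(tables, inherits, logical(1), "constru_table")))
  if (!is_scalar_number(cutoff_percentile) || cutoff_percentile <= 0 ||
      cutoff_percentile >= 50)
    stop_constru("cutoff_percentile must lie in (0, 50)")
  ranked <- lapply(tables, function(t) {
    r <- t$records
    r[!is.na(r$parity_percentile), c("gene", "parity_percentile")]
  })
  universe <- Reduce(intersect, lapply(ranked, `[[`, "gene"))
  if (!length(universe))
    stop_constru("no genes shared across the ranked records of all tables")
  pct <- vapply(ranked, function(r) r$parity_percentile[match(universe, r$gene)],
                numeric(length(universe)))
  pct <- matrix(pct, nrow = length(universe))
  upper <- universe[apply(pct <= cutoff_percentile, 1, all)]
  lower <- universe[apply(pct >= 100 - cutoff_percentile, 1, all)]
  both <- intersect(upper, lower)
  structure(list(upperT_genes = setdiff(upper, both),
                 lowerT_genes = setdiff(lower, both),
                 cutoff_percentile = cutoff_percentile,
                 cohorts = vapply(tables, `[[`, character(1), "cohort")),
            class = "candidate_sets")
}

#' @export
print.candidate_sets <- function(x, ...) {
  cat(sprintf("<candidate_sets at %g%%: %d UpperT, %d LowerT (cohorts: %s)>\n",
              x$cutoff_percentile, length(x$upperT_genes),
              length(x$lowerT_genes), paste(x$cohorts, collapse = ", ")))
  invisible(x)
}

#' Write a scan table as TSV
#'
#' One row per gene with the tertile-specific score statistics, interaction
#' statistics, score correlation, parity score, percentile rank and filter
#' reason.
#'
#' @param table A `constru_table`.
#' @param path Output path.
#' @export
write_constru_table <- function(table, path) {
  stopifnot(inherits(table, "constru_table"))
  utils::write.table(table$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a scan table written by [write_constru_table()]
#' @param path TSV path.
#' @param cohort Cohort label to attach (defaults to the file name).
#' @param score_name Score label to attach.
#' @return A `constru_table`.
#' @export
read_constru_table <- function(path, cohort = basename(path),
                               score_name = "CYTscore") {
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  structure(list(records = rec, cohort = cohort, score_name = score_name,
                 covariates = character(), corr_threshold = NA_real_),
            class = "constru_table")
}
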