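# Tertile-conditional survival evaluation: score-survival tests within the
# tertiles of a stratifying signature, covariate-subgroup analyses, and a
# per-gene survival screen with Benjamini-Hochberg control.
#
# The single most consequential design rule here: score tertiles (Lo/Mid/Hi)
# and stratifier tertiles (T1/T2/T3) are frozen at the whole-cohort level
# and carried into subgroups and tertiles, never recomputed inside subsets.

# Shared core: evaluate score-survival associations within each stratifier
# tertile, given per-sample labels already fixed at the cohort level.
eval_tertiles_core <- function(cohort, idx, strat_labels, score,
                               score_groups, covariates, stratifier_name,
                               score_name) {
  covdf <- scan_covariates(
    structure(list(clinical = cohort$clinical, name = cohort$name),
              class = "cohort"),
    covariates)
  per <- lapply(levels(strat_labels), function(tl) {
    rows <- idx[strat_labels[idx] == tl]
    sub <- list(n = length(rows),
                n_events = sum(cohort$clinical$os_event[rows]),
                tertile = tl, estimable = FALSE,
                logrank = NULL, cox = NULL, km = NULL)
    if (sub$n_events < 2) return(sub)
    time <- cohort$clinical$os_time[rows]
    event <- cohort$clinical$os_event[rows]
    g <- droplevels(score_groups[rows])
    if (nlevels(g) >= 2)
      sub$logrank <- logrank_test(time, event, g)
    X <- cbind(score = score[rows])
    if (!is.null(covdf)) {
      B <- build_cox_design(covdf, REFERENCE_LEVELS, drop_constant = TRUE)
      if (!is.null(B)) {
        B <- B[rows, , drop = FALSE]
        keep <- apply(B, 2, function(cc) stats::sd(cc) > 0)
        if (any(keep)) X <- cbind(X, B[, keep, drop = FALSE])
      }
    }
    if (stats::sd(score[rows]) > 0) {
      X <- drop_degenerate_indicators(X, event)
      sub$cox <- cox_fit_matrix(X, time, event)
      sub$estimable <- sub$cox$converged
    }
    sub$km <- km_estimate(time, event, as.character(score_groups[rows]))
    sub
  })
  names(per) <- levels(strat_labels)
  structure(list(stratifier = stratifier_name, score = score_name,
                 n = length(idx), tertiles = per),
            class = "tertile_survival_report")
}

#' Score-survival associations within stratifier tertiles
#'
#' Assigns population tertiles (T1/T2/T3) to the stratifier scores and
#' population tertiles (Lo/Mid/Hi) to the score, both over the FULL cohort;
#' then, within each stratifier tertile, reports (a) the logrank test
#' across the score's Lo/Mid/Hi groups restricted to that tertile and
#' (b) the covariate-adjusted Cox model of the continuous score.
#'
#' A stratifier strongly correlated with the score (Pearson `|r| > 0.5`)
#' is rejected: its tertiles would compress the score's distribution.
#'
#' @param cohort An aligned, follow-up-capped `cohort`.
#' @param stratifier_scores Per-sample stratifying scores (e.g. STRATsig or
#'   a single gene's expression).
#' @param score Per-sample prognostic score (e.g. CYTscore).
#' @param covariates Adjustment covariates (used when present in the
#'   clinical table).
#' @param stratifier_name,score_name Labels for reporting.
#' @return A `tertile_survival_report`: per-tertile `n`, `n_events`,
#'   logrank result, Cox result (score term first) and KM curves; a
#'   tertile with fewer than 2 events is marked non-estimable.
#' @export
evaluate_tertiles <- function(cohort, stratifier_scores, score,
                              covariates = c("age", "stage", "debulking"),
                              stratifier_name = "stratifier",
                              score_name = "score") {
  stopifnot(inherits(cohort, "cohort"))
  n <- ncol(cohort$expr)
  if (length(stratifier_scores) != n || length(score) != n)
    stop_constru("stratifier and score must have one value per sample")
  r <- stats::cor(stratifier_scores, score)
  if (is.finite(r) && abs(r) > 0.5)
    stop_constru("stratifier correlated with score (Pearson r = %.2f, |r| > 0.5); its tertiles would compress the score distribution", r)
  strat_labels <- assign_score_tertiles(stratifier_scores, "T")
  score_groups <- assign_score_tertiles(score, "LoMidHi")
  eval_tertiles_core(cohort, seq_len(n), strat_labels, score, score_groups,
                     covariates, stratifier_name, score_name)
}

#' @export
print.tertile_survival_report <- function(x, ...) {
  cat(sprintf("<tertile_survival_report: %s tertiles x %s, n = %d>\n",
              x$stratifier, x$score, x$n))
  for (tl in names(x$tertiles)) {
    s <- x$tertiles[[tl]]
    if (!s$estimable) {
      cat(sprintf("  %s: n = %d, events = %d (non-estimable)\n",
                  tl, s$n, s$n_events))
    } else {
      sc <- s$cox$terms[1L, ]
      cat(sprintf("  %s: n = %d, events = %d, score HR = %.3f (%.3f-%.3f), Wald p = %.3g%s\n",
                  tl, s$n, s$n_events, sc$hazard_ratio, sc$ci95_low,
                  sc$ci95_high, sc$wald_p,
                  if (!is.null(s$logrank))
                    sprintf(", logrank p = %.3g", s$logrank$p_value) else ""))
    }
  }
  invisible(x)
}

#' Tertile-conditional evaluation within covariate subgroups
#'
#' Runs the tertile evaluation within each subgroup (e.g. optimally
#' debulked cases, stage high, age below the cohort median), with the
#' stratifier and score tertiles inherited from the FULL cohort, never
#' recomputed inside a subgroup.  An empty subgroup is skipped with a
#' warning; the trivial all-samples subgroup reproduces
#' [evaluate_tertiles()] exactly.
#'
#' @inheritParams evaluate_tertiles
#' @param subgroup_specs Named list; each element is either a logical
#'   vector over samples or a one-argument function mapping the clinical
#'   table to such a vector.
#' @return Named list of `subgroup_report`s (`subgroup`, `n`, `report`).
#' @export
evaluate_subgroups <- function(cohort, stratifier_scores, score,
                               covariates = c("age", "stage", "debulking"),
                               subgroup_specs = list(),
                               stratifier_name = "stratifier",
                               score_name = "score") {
  stopifnot(inherits(cohort, "cohort"))
  n <- ncol(cohort$expr)
  r <- stats::cor(stratifier_scores, score)
  if (is.finite(r) && abs(r) > 0.5)
    stop_constru("stratifier correlated with score (Pearson r = %.2f, |r| > 0.5)", r)
  strat_labels <- assign_score_tertiles(stratifier_scores, "T")
  score_groups <- assign_score_tertiles(score, "LoMidHi")
  out <- list()
  for (nm in names(subgroup_specs)) {
    sel <- subgroup_specs[[nm]]
    if (is.function(sel)) {
      sel <- tryCatch(sel(cohort$clinical), error = function(e) NULL)
      if (is.null(sel)) {
        warning(sprintf("subgroup '%s' could not be evaluated; skipped", nm),
                call. = FALSE)
        next
      }
    }
    sel <- as.logical(sel)
    sel[is.na(sel)] <- FALSE
    if (length(sel) != n) {
      warning(sprintf("subgroup '%s' selector does not match the cohort; skipped",
                      nm), call. = FALSE)
      next
    }
    if (!any(sel)) {
      warning(sprintf("subgroup '%s' is empty; skipped", nm), call. = FALSE)
      next
    }
    rep_ <- eval_tertiles_core(cohort, which(sel), strat_labels, score,
                               score_groups, covariates, stratifier_name,
                               score_name)
    out[[nm]] <- structure(list(subgroup = nm, n = sum(sel), report = rep_),
                           class = "subgroup_report")
  }
  out
}

#' Standard covariate subgroup specifications
#'
#' Debulking optimal/suboptimal, stage high, and age dichotomized at
#' `age_cut` (cohort median when `NULL`).
#'
#' @param clinical A [clinical_table()].
#' @param age_cut Age cut in years, or `NULL` for the cohort median.
#' @return Named list of logical selectors for [evaluate_subgroups()].
#' @export
standard_subgroups <- function(clinical, age_cut = NULL) {
  out <- list()
  if ("debulking" %in% colnames(clinical)) {
    out[["debulking_optimal"]] <- clinical$debulking == "optimal"
    out[["debulking_suboptimal"]] <- clinical$debulking == "suboptimal"
  }
  if ("stage" %in% colnames(clinical))
    out[["stage_high"]] <- clinical$stage == "high"
  if ("age" %in% colnames(clinical) && !all(is.na(clinical$age))) {
    cut <- age_cut %||% stats::median(clinical$age, na.rm = TRUE)
    out[[sprintf("age_lt_%g", cut)]] <- clinical$age < cut
    out[[sprintf("age_ge_%g", cut)]] <- clinical$age >= cut
  }
  out
}

#' Per-gene survival screen with Benjamini-Hochberg control
#'
#' Fits a Cox model of each gene's (continuous) expression on survival —
#' univariable, or adjusted when `covariates` are supplied — over the
#' given samples (typically one stratifier tertile), adjusts the Wald
#' p-values by Benjamini-Hochberg across all estimable genes, and flags
#' genes with `hazard_ratio < hr_threshold` and adjusted p below
#' `fdr_alpha`.
#'
#' @param cohort An aligned `cohort`, already restricted to the samples of
#'   interest (e.g. via [subset_cohort()]).
#' @param hr_threshold Hazard-ratio flag threshold (default 0.80,
#'   protective genes).
#' @param fdr_alpha Adjusted-p flag threshold (default 0.01).
#' @param covariates Optional adjustment covariates; `NULL` for
#'   univariable fits.
#' @return Data frame (gene, hazard_ratio, p, adjusted_p, flagged), sorted
#'   by p; non-estimable genes are dropped and their count logged.
#' @export
gene_survival_screen <- function(cohort, hr_threshold = 0.80,
                                 fdr_alpha = 0.01, covariates = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  expr <- unclass(cohort$expr)
  time <- cohort$clinical$os_time
  event <- cohort$clinical$os_event
  base <- NULL
  if (!is.null(covariates)) {
    covdf <- scan_covariates(cohort, covariates)
    if (!is.null(covdf))
      base <- build_cox_design(covdf, REFERENCE_LEVELS, drop_constant = TRUE)
  }
  ng <- nrow(expr)
  hr <- p <- rep(NA_real_, ng)
  for (gi in seq_len(ng)) {
    x <- expr[gi, ]
    if (stats::sd(x) == 0) next
    X <- cbind(gene = x)
    if (!is.null(base)) X <- cbind(X, drop_degenerate_indicators(base, event, protect = integer()))
    fit <- cox_fit_matrix(X, time, event)
    if (fit$converged) {
      hr[gi] <- fit$terms$hazard_ratio[1L]
      p[gi] <- fit$terms$wald_p[1L]
    }
  }
  ok <- !is.na(p)
  if (any(!ok))
    constru_log("evaluation", "%d gene(s) non-estimable and dropped from the screen",
                sum(!ok))
  out <- data.frame(gene = rownames(expr)[ok], hazard_ratio = hr[ok],
                    p = p[ok], stringsAsFactors = FALSE)
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$hazard_ratio < hr_threshold & out$adjusted_p < fdr_alpha
  out[order(out$p), , drop = FALSE]
}

#' Restrict a cohort to a sample subset
#'
#' @param cohort A `cohort`.
#' @param samples Logical vector, integer indices, or sample IDs.
#' @return The restricted `cohort`.
#' @export
subset_cohort <- function(cohort, samples) {
  stopifnot(inherits(cohort, "cohort"))
  ids <- colnames(cohort$expr)
  keep <- if (is.character(samples)) ids %in% samples
          else if (is.logical(samples)) samples
          else seq_along(ids) %in% samples
  if (!any(keep)) stop_constru("empty sample subset")
  ex <- expression_matrix(unclass(cohort$expr)[, keep, drop = FALSE],
                          attr(cohort$expr, "feature_kind") %||% "gene")
  cl <- cohort$clinical[keep, , drop = FALSE]
  rownames(cl) <- NULL
  structure(list(expr = ex, clinical = cl, name = cohort$name),
            class = "cohort")
}
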