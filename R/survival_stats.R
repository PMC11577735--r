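# Survival-analysis primitives: multivariable Cox PH with Wald inference,
# logrank tests, Kaplan-Meier estimation, and the normality-gated two-sample
# location test.  Fitting is delegated to the survival package (Efron ties);
# this module owns design-matrix construction, convergence policy and the
# result contract the scan consumes.

# Build a Cox design matrix from a covariate data frame.  Numeric columns
# enter as-is; character/factor columns are expanded to indicator contrasts
# against a declared reference level, with missing values coded as an
# explicit "NA" level.  Indicator columns for levels absent from the data
# are dropped; a column that is constant after encoding is an error unless
# drop_constant = TRUE (used by the per-tertile scan, where e.g. all samples
# of a tertile may share one stage).
build_cox_design <- function(covariates, reference_levels = list(),
                             drop_constant = FALSE) {
  stopifnot(is.data.frame(covariates))
  cols <- list()
  for (nm in colnames(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      if (anyNA(v)) stop_constru("continuous covariate '%s' has missing values; impute upstream", nm)
      if (stats::sd(v) == 0) {
        if (drop_constant) next
        stop_constru("covariate '%s' is constant across samples", nm)
      }
      cols[[nm]] <- v
    } else {
      v <- as.character(v)
      v[is.na(v)] <- "NA"
      ref <- reference_levels[[nm]] %||% sort(unique(v))[1L]
      lev <- unique(c(ref, setdiff(sort(unique(v)), ref)))
      if (!ref %in% v)
        stop_constru("reference level '%s' of covariate '%s' absent from data", ref, nm)
      kept <- 0L
      for (l in setdiff(lev, ref)) {
        ind <- as.numeric(v == l)
        if (stats::sd(ind) == 0) next   # level absent (or universal) here
        cols[[paste0(nm, l)]] <- ind
        kept <- kept + 1L
      }
      if (kept == 0L && !drop_constant)
        stop_constru("covariate '%s' is constant across samples", nm)
    }
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

# Drop binary indicator columns that would force monotone likelihood: an
# indicator level with zero events among its carriers (or among the rest)
# carries no partial-likelihood information and sends its coefficient to
# +/- infinity.  Columns listed in `protect` are never dropped.
drop_degenerate_indicators <- function(x, event, protect = 1L) {
  keep <- rep(TRUE, ncol(x))
  for (j in setdiff(seq_len(ncol(x)), protect)) {
    v <- x[, j]
    if (all(v %in% c(0, 1))) {
      if (sum(event[v == 1]) == 0 || sum(event[v == 0]) == 0) keep[j] <- FALSE
    }
  }
  x[, keep, drop = FALSE]
}

# Core Cox fit on a prebuilt numeric design matrix; returns the cox_result
# contract.  Non-convergence and monotone-likelihood degeneracy are reported
# via converged = FALSE with inferential fields set to NA, never an error.
cox_fit_matrix <- function(x, time, event, ties = "efron",
                           control = survival::coxph.control()) {
  storage.mode(x) <- "double"
  y <- survival::Surv(as.double(time), as.double(event))
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                          control = control, weights = NULL, method = ties,
                          rownames = NULL)),
    error = function(e) NULL)
  terms <- colnames(x)
  n <- length(time)
  nev <- sum(event)
  bad <- function(msg = NA_character_) {
    structure(list(
      terms = data.frame(term = terms, coef = NA_real_, hazard_ratio = NA_real_,
                         se = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_,
                         wald_p = NA_real_, stringsAsFactors = FALSE),
      n = n, n_events = nev, converged = FALSE,
      log_partial_likelihood = NA_real_),
      class = "cox_result")
  }
  if (is.null(fit) || is.character(fit) || is.null(fit$coefficients)) return(bad())
  beta <- fit$coefficients
  var <- fit$var
  se <- sqrt(pmax(diag(as.matrix(var)), 0))
  converged <- all(is.finite(beta)) && all(is.finite(se)) && all(se > 0) &&
    max(abs(beta)) < 15 && fit$iter < control$iter.max
  if (!converged) return(bad())
  z <- beta / se
  res <- data.frame(
    term = terms,
    coef = unname(beta),
    hazard_ratio = exp(unname(beta)),
    se = unname(se),
    ci95_low = exp(unname(beta - 1.959963984540054 * se)),
    ci95_high = exp(unname(beta + 1.959963984540054 * se)),
    wald_p = clamp_p(2 * stats::pnorm(-abs(unname(z)))),
    stringsAsFactors = FALSE)
  structure(list(terms = res, n = n, n_events = nev, converged = TRUE,
                 log_partial_likelihood = fit$loglik[length(fit$loglik)]),
            class = "cox_result")
}

#' Fit a multivariable Cox proportional-hazards model
#'
#' Coefficients maximize the Cox partial likelihood with Efron handling of
#' tied event times (via the survival package).  Per-term inference is by
#' two-sided Wald test; 95% confidence intervals are `exp(beta +/- 1.96 se)`.
#' Categorical covariates (character or factor columns) are expanded to
#' indicator contrasts against a declared reference level, with missing
#' values coded as an explicit `"NA"` level.  Monotone likelihood or
#' non-convergence yields `converged = FALSE` with all inferential fields
#' `NA`, not an error.
#'
#' @param time Follow-up times (years).
#' @param event Event indicators, 0 = censored, 1 = event.
#' @param covariates Data frame of model terms; numeric columns are treated
#'   as continuous, character/factor columns as categorical.
#' @param reference_levels Named list giving the reference level of each
#'   categorical term; defaults to the alphabetically first level.
#' @param ties Tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return A `cox_result`: list with a per-term data frame (`term`, `coef`,
#'   `hazard_ratio`, `se`, `ci95_low`, `ci95_high`, `wald_p`), `n`,
#'   `n_events`, `converged`, `log_partial_likelihood`.
#' @examples
#' set.seed(1)
#' x <- rbinom(30, 1, 0.5)
#' t <- rexp(30, exp(0.8 * x))
#' fit_cox(t, rep(1, 30), data.frame(x = x))
#' @export
fit_cox <- function(time, event, covariates, reference_levels = list(),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(time) != length(event) || nrow(covariates) != length(time))
    stop_constru("time, event and covariates must have matching lengths")
  if (!all(event %in% c(0, 1))) stop_constru("event must be 0/1")
  if (sum(event) < 2) stop_constru("at least 2 events required for a Cox fit")
  if (!ncol(covariates)) stop_constru("at least one model term required")
  x <- build_cox_design(covariates, reference_levels)
  cox_fit_matrix(x, time, event, ties = ties)
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d, converged = %s\n",
              x$n, x$n_events, x$converged))
  print(x$terms, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Multi-group logrank test
#'
#' Standard (unweighted) logrank statistic across k groups, compared to a
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param time,event Survival times and 0/1 event indicators.
#' @param group Group labels (factor or character); every declared factor
#'   level must be non-empty.
#' @return List with `chi_square`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(time, event, group) {
  g <- if (is.factor(group)) group else factor(group)
  counts <- table(g)
  if (any(counts == 0))
    stop_constru("logrank group(s) empty after filtering: %s",
                 paste(names(counts)[counts == 0], collapse = ", "))
  if (nlevels(g) < 2) stop_constru("logrank test requires at least 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- nlevels(g) - 1L
  list(chi_square = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n_groups = nlevels(g))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event Survival times and 0/1 event indicators.
#' @param group Optional group labels for per-group curves.
#' @return A `km_estimate`: list of per-group data frames with columns
#'   `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (!length(time)) stop_constru("no samples")
  if (is.null(group)) group <- rep("all", length(time))
  g <- factor(group)
  out <- lapply(levels(g), function(l) {
    i <- g == l
    sf <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
               surv = sf$surv)
  })
  names(out) <- levels(g)
  structure(out, class = "km_estimate")
}

#' Two-sample location test gated on normality
#'
#' Runs a Shapiro-Wilk normality test on each sample at alpha = 0.05; if
#' both pass, compares the samples by two-sided Welch t-test, otherwise by
#' the two-sided Mann-Whitney (Wilcoxon) rank-sum test.
#'
#' @param x,y Numeric vectors of length >= 3.
#' @return List with `test_name` (`"t-test"` or `"mann-whitney"`),
#'   `statistic`, `p_value`, and the two Shapiro-Wilk p-values.
#' @export
compare_distributions <- function(x, y) {
  if (length(x) < 3 || length(y) < 3)
    stop_constru("each sample needs at least 3 observations")
  sw <- function(v) {
    if (length(v) > 5000) v <- v[seq_len(5000)]
    if (stats::sd(v) == 0) return(0)  # degenerate: clearly non-normal
    stats::shapiro.test(v)$p.value
  }
  px <- sw(x); py <- sw(y)
  if (px > 0.05 && py > 0.05) {
    tt <- stats::t.test(x, y)
    list(test_name = "t-test", statistic = unname(tt$statistic),
         p_value = tt$p.value, shapiro_p = c(x = px, y = py))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    list(test_name = "mann-whitney", statistic = unname(wt$statistic),
         p_value = wt$p.value, shapiro_p = c(x = px, y = py))
  }
}
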