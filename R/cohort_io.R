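# Cohort input/output: expression matrices, clinical tables, alignment,
# follow-up capping, probe collapsing.

#' Construct an expression matrix
#'
#' An expression matrix is a numeric matrix of log2-scale expression values
#' with feature identifiers (gene symbols or array probe IDs) as row names
#' and sample identifiers as column names.
#'
#' @param values Numeric matrix (features x samples) with row and column
#'   names set.
#' @param feature_kind Either `"gene"` or `"probe"`.
#' @return A matrix of class `expr_matrix` with a `feature_kind` attribute.
#' @export
expression_matrix <- function(values, feature_kind = c("gene", "probe")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop_constru("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || nrow(values) == 0L)
    stop_constru("expression matrix needs non-empty feature identifiers (row names)")
  if (is.null(colnames(values)))
    stop_constru("expression matrix needs sample identifiers (column names)")
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop_constru("duplicate sample identifier(s): %s",
                 paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values)))
    stop_constru("expression matrix contains non-finite values")
  structure(values, feature_kind = feature_kind,
            class = c("expr_matrix", class(values)))
}

#' Read an expression matrix from a delimited text file
#'
#' The file must be tab- or comma-delimited with a header row of sample IDs
#' and a first column of feature IDs.  Duplicate feature IDs are retained as
#' distinct rows (collapse them later with [collapse_probes()]); duplicate
#' sample IDs are an error.  Values are assumed to be on log2 scale; for
#' raw-scale inputs set `log2_offset` to apply `log2(x + log2_offset)`.
#'
#' @param path Path to the matrix file.
#' @param feature_kind `"gene"` or `"probe"`.
#' @param sep Field separator; guessed from the file extension/first line
#'   when `NULL`.
#' @param log2_offset If non-`NULL`, values are transformed by
#'   `log2(x + log2_offset)` after loading.
#' @param impute `"none"` (default, strict: any missing cell is an error) or
#'   `"gene_mean"` (missing cells replaced by the gene's mean across the
#'   samples where it is observed).
#' @return An [expression_matrix()].
#' @export
load_expression_matrix <- function(path, feature_kind = c("gene", "probe"),
                                   sep = NULL, log2_offset = NULL,
                                   impute = c("none", "gene_mean")) {
  feature_kind <- match.arg(feature_kind)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop_constru("expression file not found: %s", path)
  sep <- sep %||% guess_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", colClasses = "character")
  if (ncol(raw) < 2L) stop_constru("expression file has no sample columns: %s", path)
  feat <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop_constru("duplicate sample identifier(s) in header: %s",
                 paste(unique(dup), collapse = ", "))
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & !col %in% c("", "NA"))
    if (length(bad))
      stop_constru("non-numeric expression value '%s' at feature '%s', sample '%s'",
                   col[bad[1L]], feat[bad[1L]], samples[j])
    vals[, j] <- num
  }
  rownames(vals) <- feat
  if (anyNA(vals)) {
    if (impute == "none") {
      miss <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop_constru("missing expression value at feature '%s', sample '%s' (strict mode; use impute = 'gene_mean' to allow)",
                   feat[miss[1L]], samples[miss[2L]])
    }
    n_imp <- sum(is.na(vals))
    gm <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- gm[idx[, 1L]]
    constru_log("cohort_io", "imputed %d missing expression cells with per-gene means", n_imp)
  }
  if (!is.null(log2_offset)) {
    if (!is_scalar_number(log2_offset) || log2_offset < 0)
      stop_constru("log2_offset must be a non-negative number")
    vals <- log2(vals + log2_offset)
  }
  expression_matrix(vals, feature_kind)
}

guess_sep <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(",")
  if (ext %in% c("tsv", "txt", "tab")) return("\t")
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Write an expression matrix to a delimited text file
#'
#' @param expr An [expression_matrix()].
#' @param path Output path; `.csv` extension selects comma delimiting,
#'   anything else tab.
#' @param id_column Header for the feature-ID column.
#' @export
write_expression_matrix <- function(expr, path, id_column = "feature_id") {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' Requires columns `sample_id`, `os_time` (years), `os_event` (0/1);
#' optional `age` (years), `stage`, `debulking`.  Stage accepts
#' `low`/`high`/`NA`, or FIGO numerals (`I`,`II` -> low; `III`,`IV` -> high)
#' when `map_figo = TRUE`.  Debulking accepts `optimal`/`suboptimal`/`NA`.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator, guessed when `NULL`.
#' @param map_figo Map FIGO numerals to the low/high coding.
#' @return A `data.frame` of class `clinical_table`.
#' @export
load_clinical_table <- function(path, sep = NULL, map_figo = TRUE) {
  if (!file.exists(path)) stop_constru("clinical file not found: %s", path)
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = c("NA", ""))
  clinical_table(df, map_figo = map_figo)
}

#' Validate a clinical table
#'
#' @param df Data frame with at least `sample_id`, `os_time`, `os_event`.
#' @param map_figo Map FIGO numerals (I-IV) in `stage` to low/high.
#' @return The validated `data.frame` with class `clinical_table`.
#' @export
clinical_table <- function(df, map_figo = TRUE) {
  req <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop_constru("clinical table lacks required column(s): %s",
                 paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_constru("duplicate sample_id in clinical table: %s",
                 df$sample_id[duplicated(df$sample_id)][1L])
  df$os_time <- as.numeric(df$os_time)
  df$os_event <- as.numeric(df$os_event)
  bad_time <- !is.na(df$os_time) & df$os_time < 0
  if (any(bad_time))
    stop_constru("negative os_time for sample %s", df$sample_id[bad_time][1L])
  bad_ev <- !is.na(df$os_event) & !df$os_event %in% c(0, 1)
  if (any(bad_ev))
    stop_constru("os_event must be 0/1; offending sample %s", df$sample_id[bad_ev][1L])
  if ("age" %in% colnames(df)) df$age <- as.numeric(df$age)
  if ("stage" %in% colnames(df)) {
    st <- tolower(as.character(df$stage))
    if (map_figo) {
      st[st %in% c("i", "ii", "1", "2")] <- "low"
      st[st %in% c("iii", "iv", "3", "4")] <- "high"
    }
    bad <- !is.na(st) & !st %in% c("low", "high")
    if (any(bad))
      stop_constru("stage value '%s' not in {low, high, NA}", st[bad][1L])
    df$stage <- st
  }
  if ("debulking" %in% colnames(df)) {
    db <- tolower(as.character(df$debulking))
    bad <- !is.na(db) & !db %in% c("optimal", "suboptimal")
    if (any(bad))
      stop_constru("debulking value '%s' not in {optimal, suboptimal, NA}", db[bad][1L])
    df$debulking <- db
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table
#' @param clinical A `clinical_table`.
#' @param path Output path (`.csv` for comma delimiting, else tab).
#' @export
write_clinical_table <- function(clinical, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::write.table(as.data.frame(clinical), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Average multi-probe features into one row per gene
#'
#' Each gene's row becomes the arithmetic mean of its probes' log2 values,
#' per sample.  Probes absent from the mapping are passed through unchanged
#' (keyed by their probe ID) when `passthrough = TRUE`, otherwise dropped.
#'
#' @param expr An [expression_matrix()] with `feature_kind = "probe"`.
#' @param probe_to_gene Named character vector or two-column data frame
#'   (probe, gene) mapping probe IDs to gene symbols.
#' @param passthrough Keep unmapped probes under their own IDs.
#' @return An [expression_matrix()] with `feature_kind = "gene"`.
#' @export
collapse_probes <- function(expr, probe_to_gene, passthrough = TRUE) {
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene[[2L]]),
                           as.character(probe_to_gene[[1L]]))
  } else map <- probe_to_gene
  if (!length(map) && !passthrough)
    stop_constru("empty probe-to-gene mapping with pass-through disabled")
  probes <- rownames(expr)
  gene <- unname(map[probes])
  unmapped <- is.na(gene)
  if (any(unmapped) && passthrough) gene[unmapped] <- probes[unmapped]
  keep <- !is.na(gene)
  gene <- gene[keep]
  sub <- expr[keep, , drop = FALSE]
  out <- rowsum(unclass(sub), group = gene, reorder = FALSE) /
    as.vector(table(factor(gene, levels = unique(gene))))
  expression_matrix(out, feature_kind = "gene")
}

#' Join an expression matrix to clinical annotations
#'
#' Restricts both inputs to their shared sample IDs (in expression-matrix
#' order), drops samples lacking `os_time` or `os_event` (and samples with
#' `os_time` of exactly 0, whose survival contribution is undefined), and
#' reports every dropped sample.
#'
#' @param expr An [expression_matrix()].
#' @param clinical A [clinical_table()].
#' @param name Cohort label used in reports and output files.
#' @return A `cohort` object: list with elements `expr`, `clinical`, `name`
#'   and a `dropped` attribute naming excluded samples with reasons.
#' @export
align_cohort <- function(expr, clinical, name = "cohort") {
  shared <- intersect(colnames(expr), clinical$sample_id)
  if (!length(shared))
    stop_constru("no samples shared between expression matrix and clinical table")
  shared <- colnames(expr)[colnames(expr) %in% shared]
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  drop_na <- is.na(cl$os_time) | is.na(cl$os_event)
  drop_zero <- !drop_na & cl$os_time == 0
  reason <- character(nrow(cl))
  reason[drop_na] <- "missing os_time/os_event"
  reason[drop_zero] <- "os_time = 0"
  dropped <- data.frame(sample_id = cl$sample_id[drop_na | drop_zero],
                        reason = reason[drop_na | drop_zero],
                        stringsAsFactors = FALSE)
  not_in_clinical <- setdiff(colnames(expr), clinical$sample_id)
  if (nrow(dropped) || length(not_in_clinical))
    constru_log("cohort_io",
                "cohort '%s': dropped %d sample(s) (%d missing survival, %d zero time, %d without clinical record)",
                name, nrow(dropped) + length(not_in_clinical),
                sum(drop_na), sum(drop_zero), length(not_in_clinical))
  if (sum(drop_zero))
    warning(sprintf("cohort '%s': %d sample(s) with os_time = 0 dropped",
                    name, sum(drop_zero)), call. = FALSE)
  keep <- !(drop_na | drop_zero)
  cl <- cl[keep, , drop = FALSE]
  if (!nrow(cl)) stop_constru("no samples remain after dropping incomplete survival records")
  rownames(cl) <- NULL
  ex <- expr[, cl$sample_id, drop = FALSE]
  ex <- expression_matrix(unclass(ex), attr(expr, "feature_kind") %||% "gene")
  structure(list(expr = ex, clinical = cl, name = name),
            dropped = dropped, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s': %d features x %d samples, %d events>\n",
              x$name, nrow(x$expr), ncol(x$expr), sum(x$clinical$os_event)))
  invisible(x)
}

#' Apply an administrative follow-up horizon
#'
#' Samples observed beyond the horizon are censored at the horizon: their
#' `os_time` becomes the horizon and `os_event` 0.  The boundary is
#' inclusive — an event at exactly the horizon is retained as an event.
#'
#' @param clinical A [clinical_table()] or a `cohort`.
#' @param horizon_years Positive horizon (default 8 years).
#' @return Object of the same class with capped follow-up.
#' @export
cap_followup <- function(clinical, horizon_years = 8) {
  if (!is_scalar_number(horizon_years) || horizon_years <= 0)
    stop_constru("horizon_years must be a positive number")
  if (inherits(clinical, "cohort")) {
    clinical$clinical <- cap_followup(clinical$clinical, horizon_years)
    return(clinical)
  }
  over <- clinical$os_time > horizon_years
  clinical$os_event[over] <- 0
  clinical$os_time[over] <- horizon_years
  clinical
}
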