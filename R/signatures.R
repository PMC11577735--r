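# Gene-signature scoring: mean-log2, sum-of-z and difference signatures,
# built-in definitions (CYTscore, UpperT, LowerT, STRATsig, APM), and
# population-tertile assignment of scores.

#' Define a gene signature
#'
#' @param name Signature name.
#' @param genes Character vector of gene symbols (for `mean_log2` and
#'   `sum_z`).
#' @param method Scoring method: `"mean_log2"` (mean of log2 expression),
#'   `"sum_z"` (sum of per-gene cohort z-scores), or `"difference"`
#'   (positive signature score minus negative signature score).
#' @param positive,negative Component signatures for `method = "difference"`.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(name, genes = NULL,
                           method = c("mean_log2", "sum_z", "difference"),
                           positive = NULL, negative = NULL) {
  method <- match.arg(method)
  if (method == "difference") {
    if (!inherits(positive, "gene_signature") || !inherits(negative, "gene_signature"))
      stop_constru("difference signatures need two component gene_signature objects")
  } else {
    genes <- unique(as.character(genes))
    if (!length(genes)) stop_constru("signature '%s' has an empty gene list", name)
  }
  structure(list(name = name, genes = genes, method = method,
                 positive = positive, negative = negative),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  if (x$method == "difference")
    cat(sprintf("<gene_signature '%s': %s - %s>\n", x$name,
                x$positive$name, x$negative$name))
  else
    cat(sprintf("<gene_signature '%s' (%s, %d genes)>\n", x$name, x$method,
                length(x$genes)))
  invisible(x)
}

#' Read a signature file (one gene symbol per line, `#` comments allowed)
#' @param path File path.
#' @param name Signature name (defaults to the file name sans extension).
#' @param method Scoring method, see [gene_signature()].
#' @export
read_signature <- function(path, name = NULL,
                           method = c("mean_log2", "sum_z")) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  genes <- lines[nzchar(lines)]
  gene_signature(name %||% tools::file_path_sans_ext(basename(path)),
                 genes, match.arg(method))
}

#' Built-in signature definitions
#'
#' Ships the signatures the stratification workflow is built around:
#' `CYTscore` (cytolytic activity; mean log2 of GZMA and PRF1), `UpperT`
#' (13 genes), `LowerT` (27 genes), `STRATsig` (UpperT minus LowerT) and
#' `APM` (antigen-presentation machinery; sum of z-scores of 8 genes).
#' Gene symbols are the canonical keys; probe-level data should be
#' collapsed first with [collapse_probes()].
#'
#' @param name One of `"CYTscore"`, `"UpperT"`, `"LowerT"`, `"STRATsig"`,
#'   `"APM"`.
#' @return A [gene_signature()].
#' @export
builtin_signature <- function(name = c("CYTscore", "UpperT", "LowerT",
                                       "STRATsig", "APM")) {
  name <- match.arg(name)
  file_of <- function(n) system.file("extdata", "signatures",
                                     paste0(tolower(n), ".txt"),
                                     package = "constru", mustWork = TRUE)
  switch(name,
    CYTscore = read_signature(file_of("cytscore"), "CYTscore", "mean_log2"),
    UpperT = read_signature(file_of("uppert"), "UpperT", "mean_log2"),
    LowerT = read_signature(file_of("lowert"), "LowerT", "mean_log2"),
    APM = read_signature(file_of("apm"), "APM", "sum_z"),
    STRATsig = gene_signature("STRATsig", method = "difference",
                              positive = builtin_signature("UpperT"),
                              negative = builtin_signature("LowerT")))
}

match_signature_genes <- function(expr, signature, min_fraction) {
  present <- intersect(signature$genes, rownames(expr))
  missing <- setdiff(signature$genes, rownames(expr))
  if (!length(present))
    stop_constru("no genes of signature '%s' present in the matrix (missing: %s)",
                 signature$name, paste(signature$genes, collapse = ", "))
  if (length(present) < min_fraction * length(signature$genes))
    stop_constru("only %d/%d genes of signature '%s' present (below the %.0f%% floor; lower min_fraction to override). Missing: %s",
                 length(present), length(signature$genes), signature$name,
                 100 * min_fraction, paste(missing, collapse = ", "))
  if (length(missing))
    constru_log("signatures", "signature '%s': %d gene(s) absent and omitted: %s",
                signature$name, length(missing), paste(missing, collapse = ", "))
  list(present = present, missing = missing)
}

#' Score a signature on an expression matrix
#'
#' `mean_log2` signatures score each sample as the arithmetic mean of the
#' available signature genes' log2 values; absent genes are omitted and
#' reported (in the `missing_genes` attribute), with an error when fewer
#' than `min_fraction` of the list is present.  `sum_z` signatures z-score
#' each gene across the cohort's samples (population standard deviation)
#' and sum the z-scores per sample; a zero-variance signature gene is an
#' error.  `difference` signatures subtract the negative component's score
#' from the positive component's.
#'
#' @param expr An [expression_matrix()] (or any named numeric matrix,
#'   genes x samples).
#' @param signature A [gene_signature()].
#' @param min_fraction Minimum fraction of the gene list that must be
#'   present (default 0.5); set to 0 to score over whatever is available.
#' @return Named numeric vector of per-sample scores, with attribute
#'   `missing_genes`.
#' @export
score_signature <- function(expr, signature, min_fraction = 0.5) {
  stopifnot(inherits(signature, "gene_signature"))
  switch(signature$method,
         mean_log2 = score_mean_log2(expr, signature, min_fraction),
         sum_z = score_sum_z(expr, signature, min_fraction),
         difference = {
           pos <- score_signature(expr, signature$positive, min_fraction)
           neg <- score_signature(expr, signature$negative, min_fraction)
           out <- pos - neg
           miss <- union(attr(pos, "missing_genes"),
                         attr(neg, "missing_genes"))
           if (length(miss)) attr(out, "missing_genes") <- miss
           out
         })
}

#' @rdname score_signature
#' @export
score_mean_log2 <- function(expr, signature, min_fraction = 0.5) {
  m <- match_signature_genes(expr, signature, min_fraction)
  vals <- unclass(expr)[m$present, , drop = FALSE]
  out <- colMeans(vals)
  if (length(m$missing)) attr(out, "missing_genes") <- m$missing
  out
}

#' @rdname score_signature
#' @export
score_sum_z <- function(expr, signature, min_fraction = 0.5) {
  m <- match_signature_genes(expr, signature, min_fraction)
  vals <- unclass(expr)[m$present, , drop = FALSE]
  mu <- rowMeans(vals)
  # population (n-denominator) standard deviation, fixed for determinism
  sdp <- sqrt(rowMeans((vals - mu)^2))
  if (any(sdp == 0))
    stop_constru("zero-variance signature gene(s): %s",
                 paste(m$present[sdp == 0], collapse = ", "))
  out <- colSums((vals - mu) / sdp)
  if (length(m$missing)) attr(out, "missing_genes") <- m$missing
  out
}

#' STRATsig score: UpperT minus LowerT
#'
#' When one component is `NULL` (e.g. candidate selection returned an empty
#' set for that side), the score reduces to the other component alone, with
#' a logged note.
#'
#' @param expr An [expression_matrix()].
#' @param upperT,lowerT The component `mean_log2` signatures (defaults:
#'   the built-in 13-gene UpperT and 27-gene LowerT lists); one of the two
#'   may be `NULL`.
#' @param min_fraction See [score_signature()].
#' @return Per-sample STRATsig scores.
#' @export
score_stratsig <- function(expr, upperT = builtin_signature("UpperT"),
                           lowerT = builtin_signature("LowerT"),
                           min_fraction = 0.5) {
  if (is.null(upperT) && is.null(lowerT))
    stop_constru("STRATsig needs at least one component signature")
  if (is.null(upperT) || is.null(lowerT)) {
    have <- if (is.null(lowerT)) upperT else lowerT
    constru_log("signatures",
                "STRATsig: %s component absent; score is %s%s alone",
                if (is.null(upperT)) "UpperT" else "LowerT",
                if (is.null(upperT)) "-" else "", have$name)
    s <- score_signature(expr, have, min_fraction)
    return(if (is.null(upperT)) -s else s)
  }
  sig <- gene_signature("STRATsig", method = "difference",
                        positive = upperT, negative = lowerT)
  score_signature(expr, sig, min_fraction)
}

#' Assign population tertiles to signature scores
#'
#' Tertile labels are determined over all supplied scores (i.e. the full
#' cohort), via the same stable rule as [tertile_split()].
#'
#' @param scores Per-sample numeric scores.
#' @param label_style `"T"` for T1/T2/T3 (used for STRATsig) or
#'   `"LoMidHi"` for Lo/Mid/Hi (used for CYTscore).
#' @return Factor of per-sample tertile labels.
#' @export
assign_score_tertiles <- function(scores, label_style = c("T", "LoMidHi")) {
  label_style <- match.arg(label_style)
  labs <- if (label_style == "T") c("T1", "T2", "T3") else c("Lo", "Mid", "Hi")
  tertile_split(scores, labels = labs)$labels
}

#' Score several signatures and write a per-sample table
#'
#' @param expr An [expression_matrix()].
#' @param signatures Named list of [gene_signature()] objects.
#' @param tertiles Names of signatures for which tertile labels should be
#'   added (label style `"LoMidHi"` for CYTscore, `"T"` otherwise).
#' @param min_fraction See [score_signature()].
#' @return Data frame with `sample_id`, one score column per signature and
#'   one `<name>_tertile` column per requested tertile labelling.
#' @export
score_signature_set <- function(expr, signatures,
                                tertiles = names(signatures),
                                min_fraction = 0.5) {
  out <- data.frame(sample_id = colnames(expr), stringsAsFactors = FALSE)
  for (nm in names(signatures)) {
    s <- score_signature(expr, signatures[[nm]], min_fraction)
    out[[nm]] <- as.numeric(s)
    if (nm %in% tertiles) {
      style <- if (identical(nm, "CYTscore")) "LoMidHi" else "T"
      out[[paste0(nm, "_tertile")]] <-
        as.character(assign_score_tertiles(out[[nm]], style))
    }
  }
  out
}
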