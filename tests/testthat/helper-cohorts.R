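# Small cohort fixtures built in code.

# Minimal hand-built cohort (no simulator involvement) for io/eval tests.
make_tiny_cohort <- function(n = 60, n_genes = 10, seed = 1) {
  set.seed(seed)
  genes <- c("GZMA", "PRF1", sprintf("GENE%02d", seq_len(n_genes - 2)))
  expr <- matrix(rnorm(n_genes * n, mean = 8), n_genes, n,
                 dimnames = list(genes, sprintf("S%03d", seq_len(n))))
  clinical <- clinical_table(data.frame(
    sample_id = colnames(expr),
    os_time = round(runif(n, 0.2, 12), 3),
    os_event = rbinom(n, 1, 0.6),
    age = rnorm(n, 60, 8),
    stage = sample(c("low", "high"), n, replace = TRUE, prob = c(0.2, 0.8)),
    debulking = sample(c("optimal", "suboptimal"), n, replace = TRUE),
    stringsAsFactors = FALSE))
  suppressMessages(align_cohort(expression_matrix(expr, "gene"), clinical,
                                name = "tiny"))
}

# Proportional-hazards cohort where named genes act DIRECTLY on the hazard
# (continuous, not tertile-conditional) — used by the per-gene screen tests.
make_ph_cohort <- function(n = 600, n_genes = 50, seed = 1,
                           beta_genes = numeric(0)) {
  set.seed(seed)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  expr <- matrix(rnorm(n_genes * n, mean = 8), n_genes, n,
                 dimnames = list(genes, sprintf("S%04d", seq_len(n))))
  eta <- rep(0, n)
  for (nm in names(beta_genes))
    eta <- eta + beta_genes[[nm]] * (expr[nm, ] - mean(expr[nm, ]))
  t_event <- 9.6 * (-log(runif(n)) / exp(eta))^(1 / 1.2)
  cens <- pmin(10, runif(n, 1, 25))
  clinical <- clinical_table(data.frame(
    sample_id = colnames(expr),
    os_time = pmin(t_event, cens),
    os_event = as.numeric(t_event <= cens),
    stringsAsFactors = FALSE))
  suppressMessages(align_cohort(expression_matrix(expr, "gene"), clinical,
                                name = "ph"))
}

write_cohort_fixture <- function(cohort, dir) {
  suppressMessages(write_cohort(cohort, dir, prefix = "fix"))
}
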