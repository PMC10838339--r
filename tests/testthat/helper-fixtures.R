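# Small builders shared across test files.

# Named integer matrix from a vector, genes x samples.
make_counts <- function(values, n_genes, n_samples,
                        genes = sprintf("g%d", seq_len(n_genes)),
                        samples = sprintf("s%d", seq_len(n_samples))) {
  matrix(values, n_genes, n_samples, dimnames = list(genes, samples))
}

# Random all-positive count matrix.
random_positive_counts <- function(n_genes, n_samples) {
  make_counts(sample(1:200, n_genes * n_samples, replace = TRUE),
              n_genes, n_samples)
}

# Brute-force median-of-ratios, written directly from the defining formula
# (independent of the package implementation).
brute_force_size_factors <- function(m) {
  ref <- apply(m > 0, 1, all)
  stopifnot(any(ref))
  geo <- apply(m[ref, , drop = FALSE], 1, function(x) prod(x)^(1 / length(x)))
  vapply(seq_len(ncol(m)),
         function(j) median(m[ref, j] / geo), numeric(1))
}

# Brute-force transcription of the stratification rules.
brute_force_stratum <- function(s0, s14) {
  cum <- s0 + s14
  if (cum >= 6 && !(s0 < 2 || s14 < 2)) return("high")
  if (cum <= 4 && !(s0 > 3 || s14 > 3)) return("low")
  "intermediate"
}

# A tiny paired cohort: one sample per patient per week, expression set
# directly (values are already "normalized" for scoring purposes).
toy_cohort <- function(expr_by_gene, arms) {
  n_pat <- length(arms)
  patients <- sprintf("P%02d", seq_len(n_pat))
  design <- data.frame(
    sample_id = paste0(rep(patients, each = 2), "_w", rep(c(0L, 14L), n_pat)),
    patient_id = rep(patients, each = 2),
    arm = rep(arms, each = 2),
    week = rep(c(0L, 14L), n_pat),
    tissue = "terminal ileum")
  norm <- do.call(rbind, expr_by_gene)
  rownames(norm) <- names(expr_by_gene)
  colnames(norm) <- design$sample_id
  list(norm = norm, design = design, patients = patients)
}

# Adjusted Rand index between two labelings (independent implementation;
# used to score cluster recovery against planted truth).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
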