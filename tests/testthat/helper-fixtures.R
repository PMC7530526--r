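# Shared builders and independent oracles used across the suite.

# Printed per-biopsy derived columns of the reference cohort tables, frozen
# as the independent check that the raw counts and component scores in the
# fixtures regenerate them.
PRINTED <- list(
  fshd_quadriceps = list(
    proportion = c(0.00, 0.00, 0.30, 0.30, 1.46, 0.14, 0.73, 0.37, 0.00, 0.00,
                   0.00, 0.14, 0.35, 0.00, 0.13, 0.00, 0.00, 0.16, 0.13, 0.06,
                   0.07, 0.85, 0.70, 0.24, 0.38, 0.32, 0.49, 0.20, 0.12, 0.92,
                   0.57, 1.51, 4.95, 0.65),
    score = c(1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 3, 3, 3, 4, 4, 4,
              4, 4, 4, 5, 5, 5, 5, 6, 6, 6, 8, 10, 10, 10),
    score_no_nri = c(1, 1, 1, 2, 1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 3, 2, 3, 3, 4, 3,
                     4, 2, 3, 5, 5, 3, 3, 4, 5, 4, 7, 7, 9, 8)),
  fshd_tibialis = list(
    proportion = c(0.17, 0.00, 0.15, 0.23, 0.35, 0.51, 0.05, 1.50, 3.09, 3.47, 9.43),
    score = c(1, 2, 2, 3, 3, 5, 7, 8, 8, 9, 10),
    score_no_nri = c(0, 1, 2, 3, 3, 3, 6, 6, 5, 6, 8)),
  dm2 = list(
    proportion = c(0.49, 0.15, 0.18, 3.04, 3.24, 2.21, 0.34, 0.82, 0.72),
    score = c(4, 5, 5, 6, 7, 8, 8, 8, 10),
    score_no_nri = c(4, 5, 4, 5, 6, 7, 7, 6, 8))
)

extdata <- function(name) {
  system.file("extdata", name, package = "myoregen", mustWork = TRUE)
}

load_fixture_cohorts <- function() {
  list(fshd_quadriceps = load_biopsy_table(extdata("fshd_quadriceps.csv")),
       fshd_tibialis = load_biopsy_table(extdata("fshd_tibialis.csv")),
       dm2 = load_biopsy_table(extdata("dm2.csv")))
}

small_gene_set <- function(k = 20L) {
  gene_set("TESTSET", sprintf("TG%03d", seq_len(k)))
}

# Directly build a gene_matrix (bypassing collapse) for unit-level tests.
make_gene_matrix <- function(values, normalized = FALSE, group = NULL,
                             study_id = "gm") {
  structure(list(study_id = study_id, values = values, group = group,
                 normalized = normalized),
            class = "gene_matrix")
}

# Brute-force AUC: average over all case-control pairs, ties 0.5.
brute_auc <- function(scores, is_case) {
  ca <- scores[is_case]
  co <- scores[!is_case]
  wins <- outer(ca, co, function(a, b) (a > b) + 0.5 * (a == b))
  mean(wins)
}

# Monte-Carlo two-sided Mann-Whitney p by label permutation.
perm_wilcoxon_p <- function(case, control, n_perm = 20000L) {
  pooled <- c(case, control)
  n1 <- length(case)
  u_obs <- sum(rank(pooled)[seq_len(n1)])
  dev_obs <- abs(u_obs - n1 * (length(pooled) + 1) / 2)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), n1)
    u <- sum(rank(pooled)[idx])
    if (abs(u - n1 * (length(pooled) + 1) / 2) >= dev_obs - 1e-9) hits <- hits + 1L
  }
  hits / n_perm
}

# Exact two-sided Mann-Whitney p by full enumeration of case assignments.
enum_wilcoxon_p <- function(case, control) {
  pooled <- c(case, control)
  n1 <- length(case)
  r <- rank(pooled)
  centre <- n1 * (length(pooled) + 1) / 2
  dev_obs <- abs(sum(r[seq_len(n1)]) - centre)
  combs <- utils::combn(length(pooled), n1)
  devs <- abs(colSums(matrix(r[combs], nrow = n1)) - centre)
  mean(devs >= dev_obs - 1e-9)
}

# Chi-square upper tail for even df, closed form:
# P(X > x) = exp(-x/2) * sum_{j=0}^{df/2 - 1} (x/2)^j / j!
chisq_upper_even_df <- function(x, df) {
  k <- df / 2
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

# Hand-rolled quantile normalization oracle for tie-free columns.
qn_tie_free_oracle <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) ref[rank(col)])
}
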