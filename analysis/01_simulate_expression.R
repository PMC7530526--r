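#!/usr/bin/env Rscript
# Generates the synthetic multi-study expression corpus used by the
# transcriptomic arm: three case/control studies (two microarray with
# multi-probe platforms, one RNA-seq) carrying a moderate signature shift
# in cases, written in the TSV dialect the pipeline readers consume.
#
# Public expression studies are not redistributable here, so the corpus is
# simulated with known ground truth (effect size 1 on the log2 scale); the
# goal of this arm is validation of the pipeline's behaviour, not
# reproduction of any particular cohort's numbers.

suppressPackageStartupMessages(library(myoregen))

out_dir <- "results/sim_studies"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

gmt <- system.file("extdata", "hallmark_myogenesis_synthetic.gmt",
                   package = "myoregen", mustWork = TRUE)
signature <- read_gmt(gmt)[[1]]
cat(sprintf("signature: %s (%d genes)\n", signature$name, length(signature)))

configs <- list(
  list(id = "sim_array_a", platform = "microarray", n_case = 12, n_control = 10),
  list(id = "sim_array_b", platform = "microarray", n_case = 8, n_control = 8),
  list(id = "sim_rnaseq_c", platform = "rnaseq", n_case = 15, n_control = 12)
)

rows <- lapply(seq_along(configs), function(i) {
  cfg <- configs[[i]]
  st <- gen_expression_study(cfg$id, signature,
                             n_case = cfg$n_case, n_control = cfg$n_control,
                             n_genes = 1000, effect_delta = 1,
                             platform = cfg$platform, seed = 100 + i)
  cat(sprintf("%s: %d rows x %d samples (%s)\n", cfg$id, nrow(st$values),
              ncol(st$values), cfg$platform))
  write_expression_study(st, out_dir)
})
write_study_manifest(rows, file.path(out_dir, "manifest.tsv"))
cat(sprintf("manifest: %s\n", file.path(out_dir, "manifest.tsv")))
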