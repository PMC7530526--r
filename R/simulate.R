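#' Simulate a case/control expression study
#'
#' Generates one study with known ground truth, emulating the structure of
#' deposited dystrophy biopsy studies: log-normal expression, a case-group
#' shift confined to the signature genes, and either gene-keyed rows
#' (RNA-seq) or probe-level rows with a probe map (microarray).
#'
#' Per gene, a log2 baseline is drawn uniformly from
#' `baseline_mean_range`; each sample's log2 value adds `Normal(0,
#' noise_sd)` noise, and case samples add `effect_delta` on the gene-set
#' rows. Values are exponentiated back to intensity scale (`2^x`). In
#' microarray mode each gene expands into 1 or more probes (count drawn
#' uniformly from `probes_per_gene`) with probe-level `Normal(0,
#' probe_noise_sd)` log2 noise, and a probe map is emitted.
#'
#' @param study_id Study identifier.
#' @param gene_set A [gene_set()]; its genes occupy the first rows.
#' @param n_case,n_control Samples per group (default 10 each).
#' @param n_genes Total genes, at least `length(gene_set)` (default 1000).
#' @param effect_delta Log2-scale shift added to gene-set genes in cases
#'   (>= 0; default 0, the null).
#' @param baseline_mean_range Log2 baseline range (default `c(2, 12)`).
#' @param noise_sd Log2-scale biological + technical noise sd (default 1).
#' @param platform `"rnaseq"` (one row per gene) or `"microarray"`.
#' @param probes_per_gene Integer range of probes per gene for microarray
#'   mode (default `c(1, 4)`).
#' @param probe_noise_sd Probe-level log2 noise sd (default 0.25).
#' @param seed Integer seed; fully determines the output.
#' @return An [expression_study()].
#' @export
gen_expression_study <- function(study_id, gene_set, n_case = 10L,
                                 n_control = 10L, n_genes = 1000L,
                                 effect_delta = 0,
                                 baseline_mean_range = c(2, 12),
                                 noise_sd = 1,
                                 platform = c("rnaseq", "microarray"),
                                 probes_per_gene = c(1L, 4L),
                                 probe_noise_sd = 0.25,
                                 seed = NULL) {
  platform <- match.arg(platform)
  stopifnot(inherits(gene_set, "gene_set"))
  if (n_genes < length(gene_set)) {
    stop_fmt("n_genes (%d) must be >= gene set size (%d)",
             n_genes, length(gene_set))
  }
  if (effect_delta < 0 || noise_sd <= 0) {
    stop_fmt("effect_delta must be >= 0 and noise_sd > 0")
  }
  with_seed(seed, {
    genes <- c(gene_set$genes,
               sprintf("BG%04d", seq_len(n_genes - length(gene_set))))
    n <- n_case + n_control
    group <- c(rep("case", n_case), rep("control", n_control))
    samples <- sprintf("%s_s%02d", study_id, seq_len(n))
    baseline <- stats::runif(n_genes, baseline_mean_range[1], baseline_mean_range[2])
    logv <- baseline + matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n)
    in_set <- seq_len(length(gene_set))
    logv[in_set, group == "case"] <- logv[in_set, group == "case"] + effect_delta
    dimnames(logv) <- list(genes, samples)
    if (platform == "rnaseq") {
      expression_study(study_id, 2^logv, group, "rnaseq")
    } else {
      k <- sample(seq.int(probes_per_gene[1], probes_per_gene[2]),
                  n_genes, replace = TRUE)
      gi <- rep(seq_len(n_genes), k)
      probes <- sprintf("%s_p%d", genes[gi], sequence(k))
      pv <- logv[gi, , drop = FALSE] +
        matrix(stats::rnorm(length(gi) * n, sd = probe_noise_sd), length(gi), n)
      dimnames(pv) <- list(probes, samples)
      expression_study(study_id, 2^pv, group, "microarray",
                       probe_map = data.frame(probe_id = probes,
                                              gene_id = genes[gi],
                                              stringsAsFactors = FALSE))
    }
  })
}

#' Simulate a biopsy cohort with known regeneration structure
#'
#' Generates biopsy records that always satisfy the record invariants, with
#' a single latent severity variable driving the pathology components (which
#' are strongly inter-correlated in real cohorts) and, through
#' `latent_corr_rho`, the regeneration propensity:
#'
#' * latent severity `z ~ Normal(0, 1)` per subject;
#' * each 0-3 pathology component is a thresholded monotone function of a
#'   noisy copy of `z`; `necrosis` thresholds the NRI component;
#' * regeneration probability is
#'   `plogis(base_logit + muscle_effect * [tibialis] + rho * z)` and
#'   `dev_myhc_count ~ Binomial(fibre_count, probability)`;
#' * `fibre_count` is uniform over `fibre_count_range`.
#'
#' With `rho = 0` regeneration is independent of pathology (a null design
#' for the adjusted-correlation machinery); with `muscle_effect != 0` and
#' `rho = 0` muscle type is a pure confound, isolating what the adjustment
#' must remove.
#'
#' @param n Number of biopsies.
#' @param muscle_mix Fraction of quadriceps biopsies (default 0.75,
#'   mirroring a predominantly quadriceps cohort).
#' @param latent_corr_rho Strength linking latent severity to regeneration
#'   propensity, in `[-1, 1]`-ish logit units (default 0).
#' @param fibre_count_range Integer range of fibres per section (default
#'   `c(100, 2000)`).
#' @param base_logit Baseline log-odds of a fibre being Dev MyHC+ (default
#'   -5.5, about 0.4%).
#' @param muscle_effect Additional log-odds for tibialis anterior (default
#'   1.3).
#' @param component_noise_sd Noise sd on the per-component copies of `z`
#'   (default 0.6).
#' @param seed Integer seed; fully determines the output.
#' @return A data frame of valid biopsy records with the latent severity
#'   attached as attribute `"latent_z"`.
#' @export
gen_biopsy_cohort <- function(n, muscle_mix = 0.75, latent_corr_rho = 0,
                              fibre_count_range = c(100L, 2000L),
                              base_logit = -5.5, muscle_effect = 1.3,
                              component_noise_sd = 0.6, seed = NULL) {
  if (n < 1L) stop_fmt("n must be >= 1")
  if (abs(latent_corr_rho) > 1) stop_fmt("latent_corr_rho must be in [-1, 1]")
  with_seed(seed, {
    z <- stats::rnorm(n)
    muscle <- ifelse(stats::runif(n) < muscle_mix, "quadriceps",
                     "tibialis_anterior")
    # 0-3 components: monotone thresholding of noisy severity copies at the
    # standard-normal quartile-ish cutpoints
    comp <- function() {
      zz <- z + stats::rnorm(n, sd = component_noise_sd)
      findInterval(zz, c(-0.6, 0.45, 1.5))
    }
    fsv <- comp(); cn <- comp(); fib <- comp(); nri <- comp()
    fibre_count <- sample(seq.int(fibre_count_range[1], fibre_count_range[2]),
                          n, replace = TRUE)
    p <- stats::plogis(base_logit +
                         muscle_effect * (muscle == "tibialis_anterior") +
                         latent_corr_rho * z)
    dev <- stats::rbinom(n, fibre_count, p)
    recs <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      diagnosis = "FSHD1",
      sex = sample(c("M", "F"), n, replace = TRUE),
      age = sample(25:75, n, replace = TRUE),
      d4z4_kb = round(stats::runif(n, 10, 40)),
      muscle = muscle,
      dev_myhc_count = dev,
      fibre_count = fibre_count,
      fibre_size_variation = fsv,
      central_nuclei = cn,
      fibrosis = fib,
      nri = nri,
      necrosis = as.integer(nri >= 2),
      stringsAsFactors = FALSE)
    validate_biopsy_records(recs)
    attr(recs, "latent_z") <- z
    recs
  })
}

#' Write an expression study in the TSV dialect the readers consume
#'
#' Emits `<study_id>_matrix.tsv` (first column `row_id`, header = sample
#' ids), `<study_id>_annotation.tsv` (`sample_id`, `group`) and, for
#' microarray studies, `<study_id>_probe_map.tsv` (`probe_id`, `gene_id`)
#' under `dir`.
#'
#' @param study An [expression_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written (a manifest row).
#' @export
write_expression_study <- function(study, dir) {
  stopifnot(inherits(study, "expression_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, paste0(study$study_id, "_matrix.tsv"))
  apath <- file.path(dir, paste0(study$study_id, "_annotation.tsv"))
  mat <- data.frame(row_id = rownames(study$values), study$values,
                    check.names = FALSE)
  utils::write.table(mat, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(study$group),
                                group = unname(study$group)),
                     apath, sep = "\t", quote = FALSE, row.names = FALSE)
  ppath <- ""
  if (!is.null(study$probe_map)) {
    ppath <- file.path(dir, paste0(study$study_id, "_probe_map.tsv"))
    utils::write.table(study$probe_map, ppath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(study_id = study$study_id, platform = study$platform,
                 matrix = mpath, annotation = apath, probe_map = ppath))
}

#' Write a study manifest for a set of written studies
#'
#' @param rows List of manifest rows as returned by
#'   [write_expression_study()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_study_manifest <- function(rows, path) {
  man <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a biopsy cohort in the CSV dialect [load_biopsy_table()] consumes
#'
#' @param records Biopsy records.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_biopsy_table <- function(records, path) {
  utils::write.csv(records[BIOPSY_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
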