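#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# The cohort stands in for a family-structured population sample typed
# on a genome-wide SNP array: 1000 individuals x 2000 autosomal SNPs in
# HWE, mild two-population stratification, a handful of planted close
# relatives (duplicates and sib pairs), batch-structured missingness,
# and a clinical covariate panel whose lipid and blood-pressure traits
# carry a polygenic component, so the downstream risk-score phenotype
# is heritable through its biological inputs.
#
# Outputs: PLINK fileset + covariates + simulation truth under
# scratch/cohort/ (regenerated on every run), and a cohort summary
# under results/.

library(polyfrs)

seed <- 20260922L
dir.create("scratch/cohort", recursive = TRUE, showWarnings = FALSE)
dir.create("results", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_samples = 1000, n_snps = 2000,
                  maf_range = c(0.05, 0.5), h2_true = 0.5, n_causal = 400,
                  fst = 0.01, n_duplicate_pairs = 2, n_sib_pairs = 10,
                  missing_rate = 0.002, batch_missing_boost = 0.004,
                  seed = seed)
sim <- simulate_genotypes(cfg)
write_plink(sim$panel, "scratch/cohort/cohort")

covar <- simulate_covariates(cfg$n_samples, seed = seed,
                             panel = sim$panel, genetic_sd = 0.4)
write_pheno_table(covar, "scratch/cohort/covariates.tsv")
write_pheno_table(data.frame(sample_id = sim$panel$samples$sample_id,
                             batch = sim$panel$samples$batch),
                  "scratch/cohort/batches.tsv")
write_pheno_table(sim$truth$relative_pairs, "scratch/cohort/relatives.tsv")

summary_tab <- data.frame(
  quantity = c("n_samples", "n_snps", "n_duplicate_pairs", "n_sib_pairs",
               "missing_fraction", "fst"),
  value = c(cfg$n_samples, cfg$n_snps, cfg$n_duplicate_pairs,
            cfg$n_sib_pairs, round(mean(is.na(sim$panel$dosages)), 4),
            cfg$fst))
write.table(summary_tab, "results/01_cohort_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", cfg$n_samples, "samples x", cfg$n_snps, "SNPs;",
    nrow(sim$truth$relative_pairs), "planted relative pairs;",
    sprintf("%.2f%%", 100 * mean(is.na(sim$panel$dosages))),
    "missing genotypes.\n")
cat("Cohort written to scratch/cohort/, summary to results/01_cohort_summary.tsv\n")
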