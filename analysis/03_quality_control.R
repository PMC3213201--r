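#!/usr/bin/env Rscript
# Stage 3: two-tier quality control.
#
# The association/scoring arm uses the standard regime (sample and
# marker call rate 95%, MAF 0.01, HWE 1e-4, heterozygosity and IBS
# ancestry outliers at 3 SD, close relatives pruned subject-wise at
# PIHAT > 0.25). The heritability arm reruns QC under the stricter
# regime (99% sample call rate, HWE 0.05) but keeps relatives in the
# panel: the REML arm drops subjects at GRM > 0.025 later, while the
# Haseman-Elston arm only drops the offending *pairs*.

library(polyfrs)

panel <- read_plink("scratch/cohort/cohort")
batches <- read_pheno_table("scratch/cohort/batches.tsv")
panel$samples$batch <- batches$batch[match(panel$samples$sample_id,
                                           batches$sample_id)]

qc_g <- run_qc(panel, qc_config("gwas"))
write_plink(qc_g$panel, "scratch/cohort/cohort_qc_gwas")

qc_h <- run_qc(panel, qc_config("heritability"), prune_relatives = FALSE)
write_plink(qc_h$panel, "scratch/cohort/cohort_qc_her")

log_g <- qc_g$steps[, c("pass", "filter", "threshold", "n_removed")]
log_g$regime <- "gwas"
log_h <- qc_h$steps[, c("pass", "filter", "threshold", "n_removed")]
log_h$regime <- "heritability"
write.table(rbind(log_g, log_h), "results/03_qc_log.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("GWAS regime:", length(qc_g$keep_samples), "samples,",
    length(qc_g$keep_snps), "SNPs survive.\n")
print(qc_g)
cat("Heritability regime (relatives retained):",
    length(qc_h$keep_samples), "samples,",
    length(qc_h$keep_snps), "SNPs survive.\n")
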