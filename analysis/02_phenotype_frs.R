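#!/usr/bin/env Rscript
# Stage 2: construct the cardiovascular risk-score phenotype.
#
# Applies the published sex-specific coefficients to the clinical
# covariates: the phenotype is the linear predictor on log-transformed
# age, total cholesterol, HDL, SBP (treatment-specific coefficient),
# plus smoking and diabetes indicators. Mirrors the cohort rules: a
# block of subjects has HDL replaced by a donor-exam cohort mean, and
# scores are only assigned to subjects with complete predictors. The
# analysis phenotype is the log of the linear predictor.

library(polyfrs)

covar <- read_pheno_table("scratch/cohort/covariates.tsv",
                          schema = c(sample_id = "character",
                                     age = "numeric", total_chol = "numeric",
                                     hdl = "numeric", sbp = "numeric"))

# emulate the oldest enrollment wave lacking baseline HDL measurements:
# first 10% of subjects lose HDL, then receive the donor-cohort mean
n <- nrow(covar)
original_cohort <- seq_len(n %/% 10)
donor_hdl <- covar$hdl[-original_cohort]
covar$hdl[original_cohort] <- NA
covar <- impute_hdl_cohort_mean(covar, donor_hdl)

eligible <- eligible_subjects(covar)
frs <- compute_frs(covar[covar$sample_id %in% eligible, ])
frs$log_score <- as.numeric(log_risk_score(frs$linear_predictor))

write_pheno_table(frs, "scratch/cohort/pheno.tsv")
write.table(
  data.frame(quantity = c("n_scored", "n_hdl_imputed", "lp_mean", "lp_sd"),
             value = c(nrow(frs), sum(frs$hdl_imputed),
                       round(mean(frs$linear_predictor), 4),
                       round(sd(frs$linear_predictor), 4))),
  "results/02_phenotype_summary.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

cat("Scored", nrow(frs), "subjects (", sum(frs$hdl_imputed),
    "with donor-mean HDL ). Linear predictor mean",
    round(mean(frs$linear_predictor), 3), "SD",
    round(sd(frs$linear_predictor), 3), "\n")
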