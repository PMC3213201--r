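# Small in-code fixtures shared across test files.

# random panel with optional missingness, uniform 0/1/2 dosages
random_panel <- function(n, m, missing_rate = 0, seed = 1,
                         maf = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (missing_rate > 0) d[runif(n * m) < missing_rate] <- NA
  ids <- sprintf("T%03d", seq_len(n))
  genotype_panel(
    d,
    samples = data.frame(sample_id = ids, family_id = ids,
                         sex = rep_len(c("male", "female"), n),
                         batch = rep(c("A", "B"), c(ceiling(n / 2),
                                                    floor(n / 2)))),
    snps = data.frame(snp_id = sprintf("rs%04d", seq_len(m)),
                      chromosome = rep_len(1:22, m),
                      position = seq_len(m) * 100L,
                      a1 = "A", a2 = "G")
  )
}

# a complete covariate row set for the risk-score engine
tiny_covariates <- function() {
  data.frame(
    sample_id = c("a", "b"),
    sex = c("male", "female"),
    age = c(55, 50),
    total_chol = c(210, 200),
    hdl = c(45, 55),
    sbp = c(130, 120),
    bp_treated = c(0, 1),
    smoker = c(1, 0),
    diabetic = c(0, 1),
    stringsAsFactors = FALSE
  )
}

# independent Levene-Haldane enumeration: probability of every
# attainable heterozygote count from the closed-form counting formula
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hmax <- min(nA, na)
  h <- seq(hmax %% 2, hmax, by = 2)
  logp <- lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na - h) / 2 + 1) + h * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  prob <- exp(logp)
  obs <- prob[h == nAa]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# Deterministic 20-sample x 30-SNP QC fixture with planted violations:
#   S01 call rate 27/30; S02/S03 missing only at M28; S04=S05 duplicates;
#   S06 all-heterozygous at M01..M28; M28 low call rate (via S02/S03);
#   M29 monomorphic (MAF 0); M30 void of heterozygotes (HWE violation).
# Clean markers follow a rotation pattern giving every sample ~50%
# heterozygosity and every marker ~(5,10,5) genotype counts.
qc_fixture_panel <- function() {
  n <- 20L; m <- 30L
  d <- matrix(0L, n, m)
  for (i in 1:n) for (j in 1:28) {
    d[i, j] <- if ((i + j) %% 2 == 0) 1L
               else if ((i + j) %% 4 == 1) 0L else 2L
  }
  d[, 29] <- 0L
  d[, 30] <- ifelse(seq_len(n) %% 2 == 1, 0L, 2L)
  d[5, ] <- d[4, ]          # duplicate pair S04/S05
  d[6, 1:28] <- 1L          # heterozygosity outlier
  d[1, 24:26] <- NA         # S01 call rate 0.90
  d[2, 28] <- NA            # M28 call rate 18/20 -> 17/19 after S01 drop
  d[3, 28] <- NA
  ids <- sprintf("S%02d", 1:n)
  genotype_panel(
    d,
    samples = data.frame(sample_id = ids, family_id = ids,
                         sex = rep_len(c("male", "female"), n),
                         batch = rep(c("A", "B"), each = 10)),
    snps = data.frame(snp_id = sprintf("M%02d", 1:m),
                      chromosome = rep_len(1:22, m), position = 1:m * 50L,
                      a1 = "A", a2 = "B")
  )
}
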