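#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic cohort generator.
#' Defaults describe the study conditions the analyses assume: a
#' panmictic sample of unrelated individuals, biallelic autosomal SNPs
#' in Hardy-Weinberg equilibrium with a uniform allele-frequency
#' spectrum, a trait built from many small additive effects, and a low
#' background genotyping-failure rate.
#'
#' @param n_samples,n_snps panel dimensions.
#' @param maf_range ancestral allele-frequency range, drawn uniformly.
#' @param h2_true narrow-sense heritability of the simulated trait.
#' @param n_causal number of causal SNPs (`<= n_snps`); default 10%
#'   of the panel, the many-small-effects regime.
#' @param fst two-subpopulation divergence (Balding-Nichols); 0 means
#'   panmictic.
#' @param n_duplicate_pairs,n_sib_pairs planted close-relative pairs.
#' @param missing_rate per-genotype missingness probability.
#' @param batch_missing_boost extra missingness added for samples in
#'   batch `"B"` (genotyping-plate failure structure).
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500, n_snps = 1000,
                       maf_range = c(0.05, 0.5), h2_true = 0.5,
                       n_causal = max(1, round(n_snps / 10)), fst = 0,
                       n_duplicate_pairs = 0, n_sib_pairs = 0,
                       missing_rate = 0.01, batch_missing_boost = 0,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              maf_range = maf_range, h2_true = h2_true,
              n_causal = as.integer(n_causal), fst = fst,
              n_duplicate_pairs = as.integer(n_duplicate_pairs),
              n_sib_pairs = as.integer(n_sib_pairs),
              missing_rate = missing_rate,
              batch_missing_boost = batch_missing_boost,
              seed = as.integer(seed))
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] >= cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("maf_range must be an increasing pair inside (0, 0.5]")
  if (cfg$h2_true < 0 || cfg$h2_true > 1) stop("h2_true must be in [0, 1]")
  if (cfg$n_causal > cfg$n_snps) stop("n_causal exceeds n_snps")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$fst < 0) stop("fst must be non-negative")
  if (cfg$batch_missing_boost < 0) stop("batch_missing_boost must be >= 0")
  if (2 * (cfg$n_duplicate_pairs + cfg$n_sib_pairs) > cfg$n_samples)
    stop("too many relative pairs for n_samples")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genotype panel with known structure
#'
#' Per SNP an ancestral frequency is drawn uniformly from
#' `maf_range`; with `fst > 0` two subpopulation frequencies are drawn
#' from the Balding-Nichols distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` and samples are split evenly between
#' the two subpopulations. Genotypes are independent `Binomial(2, p)`
#' draws (HWE, no LD). Duplicate pairs share all genotypes; sib pairs
#' share each allele with probability 1/2 per locus independently
#' (expected relatedness 1/2). Missingness is Bernoulli, with the rate
#' for batch-"B" samples boosted by `batch_missing_boost`; samples
#' alternate between batches "A" and "B".
#'
#' @param config a [sim_config()].
#' @return list with `panel` (a [genotype_panel()]) and `truth` (a
#'   list with `subpop`, `relative_pairs`, and per-SNP generating
#'   frequencies `freq_by_subpop`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_snps

  p_anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  subpop <- rep_len(1:2, n)
  if (config$fst > 0) {
    f <- config$fst
    pf <- cbind(stats::rbeta(m, p_anc * (1 - f) / f,
                             (1 - p_anc) * (1 - f) / f),
                stats::rbeta(m, p_anc * (1 - f) / f,
                             (1 - p_anc) * (1 - f) / f))
    pf <- pmin(pmax(pf, 1e-4), 1 - 1e-4)
  } else {
    subpop <- rep(1L, n)
    pf <- cbind(p_anc, p_anc)
  }

  # allele-level simulation so relatives can share alleles
  pmat <- t(pf[, subpop, drop = FALSE])          # n x m per-sample freq
  a1 <- matrix(stats::rbinom(n * m, 1L, pmat), n, m)
  a2 <- matrix(stats::rbinom(n * m, 1L, pmat), n, m)

  rel <- list()
  idx <- 1L
  for (k in seq_len(config$n_duplicate_pairs)) {
    i <- idx; j <- idx + 1L; idx <- idx + 2L
    a1[j, ] <- a1[i, ]; a2[j, ] <- a2[i, ]
    rel[[length(rel) + 1L]] <- c(i, j, "duplicate")
  }
  for (k in seq_len(config$n_sib_pairs)) {
    i <- idx; j <- idx + 1L; idx <- idx + 2L
    share1 <- stats::runif(m) < 0.5
    share2 <- stats::runif(m) < 0.5
    a1[j, share1] <- a1[i, share1]
    a2[j, share2] <- a2[i, share2]
    rel[[length(rel) + 1L]] <- c(i, j, "sib")
  }
  dos <- a1 + a2

  # batch in two contiguous plates (not interleaved with sex, so batch
  # dummies stay independent of the sex covariate in small samples)
  batch <- rep(c("A", "B"), c(ceiling(n / 2), floor(n / 2)))
  if (config$missing_rate > 0 || config$batch_missing_boost > 0) {
    rate <- ifelse(batch == "B",
                   min(config$missing_rate + config$batch_missing_boost,
                       0.99),
                   config$missing_rate)
    mask <- matrix(stats::runif(n * m) < rate, n, m)
    dos[mask] <- NA_integer_
  }

  ids <- sprintf("S%04d", seq_len(n))
  samples <- data.frame(sample_id = ids, family_id = ids,
                        sex = rep_len(c("male", "female"), n),
                        batch = batch, stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                     chromosome = rep_len(1:22, m),
                     position = seq_len(m) * 1000L,
                     a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  panel <- genotype_panel(dos, samples, snps)

  truth <- list(
    subpop = stats::setNames(subpop, ids),
    relative_pairs = if (length(rel))
      data.frame(id1 = ids[as.integer(vapply(rel, `[`, "", 1L))],
                 id2 = ids[as.integer(vapply(rel, `[`, "", 2L))],
                 kind = vapply(rel, `[`, "", 3L),
                 stringsAsFactors = FALSE)
    else data.frame(id1 = character(), id2 = character(),
                    kind = character()),
    freq_by_subpop = pf, p_anc = p_anc
  )
  list(panel = panel, truth = truth)
}

#' Simulate an additive polygenic phenotype over a panel
#'
#' Causal SNPs are sampled uniformly; per-allele effects are drawn
#' `Normal(0, h2_true / n_causal)` on standardized genotypes so the
#' target heritability is frequency-independent; genetic values are
#' `g = Z beta` (`Z` the mean-imputed standardized dosage matrix) and
#' the residual is `Normal(0, 1 - h2_true)`.
#'
#' @param panel a [genotype_panel()].
#' @param h2_true target heritability in `[0, 1]`.
#' @param n_causal number of causal SNPs.
#' @param seed integer RNG seed.
#' @return list with `phenotype` (named vector), `causal_ids`,
#'   `effects` (named vector over causal SNPs), `g` (genetic values)
#'   and `h2_realized` (= var(g)/var(y) in this sample).
#' @export
simulate_phenotype <- function(panel, h2_true, n_causal, seed = 1L) {
  if (h2_true < 0 || h2_true > 1) stop("h2_true must be in [0, 1]")
  m <- ncol(panel$dosages)
  if (n_causal > m) stop("n_causal exceeds panel SNP count")
  set.seed(seed)
  causal <- sort(sample.int(m, n_causal))
  Z <- standardize_dosages(panel$dosages[, causal, drop = FALSE])
  beta <- stats::rnorm(n_causal, 0, sqrt(h2_true / n_causal))
  g <- drop(Z %*% beta)
  e <- if (h2_true < 1) stats::rnorm(nrow(Z), 0, sqrt(1 - h2_true)) else
    numeric(nrow(Z))
  y <- g + e
  names(y) <- panel$samples$sample_id
  list(phenotype = y,
       causal_ids = panel$snps$snp_id[causal],
       effects = stats::setNames(beta, panel$snps$snp_id[causal]),
       g = g,
       h2_realized = if (stats::var(y) > 0) stats::var(g) / stats::var(y)
                     else NA_real_)
}

#' Simulate a clinical covariate panel
#'
#' Generates the predictor set of the cardiovascular risk-score engine:
#' age ~ Uniform(30, 74); total cholesterol ~ Normal(200, 35)
#' truncated above 100 mg/dL; HDL ~ Normal(50, 13) truncated above 20;
#' systolic blood pressure ~ Normal(125, 17) truncated above 90 mmHg;
#' treatment and smoking ~ Bernoulli(0.2); diabetes ~ Bernoulli(0.08);
#' sex balanced. All log-transformed predictors are strictly positive.
#'
#' With `genetic_sd > 0` and a panel supplied, a polygenic component
#' (from 100 random SNPs) is added to total cholesterol, HDL and SBP,
#' scaled to `genetic_sd` standard deviations of each trait, so the
#' risk score itself carries heritable signal.
#'
#' @param n number of subjects.
#' @param seed integer RNG seed.
#' @param sample_ids optional ids (default `S0001...`).
#' @param panel optional [genotype_panel()] supplying genotypes for the
#'   heritable-covariate option.
#' @param genetic_sd size of the injected genetic component, in trait
#'   SDs (0 disables; covariates are then genetically inert).
#' @return data frame with columns `sample_id`, `sex`, `age`,
#'   `total_chol`, `hdl`, `sbp`, `bp_treated`, `smoker`, `diabetic`.
#' @export
simulate_covariates <- function(n, seed = 1L, sample_ids = NULL,
                                panel = NULL, genetic_sd = 0) {
  stopifnot(n >= 1)
  set.seed(seed + 7L)  # offset so covariates are independent of genotypes
  rtnorm <- function(n, mean, sd, lower) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(panel)) panel$samples$sample_id else
      sprintf("S%04d", seq_len(n))
  }
  tab <- data.frame(
    sample_id = sample_ids,
    sex = rep_len(c("male", "female"), n),
    age = stats::runif(n, 30, 74),
    total_chol = rtnorm(n, 200, 35, 100),
    hdl = rtnorm(n, 50, 13, 20),
    sbp = rtnorm(n, 125, 17, 90),
    bp_treated = stats::rbinom(n, 1, 0.2),
    smoker = stats::rbinom(n, 1, 0.2),
    diabetic = stats::rbinom(n, 1, 0.08),
    stringsAsFactors = FALSE
  )
  if (genetic_sd > 0) {
    if (is.null(panel)) stop("genetic_sd > 0 requires a genotype panel")
    m <- ncol(panel$dosages)
    snps <- sample.int(m, min(100L, m))
    Z <- standardize_dosages(panel$dosages[, snps, drop = FALSE])
    for (col in c("total_chol", "hdl", "sbp")) {
      b <- stats::rnorm(length(snps), 0, 1 / sqrt(length(snps)))
      gc <- drop(Z %*% b)
      gc <- gc / stats::sd(gc) * genetic_sd * stats::sd(tab[[col]])
      tab[[col]] <- pmax(tab[[col]] + gc, 1)  # keep log-safe
    }
  }
  tab
}
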