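#' Cross-validation fold plan
#'
#' Uniform random partition of the samples into K folds whose sizes
#' differ by at most one; deterministic under the seed. Each fold in
#' turn is a held-out test set, the rest the discovery set, so no
#' sample ever contributes to its own discovery scan.
#'
#' @param sample_ids character vector of ids.
#' @param K number of folds (default 10).
#' @param seed integer RNG seed.
#' @return named integer vector: fold assignment per sample id.
#' @export
make_folds <- function(sample_ids, K = 10L, seed = 1L) {
  n <- length(sample_ids)
  if (K < 2 || K > n) stop("K must be in [2, n]")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(K), n))
  stats::setNames(fold, sample_ids)
}

#' The ten p-value bins
#'
#' Half-open intervals (0, .1], (.1, .2], ..., (.9, 1] partitioning
#' (0, 1]: SNPs are grouped by discovery-scan p-value so that bins
#' with smaller p-values carry a higher ratio of true associations to
#' type-I errors.
#'
#' @param n_bins number of equal-width bins (default 10).
#' @return data frame with `bin` label, `lower`, `upper`.
#' @export
pvalue_bin_spec <- function(n_bins = 10L) {
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  data.frame(bin = sprintf("(%.1f,%.1f]", breaks[-length(breaks)],
                           breaks[-1]),
             lower = breaks[-length(breaks)],
             upper = breaks[-1],
             stringsAsFactors = FALSE)
}

#' Assign SNPs to p-value bins
#'
#' @param gwas a `gwas_result` (see [run_gwas()]).
#' @param spec a [pvalue_bin_spec()].
#' @return named list mapping bin label to character vector of snp
#'   ids; every SNP with a non-missing p lands in exactly one bin
#'   (upper-inclusive: p = 0.1 is in (0, .1]).
#' @export
bin_snps <- function(gwas, spec = pvalue_bin_spec()) {
  keep <- !is.na(gwas$p)
  idx <- cut(gwas$p[keep], breaks = c(spec$lower[1], spec$upper),
             labels = spec$bin, right = TRUE)
  split(gwas$snp_id[keep], idx)
}

#' Allele-weighted polygenic risk scores
#'
#' Each sample's score sums its effect-allele dosages weighted by the
#' discovery betas; by default the sum is averaged per observed allele
#' (score = sum / (2 * #SNPs used)), the convention of PLINK's scoring
#' routine. Missing genotypes either contribute twice the discovery
#' allele frequency (mean-imputation mode, default) or are skipped.
#'
#' @param panel the test-set [genotype_panel()].
#' @param weights data frame with `snp_id`, `effect_allele`, `beta`.
#'   SNPs absent from the panel are skipped (counted in the result).
#' @param discovery_freq named vector of discovery-set effect-allele
#'   frequencies (required for mean-imputation mode).
#' @param mean_impute replace missing dosages with `2 * freq`.
#' @param average divide by twice the number of scoring SNPs
#'   (otherwise raw sums).
#' @return data frame: `sample_id`, `score`, `n_snps_used`,
#'   `n_alleles_observed`; attribute `n_snps_absent`.
#' @export
score_samples <- function(panel, weights, discovery_freq = NULL,
                          mean_impute = TRUE, average = TRUE) {
  if (nrow(weights) == 0) stop("empty weight set")
  j <- match(weights$snp_id, panel$snps$snp_id)
  absent <- is.na(j)
  w <- weights[!absent, , drop = FALSE]
  j <- j[!absent]
  if (!length(j)) stop("no weight SNPs present in the panel")

  D <- panel$dosages[, j, drop = FALSE]
  flip <- w$effect_allele != panel$snps$a1[j]
  if (any(flip)) D[, flip] <- 2L - D[, flip]

  beta <- w$beta
  obs <- !is.na(D)
  n_alleles <- 2L * rowSums(obs)

  if (mean_impute) {
    if (is.null(discovery_freq))
      stop("mean_impute = TRUE requires discovery_freq")
    f <- discovery_freq[w$snp_id]
    if (anyNA(f)) stop("discovery_freq missing for some weight SNPs")
    imp <- matrix(rep(2 * f, each = nrow(D)), nrow(D))
    D2 <- D; D2[!obs] <- imp[!obs]
    raw <- drop(D2 %*% beta)
    denom <- 2 * length(beta)
    n_used <- rep(length(beta), nrow(D))
  } else {
    D2 <- D; D2[!obs] <- 0
    raw <- drop(D2 %*% beta)
    denom <- 2 * rowSums(obs)
    n_used <- rowSums(obs)
  }
  score <- if (average) raw / denom else raw
  out <- data.frame(sample_id = panel$samples$sample_id,
                    score = as.numeric(score),
                    n_snps_used = n_used,
                    n_alleles_observed = n_alleles,
                    stringsAsFactors = FALSE)
  attr(out, "n_snps_absent") <- sum(absent)
  out
}

# adjusted R^2 of a linear model fit by least squares
adj_r2 <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  n <- length(y); k <- ncol(as.matrix(X))
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Cross-validated p-value-binned polygenic prediction
#'
#' For each fold: an association scan on the discovery 90%, SNPs
#' binned by discovery p-value, and held-out samples scored per bin
#' with the discovery betas. Held-out scores are pooled across folds
#' and, per bin, the phenotype is regressed on the score (plus
#' `test_covariates` when supplied); the report carries the two-sided
#' p for the score coefficient and the adjusted R-squared attributable
#' to the score (full-model adjusted R-squared minus covariates-only,
#' floored at 0 for reporting).
#'
#' @param panel a QC'd [genotype_panel()].
#' @param phenotype named numeric vector.
#' @param covariates covariates for the discovery association scans
#'   (data frame aligned with panel samples), or NULL.
#' @param folds fold assignment from [make_folds()].
#' @param spec bin specification, default [pvalue_bin_spec()].
#' @param test_covariates covariates for the test-set regression
#'   (default none, the minimal reading of the design).
#' @param mean_impute,average passed to [score_samples()].
#' @return list of class `bin_score_report`: `pooled` (data frame
#'   `bin`, `n_snps` mean per fold, `p`, `adj_r2`), `per_fold`
#'   (per-fold bin detail), `scores` (pooled long table).
#' @export
evaluate_bins <- function(panel, phenotype, covariates = NULL, folds,
                          spec = pvalue_bin_spec(),
                          test_covariates = NULL,
                          mean_impute = TRUE, average = TRUE) {
  ids <- panel$samples$sample_id
  phenotype <- phenotype[ids]
  K <- max(folds)
  scores <- list()
  fold_counts <- matrix(0L, nrow = nrow(spec), ncol = K,
                        dimnames = list(spec$bin, NULL))

  for (k in seq_len(K)) {
    test_ids <- ids[folds[ids] == k]
    disc_ids <- setdiff(ids, test_ids)
    disc <- subset_panel(panel, sample_ids = disc_ids)
    test <- subset_panel(panel, sample_ids = test_ids)
    disc_cov <- if (!is.null(covariates))
      covariates[match(disc_ids, ids), , drop = FALSE] else NULL
    gwas <- run_gwas(disc, phenotype[disc_ids], disc_cov)
    bins <- bin_snps(gwas, spec)
    freqs <- stats::setNames(allele_freq(disc), disc$snps$snp_id)
    betas <- stats::setNames(gwas$beta, gwas$snp_id)
    for (b in spec$bin) {
      snp_set <- bins[[b]]
      fold_counts[b, k] <- length(snp_set)
      if (!length(snp_set)) next    # empty bin in this fold: no scores
      w <- data.frame(snp_id = snp_set,
                      effect_allele = panel$snps$a1[match(snp_set,
                                                          panel$snps$snp_id)],
                      beta = betas[snp_set],
                      stringsAsFactors = FALSE)
      sc <- score_samples(test, w, discovery_freq = freqs,
                          mean_impute = mean_impute, average = average)
      sc$bin <- b
      sc$fold <- k
      scores[[length(scores) + 1L]] <- sc
    }
  }
  scores <- do.call(rbind, scores)

  pooled <- spec["bin"]
  pooled$n_snps <- round(rowMeans(fold_counts))
  pooled$p <- NA_real_
  pooled$adj_r2 <- NA_real_
  per_fold <- list()
  for (i in seq_len(nrow(spec))) {
    b <- spec$bin[i]
    sb <- scores[scores$bin == b, , drop = FALSE]
    if (!nrow(sb)) next
    y <- phenotype[sb$sample_id]
    if (!is.null(test_covariates)) {
      C <- covariate_design(test_covariates[match(sb$sample_id, ids), ,
                                            drop = FALSE],
                            nrow(sb))[, -1, drop = FALSE]
      full <- stats::lm(y ~ sb$score + C)
      p <- summary(full)$coefficients["sb$score", 4]
      a2 <- adj_r2(y, cbind(sb$score, C)) - adj_r2(y, C)
    } else {
      full <- stats::lm(y ~ sb$score)
      p <- summary(full)$coefficients["sb$score", 4]
      a2 <- adj_r2(y, matrix(sb$score))
    }
    pooled$p[i] <- p
    pooled$adj_r2[i] <- max(a2, 0)
    # per-fold adjusted R^2 detail
    pf <- vapply(unique(sb$fold), function(k) {
      s <- sb[sb$fold == k, ]
      if (nrow(s) < 4) return(NA_real_)
      max(adj_r2(phenotype[s$sample_id], matrix(s$score)), 0)
    }, numeric(1))
    per_fold[[b]] <- data.frame(bin = b, fold = unique(sb$fold),
                                n_snps = fold_counts[b, unique(sb$fold)],
                                adj_r2 = pf, stringsAsFactors = FALSE)
  }
  structure(list(pooled = pooled,
                 per_fold = do.call(rbind, per_fold),
                 fold_counts = fold_counts,
                 scores = scores),
            class = "bin_score_report")
}

#' @export
print.bin_score_report <- function(x, ...) {
  cat("cross-validated polygenic score report\n")
  print(x$pooled, row.names = FALSE)
  invisible(x)
}
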