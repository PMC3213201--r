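#' Principal components of a genotype panel
#'
#' Genotypes are mean-imputed per SNP and standardized by
#' `sqrt(2 p (1-p))`; the per-sample coordinates are the top-K left
#' singular vectors of the standardized matrix scaled by their
#' singular values (computed via the eigendecomposition of the sample
#' covariance). Signs are fixed so each component's largest-magnitude
#' coordinate is positive. Constant SNPs are excluded with a warning.
#'
#' @param panel a QC'd [genotype_panel()].
#' @param K number of components (default 20).
#' @return list of class `pc_set`: `scores` (n x K matrix),
#'   `eigenvalues` (length K, decreasing), `K`.
#' @export
compute_pcs <- function(panel, K = 20L) {
  n <- nrow(panel$dosages)
  m <- ncol(panel$dosages)
  if (K >= min(n, m)) stop("K must be smaller than min(n, m)")
  maf <- minor_allele_freq(panel)
  const <- is.na(maf) | maf == 0
  if (any(const))
    warning(sum(const), " constant SNP(s) excluded from PCA")
  Z <- standardize_dosages(panel$dosages[, !const, drop = FALSE])
  if (K == 0L)
    return(structure(list(scores = matrix(0, n, 0), eigenvalues = numeric(),
                          K = 0L), class = "pc_set"))
  S <- tcrossprod(Z) / ncol(Z)
  eig <- eigen(S, symmetric = TRUE)
  lambda <- eig$values[seq_len(K)]
  U <- eig$vectors[, seq_len(K), drop = FALSE]
  scores <- sweep(U, 2, sqrt(pmax(lambda, 0) * ncol(Z)), "*")
  for (k in seq_len(K)) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("PC", seq_len(K))
  rownames(scores) <- panel$samples$sample_id
  structure(list(scores = scores, eigenvalues = lambda, K = as.integer(K)),
            class = "pc_set")
}

#' Per-SNP additive association scan
#'
#' Ordinary least squares of the phenotype on each SNP's A1 dosage
#' plus covariates, assuming an additive mode of inheritance. Samples
#' missing the phenotype or any covariate are dropped up front;
#' genotype missingness is handled by per-SNP casewise deletion. The
#' two-sided p comes from the t distribution with
#' `n_used - (#design columns + 1)` residual degrees of freedom.
#'
#' @param panel a [genotype_panel()].
#' @param phenotype numeric vector named by sample id (or aligned with
#'   the panel's sample order).
#' @param covariates optional data frame / matrix of covariates
#'   aligned with the panel samples (character columns become one-hot
#'   dummies, first level dropped). Include PC scores here to adjust
#'   for stratification.
#' @param n_perm if positive, also compute permutation p-values by
#'   residual permutation (`n_perm` phenotype-residual shuffles,
#'   per-SNP exceedance of |t|).
#' @return data frame of class `gwas_result`: `snp_id`, `chromosome`,
#'   `position`, `a1`, `beta`, `se`, `t_stat`, `p`, `n_used` (and
#'   `p_perm` when requested). SNPs with a rank-deficient design
#'   (e.g. constant dosage) carry NA statistics.
#' @export
run_gwas <- function(panel, phenotype, covariates = NULL, n_perm = 0L) {
  if (!is.null(names(phenotype)))
    phenotype <- phenotype[panel$samples$sample_id]
  n_all <- nrow(panel$dosages)
  X <- covariate_design(covariates, n_all)
  complete <- !is.na(phenotype) & stats::complete.cases(X)
  y <- phenotype[complete]
  X <- X[complete, , drop = FALSE]
  G <- panel$dosages[complete, , drop = FALSE]
  n <- length(y)
  p_cov <- ncol(X)
  if (n <= p_cov + 1) stop("too few complete samples for the design")

  qr_x <- qr(X)
  ry <- qr.resid(qr_x, y)

  m <- ncol(G)
  beta <- se <- tstat <- pval <- rep(NA_real_, m)
  n_used <- integer(m)

  miss_cnt <- colSums(is.na(G))
  full <- miss_cnt == 0L

  if (any(full)) {
    Gf <- G[, full, drop = FALSE]
    RG <- qr.resid(qr_x, Gf)
    sxx <- colSums(RG^2)
    sxy <- drop(crossprod(RG, ry))
    syy <- sum(ry^2)
    df <- n - p_cov - 1L
    ok <- sxx > 1e-10
    b <- ifelse(ok, sxy / sxx, NA_real_)
    rss <- pmax(syy - b^2 * sxx, 0)   # exact fits: clamp rounding below 0
    s2 <- rss / df
    semod <- sqrt(s2 / sxx)
    tv <- b / semod
    beta[full] <- ifelse(ok, b, NA_real_)
    se[full] <- ifelse(ok, semod, NA_real_)
    tstat[full] <- ifelse(ok, tv, NA_real_)
    pval[full] <- ifelse(ok, 2 * stats::pt(abs(tv), df, lower.tail = FALSE),
                         NA_real_)
    n_used[full] <- n
  }
  for (j in which(!full)) {
    obs <- !is.na(G[, j])
    nj <- sum(obs)
    dfj <- nj - p_cov - 1L
    if (dfj < 1) next
    D <- cbind(X[obs, , drop = FALSE], g = G[obs, j])
    fit <- stats::lm.fit(D, y[obs])
    if (fit$rank < ncol(D)) next    # rank-deficient: skip with NA flag
    rssj <- sum(fit$residuals^2)
    XtXinv_gg <- chol2inv(chol(crossprod(D)))[ncol(D), ncol(D)]
    bj <- fit$coefficients["g"]
    sej <- sqrt(rssj / dfj * XtXinv_gg)
    beta[j] <- bj; se[j] <- sej; tstat[j] <- bj / sej
    pval[j] <- 2 * stats::pt(abs(bj / sej), dfj, lower.tail = FALSE)
    n_used[j] <- nj
  }

  res <- data.frame(snp_id = panel$snps$snp_id,
                    chromosome = panel$snps$chromosome,
                    position = panel$snps$position,
                    a1 = panel$snps$a1,
                    beta = beta, se = se, t_stat = tstat, p = pval,
                    n_used = n_used, stringsAsFactors = FALSE)

  if (n_perm > 0L) {
    # residual permutation (Freedman-Lane style) on the fully observed SNPs
    RGall <- qr.resid(qr_x, apply(G, 2, function(g) {
      g[is.na(g)] <- mean(g, na.rm = TRUE); g
    }))
    sxx <- colSums(RGall^2)
    exceed <- rep(1L, m)   # +1 smoothing
    tobs <- abs(tstat)
    for (b in seq_len(n_perm)) {
      ryp <- sample(ry)
      bp <- drop(crossprod(RGall, ryp)) / sxx
      rssp <- sum(ryp^2) - bp^2 * sxx
      tp <- abs(bp / sqrt(rssp / (n - p_cov - 1L) / sxx))
      exceed <- exceed + (tp >= tobs)
    }
    res$p_perm <- exceed / (n_perm + 1L)
  }
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' Genomic inflation factor
#'
#' Median of the 1-df chi-square quantiles of the p-values divided by
#' the null median 0.4549364 (`qchisq(0.5, 1)`).
#'
#' @param pvalues numeric vector of p-values.
#' @return lambda, a single number (1 under the null).
#' @export
genomic_lambda <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  chisq <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Genome-wide significant hits and the top-10 list
#'
#' @param result a `gwas_result`.
#' @param threshold genome-wide significance threshold (default 5e-8).
#' @return list with `hits` (SNPs below threshold, ascending p) and
#'   `top10` (ten smallest p regardless of threshold); ties broken by
#'   snp_id.
#' @export
significant_hits <- function(result, threshold = 5e-8) {
  res <- result[!is.na(result$p), , drop = FALSE]
  ord <- order(res$p, res$snp_id)
  res <- res[ord, , drop = FALSE]
  list(hits = res[res$p < threshold, , drop = FALSE],
       top10 = utils::head(res, 10L))
}

#' Q-Q plot coordinates for association p-values
#'
#' @param pvalues numeric p-values.
#' @return data frame of expected vs observed -log10(p), ready for
#'   plotting.
#' @export
qq_table <- function(pvalues) {
  p <- sort(pvalues[!is.na(pvalues)])
  data.frame(expected = -log10(stats::ppoints(length(p))),
             observed = -log10(p))
}
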