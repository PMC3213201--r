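#' Quality-control configuration and presets
#'
#' Two named presets reproduce the study's threshold sets:
#' `"gwas"` (sample call rate 0.95, marker call rate 0.95, MAF 0.01,
#' HWE p 1e-4, subject removal above relatedness 0.25) and
#' `"heritability"` (sample call rate 0.99, HWE p 0.05, subject /
#' pairwise relatedness threshold 0.025).
#'
#' @param preset `"gwas"` or `"heritability"`, or NULL for bare
#'   defaults.
#' @param ... overrides for individual thresholds:
#'   `sample_call_rate_min`, `marker_call_rate_min`, `maf_min`,
#'   `hwe_p_min`, `het_sd_limit`, `ibs_sd_limit`,
#'   `relatedness_subject_max`, `relatedness_pair_max`.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(preset = c("gwas", "heritability"), ...) {
  preset <- match.arg(preset)
  cfg <- list(sample_call_rate_min = 0.95,
              marker_call_rate_min = 0.95,
              maf_min = 0.01,
              hwe_p_min = 1e-4,
              het_sd_limit = 3,
              ibs_sd_limit = 3,
              relatedness_subject_max = 0.25,
              relatedness_pair_max = 0.025,
              preset = preset)
  if (preset == "heritability") {
    cfg$sample_call_rate_min <- 0.99
    cfg$hwe_p_min <- 0.05
    cfg$relatedness_subject_max <- 0.025
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown qc_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "qc_config")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, the
#' heterozygote count follows the Levene-Haldane distribution; the
#' p-value is the total probability of all heterozygote counts whose
#' probability does not exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype count")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("all genotype counts are zero")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1.0)  # monomorphic: single configuration
  # attainable heterozygote counts share the parity of the allele count
  hmax <- min(nA, na)
  h <- seq.int(hmax %% 2L, hmax, by = 2L)
  # log Pr(h) up to a constant: n! 2^h / ((nA-h)/2)! h! ((na-h)/2)!
  logp <- h * log(2) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na - h) / 2 + 1)
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  obs <- which(h == n_Aa)
  if (!length(obs)) stop("inconsistent genotype counts")
  sum(prob[prob <= prob[obs] * (1 + 1e-12)])
}

# HWE p-values for every marker of a panel
hwe_pvalues <- function(panel) {
  d <- panel$dosages
  nAA <- colSums(d == 2L, na.rm = TRUE)
  nAa <- colSums(d == 1L, na.rm = TRUE)
  naa <- colSums(d == 0L, na.rm = TRUE)
  vapply(seq_len(ncol(d)),
         function(j) hwe_exact_test(nAA[j], nAa[j], naa[j]),
         numeric(1))
}

#' Marker-level QC filters
#'
#' Removes a marker iff its call rate, minor allele frequency or exact
#' HWE p-value falls strictly below the configured threshold; removals
#' are attributed to the first failing filter in that order. Call
#' rates are computed over the panel's current samples, MAF from
#' non-missing dosages.
#'
#' @param panel a [genotype_panel()].
#' @param config a [qc_config()].
#' @return list with `keep_snps`, and `steps` (a data frame logging
#'   per-filter threshold, count and removed ids).
#' @export
marker_filters <- function(panel, config) {
  cr <- per_marker_call_rate(panel)
  maf <- minor_allele_freq(panel)
  maf[is.na(maf)] <- 0
  hwe <- hwe_pvalues(panel)
  fail_cr <- cr < config$marker_call_rate_min
  fail_maf <- !fail_cr & maf < config$maf_min
  fail_hwe <- !fail_cr & !fail_maf & hwe < config$hwe_p_min
  ids <- panel$snps$snp_id
  steps <- data.frame(
    filter = c("marker_call_rate", "maf", "hwe"),
    threshold = c(config$marker_call_rate_min, config$maf_min,
                  config$hwe_p_min),
    n_removed = c(sum(fail_cr), sum(fail_maf), sum(fail_hwe)),
    removed = I(list(ids[fail_cr], ids[fail_maf], ids[fail_hwe])),
    stringsAsFactors = FALSE
  )
  list(keep_snps = ids[!(fail_cr | fail_maf | fail_hwe)], steps = steps)
}

#' Sample-level call-rate and heterozygosity filters
#'
#' First removes samples whose genotyping rate is below the threshold;
#' then, on the survivors, computes the per-sample heterozygosity rate
#' (fraction of non-missing genotypes that are heterozygous) and
#' removes samples more than `het_sd_limit` standard deviations from
#' the survivor mean (two-sided). A zero standard deviation flags
#' nobody; fewer than 3 survivors skips the heterozygosity filter with
#' a warning.
#'
#' @inheritParams marker_filters
#' @return list with `keep_samples` and `steps`.
#' @export
sample_filters <- function(panel, config) {
  cr <- per_sample_call_rate(panel)
  fail_cr <- cr < config$sample_call_rate_min
  ids <- panel$samples$sample_id
  surv <- !fail_cr

  fail_het <- rep(FALSE, length(ids))
  if (sum(surv) < 3) {
    warning("fewer than 3 samples after call-rate filter; ",
            "heterozygosity filter skipped")
  } else {
    d <- panel$dosages[surv, , drop = FALSE]
    het <- rowSums(d == 1L, na.rm = TRUE) / rowSums(!is.na(d))
    s <- stats::sd(het)
    if (is.finite(s) && s > 0) {
      z <- (het - mean(het)) / s
      fail_het[surv] <- abs(z) > config$het_sd_limit
    }
  }
  steps <- data.frame(
    filter = c("sample_call_rate", "heterozygosity"),
    threshold = c(config$sample_call_rate_min, config$het_sd_limit),
    n_removed = c(sum(fail_cr), sum(fail_het)),
    removed = I(list(ids[fail_cr], ids[fail_het])),
    stringsAsFactors = FALSE
  )
  list(keep_samples = ids[!(fail_cr | fail_het)], steps = steps)
}

# per-SNP IBS-state expectations given IBD state, as functions of the
# A1 frequency -- the method-of-moments machinery behind PIHAT
ibs_expectations <- function(p) {
  q <- 1 - p
  list(e0_z0 = 2 * p^2 * q^2,
       e1_z0 = 4 * p^3 * q + 4 * p * q^3,
       e2_z0 = p^4 + q^4 + 4 * p^2 * q^2,
       e1_z1 = 2 * p^2 * q + 2 * p * q^2,
       e2_z1 = p^3 + q^3 + p^2 * q + p * q^2)
}

#' Method-of-moments IBD sharing (PIHAT) for all sample pairs
#'
#' From per-pair identity-by-state counts and panel allele
#' frequencies, solves the moment equations for the IBD-state
#' probabilities (Z0, Z1, Z2), clamps them to the probability simplex
#' and returns `PIHAT = Z1/2 + Z2` for every pair. Pairs with fewer
#' than `min_joint` jointly non-missing SNPs get `NA` with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param min_joint minimum jointly non-missing SNP count per pair.
#' @return symmetric n x n matrix of PIHAT values (diagonal `NA`).
#' @export
pihat_matrix <- function(panel, min_joint = 50L) {
  d <- panel$dosages
  G0 <- (!is.na(d) & d == 0L) + 0
  G1 <- (!is.na(d) & d == 1L) + 0
  G2 <- (!is.na(d) & d == 2L) + 0
  M <- G0 + G1 + G2

  nIBS0 <- G0 %*% t(G2) ; nIBS0 <- nIBS0 + t(nIBS0)
  nIBS1 <- G0 %*% t(G1) + G1 %*% t(G2)
  nIBS1 <- nIBS1 + t(nIBS1)
  nIBS2 <- tcrossprod(G0) + tcrossprod(G1) + tcrossprod(G2)
  njoint <- tcrossprod(M)

  p <- allele_freq(panel)
  e <- ibs_expectations(p)
  wsum <- function(w) {
    W <- tcrossprod(sweep(M, 2, w, "*"), M)
    (W + t(W)) / 2
  }
  E0z0 <- wsum(e$e0_z0); E1z0 <- wsum(e$e1_z0); E2z0 <- wsum(e$e2_z0)
  E1z1 <- wsum(e$e1_z1); E2z1 <- wsum(e$e2_z1)

  z0 <- nIBS0 / E0z0
  z1 <- (nIBS1 - z0 * E1z0) / E1z1
  z2 <- (nIBS2 - z0 * E2z0 - z1 * E2z1) / njoint
  # clamp to the simplex
  z0 <- pmin(pmax(z0, 0), 1)
  z1 <- pmin(pmax(z1, 0), 1 - z0)
  z2 <- pmin(pmax(z2, 0), 1 - z0 - z1)
  tot <- z0 + z1 + z2
  pihat <- (z1 / 2 + z2) / tot

  few <- njoint < min_joint
  diag(few) <- TRUE
  if (any(few & upper.tri(few)))
    warning(sum(few & upper.tri(few)),
            " pair(s) with fewer than ", min_joint,
            " joint SNPs: PIHAT undefined")
  pihat[few] <- NA_real_
  diag(pihat) <- NA_real_
  dimnames(pihat) <- list(panel$samples$sample_id, panel$samples$sample_id)
  pihat
}

#' @rdname pihat_matrix
#' @param pair length-2 vector of sample ids.
#' @return `estimate_pihat`: a single PIHAT value.
#' @export
estimate_pihat <- function(panel, pair, min_joint = 50L) {
  ph <- pihat_matrix(panel, min_joint = min_joint)
  ph[pair[1], pair[2]]
}

#' Greedy subject-wise pruning of close relatives
#'
#' While any pair exceeds the relatedness threshold, removes the
#' individual participating in the most over-threshold pairs (ties
#' broken by the lexicographically smallest id); the remaining graph
#' has no edge above the threshold.
#'
#' @param relmat symmetric relatedness matrix with sample ids as
#'   dimnames (PIHAT or GRM entries; `NA` entries are ignored).
#' @param threshold pairs strictly above this are edges.
#' @return character vector of removed sample ids (possibly empty).
#' @export
prune_relatives_subjectwise <- function(relmat, threshold) {
  ids <- rownames(relmat)
  adj <- !is.na(relmat) & relmat > threshold
  diag(adj) <- FALSE
  removed <- character()
  alive <- rep(TRUE, nrow(adj))
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (all(deg == 0)) break
    cand <- which(deg == max(deg))
    victim <- cand[order(ids[cand])][1]
    removed <- c(removed, ids[victim])
    alive[victim] <- FALSE
    adj[victim, ] <- FALSE
    adj[, victim] <- FALSE
  }
  removed
}

#' Ancestry outliers by mean identity-by-state distance
#'
#' Each sample's statistic is its mean IBS distance
#' (`1 - shared alleles / 2`, averaged over jointly non-missing SNPs)
#' to all other samples; samples more than `sd_limit` SDs *above* the
#' mean (one-sided: only unusually distant samples are ancestry
#' outliers) are flagged.
#'
#' @param panel a [genotype_panel()].
#' @param sd_limit z-score cutoff.
#' @return character vector of flagged sample ids.
#' @export
ibs_ancestry_outliers <- function(panel, sd_limit = 3) {
  n <- nrow(panel$dosages)
  if (n < 3) stop("need at least 3 samples for IBS outlier detection")
  d <- panel$dosages
  ok <- (!is.na(d)) + 0
  # sum over joint SNPs of |x_i - x_j| via the 0/1/2 indicator trick
  G0 <- (!is.na(d) & d == 0L) + 0
  G1 <- (!is.na(d) & d == 1L) + 0
  G2 <- (!is.na(d) & d == 2L) + 0
  absdiff <- G0 %*% t(G1) + G1 %*% t(G0) + G1 %*% t(G2) + G2 %*% t(G1) +
    2 * (G0 %*% t(G2) + G2 %*% t(G0))
  njoint <- tcrossprod(ok)
  dist <- (absdiff / 2) / njoint          # in [0, 1]
  diag(dist) <- NA
  stat <- rowMeans(dist, na.rm = TRUE)
  s <- stats::sd(stat)
  if (!is.finite(s) || s == 0) return(character())
  z <- (stat - mean(stat)) / s
  panel$samples$sample_id[z > sd_limit]
}

#' Run a full QC pass over a panel
#'
#' Applies, in order: sample call-rate filter, marker filters (call
#' rate, MAF, HWE), heterozygosity outliers, subject-wise relative
#' pruning (PIHAT), and IBS ancestry outliers. Because sample removal
#' shifts the marker statistics (and vice versa), the whole ordered
#' sequence is repeated until one pass removes nothing, so the output
#' is a fixed point of the pipeline: re-running QC on it changes
#' nothing. The pass and order are logged in the returned report.
#'
#' @param panel a [genotype_panel()].
#' @param config a [qc_config()] (or preset name).
#' @param prune_relatives run the subject-wise relatedness prune
#'   (disable when pair-level filtering is done downstream, as in the
#'   Haseman-Elston arm).
#' @param ancestry_outliers run the IBS outlier filter.
#' @param max_passes cap on fixed-point iterations.
#' @return list of class `qc_report`: `panel` (filtered), `steps`
#'   (ordered filter log with a `pass` column), `keep_samples`,
#'   `keep_snps`.
#' @export
run_qc <- function(panel, config = qc_config("gwas"),
                   prune_relatives = TRUE, ancestry_outliers = TRUE,
                   max_passes = 10L) {
  if (is.character(config)) config <- qc_config(config)
  steps <- list()
  cur <- panel

  for (pass in seq_len(max_passes)) {
    removed_this_pass <- 0L
    add_step <- function(df) {
      df$pass <- pass
      steps[[length(steps) + 1L]] <<- df
      removed_this_pass <<- removed_this_pass + sum(df$n_removed)
    }

    sf <- sample_filters(cur, config)
    add_step(sf$steps[1, ])              # call rate first
    keep <- setdiff(cur$samples$sample_id, sf$steps$removed[[1]])
    cur <- subset_panel(cur, sample_ids = keep)

    mf <- marker_filters(cur, config)
    add_step(mf$steps)
    cur <- subset_panel(cur, snp_ids = mf$keep_snps)

    # heterozygosity on the marker-filtered panel
    cfg_het <- config; cfg_het$sample_call_rate_min <- 0
    hf <- sample_filters(cur, cfg_het)
    add_step(hf$steps[2, ])
    cur <- subset_panel(cur, sample_ids = setdiff(cur$samples$sample_id,
                                                  hf$steps$removed[[2]]))

    if (prune_relatives && nrow(cur$dosages) >= 2) {
      ph <- suppressWarnings(pihat_matrix(cur))
      rem <- prune_relatives_subjectwise(ph, config$relatedness_subject_max)
      add_step(data.frame(filter = "relatedness",
                          threshold = config$relatedness_subject_max,
                          n_removed = length(rem),
                          removed = I(list(rem)),
                          stringsAsFactors = FALSE))
      if (length(rem))
        cur <- subset_panel(cur, sample_ids = setdiff(cur$samples$sample_id,
                                                      rem))
    }
    if (ancestry_outliers && nrow(cur$dosages) >= 3) {
      out <- ibs_ancestry_outliers(cur, config$ibs_sd_limit)
      add_step(data.frame(filter = "ibs_ancestry",
                          threshold = config$ibs_sd_limit,
                          n_removed = length(out), removed = I(list(out)),
                          stringsAsFactors = FALSE))
      if (length(out))
        cur <- subset_panel(cur, sample_ids = setdiff(cur$samples$sample_id,
                                                      out))
    }
    if (removed_this_pass == 0L) break
  }
  if (removed_this_pass > 0L)
    warning("QC did not reach a fixed point within ", max_passes, " passes")
  steps <- do.call(rbind, steps)
  rownames(steps) <- NULL
  structure(list(panel = cur, steps = steps,
                 keep_samples = cur$samples$sample_id,
                 keep_snps = cur$snps$snp_id,
                 config = config),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (preset:", x$config$preset, ")\n")
  for (i in seq_len(nrow(x$steps)))
    cat(sprintf("  %-18s threshold %-8g removed %d\n",
                x$steps$filter[i], x$steps$threshold[i],
                x$steps$n_removed[i]))
  cat(sprintf("  surviving: %d samples, %d SNPs\n",
              length(x$keep_samples), length(x$keep_snps)))
  invisible(x)
}
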