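#' Allele-frequency-weighted genetic relationship matrix
#'
#' GCTA-convention GRM: per SNP j with sample A1 frequency p_j, the
#' standardized genotype is `w_ij = (x_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))`;
#' off-diagonal entries average `w_ij w_kj` over jointly non-missing
#' SNPs, and the diagonal uses
#' `1 + (x^2 - (1 + 2p) x + 2 p^2) / (2 p (1 - p))` averaged over
#' non-missing SNPs.
#'
#' @param panel a QC'd [genotype_panel()] with no monomorphic SNPs.
#' @return a `grm` object: list with `A` (n x n), `N` (per-pair
#'   non-missing SNP counts), `ids`.
#' @export
compute_grm <- function(panel) {
  d <- panel$dosages
  p <- allele_freq(panel)
  if (any(is.na(p) | p <= 0 | p >= 1))
    stop("monomorphic or all-missing SNPs present; run QC first")
  n <- nrow(d)
  denom <- 2 * p * (1 - p)

  W <- sweep(d, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(denom), "/")
  obs <- !is.na(W)
  W[!obs] <- 0
  N <- tcrossprod(obs + 0)
  if (any(N == 0)) stop("sample pair with zero jointly non-missing SNPs")
  A <- tcrossprod(W) / N

  # GCTA diagonal form
  Dterm <- d^2 - sweep(d, 2, 1 + 2 * p, "*")
  Dterm <- sweep(Dterm, 2, 2 * p^2, "+")
  Dterm <- sweep(Dterm, 2, denom, "/")
  diag(A) <- 1 + rowSums(Dterm, na.rm = TRUE) / rowSums(obs)

  dimnames(A) <- dimnames(N) <-
    list(panel$samples$sample_id, panel$samples$sample_id)
  new_grm(A, N, data.frame(family_id = panel$samples$family_id,
                           sample_id = panel$samples$sample_id,
                           stringsAsFactors = FALSE))
}

#' Greedy subject pruning on GRM relatedness
#'
#' Removes subjects (as in [prune_relatives_subjectwise()]) until no
#' off-diagonal GRM entry exceeds the threshold — the subject-level
#' relatedness cut that precedes REML estimation, which costs far more
#' sample than the pair-level filter used by Haseman-Elston.
#'
#' @param grm a `grm`.
#' @param threshold off-diagonal relatedness cutoff (default 0.025).
#' @return the reduced `grm`.
#' @export
grm_prune_subjects <- function(grm, threshold = 0.025) {
  removed <- prune_relatives_subjectwise(grm$A, threshold)
  if (!length(removed)) return(grm)
  keep <- setdiff(rownames(grm$A), removed)
  new_grm(grm$A[keep, keep, drop = FALSE],
          if (!is.null(grm$N)) grm$N[keep, keep, drop = FALSE] else NULL,
          grm$ids[match(keep, grm$ids$sample_id), , drop = FALSE])
}

# Restricted log-likelihood and derived quantities in the eigenbasis
# of the GRM. With A = U diag(d) U', V = sg*A + se*I becomes diagonal
# (w = sg*d + se) after rotating y and X by U', so every REML
# iteration costs O(n^2) instead of O(n^3).
reml_internals <- function(ystar, Xstar, dvals, sg, se) {
  w <- sg * dvals + se
  if (any(w <= 0)) return(NULL)           # V not positive definite
  wi <- 1 / w
  Xw <- Xstar * wi
  XtVX <- crossprod(Xstar, Xw)
  R <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  # P~ = W^-1 - W^-1 X (X'W^-1X)^-1 X'W^-1   (n x n, rank-p update)
  B <- Xw %*% backsolve(R, diag(ncol(R)))  # W^-1 X R^-1
  Ptilde <- diag(wi) - tcrossprod(B)
  Py <- drop(Ptilde %*% ystar)
  yPy <- sum(ystar * Py)
  logdetV <- sum(log(w))
  logdetXtVX <- 2 * sum(log(diag(R)))
  logL <- -0.5 * (logdetV + logdetXtVX + yPy)
  list(Ptilde = Ptilde, Py = Py, yPy = yPy, logL = logL, w = w)
}

# traces and quadratic forms needed by the three update schemes;
# in the eigenbasis V_g maps to diag(d) and V_e to I
reml_derivs <- function(int, dvals) {
  P <- int$Ptilde
  Py <- int$Py
  trPA <- sum(diag(P) * dvals)
  trPI <- sum(diag(P))
  PD <- P * rep(dvals, each = nrow(P))    # P %*% diag(d) columnwise
  trPAPA <- sum(PD * t(PD))
  trPAPI <- sum(P * t(PD))
  trPIPI <- sum(P * P)
  APy <- dvals * Py
  yPAPy <- sum(Py * APy)
  yPIPy <- sum(Py * Py)
  PAPy <- drop(P %*% APy)
  PPy <- drop(P %*% Py)
  list(trPA = trPA, trPI = trPI, trPAPA = trPAPA, trPAPI = trPAPI,
       trPIPI = trPIPI, yPAPy = yPAPy, yPIPy = yPIPy,
       yPAPAPy = sum(APy * PAPy), yPAPIPy = sum(APy * PPy),
       yPIPIPy = sum(Py * PPy))
}

#' REML variance components on a GRM
#'
#' Fits `y = Xb + g + e` with `Var(y) = sigma2_g A + sigma2_e I` by
#' restricted maximum likelihood, using one of three iteration
#' schemes: `"AI"` (Newton with average information), `"Fisher"`
#' (Newton with expected information) or `"EM"`
#' (expectation-maximization). All three maximize the same restricted
#' likelihood and are started from an equal split of the phenotypic
#' variance (Newton schemes take one EM warm-up step). Negative
#' components are projected to `1e-6 * Vp`. Standard errors come from
#' the inverse average-information matrix at the optimum for every
#' algorithm, and `se(h2)` by the delta method.
#'
#' @param grm a `grm` object.
#' @param phenotype named numeric vector (aligned by sample id).
#' @param covariates optional data frame of fixed effects.
#' @param algorithm `"AI"`, `"Fisher"` or `"EM"`.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the change in restricted logL.
#' @param constrain project negative components back into the
#'   parameter space (disable for unconstrained estimates).
#' @param grm_eigen optional precomputed `eigen()` of the (aligned)
#'   GRM, so several algorithms can share one decomposition.
#' @return list of class `variance_fit`: `sigma2_g`, `sigma2_e`, `vp`,
#'   `h2`, `se_sigma2_g`, `se_vp`, `se_h2`, `logL`, `logL_trace`,
#'   `algorithm`, `n_iterations`, `converged`, `constrained`, `n_used`.
#' @export
reml_fit <- function(grm, phenotype, covariates = NULL,
                     algorithm = c("AI", "Fisher", "EM"),
                     max_iter = 200L, tol = 1e-8, constrain = TRUE,
                     grm_eigen = NULL) {
  algorithm <- match.arg(algorithm)
  ids <- rownames(grm$A)
  if (!is.null(names(phenotype))) phenotype <- phenotype[ids]
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  A <- grm$A[keep, keep, drop = FALSE]
  n <- length(y)
  X <- covariate_design(
    if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE], n)

  eg <- if (!is.null(grm_eigen) && length(grm_eigen$values) == n)
    grm_eigen else eigen(A, symmetric = TRUE)
  dvals <- eg$values
  U <- eg$vectors
  ystar <- drop(crossprod(U, y))
  Xstar <- crossprod(U, X)

  vp0 <- stats::var(y)
  sg <- se <- vp0 / 2
  floor_val <- 1e-6 * vp0
  constrained <- FALSE

  int <- reml_internals(ystar, Xstar, dvals, sg, se)
  if (is.null(int)) stop("initial V not positive definite")
  logL <- int$logL
  trace <- logL
  converged <- FALSE
  iter <- 0L

  em_step <- function(sg, se, int, dv) {
    # sigma_i^2' = (sigma_i^4 y'P V_i P y + tr(sigma_i^2 I - sigma_i^4 P V_i)) / n
    sg2 <- (sg^2 * dv$yPAPy + (n * sg - sg^2 * dv$trPA)) / n
    se2 <- (se^2 * dv$yPIPy + (n * se - se^2 * dv$trPI)) / n
    c(sg2, se2)
  }

  newton_step <- function(sg, se, int, dv, use_ai) {
    score <- c(-0.5 * (dv$trPA - dv$yPAPy),
               -0.5 * (dv$trPI - dv$yPIPy))
    if (use_ai) {
      info <- 0.5 * matrix(c(dv$yPAPAPy, dv$yPAPIPy,
                             dv$yPAPIPy, dv$yPIPIPy), 2, 2)
    } else {
      info <- 0.5 * matrix(c(dv$trPAPA, dv$trPAPI,
                             dv$trPAPI, dv$trPIPI), 2, 2)
    }
    delta <- tryCatch(solve(info, score), error = function(e) {
      # singular information (e.g. A ~ I): pseudo-inverse step
      sv <- svd(info)
      pos <- sv$d > max(sv$d) * 1e-10
      drop(sv$v[, pos, drop = FALSE] %*%
             (crossprod(sv$u[, pos, drop = FALSE], score) / sv$d[pos]))
    })
    c(sg, se) + delta
  }

  for (iter in seq_len(max_iter)) {
    dv <- reml_derivs(int, dvals)
    theta_new <- if (algorithm == "EM" || iter == 1L)
      em_step(sg, se, int, dv)
    else
      newton_step(sg, se, int, dv, use_ai = algorithm == "AI")

    if (constrain) {
      if (any(theta_new < 0)) constrained <- TRUE
      theta_new <- pmax(theta_new, floor_val)
    }

    # step halving if the step leaves the PD cone or drops the logL
    int_new <- reml_internals(ystar, Xstar, dvals, theta_new[1],
                              theta_new[2])
    halvings <- 0L
    while ((is.null(int_new) ||
            (algorithm != "EM" && int_new$logL < logL - 1e-10)) &&
           halvings < 10L) {
      theta_new <- (theta_new + c(sg, se)) / 2
      int_new <- reml_internals(ystar, Xstar, dvals, theta_new[1],
                                theta_new[2])
      halvings <- halvings + 1L
    }
    if (is.null(int_new))
      stop("variance matrix not positive definite after 10 step halvings")

    sg <- theta_new[1]; se <- theta_new[2]
    int <- int_new
    trace <- c(trace, int$logL)
    if (abs(int$logL - logL) < tol) {
      logL <- int$logL
      converged <- TRUE
      break
    }
    logL <- int$logL
  }

  # SEs from the average-information matrix at the optimum
  dv <- reml_derivs(int, dvals)
  AI <- 0.5 * matrix(c(dv$yPAPAPy, dv$yPAPIPy,
                       dv$yPAPIPy, dv$yPIPIPy), 2, 2)
  covmat <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, 2, 2))
  vp <- sg + se
  h2 <- sg / vp
  grad_h2 <- c(se, -sg) / vp^2
  se_h2 <- sqrt(max(drop(t(grad_h2) %*% covmat %*% grad_h2), 0))
  structure(list(sigma2_g = sg, sigma2_e = se, vp = vp, h2 = h2,
                 se_sigma2_g = sqrt(max(covmat[1, 1], 0)),
                 se_vp = sqrt(max(sum(covmat), 0)),
                 se_h2 = se_h2,
                 logL = logL, logL_trace = trace,
                 algorithm = algorithm, n_iterations = iter,
                 converged = converged, constrained = constrained,
                 n_used = n),
            class = "variance_fit")
}

#' @export
print.variance_fit <- function(x, ...) {
  cat(sprintf(
    "REML (%s): V(g) %.6g (SE %.3g), Vp %.6g, h2 %.4f (SE %.3g)\n",
    x$algorithm, x$sigma2_g, x$se_sigma2_g, x$vp, x$h2, x$se_h2))
  cat(sprintf("  logL %.4f after %d iterations (converged: %s, n = %d)\n",
              x$logL, x$n_iterations, x$converged, x$n_used))
  invisible(x)
}

# standardized covariate-residualized phenotype shared by the H-E arm
he_prepare_z <- function(grm, phenotype, covariates) {
  ids <- rownames(grm$A)
  if (!is.null(names(phenotype))) phenotype <- phenotype[ids]
  keep <- which(!is.na(phenotype))
  y <- phenotype[keep]
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  X <- covariate_design(
    if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE],
    length(y))
  z <- residualize(y, X)
  z <- z / stats::sd(z)
  list(z = z, keep = keep)
}

# slope/intercept of the pairwise regression given the pair mask
he_slope <- function(z, A, mask, form) {
  x <- A[mask]
  dep <- if (form == "cross_product") tcrossprod(z)[mask]
  else (outer(z, z, "-")^2)[mask]
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) stop("constant relatedness across pairs")
  slope <- stats::cov(x, dep) / vx
  c(slope = slope, intercept = mean(dep) - slope * mean(x))
}

#' Pair-filtered Haseman-Elston regression
#'
#' The phenotype is residualized on the covariates and standardized;
#' for every retained pair (those with relatedness at or below
#' `pair_threshold` — close-relative *pairs*, not whole subjects, are
#' excluded) the pairwise similarity statistic is regressed on the GRM
#' entry. With the cross-product statistic `z_i z_j` (default) the
#' heritability estimate is the slope; with the classical squared
#' difference `(z_i - z_j)^2` it is `-slope / 2`.
#'
#' @param grm a `grm`.
#' @param phenotype named numeric vector.
#' @param covariates optional fixed-effect data frame.
#' @param pair_threshold pairs with `A_ij` above this are dropped
#'   (default 0.025).
#' @param form `"cross_product"` or `"squared_difference"`.
#' @return list of class `he_fit`: `slope`, `intercept`,
#'   `h2_estimate`, `n_pairs_used`, `n_pairs_excluded`, `form`, `n`.
#' @export
he_regression <- function(grm, phenotype, covariates = NULL,
                          pair_threshold = 0.025,
                          form = c("cross_product", "squared_difference")) {
  form <- match.arg(form)
  prep <- he_prepare_z(grm, phenotype, covariates)
  A <- grm$A[prep$keep, prep$keep, drop = FALSE]
  n <- length(prep$z)
  ut <- upper.tri(A)
  mask <- ut & A <= pair_threshold
  n_used <- sum(mask)
  if (n_used < 2) stop("fewer than 2 pairs survive the relatedness filter")
  est <- he_slope(prep$z, A, mask, form)
  h2 <- if (form == "cross_product") est[["slope"]] else -est[["slope"]] / 2
  structure(list(slope = est[["slope"]], intercept = est[["intercept"]],
                 h2_estimate = h2,
                 n_pairs_used = n_used,
                 n_pairs_excluded = sum(ut) - n_used,
                 form = form, n = n),
            class = "he_fit")
}

#' @export
print.he_fit <- function(x, ...) {
  cat(sprintf(
    "H-E regression (%s): slope %.4f, h2 %.4f over %d pairs (%d excluded)\n",
    x$form, x$slope, x$h2_estimate, x$n_pairs_used, x$n_pairs_excluded))
  if (!is.null(x$bootstrap))
    cat(sprintf("  bootstrap (%d reps): SE %.4f, 95%% CI [%.4f, %.4f], p %.4g\n",
                x$bootstrap$n_reps, x$bootstrap$se, x$bootstrap$ci_low,
                x$bootstrap$ci_high, x$bootstrap$p_value))
  invisible(x)
}

#' Subject-level bootstrap for Haseman-Elston regression
#'
#' Pairwise comparisons sharing a subject are not independent, so
#' inference resamples *subjects* with replacement: each replicate
#' draws n subjects, forms all pairs whose two members originate from
#' distinct original subjects (and pass the relatedness filter), and
#' reruns the pairwise regression. SE is the SD of bootstrap slopes,
#' the CI the 2.5/97.5 percentiles, and the p-value the two-sided
#' percentile sign test `2 min(frac <= 0, frac >= 0)` (floored at
#' `2 / n_reps`). Degenerate resamples are redrawn and counted.
#'
#' @inheritParams he_regression
#' @param n_reps number of bootstrap replicates (>= 100).
#' @param seed integer RNG seed.
#' @return the [he_regression()] fit with a `bootstrap` element:
#'   `n_reps`, `se`, `ci_low`, `ci_high`, `p_value`, `n_degenerate`,
#'   `slopes`, `seed`.
#' @export
he_bootstrap <- function(grm, phenotype, covariates = NULL,
                         pair_threshold = 0.025, n_reps = 1000L,
                         seed = 1L,
                         form = c("cross_product", "squared_difference")) {
  form <- match.arg(form)
  if (n_reps < 100) stop("n_reps must be at least 100")
  fit <- he_regression(grm, phenotype, covariates, pair_threshold, form)
  prep <- he_prepare_z(grm, phenotype, covariates)
  A <- grm$A[prep$keep, prep$keep, drop = FALSE]
  z <- prep$z
  n <- length(z)
  ut <- upper.tri(A)

  set.seed(seed)
  slopes <- numeric(n_reps)
  n_degenerate <- 0L
  for (r in seq_len(n_reps)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      As <- A[idx, idx]
      zs <- z[idx]
      same <- outer(idx, idx, "==")
      mask <- ut & !same & As <= pair_threshold
      ok <- sum(mask) >= 2 && stats::var(As[mask]) > 0
      if (ok) break
      n_degenerate <- n_degenerate + 1L
    }
    slopes[r] <- he_slope(zs, As, mask, form)[["slope"]]
  }
  frac_le <- mean(slopes <= 0)
  frac_ge <- mean(slopes >= 0)
  pval <- max(2 * min(frac_le, frac_ge), 2 / n_reps)
  ci <- stats::quantile(slopes, c(0.025, 0.975), names = FALSE)
  fit$bootstrap <- list(n_reps = n_reps, se = stats::sd(slopes),
                        ci_low = ci[1], ci_high = ci[2],
                        p_value = min(pval, 1),
                        n_degenerate = n_degenerate,
                        slopes = slopes, seed = seed)
  fit
}
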