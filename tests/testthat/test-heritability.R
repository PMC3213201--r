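# independent restricted log-likelihood, computed directly from the
# dense matrices (no eigendecomposition, no shared code path)
dense_reml_logl <- function(y, X, A, sg, se) {
  V <- sg * A + se * diag(length(y))
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            drop(crossprod(y, P %*% y)))
}

test_that("GRM entries equal a brute-force double loop", {
  panel <- random_panel(10, 20, missing_rate = 0.1, seed = 17)
  g <- compute_grm(panel)
  d <- panel$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  for (i in 1:10) for (k in 1:10) {
    if (i == k) {
      acc <- 0; cnt <- 0
      for (j in 1:20) {
        x <- d[i, j]
        if (is.na(x)) next
        acc <- acc + 1 + (x^2 - (1 + 2 * p[j]) * x + 2 * p[j]^2) /
          (2 * p[j] * (1 - p[j]))
        cnt <- cnt + 1
      }
      expect_equal(g$A[i, i], unname(acc / cnt), tolerance = 1e-12)
    } else {
      acc <- 0; cnt <- 0
      for (j in 1:20) {
        xi <- d[i, j]; xk <- d[k, j]
        if (is.na(xi) || is.na(xk)) next
        acc <- acc + (xi - 2 * p[j]) * (xk - 2 * p[j]) /
          (2 * p[j] * (1 - p[j]))
        cnt <- cnt + 1
      }
      expect_equal(g$A[i, k], unname(acc / cnt), tolerance = 1e-12)
      expect_identical(unname(g$N[i, k]), as.numeric(cnt))
    }
  }
})

test_that("a duplicated sample's off-diagonal equals its standardized self-product", {
  panel <- random_panel(8, 40, seed = 19)
  panel$dosages[2, ] <- panel$dosages[1, ]
  g <- compute_grm(panel)
  # identical rows: A_12 is exactly the mean squared standardized dosage
  p <- colMeans(panel$dosages) / 2
  w <- (panel$dosages[1, ] - 2 * p) / sqrt(2 * p * (1 - p))
  expect_equal(g$A[1, 2], unname(mean(w^2)), tolerance = 1e-12)
  # the GCTA diagonal form agrees with it in expectation, not exactly
  expect_lt(abs(g$A[1, 2] - g$A[1, 1]), 0.35)
  expect_identical(g$A[1, 1], g$A[2, 2])
})

test_that("unrelated HWE panels give near-zero mean off-diagonals and unit diagonal", {
  cfg <- sim_config(n_samples = 300, n_snps = 1000, missing_rate = 0,
                    seed = 23)
  sim <- simulate_genotypes(cfg)
  g <- compute_grm(sim$panel)
  off <- g$A[upper.tri(g$A)]
  se <- sd(off) / sqrt(length(off))
  # sample-frequency centering forces row sums toward 0, so the mean
  # off-diagonal sits at -mean(diag)/(n-1) rather than exactly 0
  expect_lt(abs(mean(off) + mean(diag(g$A)) / (300 - 1)), 3 * se)
  expect_gt(mean(diag(g$A)), 0.9)
  expect_lt(mean(diag(g$A)), 1.1)
  expect_error(compute_grm(genotype_panel(
    matrix(c(0L, 0L), 2, 1),
    data.frame(sample_id = c("a", "b")),
    data.frame(snp_id = "m", chromosome = 1L, position = 1L,
               a1 = "A", a2 = "B"))), "monomorphic")
})

test_that("REML recovers simulated heritability and the algorithms agree", {
  cfg <- sim_config(n_samples = 500, n_snps = 1000, missing_rate = 0,
                    seed = 29)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim$panel, 0.5, 200, seed = 30)
  g <- compute_grm(sim$panel)
  eg <- eigen(g$A, symmetric = TRUE)

  fits <- lapply(c("AI", "Fisher", "EM"), function(alg)
    reml_fit(g, ph$phenotype, algorithm = alg, grm_eigen = eg))
  h2s <- vapply(fits, `[[`, 0, "h2")
  expect_true(all(abs(h2s - 0.5) < 0.25))   # single replicate: wide band
  vp <- fits[[1]]$vp
  expect_lt(max(vapply(fits, `[[`, 0, "sigma2_g")) -
              min(vapply(fits, `[[`, 0, "sigma2_g")), 1e-4 * vp)
  expect_true(all(vapply(fits, `[[`, TRUE, "converged")))

  # restricted logL at the optimum agrees with the dense-matrix form
  X <- matrix(1, 500, 1)
  expect_equal(fits[[1]]$logL,
               dense_reml_logl(unname(ph$phenotype), X, g$A,
                               fits[[1]]$sigma2_g, fits[[1]]$sigma2_e),
               tolerance = 1e-6, ignore_attr = TRUE)

  # numerical gradient of the dense restricted logL is ~0 at the optimum
  eps <- 1e-5 * vp
  for (comp in 1:2) {
    th <- c(fits[[1]]$sigma2_g, fits[[1]]$sigma2_e)
    up <- dn <- th
    up[comp] <- up[comp] + eps; dn[comp] <- dn[comp] - eps
    grad <- (dense_reml_logl(unname(ph$phenotype), X, g$A, up[1], up[2]) -
               dense_reml_logl(unname(ph$phenotype), X, g$A, dn[1],
                               dn[2])) / (2 * eps)
    expect_lt(abs(grad * vp), 0.05)   # scale-free gradient criterion
  }
})

test_that("EM iterations never decrease the restricted likelihood", {
  cfg <- sim_config(n_samples = 200, n_snps = 400, missing_rate = 0,
                    seed = 31)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim$panel, 0.3, 100, seed = 32)
  g <- compute_grm(sim$panel)
  fit <- reml_fit(g, ph$phenotype, algorithm = "EM", max_iter = 50)
  expect_true(all(diff(fit$logL_trace) > -1e-8))
})

test_that("without genetic structure the fit collapses to the OLS likelihood", {
  set.seed(33)
  n <- 120
  ids <- sprintf("s%03d", 1:n)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  g <- polyfrs:::new_grm(A, NULL, data.frame(family_id = ids,
                                             sample_id = ids))
  y <- setNames(rnorm(n), ids)
  fit <- reml_fit(g, y, algorithm = "EM", max_iter = 500, tol = 1e-10)
  # closed-form restricted likelihood of the iid model
  X <- matrix(1, n, 1)
  rss <- sum((y - mean(y))^2)
  s2 <- rss / (n - 1)
  logl_ols <- -0.5 * ((n - 1) * log(s2) + log(n) + (n - 1))
  expect_equal(fit$logL, logl_ols, tolerance = 1e-6)

  # h2 on an unstructured GRM with a null phenotype stays near zero
  cfg <- sim_config(n_samples = 300, n_snps = 800, missing_rate = 0,
                    seed = 34)
  sim <- simulate_genotypes(cfg)
  ph0 <- simulate_phenotype(sim$panel, 0, 100, seed = 35)
  gg <- compute_grm(sim$panel)
  for (alg in c("AI", "Fisher")) {
    f <- reml_fit(gg, ph0$phenotype, algorithm = alg)
    expect_lt(f$h2, 0.25)
  }
})

test_that("H-E slope equals a naive two-column OLS oracle over the pair list", {
  cfg <- sim_config(n_samples = 150, n_snps = 500, missing_rate = 0,
                    seed = 37)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim$panel, 0.4, 100, seed = 38)
  g <- compute_grm(sim$panel)
  fit <- he_regression(g, ph$phenotype, pair_threshold = 0.025)

  # oracle: build the pair list with loops and fit lm()
  z <- ph$phenotype - mean(ph$phenotype)
  z <- z / sd(z)
  xs <- c(); ys <- c()
  for (i in 1:149) for (j in (i + 1):150) {
    if (g$A[i, j] > 0.025) next
    xs <- c(xs, g$A[i, j]); ys <- c(ys, z[i] * z[j])
  }
  oracle <- lm(ys ~ xs)
  expect_equal(fit$slope, unname(coef(oracle)[2]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-10)
  expect_identical(fit$n_pairs_used, length(xs))
  expect_equal(fit$n_pairs_used + fit$n_pairs_excluded, 150 * 149 / 2)

  # squared-difference form maps through -slope/2 and lands nearby
  fit2 <- he_regression(g, ph$phenotype, form = "squared_difference")
  expect_equal(fit2$h2_estimate, -fit2$slope / 2, tolerance = 1e-12)

  # constant regressor errors out
  Ac <- matrix(0.01, 10, 10); diag(Ac) <- 1
  ids <- letters[1:10]; dimnames(Ac) <- list(ids, ids)
  gc <- polyfrs:::new_grm(Ac, NULL, data.frame(family_id = ids,
                                               sample_id = ids))
  expect_error(he_regression(gc, setNames(rnorm(10), ids)), "constant")
  expect_error(he_regression(g, setNames(rep(1, 150),
                                         rownames(g$A))), "zero variance")
})

test_that("subject-level bootstrap is deterministic and sized sanely", {
  cfg <- sim_config(n_samples = 120, n_snps = 400, missing_rate = 0,
                    seed = 41)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim$panel, 0.4, 100, seed = 42)
  g <- compute_grm(sim$panel)
  b1 <- he_bootstrap(g, ph$phenotype, n_reps = 150, seed = 7)
  b2 <- he_bootstrap(g, ph$phenotype, n_reps = 150, seed = 7)
  expect_identical(b1$bootstrap$slopes, b2$bootstrap$slopes)
  expect_identical(b1$bootstrap$p_value, b2$bootstrap$p_value)
  expect_true(b1$bootstrap$ci_low <= b1$bootstrap$ci_high)
  expect_gt(b1$bootstrap$se, 0)
  expect_error(he_bootstrap(g, ph$phenotype, n_reps = 50), "at least 100")

  # cross-product and squared-difference agree within 2 bootstrap SEs
  bsq <- he_bootstrap(g, ph$phenotype, n_reps = 150, seed = 8,
                      form = "squared_difference")
  tol <- 2 * sqrt(b1$bootstrap$se^2 + (bsq$bootstrap$se / 2)^2)
  expect_lt(abs(b1$h2_estimate - bsq$h2_estimate), tol)
})

test_that("phenotype permutation destroys the heritability signal", {
  cfg <- sim_config(n_samples = 200, n_snps = 600, missing_rate = 0,
                    seed = 43)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim$panel, 0.6, 150, seed = 44)
  g <- compute_grm(sim$panel)
  set.seed(45)
  h2_perm <- replicate(20, {
    yp <- setNames(sample(ph$phenotype), names(ph$phenotype))
    he_regression(g, yp)$h2_estimate
  })
  band <- quantile(h2_perm, c(0.025, 0.975))
  expect_lt(band[1], 0)
  expect_gt(band[2], 0)
})

test_that("GRM subject pruning removes planted relatives and is else identity", {
  cfg <- sim_config(n_samples = 200, n_snps = 500, missing_rate = 0,
                    n_sib_pairs = 50, seed = 47)
  sim <- simulate_genotypes(cfg)
  g <- compute_grm(sim$panel)
  pruned <- grm_prune_subjects(g, 0.025)
  expect_gte(200 - nrow(pruned$A), 50)
  off <- pruned$A[upper.tri(pruned$A)]
  expect_true(all(off <= 0.025))

  # single related pair: exactly one subject lost
  ids <- letters[1:5]
  A <- diag(5); dimnames(A) <- list(ids, ids)
  A["a", "b"] <- A["b", "a"] <- 0.5
  g2 <- polyfrs:::new_grm(A, NULL, data.frame(family_id = ids,
                                              sample_id = ids))
  expect_identical(nrow(grm_prune_subjects(g2, 0.025)$A), 4L)

  # nothing above threshold: identity
  g3 <- grm_prune_subjects(g2, 0.6)
  expect_identical(g3$A, A)
})
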