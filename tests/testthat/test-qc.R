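test_that("HWE exact test matches the enumeration oracle across counts", {
  # spot values
  expect_equal(hwe_exact_test(25, 50, 25), 1.0, tolerance = 1e-12)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  expect_equal(hwe_exact_test(50, 0, 50), hwe_oracle(50, 0, 50),
               tolerance = 1e-25)
  expect_identical(hwe_exact_test(100, 0, 0), 1.0)
  expect_error(hwe_exact_test(0, 0, 0), "zero")

  # randomized agreement with the closed-form counting oracle
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:100, 1)
    counts <- as.vector(stats::rmultinom(1, n, runif(3)))
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 hwe_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-12)
  }
})

test_that("marker filters remove the planted violations with correct attribution", {
  # 20 clean markers in HWE, then one violating each criterion
  set.seed(7)
  n <- 100
  clean <- sapply(runif(20, 0.2, 0.4), function(p) rbinom(n, 2, p))
  low_cr <- rbinom(n, 2, 0.3); low_cr[1:20] <- NA        # call rate 0.80
  low_maf <- c(rbinom(1, 2, 0.5), rep(0L, n - 1))        # maf 1/200 = 0.005
  hwe_bad <- rep(c(0L, 2L), n / 2)                       # no hets at p = 0.5
  d <- cbind(clean, low_cr, low_maf, hwe_bad)
  panel <- genotype_panel(
    d, samples = data.frame(sample_id = sprintf("s%d", 1:n)),
    snps = data.frame(snp_id = sprintf("m%02d", 1:23), chromosome = 1L,
                      position = 1:23, a1 = "A", a2 = "B"))
  res <- marker_filters(panel, qc_config("gwas"))
  expect_identical(res$steps$n_removed, c(1L, 1L, 1L))
  expect_identical(res$steps$removed[[1]], "m21")
  expect_identical(res$steps$removed[[2]], "m22")
  expect_identical(res$steps$removed[[3]], "m23")
  expect_identical(res$keep_snps, sprintf("m%02d", 1:20))
})

test_that("MAF exactly at threshold is retained (strict less-than)", {
  # 100 samples: one heterozygote in 50 alleles would be maf 0.01 at n=50
  set.seed(1)
  n <- 50
  d <- cbind(sapply(runif(5, 0.3, 0.5), function(p) rbinom(n, 2, p)),
             c(1L, rep(0L, n - 1)))                      # maf = 1/100 = 0.01
  panel <- genotype_panel(
    d, samples = data.frame(sample_id = sprintf("s%d", 1:n)),
    snps = data.frame(snp_id = sprintf("m%d", 1:6), chromosome = 1L,
                      position = 1:6, a1 = "A", a2 = "B"))
  res <- marker_filters(panel, qc_config("gwas"))
  expect_identical(res$steps$n_removed[2], 0L)
  expect_length(res$keep_snps, 6L)
})

test_that("sample filters remove low call rate and heterozygosity outliers", {
  set.seed(9)
  n <- 40; m <- 200
  d <- sapply(runif(m, 0.4, 0.5), function(p) rbinom(n, 2, p))
  d[1, 1:20] <- NA                      # sample 1: call rate 0.90
  d[2, ] <- rep(c(0L, 2L), m / 2)       # sample 2: zero heterozygosity
  panel <- genotype_panel(
    d, samples = data.frame(sample_id = sprintf("s%02d", 1:n)),
    snps = data.frame(snp_id = sprintf("m%d", 1:m), chromosome = 1L,
                      position = 1:m, a1 = "A", a2 = "B"))
  res <- sample_filters(panel, qc_config("gwas"))
  expect_identical(res$steps$removed[[1]], "s01")
  expect_true("s02" %in% res$steps$removed[[2]])
  expect_false("s03" %in% res$steps$removed[[2]])
})

test_that("degenerate heterozygosity SD flags no one", {
  d <- matrix(rep(c(0L, 1L, 2L, 1L), each = 5), nrow = 5, ncol = 4,
              byrow = FALSE)  # identical rows
  panel <- genotype_panel(
    d, samples = data.frame(sample_id = sprintf("s%d", 1:5)),
    snps = data.frame(snp_id = sprintf("m%d", 1:4), chromosome = 1L,
                      position = 1:4, a1 = "A", a2 = "B"))
  res <- sample_filters(panel, qc_config("gwas"))
  expect_identical(sum(res$steps$n_removed), 0L)

  tiny <- subset_panel(panel, sample_ids = c("s1", "s2"))
  expect_warning(sample_filters(tiny, qc_config("gwas")), "skipped")
})

test_that("PIHAT recovers duplicate, unrelated and sib relatedness", {
  cfg <- sim_config(n_samples = 120, n_snps = 2000, missing_rate = 0,
                    n_duplicate_pairs = 2, n_sib_pairs = 3, seed = 15)
  sim <- simulate_genotypes(cfg)
  ph <- pihat_matrix(sim$panel)
  rp <- sim$truth$relative_pairs
  dup <- rp[rp$kind == "duplicate", ]
  sib <- rp[rp$kind == "sib", ]
  for (i in seq_len(nrow(dup)))
    expect_lt(abs(ph[dup$id1[i], dup$id2[i]] - 1), 0.05)
  for (i in seq_len(nrow(sib)))
    expect_lt(abs(ph[sib$id1[i], sib$id2[i]] - 0.5), 0.07)
  # unrelated block: everything outside the planted pairs
  rel_ids <- unique(c(rp$id1, rp$id2))
  un <- ph[setdiff(rownames(ph), rel_ids), setdiff(rownames(ph), rel_ids)]
  expect_lt(abs(mean(un[upper.tri(un)])), 0.02)
  expect_lt(un["S0020", "S0050"], 0.05)
  expect_lt(abs(estimate_pihat(sim$panel, c(dup$id1[1], dup$id2[1])) - 1),
            0.05)
})

test_that("PIHAT is undefined below the joint-SNP floor", {
  panel <- random_panel(4, 60, seed = 3)
  expect_warning(ph <- pihat_matrix(panel, min_joint = 100L), "undefined")
  expect_true(all(is.na(ph)))
})

test_that("greedy relative pruning removes hubs first and leaves no edges", {
  ids <- c("a", "b", "c", "d", "e")
  M <- matrix(0, 5, 5, dimnames = list(ids, ids))
  # star: a related to b, c, d
  M["a", c("b", "c", "d")] <- M[c("b", "c", "d"), "a"] <- 0.5
  expect_identical(prune_relatives_subjectwise(M, 0.25), "a")

  # single pair: exactly one removed, lexicographically smallest
  M2 <- matrix(0, 5, 5, dimnames = list(ids, ids))
  M2["b", "d"] <- M2["d", "b"] <- 0.4
  expect_identical(prune_relatives_subjectwise(M2, 0.25), "b")

  # nothing above threshold
  expect_identical(prune_relatives_subjectwise(M2, 0.5), character())

  # random matrices: remaining graph never has an edge above threshold
  set.seed(2)
  for (i in 1:10) {
    R <- matrix(runif(64, 0, 0.3), 8, 8)
    R <- (R + t(R)) / 2
    diag(R) <- 1
    dimnames(R) <- list(letters[1:8], letters[1:8])
    rem <- prune_relatives_subjectwise(R, 0.2)
    keep <- setdiff(letters[1:8], rem)
    sub <- R[keep, keep]
    expect_true(all(sub[upper.tri(sub)] <= 0.2))
  }
})

test_that("IBS ancestry outliers flag a planted minority subpopulation", {
  set.seed(19)
  n_maj <- 57; n_min <- 3; m <- 400
  p_maj <- runif(m, 0.1, 0.5)
  # strongly diverged minority frequencies
  p_min <- pmin(pmax(p_maj + sample(c(-1, 1), m, TRUE) * 0.4, 0.02), 0.98)
  d <- rbind(sapply(seq_len(m), function(j) rbinom(n_maj, 2, p_maj[j])),
             sapply(seq_len(m), function(j) rbinom(n_min, 2, p_min[j])))
  ids <- sprintf("s%02d", seq_len(n_maj + n_min))
  panel <- genotype_panel(
    d, samples = data.frame(sample_id = ids),
    snps = data.frame(snp_id = sprintf("m%03d", 1:m), chromosome = 1L,
                      position = 1:m, a1 = "A", a2 = "B"))
  out <- ibs_ancestry_outliers(panel, 3)
  expect_setequal(out, ids[(n_maj + 1):(n_maj + n_min)])

  # homogeneous panel: nothing flagged at 3 SD (one-sided rule)
  hom <- random_panel(60, 400, seed = 23)
  expect_length(ibs_ancestry_outliers(hom, 3), 0L)

  expect_error(ibs_ancestry_outliers(subset_panel(panel,
                                                  sample_ids = ids[1:2])),
               "at least 3")
})

test_that("the two presets carry the published threshold sets", {
  g <- qc_config("gwas")
  expect_identical(c(g$sample_call_rate_min, g$maf_min, g$hwe_p_min),
                   c(0.95, 0.01, 1e-4))
  h <- qc_config("heritability")
  expect_identical(c(h$sample_call_rate_min, h$maf_min, h$hwe_p_min,
                     h$relatedness_pair_max),
                   c(0.99, 0.01, 0.05, 0.025))
  expect_error(qc_config("gwas", not_a_field = 1), "unknown")
})

test_that("QC is a fixed point on its own output", {
  cfg <- sim_config(n_samples = 80, n_snps = 300, missing_rate = 0.03,
                    n_sib_pairs = 2, seed = 33)
  sim <- simulate_genotypes(cfg)
  r1 <- run_qc(sim$panel, qc_config("gwas"))
  r2 <- run_qc(r1$panel, qc_config("gwas"))
  expect_identical(r2$keep_samples, r1$keep_samples)
  expect_identical(r2$keep_snps, r1$keep_snps)
  expect_true(all(r2$steps$n_removed == 0L))
  # filter order is deterministic and logged
  expect_identical(r1$steps$filter[1:5],
                   c("sample_call_rate", "marker_call_rate", "maf", "hwe",
                     "heterozygosity"))
})
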