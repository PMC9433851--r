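test_that("spec validation rejects bad fields with informative messages", {
  expect_error(cohort_spec(noise_sd = NaN), "noise_sd")
  expect_error(cohort_spec(factor_strengths = c(1, 2, 3)),
               "strictly decreasing")
  expect_error(cohort_spec(factor_strengths = c(3, 2), k_true = 3), "length")
  expect_error(cohort_spec(loading_sparsity = 0), "loading_sparsity")
  expect_error(cohort_spec(maf_range = c(0, 0.6)), "maf_range")
  expect_error(
    cohort_spec(perturbed_entries = list(list(mode = 1, side = "hc", index = 99))),
    "out-of-range")
  expect_error(
    cohort_spec(perturbed_entries = list(list(mode = 9, side = "dn", index = 1))),
    "out-of-range")
})

test_that("generation is deterministic and warns when per-group n is small", {
  spec <- cohort_spec(n_per_group = 60, p_dn = 10, q_hc = 8, n_snps = 40,
                      seed = 3)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$dn_volumes$data, b$dn_volumes$data)
  expect_identical(a$hc_volumes$data, b$hc_volumes$data)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$confounds, b$confounds)
  expect_warning(generate_cohort(cohort_spec(n_per_group = 50, seed = 1)),
                 "overfit")
})

test_that("cohort structure honors its contracts", {
  co <- generate_cohort(cohort_spec(n_per_group = 80, p_dn = 12, q_hc = 9,
                                    n_snps = 60, seed = 5))
  expect_true(all(co$genotypes %in% 0:2))
  expect_equal(sum(co$group_labels == 1), 80)
  expect_equal(sum(co$group_labels == 0), 80)
  # truth loadings unit norm per mode per side
  expect_equal(colSums(co$truth$loadings_dn^2), rep(1, 3), tolerance = 1e-12)
  expect_equal(colSums(co$truth$loadings_hc^2), rep(1, 3), tolerance = 1e-12)
  # volume sub-stream independent of the genotype block when uncoupled
  co2 <- generate_cohort(cohort_spec(n_per_group = 80, p_dn = 12, q_hc = 9,
                                     n_snps = 120, seed = 5))
  expect_identical(co$dn_volumes$data, co2$dn_volumes$data)
})

test_that("noiseless single shared factor gives canonical correlation ~ 1", {
  spec <- cohort_spec(n_per_group = 2500, p_dn = 10, q_hc = 8, k_true = 1,
                      factor_strengths = 2, noise_sd = 0, delta = 0,
                      confound_strength = 0, n_snps = 20, seed = 11)
  co <- generate_cohort(spec)
  # rank-deficient views: a small ridge regularizes the within-view covariance
  sol <- fit_cca(co$dn_volumes, co$hc_volumes, k = 1, ridge = 1e-8)
  expect_gte(sol$cor[1], 0.999)
})

test_that("empirical allele frequencies match the spec within 3 SE", {
  co <- generate_cohort(cohort_spec(n_per_group = 400, p_dn = 6, q_hc = 5,
                                    n_snps = 300, seed = 7))
  n <- nrow(co$genotypes)
  f_hat <- colMeans(co$genotypes) / 2
  f <- co$snp_effects$maf
  se <- sqrt(f * (1 - f) / (2 * n))
  # ~0.3% of SNPs are expected beyond 3 SE by chance; none should be far out
  expect_gte(mean(abs(f_hat - f) <= 3 * se), 0.985)
  expect_lt(max(abs(f_hat - f) / se), 5)
})

test_that("deconfounded volumes recover the planted latent factors", {
  # the two-view projection (X a_l + Y b_l)/2 estimates z_l with population
  # correlation sqrt(2 s_l^2 / (2 s_l^2 + sigma^2)); at sigma = 0.5 that is
  # > 0.94 for every planted strength, so 0.9 is attainable with margin
  co <- generate_cohort(cohort_spec(n_per_group = 1000, noise_sd = 0.5,
                                    seed = 13))
  dn <- residualize(co$dn_volumes, co$confounds)
  hc <- residualize(co$hc_volumes, co$confounds)
  Z <- co$truth$factors
  A <- co$truth$loadings_dn
  B <- co$truth$loadings_hc
  for (l in 1:3) {
    est <- (as_matrix(dn) %*% A[, l] + as_matrix(hc) %*% B[, l]) / 2
    expect_gt(abs(cor(est, Z[, l])), 0.9)
  }
})

test_that("without perturbation the groups are exchangeable in variance", {
  # permutation p-values of a group variance contrast should look uniform
  pvals <- vapply(1:12, function(s) {
    co <- generate_cohort(cohort_spec(n_per_group = 150, p_dn = 8, q_hc = 6,
                                      n_snps = 20, delta = 0, seed = 100 + s))
    x <- co$dn_volumes$data[, 1]
    g <- co$group_labels
    obs <- abs(var(x[g == 1]) - var(x[g == 0]))
    set.seed(s)
    perm <- replicate(200, {
      gp <- sample(g)
      abs(var(x[gp == 1]) - var(x[gp == 0]))
    })
    mean(perm >= obs)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("cohort bundles round-trip through TSV + JSON", {
  co <- generate_cohort(cohort_spec(n_per_group = 40, p_dn = 7, q_hc = 5,
                                    n_snps = 25, seed = 21))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("dn_volumes.tsv", "hc_volumes.tsv", "confounds.tsv",
           "phenotype.tsv", "genotypes.tsv", "snp_effects.tsv",
           "truth.json", "cohort_spec.yaml")))))
  back <- read_cohort(dir)
  expect_equal(back$dn_volumes$data, co$dn_volumes$data, tolerance = 1e-6)
  expect_identical(back$genotypes, co$genotypes)
  expect_identical(back$group_labels, co$group_labels)
  expect_equal(as.matrix(back$truth$loadings_hc), co$truth$loadings_hc,
               tolerance = 1e-6, ignore_attr = TRUE)
})
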