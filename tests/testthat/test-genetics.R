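test_that("SNP QC applies the stated thresholds literally", {
  m <- prs_model(snp_id = c("s1", "s2", "s3"),
                 beta = c(0.1, -0.2, 0.3),
                 maf = c(0.005, 0.25, 0.3),
                 info = c(0.99, 0.8, 0.79))
  qc <- snp_qc(m)
  expect_false(qc$qc_pass[1]); expect_equal(qc$qc_reason[1], "maf")
  expect_true(qc$qc_pass[2])    # info == 0.8 retained (strict "< 0.8")
  expect_false(qc$qc_pass[3]); expect_equal(qc$qc_reason[3], "info")
})

test_that("a hand-written SNP table filters exactly as a manual pass", {
  tab <- data.frame(
    snp_id = c("a", "b", "c", "d", "d", "e", "f", "g", "h", "i"),
    beta = seq(-0.5, 0.4, by = 0.1),
    maf = c(0.2, 0.009, 0.3, 0.4, 0.4, 0.05, 0.1, 0.2, 0.3, 0.45),
    info = c(0.9, 0.95, 0.7, 0.85, 0.85, 0.99, 0.9, 0.81, 0.92, 0.88),
    effect_allele = c("A", "C", "G", "T", "T", "A", "C", "G", "A", "T"),
    other_allele = c("G", "G", "C", "C", "C", "T", "T", "A", "C", "A"),
    stringsAsFactors = FALSE)
  qc <- snp_qc(prs_model(tab$snp_id, tab$beta, tab$maf, tab$info,
                         tab$effect_allele, tab$other_allele))
  # manual: b fails maf, c fails info, d twice duplicated, e and i are
  # palindromic (A/T, T/A); a, f, g, h survive
  manual_keep <- c("a", "f", "g", "h")
  expect_identical(qc$snp_id[qc$qc_pass], manual_keep)
  counts <- attr(qc, "qc_counts")
  expect_equal(unname(counts["maf"]), 1)
  expect_equal(unname(counts["info"]), 1)
  expect_equal(unname(counts["duplicate"]), 2)
  expect_equal(unname(counts["ambiguous"]), 2)
})

test_that("polygenic scores are the weighted dosage sums", {
  m <- prs_model(c("s1", "s2"), beta = c(0.5, -0.25),
                 maf = c(0.2, 0.3), info = c(1, 1))
  G0 <- matrix(0L, 3, 2, dimnames = list(paste0("P", 1:3), c("s1", "s2")))
  expect_equal(compute_prs(G0, m)$prs, c(0, 0, 0))
  G1 <- matrix(c(2L, 0L), 1, 2, dimnames = list("P1", c("s1", "s2")))
  expect_equal(compute_prs(G1, m)$prs, 1.0)
  # naive double-loop oracle on a random dosage matrix
  set.seed(4)
  G <- matrix(sample(0:2, 20 * 50, replace = TRUE), 20, 50,
              dimnames = list(sprintf("P%02d", 1:20), sprintf("s%02d", 1:50)))
  mm <- prs_model(colnames(G), beta = rnorm(50), maf = runif(50, 0.05, 0.5),
                  info = runif(50, 0.9, 1))
  got <- compute_prs(G, mm)$prs
  oracle <- numeric(20)
  for (i in 1:20) for (j in 1:50) oracle[i] <- oracle[i] + G[i, j] * mm$beta[j]
  expect_equal(got, oracle, tolerance = 1e-12)
  # linearity: doubling effect sizes doubles the scores
  mm2 <- prs_model(colnames(G), beta = 2 * mm$beta, maf = mm$maf, info = mm$info)
  expect_equal(compute_prs(G, mm2)$prs, 2 * got, tolerance = 1e-12)
  # contract violations
  Gbad <- G; Gbad[1, 1] <- 3L
  expect_error(compute_prs(Gbad, mm), "0, 1 or 2")
  expect_error(compute_prs(G[, 1:10], mm), "missing")
})

test_that("extreme-group selection follows order statistics and the stable tie rule", {
  sc <- data.frame(participant_id = sprintf("P%03d", 1:100), prs = 1:100,
                   stringsAsFactors = FALSE)
  ex <- select_extremes(sc, 0.05)
  expect_equal(sum(ex$outcome == 1), 5)
  expect_equal(sum(ex$outcome == 0), 5)
  expect_setequal(ex$prs[ex$outcome == 1], 96:100)
  expect_setequal(ex$prs[ex$outcome == 0], 1:5)
  expect_error(select_extremes(data.frame(participant_id = 1:10,
                                          prs = rep(1, 10)), 0.1),
               "tied")
  expect_error(select_extremes(sc, 0.6), "q must")
  # ties at the boundary: stable (score, id) sort oracle
  sc2 <- data.frame(participant_id = sprintf("P%03d", 1:20),
                    prs = c(rep(0, 4), 1:12, rep(9, 4)),
                    stringsAsFactors = FALSE)
  ex2 <- select_extremes(sc2, 0.10)
  ord <- order(sc2$prs, sc2$participant_id)
  expect_identical(ex2$participant_id[ex2$outcome == 0],
                   sc2$participant_id[ord[1:2]])
  expect_identical(ex2$participant_id[ex2$outcome == 1],
                   sc2$participant_id[ord[19:20]])
  # invariance under monotone transformation of the scores
  sc3 <- sc; sc3$prs <- exp(sc$prs / 25)
  ex3 <- select_extremes(sc3, 0.05)
  expect_identical(ex3$participant_id, ex$participant_id)
  expect_identical(ex3$outcome, ex$outcome)
})

test_that("the Bayesian logistic fit recovers a strong coefficient quickly", {
  set.seed(12)
  n <- 400
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(1.5 * X[, 2]))
  sex <- rbinom(n, 1, 0.5); age <- rnorm(n, 55, 7.5)
  post <- suppressWarnings(
    fit_bayesian_logistic(X, y, sex, age, n_iter = 500, n_adapt = 300,
                          seed = 12))
  s <- post$summary
  expect_setequal(
    s$term,
    c(paste0("beta_mode_", 1:3), "alpha_men", "alpha_women",
      "alpha_men_age", "alpha_women_age"))
  expect_true(s$flagged[s$term == "beta_mode_2"])
  expect_gt(s$mean[s$term == "beta_mode_2"], 0.8)
  expect_true(all(s$excl_prob >= 0.5 & s$excl_prob <= 1))
  expect_identical(s$flagged, s$excl_prob >= 0.975)
  expect_identical(flagged_modes(post),
                   sort(as.integer(sub("beta_mode_", "",
                                       s$term[s$flagged & grepl("beta_mode", s$term)]))))
})

test_that("the linear-outcome variant recovers a regression slope", {
  set.seed(13)
  n <- 300
  X <- matrix(rnorm(n * 2), n, 2)
  y <- 0.7 * X[, 1] + rnorm(n, sd = 0.5)
  post <- suppressWarnings(
    fit_bayesian_logistic(X, y, rbinom(n, 1, 0.5), rnorm(n, 55, 7.5),
                          n_iter = 500, n_adapt = 300, family = "linear",
                          seed = 13))
  expect_equal(post$summary$mean[post$summary$term == "beta_mode_1"], 0.7,
               tolerance = 0.15)
})

test_that("input contract violations are rejected", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_bayesian_logistic(X, rep(2, 20), rbinom(20, 1, 0.5),
                                     rnorm(20)),
               "binary")
  expect_error(fit_bayesian_logistic(X, rbinom(20, 1, 0.5), rep(2, 20),
                                     rnorm(20)),
               "sex")
  expect_error(fit_bayesian_logistic(X, rbinom(10, 1, 0.5), rbinom(10, 1, 0.5),
                                     rnorm(10)),
               "match")
})
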