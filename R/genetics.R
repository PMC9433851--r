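#' Per-SNP effect-size table for polygenic scoring
#'
#' Container for GWAS summary statistics consumed as given: SNP ids, per-allele
#' effect sizes, minor-allele frequencies and imputation information scores,
#' optionally with effect/other allele codes (needed for strand-ambiguity QC).
#'
#' @param snp_id Character SNP identifiers.
#' @param beta Per-allele effect sizes (finite).
#' @param maf Minor-allele frequencies in \[0, 0.5\].
#' @param info Imputation information scores in \[0, 1\].
#' @param effect_allele,other_allele Optional allele codes (A/C/G/T).
#' @return An object of class `prs_model` (a data.frame underneath).
#' @export
prs_model <- function(snp_id, beta, maf, info,
                      effect_allele = NULL, other_allele = NULL) {
  if (any(!is.finite(beta))) stop("effect sizes must be finite")
  if (any(maf < 0 | maf > 0.5)) stop("maf must lie in [0, 0.5]")
  if (any(info < 0 | info > 1)) stop("info scores must lie in [0, 1]")
  df <- data.frame(snp_id = as.character(snp_id), beta = beta, maf = maf,
                   info = info, stringsAsFactors = FALSE)
  if (!is.null(effect_allele)) df$effect_allele <- toupper(effect_allele)
  if (!is.null(other_allele)) df$other_allele <- toupper(other_allele)
  class(df) <- c("prs_model", "data.frame")
  df
}

#' Quality control of the SNP effect-size table
#'
#' Flags and excludes from scoring: SNPs with minor-allele frequency below 1%,
#' SNPs with imputation information score below 0.8 (strict inequalities:
#' `info == 0.8` is retained), duplicated SNP ids (all copies), and
#' strand-ambiguous (palindromic A/T or C/G) SNPs when allele columns are
#' present. Exclusion counts per reason are attached as the `qc_counts`
#' attribute.
#'
#' @param model A [prs_model()].
#' @return The model with added `qc_pass` and `qc_reason` columns.
#' @export
snp_qc <- function(model) {
  need <- c("snp_id", "beta", "maf", "info")
  if (!all(need %in% names(model)))
    stop("missing QC columns: ", paste(setdiff(need, names(model)), collapse = ", "))
  reason <- rep(NA_character_, nrow(model))
  flag <- function(bad, why) {
    take <- bad & is.na(reason)
    reason[take] <<- why
  }
  flag(model$maf < 0.01, "maf")
  flag(model$info < 0.8, "info")
  flag(model$snp_id %in% model$snp_id[duplicated(model$snp_id)], "duplicate")
  if (all(c("effect_allele", "other_allele") %in% names(model))) {
    pair <- paste0(model$effect_allele, model$other_allele)
    flag(pair %in% c("AT", "TA", "CG", "GC"), "ambiguous")
  }
  model$qc_pass <- is.na(reason)
  model$qc_reason <- reason
  attr(model, "qc_counts") <- table(factor(
    reason, levels = c("maf", "info", "duplicate", "ambiguous")))
  model
}

#' Polygenic score as the weighted sum of allele dosages
#'
#' Computes, per participant, `prs = sum_i g_i * beta_i` over the QC-passing
#' SNPs, where `g_i` is the dosage (0, 1 or 2) at SNP `i`.
#'
#' @param genotypes Integer dosage matrix, participants x SNPs, values in
#'   \{0, 1, 2\}, with SNP ids as column names and participant ids as row
#'   names.
#' @param model A [prs_model()]; if [snp_qc()] has been run, only `qc_pass`
#'   SNPs contribute.
#' @return Data.frame of class `prs_scores` with `participant_id` and `prs`.
#' @export
compute_prs <- function(genotypes, model) {
  if (!all(genotypes %in% c(0L, 1L, 2L)))
    stop("dosages must take values 0, 1 or 2")
  use <- if ("qc_pass" %in% names(model)) model[model$qc_pass, ] else model
  missing_snps <- setdiff(use$snp_id, colnames(genotypes))
  if (length(missing_snps))
    stop("genotype columns missing for SNPs: ",
         paste(utils::head(missing_snps, 5), collapse = ", "))
  G <- genotypes[, use$snp_id, drop = FALSE]
  out <- data.frame(participant_id = rownames(genotypes),
                    prs = as.numeric(G %*% use$beta),
                    stringsAsFactors = FALSE)
  class(out) <- c("prs_scores", "data.frame")
  out
}

#' Extreme-score groups as a binary outcome
#'
#' Labels the top-`q` fraction of scores 1 (highest genetic liability) and the
#' bottom-`q` fraction 0; everyone in between is excluded from the regression
#' sample. Ties are broken by the documented stable rule: sort by
#' (score, participant_id), then slice. A fully tied score vector has no
#' defined extremes and is rejected.
#'
#' @param scores A [compute_prs()] result (or data.frame with
#'   `participant_id`, `prs`).
#' @param q Extreme fraction per tail, in (0, 0.5).
#' @return Data.frame with `participant_id`, `prs` and binary `outcome`,
#'   restricted to the kept extremes.
#' @export
select_extremes <- function(scores, q = 0.05) {
  if (!(q > 0 && q < 0.5)) stop("q must lie in (0, 0.5)")
  n <- nrow(scores)
  n_ext <- floor(q * n)
  if (n_ext < 1) stop("too few participants for nonempty extreme groups")
  if (length(unique(scores$prs)) == 1)
    stop("all scores tied: extreme groups are undefined")
  ord <- order(scores$prs, scores$participant_id)
  bottom <- ord[seq_len(n_ext)]
  top <- ord[seq(n - n_ext + 1, n)]
  out <- rbind(
    data.frame(participant_id = scores$participant_id[bottom],
               prs = scores$prs[bottom], outcome = 0L,
               stringsAsFactors = FALSE),
    data.frame(participant_id = scores$participant_id[top],
               prs = scores$prs[top], outcome = 1L,
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Bayesian logistic regression of extreme genetic liability on mode expressions
#'
#' Fits, by MCMC, the logistic model
#' `logit P(y = 1) = sum_j x_j beta_mode_j + alpha_sex + alpha_sex_age * age`
#' with standard-normal priors on every slope and on the sex-specific
#' intercepts and age slopes; `y` is the top-vs-bottom extreme-group
#' indicator and `x_j` are participant-wise mode expressions (canonical
#' variates). Age is z-scored before entering the model; the variates are
#' z-scored by default as well (switchable). Sampling uses JAGS with its GLM
#' block sampler, three chains by default, with per-chain seeds derived from
#' `seed`.
#'
#' A coefficient is "relevant" when at least `prob_threshold` (default 95%) of
#' its central posterior mass excludes zero, i.e. the equal-tailed
#' `prob_threshold` credible interval does not cover zero (the standard
#' operationalization of a coefficient posterior "excluding" zero). The
#' posterior one-sidedness `P(sign constant)` is also reported per
#' coefficient as `excl_prob`; the flag is equivalent to
#' `excl_prob >= 1 - (1 - prob_threshold)/2`. Convergence
#' is checked per coefficient (split-chain R-hat <= `rhat_max`, effective
#' sample size >= `ess_min`); a failing fit is returned with
#' `reliable = FALSE` and a warning, never silently.
#'
#' An alternative continuous-outcome variant (`family = "linear"`, identity
#' link, Gaussian noise with a half-Cauchy-free `sigma ~ Uniform(0, 10)`) is
#' available for regressing the raw score instead of the extreme-group label.
#'
#' @param variates Numeric matrix (n x m) of mode expressions.
#' @param outcome Binary 0/1 vector (ignored for `family = "linear"`, where
#'   a numeric outcome is expected).
#' @param sex Binary 0/1 vector (0 = men convention is immaterial; the two
#'   levels get separate intercepts and age slopes).
#' @param age Numeric age vector (z-scored internally).
#' @param chains,n_iter,n_adapt MCMC run count and lengths.
#' @param scale_variates z-score the predictor columns (default `TRUE`).
#' @param prob_threshold Posterior one-sided mass required to flag.
#' @param rhat_max,ess_min Convergence thresholds.
#' @param family `"logistic"` (default) or `"linear"`.
#' @param seed Integer seed.
#' @return An object of class `posterior_summary`: `summary` data.frame
#'   (term, mean, sd, lower95, upper95, excl_prob, flagged, rhat, ess),
#'   `draws` (coda::mcmc.list), `reliable`, and the model configuration.
#' @export
fit_bayesian_logistic <- function(variates, outcome, sex, age,
                                  chains = 3, n_iter = 1000, n_adapt = 500,
                                  scale_variates = TRUE, prob_threshold = 0.95,
                                  rhat_max = 1.01, ess_min = 400,
                                  family = c("logistic", "linear"), seed = 1) {
  family <- match.arg(family)
  X <- as.matrix(variates)
  n <- nrow(X); m <- ncol(X)
  if (length(outcome) != n || length(sex) != n || length(age) != n)
    stop("outcome, sex and age must match the variate rows")
  if (family == "logistic" && !all(outcome %in% c(0, 1)))
    stop("logistic family requires a binary 0/1 outcome")
  if (!all(sex %in% c(0, 1))) stop("sex must be coded {0,1}")
  if (scale_variates) X <- scale(X)
  zage <- as.numeric(scale(age))

  lik <- if (family == "logistic")
    "logit(mu[i]) <- eta[i]\n      y[i] ~ dbern(mu[i])"
  else
    "y[i] ~ dnorm(eta[i], tau)"
  extra <- if (family == "linear")
    "sigma ~ dunif(0, 10)\n    tau <- pow(sigma, -2)" else ""
  model_str <- sprintf("
  model {
    for (i in 1:n) {
      eta[i] <- inprod(X[i,], beta) + alpha[sex[i] + 1] + alpha_age[sex[i] + 1] * age[i]
      %s
    }
    for (j in 1:m) { beta[j] ~ dnorm(0, 1) }
    for (s in 1:2) { alpha[s] ~ dnorm(0, 1); alpha_age[s] ~ dnorm(0, 1) }
    %s
  }", lik, extra)

  inits <- lapply(seq_len(chains), function(c)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = block_seed(seed, 100 + c)))
  rjags::load.module("glm", quiet = TRUE)
  con <- textConnection(model_str)
  on.exit(close(con), add = TRUE)
  jm <- rjags::jags.model(con,
                          data = list(y = outcome, X = X, sex = sex,
                                      age = zage, n = n, m = m),
                          inits = inits, n.chains = chains,
                          n.adapt = n_adapt, quiet = TRUE)
  draws <- rjags::coda.samples(jm, c("beta", "alpha", "alpha_age"),
                               n.iter = n_iter)

  all_draws <- do.call(rbind, lapply(draws, as.matrix))
  terms <- colnames(all_draws)
  pretty <- sub("^beta\\[(\\d+)\\]$", "beta_mode_\\1", terms)
  pretty <- sub("^alpha\\[1\\]$", "alpha_men", pretty)
  pretty <- sub("^alpha\\[2\\]$", "alpha_women", pretty)
  pretty <- sub("^alpha_age\\[1\\]$", "alpha_men_age", pretty)
  pretty <- sub("^alpha_age\\[2\\]$", "alpha_women_age", pretty)
  p_pos <- colMeans(all_draws > 0)
  excl <- pmax(p_pos, 1 - p_pos)
  flag_cut <- 1 - (1 - prob_threshold) / 2
  rhat <- tryCatch(
    coda::gelman.diag(draws, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, length(terms)))
  ess <- coda::effectiveSize(draws)
  summ <- data.frame(
    term = pretty,
    mean = colMeans(all_draws),
    sd = apply(all_draws, 2, stats::sd),
    lower95 = apply(all_draws, 2, stats::quantile, 0.025),
    upper95 = apply(all_draws, 2, stats::quantile, 0.975),
    excl_prob = excl,
    flagged = excl >= flag_cut,
    rhat = rhat[terms],
    ess = as.numeric(ess[terms]),
    row.names = NULL, stringsAsFactors = FALSE)
  reliable <- all(summ$rhat <= rhat_max, na.rm = TRUE) &&
    all(summ$ess >= ess_min)
  if (!reliable)
    warning("MCMC convergence diagnostics failed (R-hat > ", rhat_max,
            " or ESS < ", ess_min, "); treat this fit as unreliable")
  structure(list(summary = summ, draws = draws, reliable = reliable,
                 config = list(chains = chains, n_iter = n_iter,
                               n_adapt = n_adapt, family = family,
                               prob_threshold = prob_threshold,
                               scale_variates = scale_variates, seed = seed)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  nb <- grepl("^beta_mode_", x$summary$term)
  cat(sprintf(
    "posterior_summary (%s): %d chains x %d draws, %d/%d mode coefficients flagged%s\n",
    x$config$family, x$config$chains, x$config$n_iter,
    sum(x$summary$flagged[nb]), sum(nb),
    if (x$reliable) "" else " [UNRELIABLE: diagnostics failed]"))
  invisible(x)
}

#' Flagged mode coefficients of a posterior summary
#'
#' @param x A `posterior_summary`.
#' @return Integer indices of the mode coefficients whose posterior mass
#'   excludes zero at the configured threshold.
#' @export
flagged_modes <- function(x) {
  s <- x$summary[grepl("^beta_mode_", x$summary$term), ]
  idx <- as.integer(sub("^beta_mode_", "", s$term))
  sort(idx[s$flagged])
}

#' Read / write SNP effect tables and score tables as TSV
#'
#' @param path TSV path with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `maf`, `info` (allele columns optional).
#' @return A [prs_model()].
#' @export
read_prs_model <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  prs_model(df$snp_id, df$beta, df$maf, df$info,
            effect_allele = df$effect_allele, other_allele = df$other_allele)
}
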