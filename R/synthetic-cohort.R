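#' Specification of a synthetic two-view cohort
#'
#' Defines the generative model for a cohort whose two volume matrices (DN and
#' HC) share `k_true` planted latent modes of co-variation with strictly
#' decreasing strengths. Each participant draws latent factors
#' `z_l ~ N(0, factor_strengths[l]^2)`; the DN matrix is
#' `sum_l z_l a_l' + noise` and the HC matrix `sum_l z_l b_l' + noise`, with
#' sparse unit-norm loading vectors `a_l`, `b_l`. Participants in the
#' "isolated" group (label 1) use loadings shifted by `delta` at
#' `perturbed_entries`, which plants a group difference in the canonical
#' vectors rather than in volume means. Confound columns (age, age^2, sex,
#' sex x age interactions, plus three scanner-like nuisances) contribute
#' linearly with known coefficients. Genotypes are binomial dosages; when
#' `prs_mode_coupling > 0` the weighted genotype score feeds the designated
#' mode's latent factor, so genetic liability and that mode's expression are
#' correlated by construction.
#'
#' @param n_per_group Participants per group (two groups).
#' @param p_dn,q_hc Subregion counts for the DN and HC views. When they equal
#'   the default atlas sizes (91 / 38) columns carry the default anatomy.
#' @param k_true Number of planted latent modes.
#' @param factor_strengths Per-mode latent signal standard deviations; must be
#'   positive and strictly decreasing.
#' @param loading_sparsity Fraction of nonzero loading entries per mode, in
#'   (0, 1].
#' @param noise_sd Residual standard deviation of the volume noise.
#' @param delta Loading perturbation magnitude for group 1.
#' @param perturbed_entries List of `list(mode=, side=, index=)` triplets
#'   (`side` is `"dn"` or `"hc"`) naming which loading entries are shifted.
#' @param n_snps Number of simulated SNPs.
#' @param maf_range Minor-allele frequency interval, within (0, 0.5].
#' @param prs_mode_coupling Correlation (in \[0, 1)) between the standardized
#'   true polygenic score and the designated mode's latent factor.
#' @param coupled_mode Which mode the polygenic score feeds (default 1).
#' @param confound_strength Standard deviation of the planted confound
#'   coefficients (0 switches confound contamination off).
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 500, p_dn = 91, q_hc = 38, k_true = 3,
                        factor_strengths = c(3, 2, 1), loading_sparsity = 0.5,
                        noise_sd = 1, delta = 0, perturbed_entries = list(),
                        n_snps = 1000, maf_range = c(0.05, 0.5),
                        prs_mode_coupling = 0, coupled_mode = 1,
                        confound_strength = 0.5, seed = 1) {
  spec <- list(n_per_group = n_per_group, p_dn = p_dn, q_hc = q_hc,
               k_true = k_true, factor_strengths = factor_strengths,
               loading_sparsity = loading_sparsity, noise_sd = noise_sd,
               delta = delta, perturbed_entries = perturbed_entries,
               n_snps = n_snps, maf_range = maf_range,
               prs_mode_coupling = prs_mode_coupling,
               coupled_mode = coupled_mode,
               confound_strength = confound_strength, seed = seed)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  num_fields <- c("n_per_group", "p_dn", "q_hc", "k_true", "factor_strengths",
                  "loading_sparsity", "noise_sd", "delta", "n_snps",
                  "maf_range", "prs_mode_coupling", "coupled_mode",
                  "confound_strength", "seed")
  for (f in num_fields) {
    v <- spec[[f]]
    if (is.null(v) || !is.numeric(v) || any(!is.finite(v)))
      stop("cohort spec field `", f, "` must be finite numeric")
  }
  ks <- spec$factor_strengths
  if (length(ks) != spec$k_true)
    stop("cohort spec field `factor_strengths` must have length k_true")
  if (any(ks <= 0) || (length(ks) > 1 && any(diff(ks) >= 0)))
    stop("cohort spec field `factor_strengths` must be positive and strictly decreasing")
  if (spec$loading_sparsity <= 0 || spec$loading_sparsity > 1)
    stop("cohort spec field `loading_sparsity` must be in (0, 1]")
  if (length(spec$maf_range) != 2 || spec$maf_range[1] <= 0 ||
      spec$maf_range[2] > 0.5 || spec$maf_range[1] > spec$maf_range[2])
    stop("cohort spec field `maf_range` must lie within (0, 0.5]")
  if (spec$prs_mode_coupling < 0 || spec$prs_mode_coupling >= 1)
    stop("cohort spec field `prs_mode_coupling` must be in [0, 1)")
  if (spec$coupled_mode < 1 || spec$coupled_mode > spec$k_true)
    stop("cohort spec field `coupled_mode` must index a planted mode")
  for (pe in spec$perturbed_entries) {
    if (!all(c("mode", "side", "index") %in% names(pe)))
      stop("perturbed_entries must be lists with mode, side, index")
    if (!pe$side %in% c("dn", "hc"))
      stop("perturbed entry side must be 'dn' or 'hc'")
    pmax <- if (pe$side == "dn") spec$p_dn else spec$q_hc
    if (pe$mode < 1 || pe$mode > spec$k_true || pe$index < 1 || pe$index > pmax)
      stop("perturbed entry references an out-of-range mode or subregion")
  }
  invisible(spec)
}

# deterministic sub-stream seeds so e.g. changing n_snps leaves volumes alone
block_seed <- function(seed, block) {
  (abs(seed) * 48271 + block * 16807) %% 2147483629
}

sparse_unit_loadings <- function(p, k, sparsity) {
  A <- matrix(0, p, k)
  m <- max(1L, ceiling(sparsity * p))
  for (l in seq_len(k)) {
    idx <- sample.int(p, m)
    A[idx, l] <- stats::rnorm(m)
    A[, l] <- A[, l] / sqrt(sum(A[, l]^2))
  }
  A
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort (two volume views, confound table, group labels,
#' genotypes with per-SNP effect sizes, and a ground-truth record) from a
#' [cohort_spec()]. Deterministic given `spec$seed`; separate RNG sub-streams
#' drive loadings, genotypes, factors/noise and confounds, so changing
#' `n_snps` does not alter the volume draws (unless the polygenic coupling is
#' active, which by construction mixes the genotype stream into the coupled
#' mode's factor).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `dn_volumes`,
#'   `hc_volumes` (both [volume_matrix()]), `confounds` (data.frame),
#'   `group_labels` (0/1 integer, 1 = low support), `genotypes` (n x n_snps
#'   dosage matrix), `snp_effects` (data.frame: snp_id, effect_allele,
#'   other_allele, beta, maf, info), and `truth` (planted loadings, factors,
#'   confound coefficients, perturbation and coupling record).
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  n <- 2L * spec$n_per_group
  p <- spec$p_dn; q <- spec$q_hc; k <- spec$k_true
  if (spec$n_per_group < p + q)
    warning("n_per_group < p_dn + q_hc: per-group CCA will overfit")
  ids <- sprintf("P%05d", seq_len(n))
  groups <- rep(c(0L, 1L), each = spec$n_per_group)

  # block 1: loadings
  set.seed(block_seed(spec$seed, 1))
  A <- sparse_unit_loadings(p, k, spec$loading_sparsity)  # DN side
  B <- sparse_unit_loadings(q, k, spec$loading_sparsity)  # HC side

  # block 2: genotypes and per-SNP effects
  set.seed(block_seed(spec$seed, 2))
  maf <- stats::runif(spec$n_snps, spec$maf_range[1], spec$maf_range[2])
  G <- matrix(stats::rbinom(n * spec$n_snps, 2L, rep(maf, each = n)),
              nrow = n, ncol = spec$n_snps)
  rownames(G) <- ids
  colnames(G) <- sprintf("rs%06d", seq_len(spec$n_snps))
  beta <- stats::rnorm(spec$n_snps) / sqrt(spec$n_snps)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, spec$n_snps, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), character(1))
  snp_effects <- data.frame(snp_id = colnames(G), effect_allele = ea,
                            other_allele = unname(oa), beta = beta, maf = maf,
                            info = stats::runif(spec$n_snps, 0.85, 1),
                            stringsAsFactors = FALSE)
  prs_true <- as.numeric(G %*% beta)
  prs_std <- as.numeric(scale(prs_true))

  # block 3: latent factors and volume noise
  set.seed(block_seed(spec$seed, 3))
  Z <- matrix(stats::rnorm(n * k), n, k)
  rho <- spec$prs_mode_coupling
  if (rho > 0)
    Z[, spec$coupled_mode] <- rho * prs_std +
      sqrt(1 - rho^2) * Z[, spec$coupled_mode]
  Z <- sweep(Z, 2, spec$factor_strengths, `*`)
  Edn <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
  Ehc <- matrix(stats::rnorm(n * q, sd = spec$noise_sd), n, q)

  # group-1 rows mix through perturbed loadings
  A1 <- A; B1 <- B
  for (pe in spec$perturbed_entries) {
    if (pe$side == "dn") A1[pe$index, pe$mode] <- A1[pe$index, pe$mode] + spec$delta
    else B1[pe$index, pe$mode] <- B1[pe$index, pe$mode] + spec$delta
  }
  g1 <- groups == 1L
  Xdn <- Edn; Xhc <- Ehc
  Xdn[!g1, ] <- Xdn[!g1, ] + Z[!g1, , drop = FALSE] %*% t(A)
  Xdn[g1, ]  <- Xdn[g1, ]  + Z[g1, , drop = FALSE] %*% t(A1)
  Xhc[!g1, ] <- Xhc[!g1, ] + Z[!g1, , drop = FALSE] %*% t(B)
  Xhc[g1, ]  <- Xhc[g1, ]  + Z[g1, , drop = FALSE] %*% t(B1)

  # block 4: confounds with known linear contribution
  set.seed(block_seed(spec$seed, 4))
  age <- stats::rnorm(n, 55, 7.5)
  sex <- stats::rbinom(n, 1, 0.5)
  conf <- data.frame(participant_id = ids, age = age, sex = sex,
                     head_motion = stats::rnorm(n),
                     head_position = stats::rnorm(n),
                     site_proxy = stats::rnorm(n),
                     stringsAsFactors = FALSE)
  design <- confound_design(conf)
  Cstd <- scale(design$matrix[, -1, drop = FALSE])  # drop intercept, z-scale
  Gamma <- matrix(stats::rnorm(ncol(Cstd) * (p + q), sd = spec$confound_strength),
                  ncol(Cstd), p + q)
  contrib <- Cstd %*% Gamma
  Xdn <- Xdn + contrib[, seq_len(p), drop = FALSE]
  Xhc <- Xhc + contrib[, p + seq_len(q), drop = FALSE]

  dn_anat <- if (p == 91) dn_atlas() else generic_anatomy("DN", p)
  hc_anat <- if (q == 38) hc_atlas() else generic_anatomy("HC", q)
  dimnames(Xdn) <- list(ids, dn_anat$subregion)
  dimnames(Xhc) <- list(ids, hc_anat$subregion)

  truth <- list(loadings_dn = A, loadings_hc = B,
                loadings_dn_group1 = A1, loadings_hc_group1 = B1,
                factor_strengths = spec$factor_strengths, factors = Z,
                confound_coef = Gamma, confound_columns = colnames(Cstd),
                confound_contribution = contrib,
                perturbed_entries = spec$perturbed_entries, delta = spec$delta,
                prs_true = prs_true, prs_mode_coupling = rho,
                coupled_mode = spec$coupled_mode)

  structure(list(spec = spec,
                 dn_volumes = volume_matrix(Xdn, dn_anat),
                 hc_volumes = volume_matrix(Xhc, hc_anat),
                 confounds = conf, group_labels = groups,
                 genotypes = G, snp_effects = snp_effects, truth = truth),
            class = "synthetic_cohort")
}

generic_anatomy <- function(structure, m) {
  data.frame(subregion = sprintf("%s_%03d", structure, seq_len(m)),
             structure = structure,
             hemisphere = rep(c("L", "R"), length.out = m),
             category = structure, part = NA_character_,
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d participants (%d per group), %d DN + %d HC subregions, %d SNPs, %d planted modes\n",
    length(x$group_labels), x$spec$n_per_group, ncol(x$dn_volumes$data),
    ncol(x$hc_volumes$data), ncol(x$genotypes), x$spec$k_true))
  invisible(x)
}

#' Write / read a synthetic cohort as a TSV + JSON bundle
#'
#' Writes `dn_volumes.tsv`, `hc_volumes.tsv`, `confounds.tsv`,
#' `phenotype.tsv`, `genotypes.tsv`, `snp_effects.tsv` and a `truth.json`
#' sidecar (plus the spec as `cohort_spec.yaml`) into `dir`. All tables carry
#' a `participant_id` key column.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` the cohort.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume_tsv(cohort$dn_volumes, file.path(dir, "dn_volumes.tsv"))
  write_volume_tsv(cohort$hc_volumes, file.path(dir, "hc_volumes.tsv"))
  utils::write.table(rbind(cohort$dn_volumes$anatomy, cohort$hc_volumes$anatomy),
                     file.path(dir, "anatomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$confounds, file.path(dir, "confounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pheno <- data.frame(participant_id = rownames(cohort$genotypes),
                      low_support = cohort$group_labels)
  utils::write.table(pheno, file.path(dir, "phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gdf <- data.frame(participant_id = rownames(cohort$genotypes),
                    cohort$genotypes, check.names = FALSE)
  utils::write.table(gdf, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$snp_effects, file.path(dir, "snp_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  tr$factors <- NULL  # large; regenerable from the spec
  tr$confound_contribution <- NULL
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(cohort$spec), file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  raw_spec <- yaml::read_yaml(file.path(dir, "cohort_spec.yaml"))
  spec <- do.call(cohort_spec, raw_spec)
  conf <- utils::read.delim(file.path(dir, "confounds.tsv"),
                            stringsAsFactors = FALSE)
  pheno <- utils::read.delim(file.path(dir, "phenotype.tsv"),
                             stringsAsFactors = FALSE)
  gdf <- utils::read.delim(file.path(dir, "genotypes.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  G <- as.matrix(gdf[, -1, drop = FALSE])
  rownames(G) <- gdf$participant_id
  storage.mode(G) <- "integer"
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  for (f in c("loadings_dn", "loadings_hc", "loadings_dn_group1",
              "loadings_hc_group1", "confound_coef"))
    if (!is.null(truth[[f]])) truth[[f]] <- as.matrix(truth[[f]])
  anat <- utils::read.delim(file.path(dir, "anatomy.tsv"),
                            stringsAsFactors = FALSE)
  anat$part[anat$part %in% c("NA", "")] <- NA_character_
  structure(list(spec = spec,
                 dn_volumes = read_volume_tsv(file.path(dir, "dn_volumes.tsv"),
                                              anatomy = anat[anat$structure == "DN", ]),
                 hc_volumes = read_volume_tsv(file.path(dir, "hc_volumes.tsv"),
                                              anatomy = anat[anat$structure == "HC", ]),
                 confounds = conf, group_labels = as.integer(pheno$low_support),
                 genotypes = G,
                 snp_effects = utils::read.delim(file.path(dir, "snp_effects.tsv"),
                                                 stringsAsFactors = FALSE),
                 truth = truth),
            class = "synthetic_cohort")
}
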