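#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()]. A
#' configuration either names input TSV paths (volumes, confounds, phenotype,
#' genotypes, SNP effects) or carries a [cohort_spec()] under `simulate`, in
#' which case the cohort is generated (and written) first. All randomness is
#' funneled through named seed fields.
#'
#' @param out_dir Output directory for all artifacts.
#' @param stages Character subset of
#'   `c("simulate", "deconfound", "cca", "contrast", "prs", "report")`.
#' @param simulate A `cohort_spec` (or plain list of its fields), required
#'   when the `"simulate"` stage is enabled.
#' @param paths Named list of input TSVs (`dn`, `hc`, `confounds`,
#'   `phenotype`, `genotypes`, `snp_effects`), required for stages that
#'   consume them when `"simulate"` is disabled.
#' @param k Modes to fit (default 25).
#' @param bootstrap_B Bootstrap replicates (default 100).
#' @param interval Percentile interval bounds (default `c(10, 90)`).
#' @param extreme_q Extreme-group fraction per tail (default 0.05).
#' @param prs_side Which view's variates enter the genetic regression,
#'   `"hc"` or `"dn"`.
#' @param ridge Ridge for the CCA fits.
#' @param seed Master seed.
#' @param mcmc Named list overriding MCMC settings
#'   (`chains`, `n_iter`, `n_adapt`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, stages = c("simulate", "deconfound",
                                                "cca", "contrast", "prs",
                                                "report"),
                            simulate = NULL, paths = list(), k = 25,
                            bootstrap_B = 100, interval = c(10, 90),
                            extreme_q = 0.05, prs_side = c("hc", "dn"),
                            ridge = 0, seed = 1, mcmc = list()) {
  prs_side <- match.arg(prs_side)
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- list(out_dir = out_dir, stages = stages, simulate = simulate,
              paths = paths, k = k, bootstrap_B = bootstrap_B,
              interval = interval, extreme_q = extreme_q,
              prs_side = prs_side, ridge = ridge, seed = seed, mcmc = mcmc)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if ("simulate" %in% cfg$stages) {
    if (is.null(cfg$simulate))
      stop("pipeline config error [field: simulate]: stage enabled but no cohort spec")
  } else {
    need <- c("dn", "hc")
    if ("deconfound" %in% cfg$stages) need <- c(need, "confounds")
    if ("contrast" %in% cfg$stages) need <- c(need, "phenotype")
    if ("prs" %in% cfg$stages) need <- c(need, "genotypes", "snp_effects")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss))
      stop("pipeline config error [field: paths$", miss[1],
           "]: required input path missing")
    gone <- unlist(cfg$paths[need])[!file.exists(unlist(cfg$paths[need]))]
    if (length(gone))
      stop("pipeline config error: input file does not exist: ", gone[1])
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) raw$simulate <- do.call(cohort_spec, raw$simulate)
  do.call(pipeline_config, raw)
}

# cheap stable FNV-1a content hash for provenance stamping
config_hash <- function(cfg) {
  txt <- yaml::as.yaml(unclass(cfg))
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: simulate (or load inputs) ->
#' deconfound (residualize + z-score) -> CCA -> bootstrap group contrast ->
#' polygenic scoring, extreme-group selection and Bayesian logistic
#' association -> anatomical hit report. Every output bundle carries a
#' provenance block (`provenance.json`: config hash, seed, package version,
#' stages run), making a run reproducible from its own record. A stage
#' failure aborts with the stage name and an error code.
#'
#' @param config A [pipeline_config()] (or path to its YAML).
#' @return Invisible list with the in-memory stage products: `cohort`,
#'   `dn`, `hc` (deconfounded), `cca`, `contrast`, `prs`, `posterior`,
#'   `tables`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] [code %s] %s", name,
                   paste0("E_", toupper(name)), conditionMessage(e)),
           call. = FALSE))
  }
  out <- list()

  if ("simulate" %in% config$stages) {
    out$cohort <- stage("simulate", {
      co <- generate_cohort(config$simulate)
      write_cohort(co, file.path(config$out_dir, "cohort"))
      co
    })
    dn <- out$cohort$dn_volumes; hc <- out$cohort$hc_volumes
    confounds <- out$cohort$confounds
    groups <- out$cohort$group_labels
    genotypes <- out$cohort$genotypes
    snp_effects <- out$cohort$snp_effects
  } else {
    dn <- stage("load", read_volume_tsv(config$paths$dn))
    hc <- stage("load", read_volume_tsv(config$paths$hc))
    confounds <- if (!is.null(config$paths$confounds))
      stage("load", utils::read.delim(config$paths$confounds,
                                      stringsAsFactors = FALSE))
    groups <- if (!is.null(config$paths$phenotype))
      stage("load", utils::read.delim(config$paths$phenotype)$low_support)
    genotypes <- if (!is.null(config$paths$genotypes)) stage("load", {
      g <- utils::read.delim(config$paths$genotypes, check.names = FALSE)
      m <- as.matrix(g[, -1, drop = FALSE]); rownames(m) <- g$participant_id
      storage.mode(m) <- "integer"; m
    })
    snp_effects <- if (!is.null(config$paths$snp_effects))
      stage("load", utils::read.delim(config$paths$snp_effects,
                                      stringsAsFactors = FALSE))
  }

  if ("deconfound" %in% config$stages) {
    dn <- stage("deconfound", deconfound(dn, confounds))
    hc <- stage("deconfound", deconfound(hc, confounds))
  }
  out$dn <- dn; out$hc <- hc

  if ("cca" %in% config$stages) {
    out$cca <- stage("cca", fit_cca(dn, hc, k = config$k, ridge = config$ridge))
    write_cca_solution(out$cca, file.path(config$out_dir, "cca"))
  }

  if ("contrast" %in% config$stages) {
    out$contrast <- stage("contrast", bootstrap_group_difference(
      dn, hc, groups, B = config$bootstrap_B, k = config$k,
      seed = block_seed(config$seed, 11), interval = config$interval,
      ridge = config$ridge))
    write_contrast_tables(out$contrast, file.path(config$out_dir, "contrast"))
  }

  if ("prs" %in% config$stages) {
    prs_out <- stage("prs", {
      model <- snp_qc(prs_model(snp_effects$snp_id, snp_effects$beta,
                                snp_effects$maf, snp_effects$info,
                                effect_allele = snp_effects$effect_allele,
                                other_allele = snp_effects$other_allele))
      scores <- compute_prs(genotypes, model)
      extremes <- select_extremes(scores, q = config$extreme_q)
      sol <- out$cca
      if (is.null(sol)) stop("prs stage requires the cca stage")
      variates <- if (config$prs_side == "hc") sol$hc_variates else sol$dn_variates
      rows <- match(extremes$participant_id, rownames(variates))
      crows <- match(extremes$participant_id, confounds$participant_id)
      mc <- utils::modifyList(list(chains = 3, n_iter = 1000, n_adapt = 500),
                              config$mcmc)
      post <- fit_bayesian_logistic(
        variates[rows, , drop = FALSE], extremes$outcome,
        sex = confounds$sex[crows], age = confounds$age[crows],
        chains = mc$chains, n_iter = mc$n_iter, n_adapt = mc$n_adapt,
        seed = block_seed(config$seed, 12))
      utils::write.table(post$summary,
                         file.path(config$out_dir, "posterior_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(scores = scores, posterior = post)
    })
    out$prs <- prs_out$scores
    out$posterior <- prs_out$posterior
  }

  if ("report" %in% config$stages && !is.null(out$contrast)) {
    out$tables <- stage("report", {
      tabs <- tally_hits(out$contrast)
      write_hit_tables(tabs, file.path(config$out_dir, "report"))
      writeLines(c(format_hit_table(tabs$hc, "HC subregion hits by mode"), "",
                   format_hit_table(tabs$dn, "DN subregion hits by mode")),
                 file.path(config$out_dir, "report", "hit_tables.md"))
      tabs
    })
  }

  out$provenance <- list(config_hash = config_hash(config), seed = config$seed,
                         stages = config$stages,
                         package_version = as.character(
                           utils::packageVersion("ccamodes")),
                         config = unclass(config)[setdiff(names(config),
                                                          "simulate")],
                         cohort_spec = if (!is.null(config$simulate))
                           unclass(config$simulate))
  jsonlite::write_json(out$provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
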