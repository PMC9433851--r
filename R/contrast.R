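#' Bootstrap difference test of group-specific canonical vectors
#'
#' The central inferential procedure: for each of `B` bootstrap replicates,
#' both groups are resampled with replacement (each to its own original size),
#' one CCA is fitted per group, both group solutions are aligned — in mode
#' order and sign — to a single reference CCA fitted once on the full cohort,
#' and the elementwise difference of the aligned canonical vectors (group 1,
#' "low support", minus group 0) is recorded per mode and per subregion. The
#' B difference draws per (mode, subregion) cell form a non-parametric
#' distribution of group-contrast estimates; a cell is a "hit" when the
#' two-sided percentile interval (default 10th/90th, an 80%-coverage interval)
#' excludes zero.
#'
#' Aligning both group solutions to the same full-cohort reference fixes their
#' mutual correspondence within a replicate and a stable orientation across
#' replicates in one step. Replicates whose match score falls below the
#' alignment flag threshold are kept but counted. No multiple-testing
#' correction is applied across the k x (p+q) cells; the number of tests is
#' recorded in the result.
#'
#' @param dn,hc Deconfounded, z-scored views over the same participants.
#' @param groups Binary labels (1 = low support), one per participant.
#' @param B Number of bootstrap replicates (default 100).
#' @param k Number of modes to test.
#' @param seed Integer seed; the full procedure is deterministic given it.
#' @param interval Percentile bounds in percent, default `c(10, 90)`.
#' @param ridge Passed to [fit_cca()] for group fits.
#' @param pooled_resample If `TRUE`, each replicate resamples the pooled
#'   cohort and splits by label (sensitivity variant); default `FALSE`
#'   (within-group stratified resampling, which guarantees both groups stay
#'   fittable at their original sizes).
#' @param resample If `FALSE`, replicates use each group's full sample as-is
#'   (identity "resampling"); a diagnostic switch — with it the per-replicate
#'   differences are the fixed group contrast with no sampling noise.
#' @param flag_threshold Match-score flag threshold, see [match_modes()].
#' @return An object of class `contrast_result`: `differences`
#'   (B x k x (p+q) array), `ci_lower`, `ci_upper`, `hit_flags` (k x (p+q)),
#'   `replicate_match_scores` (B x k, per-replicate minimum of the two group
#'   match scores), `n_flagged_replicates`, `anatomy`, `reference` (the
#'   full-cohort solution) and a `config` echo.
#' @export
bootstrap_group_difference <- function(dn, hc, groups, B = 100, k = 25,
                                       seed = 1, interval = c(10, 90),
                                       ridge = 0, pooled_resample = FALSE,
                                       resample = TRUE,
                                       flag_threshold = 0.5) {
  X <- as_matrix(dn); Y <- as_matrix(hc)
  groups <- as.integer(groups)
  if (length(groups) != nrow(X))
    stop("groups must have one label per participant")
  if (length(unique(groups)) < 2)
    stop("both groups must be nonempty (labels are all identical)")
  idx0 <- which(groups == 0L); idx1 <- which(groups == 1L)
  if (min(length(idx0), length(idx1)) <= k)
    stop("each group must exceed k participants to fit ", k, " modes")
  pq <- ncol(X) + ncol(Y)
  entry_labels <- c(colnames(X), colnames(Y))

  reference <- fit_cca(dn, hc, k = k, ridge = ridge)
  diffs <- array(NA_real_, dim = c(B, k, pq),
                 dimnames = list(NULL, paste0("mode", seq_len(k)), entry_labels))
  scores <- matrix(NA_real_, B, k)
  set.seed(seed)
  for (b in seq_len(B)) {
    if (!resample) {
      r0 <- idx0; r1 <- idx1
    } else if (pooled_resample) {
      take <- sample(length(groups), replace = TRUE)
      r0 <- take[groups[take] == 0L]; r1 <- take[groups[take] == 1L]
      if (min(length(r0), length(r1)) <= k)
        stop("pooled resample left a group with <= k participants")
    } else {
      r0 <- sample(idx0, replace = TRUE)
      r1 <- sample(idx1, replace = TRUE)
    }
    s0 <- fit_cca(X[r0, , drop = FALSE], Y[r0, , drop = FALSE],
                  k = k, ridge = ridge)
    s1 <- fit_cca(X[r1, , drop = FALSE], Y[r1, , drop = FALSE],
                  k = k, ridge = ridge)
    m0 <- match_modes(reference, s0, flag_threshold = flag_threshold)
    m1 <- match_modes(reference, s1, flag_threshold = flag_threshold)
    a0 <- apply_match(s0, m0)
    a1 <- apply_match(s1, m1)
    W0 <- rbind(a0$v_weights, a0$u_weights)
    W1 <- rbind(a1$v_weights, a1$u_weights)
    diffs[b, , ] <- t(W1 - W0)     # low support minus adequate support
    scores[b, ] <- pmin(m0$match_scores, m1$match_scores)
  }

  anatomy <- contrast_anatomy(dn, hc, entry_labels)
  res <- structure(list(differences = diffs, anatomy = anatomy,
                        replicate_match_scores = scores,
                        n_flagged_replicates = sum(apply(scores < flag_threshold,
                                                         1, any)),
                        reference = reference,
                        config = list(B = B, k = k, interval = interval,
                                      seed = seed, ridge = ridge,
                                      pooled_resample = pooled_resample,
                                      resample = resample,
                                      flag_threshold = flag_threshold,
                                      n_tests = k * pq)),
                   class = "contrast_result")
  bounds <- percentile_bounds(diffs, interval[1], interval[2])
  res$ci_lower <- bounds$lower
  res$ci_upper <- bounds$upper
  res$hit_flags <- bounds$lower > 0 | bounds$upper < 0
  res
}

contrast_anatomy <- function(dn, hc, entry_labels) {
  an <- NULL
  if (inherits(dn, "volume_matrix") && inherits(hc, "volume_matrix"))
    an <- rbind(dn$anatomy, hc$anatomy)
  if (is.null(an))
    an <- data.frame(subregion = entry_labels, structure = NA_character_,
                     hemisphere = NA_character_, category = NA_character_,
                     part = NA_character_, stringsAsFactors = FALSE)
  rownames(an) <- NULL
  an
}

percentile_bounds <- function(diffs, lower_pct, upper_pct) {
  k <- dim(diffs)[2]; pq <- dim(diffs)[3]
  lo <- hi <- matrix(NA_real_, k, pq,
                     dimnames = dimnames(diffs)[2:3])
  for (l in seq_len(k)) {
    qs <- apply(diffs[, l, , drop = FALSE], 3, stats::quantile,
                probs = c(lower_pct, upper_pct) / 100, names = FALSE)
    lo[l, ] <- qs[1, ]; hi[l, ] <- qs[2, ]
  }
  list(lower = lo, upper = hi)
}

#' Recompute hit flags at other interval bounds
#'
#' Re-derives percentile bounds from the stored difference draws at the
#' requested coverage, without refitting anything — the sensitivity knob for
#' the hit rule.
#'
#' @param result A `contrast_result`.
#' @param lower_pct,upper_pct Percentiles in (0, 100), lower < upper.
#' @return Logical k x (p+q) hit matrix (interval excludes zero).
#' @export
determine_hits <- function(result, lower_pct = 10, upper_pct = 90) {
  if (!(lower_pct > 0 && upper_pct < 100 && lower_pct < upper_pct))
    stop("percentiles must satisfy 0 < lower < upper < 100")
  bounds <- percentile_bounds(result$differences, lower_pct, upper_pct)
  bounds$lower > 0 | bounds$upper < 0
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "contrast_result: B = %d replicates, %d modes x %d subregions, %d hits (%d tests, uncorrected)\n",
    x$config$B, nrow(x$hit_flags), ncol(x$hit_flags), sum(x$hit_flags),
    x$config$n_tests))
  if (x$n_flagged_replicates > 0)
    cat(sprintf("  %d replicate(s) carried a low-quality mode match\n",
                x$n_flagged_replicates))
  invisible(x)
}

#' Write contrast outputs as TSV tables
#'
#' Emits a per-(mode, subregion) hit table (`hits.tsv`: mode, subregion,
#' hemisphere, category, ci_lower, ci_upper, hit) and the full difference
#' draws in long format (`differences.tsv`).
#'
#' @param result A `contrast_result`.
#' @param dir Output directory.
#' @param draws Also write the (large) per-replicate draws (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_contrast_tables <- function(result, dir, draws = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  k <- nrow(result$hit_flags)
  an <- result$anatomy
  tab <- do.call(rbind, lapply(seq_len(k), function(l) {
    data.frame(mode = l, subregion = an$subregion, structure = an$structure,
               hemisphere = an$hemisphere, category = an$category,
               ci_lower = result$ci_lower[l, ], ci_upper = result$ci_upper[l, ],
               hit = result$hit_flags[l, ], stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, file.path(dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (draws) {
    d <- result$differences
    long <- data.frame(
      replicate = rep(seq_len(dim(d)[1]), times = dim(d)[2] * dim(d)[3]),
      mode = rep(rep(seq_len(dim(d)[2]), each = dim(d)[1]), times = dim(d)[3]),
      subregion = rep(dimnames(d)[[3]], each = dim(d)[1] * dim(d)[2]),
      difference = as.vector(d), stringsAsFactors = FALSE)
    utils::write.table(long, file.path(dir, "differences.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
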