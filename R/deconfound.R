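#' Build the confound design matrix
#'
#' Assembles an intercept-plus-nuisance design from a confound table. When
#' `age` and `sex` are present and the derived columns are absent, `age^2`,
#' `sex*age` and `sex*age^2` are computed internally from uncentered age
#' (documented convention; centering is not applied before squaring). Any
#' additional numeric columns (body-size, head-size, motion, position, site
#' proxies, ...) enter as given, so the nuisance inventory is configurable
#' rather than hard-coded.
#'
#' @param confounds Data.frame with a `participant_id` column and numeric
#'   nuisance columns; `sex`, if present, must be coded 0/1.
#' @param interactions Add age^2 and sex-by-age interaction columns when both
#'   `age` and `sex` are available (default `TRUE`).
#' @return List with `matrix` (n x m design including intercept) and
#'   `participant_id`.
#' @export
confound_design <- function(confounds, interactions = TRUE) {
  if (!"participant_id" %in% names(confounds))
    stop("confound table must carry a participant_id column")
  ids <- as.character(confounds$participant_id)
  cols <- confounds[, setdiff(names(confounds), "participant_id"), drop = FALSE]
  if (!all(vapply(cols, is.numeric, logical(1))))
    stop("all confound columns must be numeric")
  if (anyNA(cols))
    stop("confound table contains missing values (complete cases required)")
  if ("sex" %in% names(cols) && !all(cols$sex %in% c(0, 1)))
    stop("sex must be coded {0,1}")
  if (interactions && all(c("age", "sex") %in% names(cols))) {
    if (!"age2" %in% names(cols)) cols$age2 <- cols$age^2
    if (!"sex_age" %in% names(cols)) cols$sex_age <- cols$sex * cols$age
    if (!"sex_age2" %in% names(cols)) cols$sex_age2 <- cols$sex * cols$age^2
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(cols))
  list(matrix = X, participant_id = ids)
}

#' Regress nuisance variation out of every subregion column
#'
#' Each volume column is replaced by the residual of an ordinary least-squares
#' fit on the full confound design (with intercept). Anatomy metadata is
#' preserved. This reproduces the standard neuroimaging deconfounding step in
#' which body/head-size, motion, scanner-position and demographic terms (age,
#' age^2, sex and their interactions) are removed before any multivariate
#' analysis.
#'
#' @param volumes A [volume_matrix()].
#' @param confounds Confound table (data.frame with `participant_id`) covering
#'   exactly the same participants.
#' @param interactions Passed to [confound_design()].
#' @return A deconfounded `volume_matrix`.
#' @export
residualize <- function(volumes, confounds, interactions = TRUE) {
  M <- as_matrix(volumes)
  des <- confound_design(confounds, interactions = interactions)
  if (!setequal(rownames(M), des$participant_id) ||
      length(des$participant_id) != nrow(M))
    stop("participant ids of volumes and confounds do not match")
  X <- des$matrix[match(rownames(M), des$participant_id), , drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("confound design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- M - X %*% qr.coef(qx, M)
  dimnames(res) <- dimnames(M)
  vm_like(volumes, res)
}

#' Standardize every subregion column to zero mean and unit variance
#'
#' z-scores each column using the sample standard deviation (n - 1
#' denominator). Applying the transform twice is a no-op.
#'
#' @param volumes A [volume_matrix()] (or numeric matrix).
#' @return A `volume_matrix` whose columns have mean 0 and sample sd 1.
#' @export
zscore_columns <- function(volumes) {
  M <- as_matrix(volumes)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s) cannot be z-scored: ",
         paste(colnames(M)[sds == 0], collapse = ", "))
  Z <- scale(M)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  dimnames(Z) <- dimnames(M)
  if (inherits(volumes, "volume_matrix")) vm_like(volumes, Z) else Z
}

#' Deconfound and standardize in one step
#'
#' Convenience wrapper: [residualize()] then [zscore_columns()], the exact
#' preprocessing assumed by [fit_cca()].
#'
#' @inheritParams residualize
#' @return A `volume_matrix`.
#' @export
deconfound <- function(volumes, confounds, interactions = TRUE) {
  zscore_columns(residualize(volumes, confounds, interactions = interactions))
}
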