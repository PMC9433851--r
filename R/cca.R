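#' Canonical correlation decomposition of two subregion views
#'
#' Finds the top-`k` pairs of canonical vectors `(v_l, u_l)` maximizing
#' `corr(X v_l, Y u_l)` between the DN view `X` (n x p) and the HC view `Y`
#' (n x q), subject to within-view uncorrelatedness. Computed as the SVD of
#' the whitened cross-covariance: with within-view Cholesky factors
#' `Sxx = Rx'Rx`, `Syy = Ry'Ry`, the singular triplets of
#' `Rx'^-1 Sxy Ry^-1` give the canonical correlations (singular values) and,
#' after back-substitution, the canonical vectors. This route is numerically
#' stabler than the generalized-eigenvalue formulation.
#'
#' Conventions: modes are ordered by canonical correlation, descending (ties
#' keep input order); canonical vectors are scaled so every variate has unit
#' sample variance; signs are fixed deterministically per mode so that the
#' largest-magnitude weight on the HC side is positive, making repeated fits
#' byte-identical.
#'
#' @param dn,hc Deconfounded, z-scored views ([volume_matrix()] or numeric
#'   matrix) over the same participants; see [deconfound()].
#' @param k Number of modes (default 25, capped at `min(p, q)`).
#' @param ridge Nonnegative ridge added to the within-view covariance
#'   diagonals; default 0 (no regularization, appropriate when `n >> p + q`).
#'   Useful for small-n synthetic runs where the covariance is near singular.
#' @return An object of class `cca_solution`: `v_weights` (p x k, DN side),
#'   `u_weights` (q x k, HC side), `dn_variates`, `hc_variates` (n x k),
#'   `cor` (length-k canonical correlations), `k`, `n`, plus the column labels
#'   and anatomy carried from the inputs.
#' @export
fit_cca <- function(dn, hc, k = 25, ridge = 0) {
  X <- as_matrix(dn); Y <- as_matrix(hc)
  if (nrow(X) != nrow(Y)) stop("views must cover the same participants")
  k <- as.integer(k)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (k > min(p, q))
    stop("k = ", k, " exceeds min(p, q) = ", min(p, q))
  if (n <= p + q)
    warning("n <= p + q: canonical correlations will be strongly overfit")
  # center defensively; inputs are documented as z-scored already
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  Sxx <- crossprod(X) / (n - 1) + diag(ridge, p)
  Syy <- crossprod(Y) / (n - 1) + diag(ridge, q)
  Sxy <- crossprod(X, Y) / (n - 1)
  Rx <- tryCatch(chol(Sxx), error = function(e)
    stop("DN within-view covariance is numerically singular; ",
         "reduce k or add a small ridge", call. = FALSE))
  Ry <- tryCatch(chol(Syy), error = function(e)
    stop("HC within-view covariance is numerically singular; ",
         "reduce k or add a small ridge", call. = FALSE))
  Kw <- backsolve(Rx, Sxy, transpose = TRUE)      # Rx'^-1 Sxy
  Kw <- t(backsolve(Ry, t(Kw), transpose = TRUE)) # ... Ry^-1
  sv <- svd(Kw, nu = k, nv = k)
  rho <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  V <- backsolve(Rx, sv$u)   # p x k
  U <- backsolve(Ry, sv$v)   # q x k
  # deterministic sign: largest |weight| on the HC side positive
  for (l in seq_len(k)) {
    j <- which.max(abs(U[, l]))
    if (U[j, l] < 0) { U[, l] <- -U[, l]; V[, l] <- -V[, l] }
  }
  Lx <- X %*% V; Ly <- Y %*% U
  labs <- paste0("mode", seq_len(k))
  dimnames(V) <- list(colnames(X), labs)
  dimnames(U) <- list(colnames(Y), labs)
  dimnames(Lx) <- list(rownames(X), labs)
  dimnames(Ly) <- list(rownames(Y), labs)
  structure(list(v_weights = V, u_weights = U,
                 dn_variates = Lx, hc_variates = Ly,
                 cor = unname(rho), k = k, n = n,
                 dn_labels = colnames(X), hc_labels = colnames(Y),
                 dn_anatomy = if (inherits(dn, "volume_matrix")) dn$anatomy,
                 hc_anatomy = if (inherits(hc, "volume_matrix")) hc$anatomy),
            class = "cca_solution")
}

#' @export
print.cca_solution <- function(x, ...) {
  cat(sprintf("cca_solution: %d modes, n = %d, p = %d (DN), q = %d (HC)\n",
              x$k, x$n, nrow(x$v_weights), nrow(x$u_weights)))
  cat("canonical correlations:",
      paste(sprintf("%.3f", utils::head(x$cor, 8)), collapse = " "),
      if (x$k > 8) "..." else "", "\n")
  invisible(x)
}

#' Project new participants onto fitted canonical vectors
#'
#' Applies the fitted weights to held-out data (deconfounded and z-scored with
#' its own statistics), returning per-participant mode expressions — the
#' canonical variates used downstream in the genetic-association stage.
#'
#' @param solution A [fit_cca()] result.
#' @param dn_new,hc_new New data with exactly the columns the solution was
#'   fitted on.
#' @return List with `dn_variates` and `hc_variates` (n_new x k).
#' @export
project_cca <- function(solution, dn_new, hc_new) {
  X <- as_matrix(dn_new); Y <- as_matrix(hc_new)
  if (!identical(colnames(X), solution$dn_labels))
    stop("DN columns do not match the fitted solution: ",
         paste(symdiff_labels(colnames(X), solution$dn_labels), collapse = ", "))
  if (!identical(colnames(Y), solution$hc_labels))
    stop("HC columns do not match the fitted solution: ",
         paste(symdiff_labels(colnames(Y), solution$hc_labels), collapse = ", "))
  list(dn_variates = X %*% solution$v_weights,
       hc_variates = Y %*% solution$u_weights)
}

symdiff_labels <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' Serialize a CCA solution to a TSV + JSON bundle
#'
#' Weights and variates go to TSV (full double precision), scalar metadata and
#' canonical correlations to `meta.json`, enabling an exact round trip.
#'
#' @param solution A `cca_solution`.
#' @param dir Bundle directory.
#' @return `write_cca_solution` returns `dir` invisibly; `read_cca_solution`
#'   the solution.
#' @export
write_cca_solution <- function(solution, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f) {
    df <- data.frame(id = rownames(m),
                     apply(m, 2, function(col) sprintf("%.17g", col)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("id", colnames(m))
    utils::write.table(df, file.path(dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(solution$v_weights, "v_weights.tsv")
  wr(solution$u_weights, "u_weights.tsv")
  wr(solution$dn_variates, "dn_variates.tsv")
  wr(solution$hc_variates, "hc_variates.tsv")
  jsonlite::write_json(list(cor = solution$cor, k = solution$k, n = solution$n),
                       file.path(dir, "meta.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_cca_solution
#' @export
read_cca_solution <- function(dir) {
  rd <- function(f) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE,
                            colClasses = "character")
    m <- apply(df[, -1, drop = FALSE], 2, as.numeric)
    rownames(m) <- df$id
    m
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  V <- rd("v_weights.tsv"); U <- rd("u_weights.tsv")
  structure(list(v_weights = V, u_weights = U,
                 dn_variates = rd("dn_variates.tsv"),
                 hc_variates = rd("hc_variates.tsv"),
                 cor = meta$cor, k = meta$k, n = meta$n,
                 dn_labels = rownames(V), hc_labels = rownames(U),
                 dn_anatomy = NULL, hc_anatomy = NULL),
            class = "cca_solution")
}
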