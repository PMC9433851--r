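# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, p + (p >= i))))
}

# population canonical correlations of the linear latent-factor model:
# x = A z + e, y = B z + f with z_l ~ N(0, s_l^2), iid noise sd sigma.
# Computed from the construction Sxx^-1 Sxy Syy^-1 Syx eigenvalues.
population_canonical_cor <- function(A, B, strengths, sigma) {
  D2 <- diag(strengths^2, length(strengths))
  Sxx <- A %*% D2 %*% t(A) + diag(sigma^2, nrow(A))
  Syy <- B %*% D2 %*% t(B) + diag(sigma^2, nrow(B))
  Sxy <- A %*% D2 %*% t(B)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(ev, 0))
}

# brute-force first canonical correlation for p = q = 2 by direct numerical
# maximization of corr(X v, Y u) over angle parameterizations
brute_force_cca2 <- function(X, Y) {
  obj <- function(par) {
    v <- c(cos(par[1]), sin(par[1])); u <- c(cos(par[2]), sin(par[2]))
    -stats::cor(X %*% v, Y %*% u)
  }
  starts <- as.matrix(expand.grid(th = seq(0, pi, length.out = 7),
                                  ph = seq(0, pi, length.out = 7)))
  best <- -Inf
  for (i in seq_len(nrow(starts))) {
    op <- stats::optim(starts[i, ], obj, method = "BFGS",
                       control = list(reltol = 1e-14))
    best <- max(best, -op$value)
  }
  best
}

# exhaustive mode matching: maximize total absolute correlation over all k!
# permutations of the concatenated canonical vectors
brute_force_match <- function(Wref, Woth) {
  k <- ncol(Wref)
  S <- abs(stats::cor(Wref, Woth))
  pp <- all_perms(k)
  scores <- apply(pp, 1, function(p) sum(S[cbind(seq_len(k), p)]))
  pp[which.max(scores), ]
}

# small standard deconfounded cohort used by several tests
make_small_views <- function(n = 200, p = 6, q = 4, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  X <- matrix(stats::rnorm(n * p), n, p) + z %o% stats::rnorm(p)
  Y <- matrix(stats::rnorm(n * q), n, q) + z %o% stats::rnorm(q)
  dimnames(X) <- list(sprintf("P%03d", 1:n), paste0("dn", 1:p))
  dimnames(Y) <- list(sprintf("P%03d", 1:n), paste0("hc", 1:q))
  list(dn = zscore_columns(X), hc = zscore_columns(Y))
}
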