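# Linear assignment by shortest augmenting paths (Jonker-Volgenant style,
# O(n^3)). Minimizes total cost over permutations; used for mode matching on
# negated absolute-correlation similarity. Index n+1 plays the classic role
# of the virtual column.
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost) || !all(is.finite(cost)))
    stop("cost must be a finite square matrix")
  n <- nrow(cost)
  u <- numeric(n); v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j]: row currently matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j]] <- j
  assignment
}
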