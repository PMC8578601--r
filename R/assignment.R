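# Minimum-cost one-to-one assignment (Kuhn-Munkres / Jonker-Volgenant,
# shortest augmenting path with dual potentials). Handles rectangular
# problems with nrow(cost) <= ncol(cost); O(n^2 m). Exactness is verified
# against brute-force enumeration in the test suite.
lap_solve <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n > m) stop("assignment requires nrow(cost) <= ncol(cost)")
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  # 1-based port of the classic potentials algorithm; index m + 1 plays the
  # role of the virtual "column 0" that each new row enters through.
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L) # p[j] = row matched to column j (0 = free)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assignment[p[j]] <- j
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}
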