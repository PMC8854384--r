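#' Minimal-cost assignment (Hungarian algorithm)
#'
#' Potentials-and-augmenting-paths implementation of the Hungarian (Kuhn-
#' Munkres) algorithm, O(n^2 m). Solves the rectangular assignment problem for
#' an n x m cost matrix with n <= m: every row is assigned to a distinct
#' column so the total cost is minimal.
#'
#' @param cost numeric n x m cost matrix, `n <= m`, finite entries.
#' @return integer vector of length n: `result[i]` is the column assigned to
#'   row i.
#' @export
hungarian_assign <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) abort_fluctnet("cost matrix must have nrow <= ncol (pad with zero columns)")
  if (any(!is.finite(cost))) abort_fluctnet("cost matrix must be finite")
  # 1-based translation of the classic 0-indexed potentials algorithm:
  # index j + 1 ranges over columns 0..m, column 0 being the virtual start.
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)      # p[j + 1]: row matched to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m)
    used <- logical(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}
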