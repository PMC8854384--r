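# Independent oracles used across tests: deliberately naive implementations,
# kept separate from the package's own code paths.

# participation coefficient by direct summation over modules
oracle_participation <- function(A, partition) {
  A[A < 0] <- 0
  diag(A) <- 0
  R <- nrow(A)
  sapply(seq_len(R), function(i) {
    k <- sum(A[i, ])
    if (k == 0) return(0)
    1 - sum(sapply(unique(partition), function(s)
      (sum(A[i, partition == s]) / k)^2))
  })
}

# module-degree z by direct per-module arithmetic
oracle_module_z <- function(A, partition) {
  A[A < 0] <- 0
  diag(A) <- 0
  z <- numeric(nrow(A))
  for (s in unique(partition)) {
    idx <- which(partition == s)
    if (length(idx) < 2) { z[idx] <- 0; next }
    kw <- sapply(idx, function(i) sum(A[i, idx]))
    if (sd(kw) == 0) z[idx] <- 0 else z[idx] <- (kw - mean(kw)) / sd(kw)
  }
  z
}

# exhaustive assignment search: minimal-cost row->column assignment
oracle_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(m))) {
    cols <- p[seq_len(n)]
    cc <- sum(cost[cbind(seq_len(n), cols)])
    if (cc < best_cost) { best_cost <- cc; best <- cols }
  }
  list(assignment = best, cost = best_cost)
}

# naive O(m^2) Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- m * ps / seq_len(m)
  for (i in rev(seq_len(m - 1))) qs[i] <- min(qs[i], qs[i + 1])
  qs <- pmin(qs, 1)
  qv <- numeric(m)
  qv[ord] <- qs
  list(q_values = qv, significant = qv <= q)
}

# exhaustive Mann-Whitney U null: all label assignments of the combined sample
oracle_mwu <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v <- c(x, y)
  r <- rank(v)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  U_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(U_all <= U_obs)
  p_hi <- mean(U_all >= U_obs)
  list(U = U_obs, p_value = min(1, 2 * min(p_lo, p_hi)))
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- length(a)
  expected <- ai * bj / choose(n, 2)
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}

# small deterministic parcel_ts from a matrix-producing expression
tiny_ts <- function(data, tr = 3) parcel_ts(data, sampling_interval = tr)

# wrap a raw tensor as a dynamic_connectivity for topology tests
new_dc_for_test <- function(tensor, window = 15) {
  structure(list(tensor = tensor, window = window,
                 centers = seq_len(dim(tensor)[3]),
                 parcel_labels = sprintf("R%03d", seq_len(dim(tensor)[1]))),
            class = "dynamic_connectivity")
}
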