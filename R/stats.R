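#' Covariate-adjusted permutation test for a group difference
#'
#' Residualises the outcome on an intercept plus the covariates (ordinary least
#' squares), then permutes group labels and compares the observed difference of
#' group means of the residuals against the permutation distribution
#' (Freedman-Lane-style adjustment). Two-sided p-values use the `+1`
#' correction, so p is never exactly 0. Cohen's d is computed on the
#' residualised values with the pooled (n-1 weighted) standard deviation.
#'
#' @param data data frame with one row per subject.
#' @param value unquoted column name of the outcome.
#' @param group unquoted column name of the two-level group factor; the
#'   statistic is mean(first level) - mean(second level).
#' @param covariates character vector of covariate column names (NULL for an
#'   unadjusted test).
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @return object of class `perm_test`: list with `statistic` (observed mean
#'   difference of residuals), `p_value`, `cohens_d`, `n_perm`, `groups`, `n`.
#' @export
permutation_group_test <- function(data, value, group, covariates = NULL,
                                   n_perm = 5000, seed = 1) {
  y <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  g <- factor(g)
  if (nlevels(g) != 2) abort_fluctnet("group must have exactly 2 levels")
  if (any(table(g) < 2)) abort_fluctnet("need at least 2 subjects per group")
  if (stats::sd(y) < .Machine$double.eps * 100)
    abort_fluctnet("outcome is constant; permutation p is undefined")
  n <- length(y)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(data[, covariates, drop = FALSE]))
  resid <- as.numeric(stats::lm.fit(X, y)$residuals)
  i1 <- g == levels(g)[1]
  contrast <- ifelse(i1, 1 / sum(i1), -1 / sum(!i1))
  observed <- sum(contrast * resid)
  perm_stats <- withr::with_seed(as.integer(seed), {
    C <- vapply(seq_len(n_perm), function(k) contrast[sample.int(n)], numeric(n))
    as.numeric(crossprod(resid, C))
  })
  p <- (sum(abs(perm_stats) >= abs(observed)) + 1) / (n_perm + 1)
  d <- cohens_d(resid[i1], resid[!i1])
  structure(list(statistic = observed, p_value = p, cohens_d = d,
                 n_perm = n_perm, groups = levels(g),
                 n = as.integer(table(g)), covariates = covariates),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s - %s: diff = %.4g, d = %.3g, p = %.4g (%d permutations)\n",
              x$groups[1], x$groups[2], x$statistic, x$cohens_d, x$p_value, x$n_perm))
  invisible(x)
}

#' @rdname permutation_group_test
#' @param x a `perm_test`.
#' @param ... unused.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(contrast = paste(x$groups, collapse = " - "),
                 estimate = x$statistic, cohens_d = x$cohens_d,
                 p.value = x$p_value, n_perm = x$n_perm)
}

#' @rdname permutation_group_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(n_total = sum(x$n), n_perm = x$n_perm,
                 adjusted = !is.null(x$covariates))
}

#' Cohen's d with pooled standard deviation
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @return scalar effect size (mean(x) - mean(y)) / pooled SD.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) abort_fluctnet("need at least 2 values per group")
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  if (sp < .Machine$double.eps * 100) abort_fluctnet("pooled SD is zero")
  (mean(x) - mean(y)) / sp
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure returning monotone q-values and the significance mask at
#' level `q`.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `q_values` and `significant` (logical mask); both empty
#'   for empty input.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (!length(p)) return(list(q_values = numeric(0), significant = logical(0)))
  if (any(p <= 0 | p > 1, na.rm = TRUE)) abort_fluctnet("p-values must be in (0, 1]")
  qv <- stats::p.adjust(p, method = "BH")
  list(q_values = qv, significant = !is.na(qv) & qv <= q)
}

#' Mann-Whitney U test
#'
#' U is reported for the first sample (rank-sum minus its minimum), so complete
#' separation with `x` below `y` gives U = 0 and identical samples give
#' `U = n1 n2 / 2`. The p-value is exact (null permutation distribution of U)
#' when the combined sample size is at most 12 and there are no ties; otherwise
#' a tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y numeric vectors.
#' @return list with `U`, `p_value`, `method`.
#' @export
mannwhitney_u <- function(x, y) {
  if (!length(x) || !length(y)) abort_fluctnet("both groups need at least 1 value")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n1 + n2 <= 12 && !ties) {
    # exact two-sided p from the null distribution of U
    p_lo <- stats::pwilcox(U, n1, n2)
    p_hi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
    zval <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(zval))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p_value = min(1, p), method = method)
}

#' Permutation test for a correlation
#'
#' Pearson (or Spearman, with `rank = TRUE`) correlation with a two-sided
#' label-permutation p-value (`+1` corrected).
#'
#' @param x,y numeric vectors, length >= 3.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param rank use Spearman's rank correlation.
#' @return list with `estimate`, `p_value`, `method`, `n_perm`.
#' @export
permutation_correlation <- function(x, y, n_perm = 5000, seed = 1, rank = FALSE) {
  n <- length(x)
  if (n < 3 || length(y) != n) abort_fluctnet("x and y must share length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort_fluctnet("correlation is undefined for a constant vector")
  if (rank) { x <- rank(x); y <- rank(y) }
  zx <- as.numeric(scale(x)); zy <- as.numeric(scale(y))
  observed <- sum(zx * zy) / (n - 1)
  perm_stats <- withr::with_seed(as.integer(seed), {
    P <- vapply(seq_len(n_perm), function(k) zy[sample.int(n)], numeric(n))
    as.numeric(crossprod(zx, P)) / (n - 1)
  })
  p <- (sum(abs(perm_stats) >= abs(observed)) + 1) / (n_perm + 1)
  list(estimate = observed, p_value = p,
       method = if (rank) "spearman" else "pearson", n_perm = n_perm)
}

#' Bin-wise correlation of cartographic profiles with an outcome
#'
#' Correlates each bin's occupancy across subjects with a subject-level outcome
#' (Pearson, t-distribution p), masks bins with zero variance across subjects,
#' and controls the FDR over the remaining bins with Benjamini-Hochberg.
#'
#' @param profiles list of `cartographic_profile`s sharing bin edges.
#' @param outcome numeric vector, one value per subject.
#' @param q FDR level (default 0.05).
#' @return object of class `carto_map`: `r` and `q_values` matrices on the
#'   (participation x z) bin grid (NA where masked), `significant` logical
#'   matrix, `b_edges`, `z_edges`, `n_subjects`.
#' @export
cartographic_binwise <- function(profiles, outcome, q = 0.05) {
  n <- length(profiles)
  if (n != length(outcome)) abort_fluctnet("one outcome value per profile required")
  if (n < 3) abort_fluctnet("need at least 3 subjects")
  if (stats::sd(outcome) == 0) abort_fluctnet("outcome is constant")
  edges_b <- profiles[[1]]$b_edges; edges_z <- profiles[[1]]$z_edges
  same <- vapply(profiles, function(p)
    identical(p$b_edges, edges_b) && identical(p$z_edges, edges_z), logical(1))
  if (!all(same)) abort_fluctnet("all profiles must share bin edges")
  X <- vapply(profiles, function(p) {
    cnt <- p$counts
    as.vector(cnt / sum(cnt))
  }, numeric(length(profiles[[1]]$counts)))   # bins x subjects
  sds <- apply(X, 1, stats::sd)
  ok <- sds > 0
  r <- rep(NA_real_, nrow(X)); pv <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    zo <- as.numeric(scale(outcome))
    Zx <- t(scale(t(X[ok, , drop = FALSE])))
    r_ok <- as.numeric(Zx %*% zo) / (n - 1)
    r_ok <- pmin(1, pmax(-1, r_ok))
    tval <- r_ok * sqrt((n - 2) / pmax(1e-300, 1 - r_ok^2))
    pv_ok <- 2 * stats::pt(-abs(tval), df = n - 2)
    r[ok] <- r_ok; pv[ok] <- pmax(pv_ok, .Machine$double.xmin)
  }
  fdr <- fdr_bh(pv[ok], q)
  qv <- rep(NA_real_, length(pv)); sig <- rep(FALSE, length(pv))
  qv[ok] <- fdr$q_values; sig[ok] <- fdr$significant
  dims <- dim(profiles[[1]]$counts)
  structure(list(r = matrix(r, dims[1], dims[2]),
                 q_values = matrix(qv, dims[1], dims[2]),
                 significant = matrix(sig, dims[1], dims[2]),
                 b_edges = edges_b, z_edges = edges_z, n_subjects = n),
            class = "carto_map")
}
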