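#' Epoch-wise brain patterns
#'
#' Builds the sequence of pattern vectors whose pairwise correlations define
#' the temporal-similarity statistics. In `"activity"` mode each epoch (TR)
#' contributes the regions-long BOLD vector; in `"connectivity"` mode each MTD
#' window contributes the vectorised upper triangle of its connectivity matrix
#' (column-major order, i < j).
#'
#' @param ts a [parcel_ts()] (required for activity mode).
#' @param dc a `dynamic_connectivity` (required for connectivity mode).
#' @param mode `"activity"` or `"connectivity"`.
#' @return numeric matrix, pattern length x epochs (one column per epoch).
#' @export
epoch_patterns <- function(ts = NULL, dc = NULL,
                           mode = c("activity", "connectivity")) {
  mode <- match.arg(mode)
  if (mode == "activity") {
    if (is.null(ts)) abort_fluctnet("activity mode requires a parcel time series")
    return(ts$data)
  }
  if (is.null(dc)) abort_fluctnet("connectivity mode requires a dynamic connectivity tensor")
  R <- dim(dc$tensor)[1]; W <- dim(dc$tensor)[3]
  ut <- upper.tri(matrix(0, R, R))
  vapply(seq_len(W), function(t) dc$tensor[, , t][ut], numeric(sum(ut)))
}

#' Time-by-time pattern similarity matrix
#'
#' Pearson correlation between every pair of epoch patterns.
#'
#' @param patterns matrix from [epoch_patterns()] (columns = epochs).
#' @return n x n symmetric correlation matrix with unit diagonal.
#' @export
similarity_matrix <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (ncol(patterns) < 2) abort_fluctnet("need at least 2 epochs")
  sds <- apply(patterns, 2, stats::sd)
  zero <- sds < .Machine$double.eps * 100
  if (any(zero))
    abort_fluctnet(sprintf("zero-variance pattern at epoch(s): %s",
                           paste(which(zero), collapse = ", ")))
  r <- stats::cor(patterns)
  diag(r) <- 1
  r
}

#' Local similarity: mean correlation of contiguous epochs
#'
#' The arithmetic mean of the `n - 1` correlations between temporally adjacent
#' epoch patterns (the first off-diagonal of the similarity matrix). High
#' values indicate stationary, slowly reconfiguring dynamics.
#'
#' @param r_matrix similarity matrix from [similarity_matrix()].
#' @return scalar in `[-1, 1]`.
#' @export
local_similarity <- function(r_matrix) {
  n <- nrow(r_matrix)
  if (n < 2) abort_fluctnet("need at least 2 epochs")
  mean(r_matrix[cbind(seq_len(n - 1), seq_len(n - 1) + 1)])
}

#' Global similarity: mean absolute correlation across all epoch pairs
#'
#' The sum of absolute pairwise correlations (diagonal included) minus the `n`
#' unit diagonal terms, divided by `n(n - 1)`; equivalently the mean absolute
#' off-diagonal correlation. High values indicate a small repertoire of
#' recurring configurations.
#'
#' @param r_matrix similarity matrix from [similarity_matrix()].
#' @return scalar in `[0, 1]`.
#' @export
global_similarity <- function(r_matrix) {
  n <- nrow(r_matrix)
  if (n < 2) abort_fluctnet("need at least 2 epochs")
  (sum(abs(r_matrix)) - n) / (n * (n - 1))
}

#' Temporal similarity statistics for one subject
#'
#' Convenience wrapper: builds epoch patterns, the time-by-time similarity
#' matrix, and both summary statistics.
#'
#' @inheritParams epoch_patterns
#' @return object of class `similarity_result`: list with `mode`, `n`
#'   (epochs), `r_matrix`, `s_local`, `s_global`, `subject_id`.
#' @export
similarity <- function(ts = NULL, dc = NULL,
                       mode = c("activity", "connectivity")) {
  mode <- match.arg(mode)
  pat <- epoch_patterns(ts, dc, mode)
  r <- similarity_matrix(pat)
  structure(
    list(mode = mode, n = ncol(pat), r_matrix = r,
         s_local = local_similarity(r), s_global = global_similarity(r),
         subject_id = if (!is.null(ts)) ts$subject_id else "subject"),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> %s (%s mode): n = %d epochs, S_L = %.3f, S_G = %.3f\n",
              x$subject_id, x$mode, x$n, x$s_local, x$s_global))
  invisible(x)
}

#' @rdname similarity
#' @param x a `similarity_result`.
#' @param ... unused.
#' @export
tidy.similarity_result <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id, mode = x$mode, n = x$n,
                 s_local = x$s_local, s_global = x$s_global)
}

#' Heatmap of the time-by-time similarity matrix
#'
#' @param object a `similarity_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.similarity_result <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(object$n), j = seq_len(object$n))
  df$r <- as.vector(object$r_matrix)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "epoch", y = "epoch", fill = "r",
                  title = sprintf("%s: S_L = %.2f, S_G = %.2f",
                                  object$subject_id, object$s_local, object$s_global)) +
    ggplot2::theme_minimal()
}
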