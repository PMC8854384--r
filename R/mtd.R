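#' Dynamic connectivity container
#'
#' Regions x regions x windows array of time-resolved coupling scores from the
#' multiplication of temporal derivatives (MTD), with the window length and
#' window centres (in original sample coordinates). Each windowed slice is
#' symmetric with a zero diagonal.
#'
#' @keywords internal
new_dynamic_connectivity <- function(tensor, window, centers, parcel_labels) {
  structure(list(tensor = tensor, window = window, centers = centers,
                 parcel_labels = parcel_labels),
            class = "dynamic_connectivity")
}

#' @export
print.dynamic_connectivity <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<dynamic_connectivity> %d regions, %d windows (length %d)\n",
              d[1], d[3], x$window))
  invisible(x)
}

#' Normalised temporal derivative of a parcel time series
#'
#' First difference of each region's time course, divided by that region's own
#' (population) standard deviation computed over the whole derivative series.
#' This makes downstream coupling scores invariant to each region's signal
#' scale.
#'
#' @param ts a [parcel_ts()].
#' @return regions x (timepoints - 1) matrix.
#' @export
temporal_derivative <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  x <- ts$data
  if (ncol(x) < 2) abort_fluctnet("need at least 2 timepoints")
  d <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
  sds <- apply(d, 1, pop_sd)
  zero <- sds < .Machine$double.eps * 100
  if (any(zero))
    abort_fluctnet(sprintf("zero-variance derivative in region(s): %s",
                           paste(ts$parcel_labels[zero], collapse = ", ")))
  d / sds
}

#' Multiplication of temporal derivatives (MTD) connectivity tensor
#'
#' The raw coupling between regions i and j at derivative sample t is the
#' product of their normalised temporal derivatives; the windowed MTD score is
#' the simple moving average of that product over `window` consecutive
#' derivative samples ("valid" convention: windows lie fully inside the
#' derivative series, giving `timepoints - window` windows). Slices are
#' symmetric by construction; the diagonal is set to zero and excluded from all
#' downstream graph measures.
#'
#' @param ts a [parcel_ts()].
#' @param window window length in samples (default 15, ~45 s at TR = 3 s).
#' @return a `dynamic_connectivity` object.
#' @export
mtd_tensor <- function(ts, window = 15) {
  z <- temporal_derivative(ts)
  T1 <- ncol(z)
  if (T1 < window)
    abort_fluctnet(sprintf("window (%d) exceeds derivative length (%d); max feasible window is %d",
                           window, T1, T1))
  W <- T1 - window + 1
  R <- nrow(z)
  tensor <- array(0, c(R, R, W))
  # rolling cross-product: subtract the leaving column, add the entering one
  cp <- tcrossprod(z[, 1:window, drop = FALSE])
  tensor[, , 1] <- cp
  if (W > 1) {
    for (t in 2:W) {
      cp <- cp - tcrossprod(z[, t - 1]) + tcrossprod(z[, t + window - 1])
      tensor[, , t] <- cp
    }
  }
  tensor <- tensor / window
  for (t in seq_len(W)) {
    s <- tensor[, , t]
    diag(s) <- 0
    tensor[, , t] <- s
  }
  centers <- seq_len(W) + window / 2   # original sample coordinates
  new_dynamic_connectivity(tensor, window, centers, ts$parcel_labels)
}

#' Time-averaged connectivity matrix
#'
#' Mean of the MTD tensor over windows; the basis for time-averaged topology.
#'
#' @param dc a `dynamic_connectivity` from [mtd_tensor()].
#' @return regions x regions symmetric matrix (zero diagonal).
#' @export
time_average <- function(dc) {
  stopifnot(inherits(dc, "dynamic_connectivity"))
  W <- dim(dc$tensor)[3]
  if (W < 1) abort_fluctnet("dynamic connectivity has no windows")
  out <- apply(dc$tensor, c(1, 2), mean)
  dimnames(out) <- list(dc$parcel_labels, dc$parcel_labels)
  out
}
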