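#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum over the six rigid-body
#' parameters of the absolute frame-to-frame change, with rotations converted
#' to arc length on a sphere of radius `head_radius`. The first frame's FD is
#' defined as 0.
#'
#' @param motion frames x 6 numeric matrix (3 translations mm, 3 rotations rad).
#' @param head_radius head radius in mm for the rotation-to-displacement
#'   conversion (default 50 mm).
#' @return numeric vector of per-frame FD (mm), length = frames.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    abort_fluctnet(sprintf("motion must have 6 columns, got %d", ncol(motion)))
  if (nrow(motion) < 1) abort_fluctnet("motion needs at least one frame")
  if (nrow(motion) == 1) return(0)
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' DVARS: root-mean-square frame-to-frame signal change
#'
#' For each frame, the RMS over regions of the change in signal from the
#' previous frame, expressed as a percentage of the grand-mean signal of the
#' (unfiltered) series. The first frame's DVARS is defined as 0.
#'
#' @param ts a [parcel_ts()].
#' @return numeric vector of per-frame DVARS (%), length = timepoints.
#' @export
dvars <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  x <- ts$data
  gm <- mean(x)
  if (abs(gm) < 1e-12)
    abort_fluctnet("grand-mean signal is zero; DVARS percentage is undefined")
  d <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
  c(0, 100 * sqrt(colMeans(d^2)) / gm)
}

#' Per-frame QC series and exceedance flags
#'
#' `qc_series()` bundles FD and DVARS for one scan; `flag_exceedance()` marks
#' frames where either metric crosses its threshold and reports the
#' subject-level exceedance fraction. Subjects with strictly more than
#' `exclude_frac` of frames flagged are marked for exclusion.
#'
#' @param ts a [parcel_ts()].
#' @param motion frames x 6 motion matrix aligned with `ts`.
#' @param head_radius head radius (mm) for FD.
#' @return `qc_series()`: a tibble with columns `frame`, `fd`, `dvars` of class
#'   `qc_series`.
#' @export
qc_series <- function(ts, motion, head_radius = 50) {
  fd <- framewise_displacement(motion, head_radius)
  dv <- dvars(ts)
  if (length(fd) != length(dv))
    abort_fluctnet("motion trace and time series have different frame counts")
  structure(tibble::tibble(frame = seq_along(fd), fd = fd, dvars = dv),
            class = c("qc_series", "tbl_df", "tbl", "data.frame"))
}

#' @rdname qc_series
#' @param qc a `qc_series` (or any data frame with `fd` and `dvars` columns).
#' @param fd_thresh FD threshold in mm (default 0.25).
#' @param dvars_thresh DVARS threshold in % (default 2.5).
#' @param exclude_frac exclusion rule: excluded if flagged fraction is strictly
#'   greater than this (default 0.10).
#' @return `flag_exceedance()`: list with `flags` (logical per frame),
#'   `fraction` (flagged fraction) and `excluded` (logical).
#' @export
flag_exceedance <- function(qc, fd_thresh = 0.25, dvars_thresh = 2.5,
                            exclude_frac = 0.10) {
  if (length(qc$fd) != length(qc$dvars))
    abort_fluctnet("fd and dvars series are not aligned")
  flags <- (qc$fd > fd_thresh) | (qc$dvars > dvars_thresh)
  frac <- mean(flags)
  list(flags = flags, fraction = frac, excluded = frac > exclude_frac)
}

#' Regress nuisance covariates out of a parcel time series
#'
#' Ordinary least squares of each region's time course on an intercept plus the
#' supplied regressor matrix; returns the residuals (hence output is demeaned
#' and orthogonal to every regressor). Collinear regressor columns are dropped
#' with a warning.
#'
#' @param ts a [parcel_ts()].
#' @param regressors timepoints x k numeric matrix (or NULL for intercept-only
#'   demeaning).
#' @return a [parcel_ts()] of residuals, same shape and labels.
#' @export
nuisance_regress <- function(ts, regressors = NULL) {
  stopifnot(inherits(ts, "parcel_ts"))
  n <- ncol(ts$data)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(regressors)) {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) != n)
      abort_fluctnet(sprintf("regressors have %d rows; time series has %d timepoints",
                             nrow(regressors), n))
    X <- cbind(X, regressors)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning(sprintf("dropping %d collinear nuisance regressor column(s)",
                    ncol(X) - qrX$rank))
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
  }
  resid <- t(qr.resid(qrX, t(ts$data)))
  out <- parcel_ts(resid, ts$sampling_interval, ts$parcel_labels, ts$subject_id)
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering of each region's time
#' course, so filtering cannot shift connectivity timing. Defaults follow the
#' narrow band used for time-resolved connectivity at TR = 3 s
#' (0.071-0.125 Hz).
#'
#' @param ts a [parcel_ts()].
#' @param low,high band edges in Hz (`0 < low < high < Nyquist`).
#' @param order Butterworth order (applied twice by filtfilt).
#' @return a filtered [parcel_ts()], same shape and labels.
#' @export
bandpass <- function(ts, low = 0.071, high = 0.125, order = 4) {
  stopifnot(inherits(ts, "parcel_ts"))
  fs <- 1 / ts$sampling_interval
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq))
    abort_fluctnet(sprintf(
      "infeasible band [%g, %g] Hz: need 0 < low < high < Nyquist = %.4g Hz for sampling interval %g s",
      low, high, nyq, ts$sampling_interval))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filt <- t(apply(ts$data, 1, function(row) signal::filtfilt(bf, row)))
  parcel_ts(filt, ts$sampling_interval, ts$parcel_labels, ts$subject_id)
}

#' Fixed-order preprocessing of one subject
#'
#' QC (FD/DVARS flags) -> nuisance regression -> band-pass, in that order.
#' Motion-derived regressors are the 6 parameters, their temporal derivatives,
#' FD and DVARS.
#'
#' @param ts a [parcel_ts()].
#' @param motion frames x 6 motion matrix (optional; skips motion regressors
#'   and FD flagging when NULL).
#' @param filter apply the band-pass (default TRUE).
#' @param low,high band edges in Hz.
#' @param fd_thresh,dvars_thresh QC thresholds.
#' @return list: `ts` (preprocessed `parcel_ts`), `qc` (qc_series or NULL),
#'   `exceedance` (from [flag_exceedance()], or NULL).
#' @export
preprocess_subject <- function(ts, motion = NULL, filter = TRUE,
                               low = 0.071, high = 0.125,
                               fd_thresh = 0.25, dvars_thresh = 2.5) {
  qc <- NULL; exc <- NULL; regressors <- NULL
  if (!is.null(motion)) {
    qc <- qc_series(ts, motion)
    exc <- flag_exceedance(qc, fd_thresh, dvars_thresh)
    dmotion <- rbind(0, diff(as.matrix(motion)))
    regressors <- cbind(as.matrix(motion), dmotion, fd = qc$fd, dvars = qc$dvars)
  }
  out <- nuisance_regress(ts, regressors)
  if (filter) out <- bandpass(out, low, high)
  list(ts = out, qc = qc, exceedance = exc)
}
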