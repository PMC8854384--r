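#' Parcellated BOLD time series
#'
#' Container for one subject's regions x timepoints matrix of parcel-mean BOLD
#' signal, together with the sampling interval (TR, seconds) and parcel labels.
#' All preprocessing and connectivity functions consume and return this class,
#' preserving shape and labels.
#'
#' @param data numeric matrix, regions x timepoints; no missing values.
#' @param sampling_interval sampling interval (TR) in seconds.
#' @param parcel_labels character vector of unique region identifiers, one per
#'   row of `data`. Defaults to `R001, R002, ...`.
#' @param subject_id subject identifier.
#' @return an object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, sampling_interval = 3,
                      parcel_labels = NULL, subject_id = "subject") {
  data <- as.matrix(data)
  if (anyNA(data)) abort_fluctnet("parcel time series contains missing values")
  if (ncol(data) < 2) abort_fluctnet("parcel time series needs at least 2 timepoints")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    abort_fluctnet("sampling_interval must be a positive number of seconds")
  if (is.null(parcel_labels))
    parcel_labels <- sprintf("R%03d", seq_len(nrow(data)))
  if (length(parcel_labels) != nrow(data))
    abort_fluctnet("parcel_labels length must equal the number of regions (rows)")
  if (anyDuplicated(parcel_labels))
    abort_fluctnet("parcel_labels must be unique")
  rownames(data) <- parcel_labels
  structure(
    list(data = data, sampling_interval = sampling_interval,
         parcel_labels = parcel_labels, subject_id = subject_id),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %s: %d regions x %d timepoints, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$sampling_interval))
  invisible(x)
}

#' @export
dim.parcel_ts <- function(x) dim(x$data)

#' Read / write the parcel time-series TSV format
#'
#' Tab-separated, regions as rows; first column `parcel` holds region labels,
#' remaining columns are timepoints. The sampling interval is carried in a
#' `# sampling_interval: <s>` comment on the first line.
#'
#' @param path file path.
#' @param ts a [parcel_ts()].
#' @return `read_parcel_ts()` returns a `parcel_ts`; `write_parcel_ts()`
#'   returns `path` invisibly.
#' @export
write_parcel_ts <- function(ts, path) {
  stopifnot(inherits(ts, "parcel_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_interval: %.10g", ts$sampling_interval), con)
  df <- data.frame(parcel = ts$parcel_labels, ts$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("parcel", sprintf("t%04d", seq_len(ncol(ts$data))))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcel_ts
#' @param subject_id subject identifier to attach on read.
#' @export
read_parcel_ts <- function(path, subject_id = NULL) {
  first <- readLines(path, n = 1)
  si <- 3
  if (grepl("^# sampling_interval:", first))
    si <- as.numeric(sub("^# sampling_interval:\\s*", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  parcel_ts(mat, sampling_interval = si, parcel_labels = df[[1]],
            subject_id = subject_id %||% sub("\\.tsv$", "", basename(path)))
}

#' Read / write 6-parameter rigid-body motion traces
#'
#' Whitespace-delimited text, one row per frame, six columns: three
#' translations (mm) followed by three rotations (radians).
#'
#' @param motion numeric matrix, frames x 6.
#' @param path file path.
#' @export
write_motion <- function(motion, path) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    abort_fluctnet("motion parameters must have 6 columns (3 translations mm, 3 rotations rad)")
  utils::write.table(motion, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6)
    abort_fluctnet(sprintf("motion file has %d columns; expected 6", ncol(m)))
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  m
}
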