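#' Temporally match module labels across windows
#'
#' Module ids from per-window community detection are arbitrary; this matches
#' them over time so that "module 2" means the same community in consecutive
#' windows. For each consecutive window pair the maximum-overlap assignment
#' between the current window's modules and the previous (already matched)
#' labels is solved with the Hungarian algorithm on negated contingency counts;
#' matched modules inherit the previous label, while modules with no overlap
#' at all onto a previous label (or left over when the current window has more
#' modules) receive fresh ids. Region membership is never changed - only the
#' label names.
#'
#' @param assign a `module_assignment` from [detect_communities()].
#' @return the `module_assignment` with relabelled `labels` and
#'   `matched = TRUE`.
#' @export
match_labels <- function(assign) {
  stopifnot(inherits(assign, "module_assignment"))
  labels <- assign$labels
  W <- ncol(labels)
  if (W < 2) abort_fluctnet("label matching needs at least 2 windows")
  matched <- labels
  next_id <- max(matched[, 1]) + 1L
  for (t in 2:W) {
    prev <- matched[, t - 1]
    cur <- labels[, t]
    prev_ids <- sort(unique(prev))
    cur_ids <- sort(unique(cur))
    overlap <- table(factor(cur, levels = cur_ids),
                     factor(prev, levels = prev_ids))
    O <- matrix(as.numeric(overlap), length(cur_ids), length(prev_ids))
    # pad with zero-overlap dummy targets so nrow <= ncol
    n_pad <- max(0, length(cur_ids) - length(prev_ids))
    cost <- cbind(-O, matrix(0, length(cur_ids), n_pad))
    sol <- hungarian_assign(cost)
    new_lab <- integer(length(cur_ids))
    for (ci in seq_along(cur_ids)) {
      j <- sol[ci]
      if (j <= length(prev_ids) && O[ci, j] > 0) {
        new_lab[ci] <- prev_ids[j]
      } else {
        new_lab[ci] <- next_id
        next_id <- next_id + 1L
      }
    }
    matched[, t] <- new_lab[match(cur, cur_ids)]
  }
  assign$labels <- matched
  assign$n_modules <- apply(matched, 2, function(l) length(unique(l)))
  assign$matched <- TRUE
  assign
}

#' Regional modular flexibility (instability)
#'
#' For each region, the fraction of consecutive window pairs in which its
#' (temporally matched) module label changes, normalised by the number of
#' modules. High flexibility marks regions with unstable module allegiance.
#'
#' @param assign a matched `module_assignment` (see [match_labels()]).
#' @param normalise `"total"` (default): divide the switch fraction by the
#'   total number of distinct matched module labels in the subject's data;
#'   `"per_window"`: divide by the mean per-window module count.
#' @return object of class `flexibility_map`: tibble with columns `region`,
#'   `switch_fraction`, `flexibility`; attributes `n_windows`, `n_modules`.
#' @export
regional_flexibility <- function(assign, normalise = c("total", "per_window")) {
  stopifnot(inherits(assign, "module_assignment"))
  normalise <- match.arg(normalise)
  if (!assign$matched)
    abort_fluctnet("labels must be temporally matched first; call match_labels()")
  labels <- assign$labels
  W <- ncol(labels)
  if (W < 2) abort_fluctnet("flexibility is undefined for a single window")
  switches <- rowSums(labels[, -1, drop = FALSE] != labels[, -W, drop = FALSE])
  switch_fraction <- switches / (W - 1)
  n_modules <- switch(normalise,
                      total = length(unique(as.vector(labels))),
                      per_window = mean(assign$n_modules))
  out <- tibble::tibble(region = assign$parcel_labels,
                        switch_fraction = switch_fraction,
                        flexibility = switch_fraction / n_modules)
  structure(out, class = c("flexibility_map", class(out)),
            n_windows = W, n_modules = n_modules)
}

#' Bar chart of regional flexibility
#'
#' @param object a `flexibility_map`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.flexibility_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$region <- factor(df$region, levels = df$region[order(df$flexibility)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$flexibility)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "flexibility (switch fraction / modules)") +
    ggplot2::theme_minimal()
}
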