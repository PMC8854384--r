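#' Time-resolved community detection on the MTD tensor
#'
#' Runs Louvain modularity maximisation on every windowed connectivity slice.
#' Negative coupling weights are excluded (the graph is built from positive
#' weights only); each window is restarted `n_restarts` times and the partition
#' with the best modularity is kept, so results are deterministic given the
#' seed. An all-zero slice yields a single-module partition with a warning.
#'
#' @param dc a `dynamic_connectivity` from [mtd_tensor()].
#' @param gamma Louvain resolution parameter (default 1).
#' @param seed integer seed governing all restarts.
#' @param n_restarts Louvain restarts per window (best-Q kept).
#' @return object of class `module_assignment`: `labels` (regions x windows
#'   integer matrix), `n_modules` (per window), `modularity` (Q per window),
#'   `matched` (FALSE until [match_labels()]), `parcel_labels`.
#' @export
detect_communities <- function(dc, gamma = 1.0, seed = 1, n_restarts = 10) {
  stopifnot(inherits(dc, "dynamic_connectivity"))
  R <- dim(dc$tensor)[1]; W <- dim(dc$tensor)[3]
  if (W < 1) abort_fluctnet("dynamic connectivity has no windows")
  labels <- matrix(NA_integer_, R, W)
  q <- numeric(W)
  withr::with_seed(as.integer(seed), {
    for (t in seq_len(W)) {
      A <- dc$tensor[, , t]
      A[A < 0] <- 0
      diag(A) <- 0
      if (all(A == 0)) {
        warning(sprintf("window %d: empty (all-zero) positive graph; assigning a single module", t))
        labels[, t] <- 1L
        q[t] <- 0
        next
      }
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                               weighted = TRUE, diag = FALSE)
      best <- NULL; best_q <- -Inf
      for (r in seq_len(n_restarts)) {
        cl <- igraph::cluster_louvain(g, resolution = gamma)
        qq <- max(igraph::modularity(cl))
        if (qq > best_q) { best_q <- qq; best <- cl }
      }
      labels[, t] <- as.integer(igraph::membership(best))
      q[t] <- best_q
    }
  })
  structure(
    list(labels = labels, n_modules = apply(labels, 2, function(l) length(unique(l))),
         modularity = q, matched = FALSE, parcel_labels = dc$parcel_labels),
    class = "module_assignment"
  )
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> %d regions x %d windows, %s labels, median %d modules\n",
              nrow(x$labels), ncol(x$labels),
              if (x$matched) "matched" else "unmatched",
              as.integer(stats::median(x$n_modules))))
  invisible(x)
}

#' Participation coefficient of a weighted graph slice
#'
#' For each region i, `B_i = 1 - sum_s (kappa_is / k_i)^2`, where `kappa_is` is
#' i's total positive edge weight into module s and `k_i` its total positive
#' strength. 0 when all links stay within one module, approaching `1 - 1/M`
#' when strength is spread uniformly over M modules; isolated regions
#' (zero strength) get 0. Negative weights are excluded.
#'
#' @param slice regions x regions symmetric weight matrix (diagonal ignored).
#' @param partition integer module id per region.
#' @return numeric vector of participation coefficients in `[0, 1]`.
#' @export
participation <- function(slice, partition) {
  slice <- as.matrix(slice)
  R <- nrow(slice)
  if (length(partition) != R)
    abort_fluctnet("partition must cover all regions")
  P <- slice
  P[P < 0] <- 0
  diag(P) <- 0
  k <- rowSums(P)
  mods <- sort(unique(partition))
  M <- outer(partition, mods, "==") + 0   # regions x modules indicator
  kappa <- P %*% M
  b <- 1 - rowSums((kappa / ifelse(k == 0, 1, k))^2)
  b[k == 0] <- 0
  b
}

#' Module-degree z-score of a weighted graph slice
#'
#' Each region's within-module positive strength, standardised within its own
#' module (mean 0, unit SD across the module's members). Modules of size 1, or
#' with zero strength variance, get z = 0 for all members. Negative weights are
#' excluded.
#'
#' @inheritParams participation
#' @return numeric vector of within-module z-scores.
#' @export
module_degree_z <- function(slice, partition) {
  slice <- as.matrix(slice)
  R <- nrow(slice)
  if (length(partition) != R)
    abort_fluctnet("partition must cover all regions")
  P <- slice
  P[P < 0] <- 0
  diag(P) <- 0
  z <- numeric(R)
  for (s in unique(partition)) {
    idx <- which(partition == s)
    if (length(idx) < 2) { z[idx] <- 0; next }
    kwithin <- rowSums(P[idx, idx, drop = FALSE])
    sdk <- stats::sd(kwithin)
    z[idx] <- if (sdk < .Machine$double.eps * 100) 0 else (kwithin - mean(kwithin)) / sdk
  }
  z
}

#' Time-resolved topology series (participation and module-degree z)
#'
#' Applies [participation()] and [module_degree_z()] to every window of the
#' tensor, using that window's module partition.
#'
#' @param dc a `dynamic_connectivity`.
#' @param assign a `module_assignment` aligned with `dc`.
#' @return object of class `topology_series`: `participation` and `module_z`
#'   (regions x windows matrices), `parcel_labels`.
#' @export
topology_series <- function(dc, assign) {
  stopifnot(inherits(dc, "dynamic_connectivity"), inherits(assign, "module_assignment"))
  W <- dim(dc$tensor)[3]
  if (ncol(assign$labels) != W)
    abort_fluctnet("module assignment and connectivity tensor have different window counts")
  R <- dim(dc$tensor)[1]
  B <- matrix(0, R, W); Z <- matrix(0, R, W)
  for (t in seq_len(W)) {
    B[, t] <- participation(dc$tensor[, , t], assign$labels[, t])
    Z[, t] <- module_degree_z(dc$tensor[, , t], assign$labels[, t])
  }
  structure(list(participation = B, module_z = Z,
                 parcel_labels = dc$parcel_labels),
            class = "topology_series")
}

#' Cartographic profile: joint histogram of participation and module-degree z
#'
#' 2-D histogram of all (region, window) pairs over participation bins (on
#' `[0, 1]`) and module-degree-z bins (values clipped to the z range, default
#' `[-5, 5]`), so counts are always conserved: they sum to regions x windows
#' (or to 1 when normalised). Leftward (low-participation) mass indicates
#' segregation, rightward mass integration.
#'
#' @param topo a `topology_series`.
#' @param b_edges participation bin edges (default 100 bins on `[0, 1]`).
#' @param z_edges module-z bin edges (default 100 bins on `[-5, 5]`).
#' @param normalise divide counts by their total (default FALSE).
#' @return object of class `cartographic_profile`: `counts` (b bins x z bins),
#'   `b_edges`, `z_edges`, `normalised`.
#' @export
cartographic_profile <- function(topo, b_edges = seq(0, 1, length.out = 101),
                                 z_edges = seq(-5, 5, length.out = 101),
                                 normalise = FALSE) {
  stopifnot(inherits(topo, "topology_series"))
  b <- pmin(pmax(as.vector(topo$participation), min(b_edges)), max(b_edges))
  z <- pmin(pmax(as.vector(topo$module_z), min(z_edges)), max(z_edges))
  bi <- findInterval(b, b_edges, rightmost.closed = TRUE, all.inside = TRUE)
  zi <- findInterval(z, z_edges, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- length(b_edges) - 1; nz <- length(z_edges) - 1
  counts <- matrix(0, nb, nz)
  tab <- table(factor(bi, levels = seq_len(nb)), factor(zi, levels = seq_len(nz)))
  counts[] <- as.numeric(tab)
  if (normalise) counts <- counts / sum(counts)
  structure(list(counts = counts, b_edges = b_edges, z_edges = z_edges,
                 normalised = normalise),
            class = "cartographic_profile")
}

#' Heatmap of a cartographic profile
#'
#' @param object a `cartographic_profile`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cartographic_profile <- function(object, ...) {
  bmid <- (utils::head(object$b_edges, -1) + utils::tail(object$b_edges, -1)) / 2
  zmid <- (utils::head(object$z_edges, -1) + utils::tail(object$z_edges, -1)) / 2
  df <- tibble::tibble(
    b = rep(bmid, times = length(zmid)),
    z = rep(zmid, each = length(bmid)),
    count = as.vector(object$counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$z, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "participation (B_T)", y = "module-degree z (W_T)",
                  fill = if (object$normalised) "density" else "count") +
    ggplot2::theme_minimal()
}

#' Segregated-state occupancy via k-means on participation
#'
#' Pools a subject's participation values over all regions and windows, splits
#' them with k-means (k = 2), calls the cluster with the lower centroid the
#' "segregated" state, and reports the fraction of windows each region spends
#' there.
#'
#' @param topo a `topology_series`.
#' @param k number of clusters (default and intended value 2).
#' @param seed integer seed for k-means.
#' @param retries re-seeding attempts if k-means degenerates.
#' @return object of class `segregation_occupancy`: `occupancy` (per-region
#'   fraction in `[0, 1]`), `centroids` (sorted ascending), `parcel_labels`.
#' @export
segregated_occupancy <- function(topo, k = 2, seed = 1, retries = 5) {
  stopifnot(inherits(topo, "topology_series"))
  v <- as.vector(topo$participation)
  if (length(unique(v)) < k)
    abort_fluctnet("need at least k distinct participation values")
  km <- NULL
  for (att in seq_len(retries)) {
    km <- withr::with_seed(as.integer(seed) + att - 1L, {
      tryCatch(stats::kmeans(v, centers = k, nstart = 10),
               error = function(e) NULL)
    })
    if (!is.null(km) && all(km$size > 0)) break
    km <- NULL
  }
  if (is.null(km))
    abort_fluctnet(sprintf("k-means failed to produce %d non-empty clusters after %d attempts",
                           k, retries))
  seg_cluster <- which.min(km$centers)
  seg <- matrix(km$cluster == seg_cluster, nrow(topo$participation))
  structure(list(occupancy = rowMeans(seg),
                 centroids = sort(as.numeric(km$centers)),
                 parcel_labels = topo$parcel_labels),
            class = "segregation_occupancy")
}
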