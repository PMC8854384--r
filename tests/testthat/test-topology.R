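test_that("community detection recovers ideal and planted structure", {
  # two disconnected 10-region cliques: exactly two modules, cliques intact
  A <- matrix(0, 20, 20)
  A[1:10, 1:10] <- 1; A[11:20, 11:20] <- 1
  diag(A) <- 0
  dc <- new_dc_for_test(array(A, c(20, 20, 1)))
  asn <- detect_communities(dc, seed = 1)
  expect_identical(length(unique(asn$labels[, 1])), 2L)
  expect_identical(length(unique(asn$labels[1:10, 1])), 1L)
  expect_identical(length(unique(asn$labels[11:20, 1])), 1L)
  # determinism
  asn2 <- detect_communities(dc, seed = 1)
  expect_identical(asn$labels, asn2$labels)
  # all-zero slice: single module with a warning
  dz <- new_dc_for_test(array(0, c(5, 5, 1)))
  expect_warning(az <- detect_communities(dz, seed = 1), "single module")
  expect_identical(unique(az$labels[, 1]), 1L)
})

test_that("planted modular states are recovered window by window", {
  # 30-sample windows: long enough that spurious module-factor correlations
  # (which can make merging two planted modules genuinely Q-optimal for a
  # single window's data) are rare; at 15 samples such merges occur in ~10%
  # of windows, an estimation-noise floor, not a detection defect
  part <- rep(1:3, each = 20)
  m <- state_model(60, list(part), 0.9, 0, noise_sd = 0.2)
  ts <- simulate_subject(m, 2000, seed = 41)
  dc <- mtd_tensor(ts, window = 30)
  asn <- detect_communities(dc, seed = 41)
  aris <- vapply(seq_len(ncol(asn$labels)), function(t)
    ari(asn$labels[, t], part), numeric(1))
  expect_gte(mean(aris > 0.9), 0.9)
})

test_that("participation hits its analytic limits and matches the oracle", {
  # all edges within the own module: B = 0
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  expect_equal(participation(A, rep(1:2, each = 4)), rep(0, 8))
  # strength split equally across 4 modules: B = 1 - 1/4
  B <- matrix(1, 8, 8); diag(B) <- 0
  part4 <- rep(1:4, each = 2)
  b <- participation(B, part4)
  # each region: 1 within-module edge, 6 between (2 per other module):
  # shares (1/7)^2 + 3 * (2/7)^2
  expect_equal(b, rep(1 - (1 / 49 + 3 * 4 / 49), 8), tolerance = 1e-12)
  # bounded by the uniform limit 1 - 1/M
  expect_true(all(b <= 1 - 1 / 4 + 1e-12))
  # exact uniform split across 4 modules of one external region's strength
  E <- matrix(0, 9, 9)
  E[9, 1:8] <- 0.25; E[1:8, 9] <- 0.25
  # strength split equally over M = 4 modules: B = 1 - 4 (1/4)^2 = 0.75
  expect_equal(participation(E, c(rep(1:4, each = 2), 5))[9], 0.75,
               tolerance = 1e-12)
  # isolated region
  A2 <- A; A2[1, ] <- 0; A2[, 1] <- 0
  expect_equal(participation(A2, rep(1:2, each = 4))[1], 0)
  # oracle equality on random weighted graphs with negative weights present
  withr::with_seed(42, {
    for (k in 1:10) {
      W <- matrix(rnorm(144), 12, 12); W <- (W + t(W)) / 2; diag(W) <- 0
      p <- sample(1:4, 12, replace = TRUE)
      expect_equal(participation(W, p), oracle_participation(W, p),
                   tolerance = 1e-12)
    }
  })
})

test_that("module-degree z standardises within modules and matches the oracle", {
  # regular within-module graph: all z = 0
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  expect_equal(module_degree_z(A, rep(1:2, each = 4)), rep(0, 8))
  # one hub with twice the within-module strength of 9 identical peers
  H <- matrix(0, 10, 10)
  H[1, 2:10] <- 2 / 3; H[2:10, 1] <- 2 / 3
  H[2:10, 2:10] <- 1 / 3; diag(H) <- 0
  z <- module_degree_z(H, rep(1, 10))
  expect_gt(z[1], 0)
  expect_true(all(z[-1] < 0))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  withr::with_seed(43, {
    for (k in 1:10) {
      W <- matrix(rnorm(144), 12, 12); W <- (W + t(W)) / 2; diag(W) <- 0
      p <- sample(1:3, 12, replace = TRUE)
      expect_equal(module_degree_z(W, p), oracle_module_z(W, p), tolerance = 1e-12)
    }
  })
})

test_that("within-module z sums to zero in every module-window", {
  m <- preset_state_model("control", n_regions = 24)
  ts <- simulate_subject(m, 60, seed = 44)
  dc <- mtd_tensor(ts)
  asn <- detect_communities(dc, seed = 44)
  topo <- topology_series(dc, asn)
  for (t in c(1, 10, 30)) {
    for (s in unique(asn$labels[, t])) {
      idx <- asn$labels[, t] == s
      if (sum(idx) > 1) expect_equal(sum(topo$module_z[idx, t]), 0, tolerance = 1e-8)
    }
  }
  M <- asn$n_modules
  for (t in seq_along(M))
    expect_true(all(topo$participation[, t] <= 1 - 1 / M[t] + 1e-12))
})

test_that("cartographic profiles conserve counts under any binning", {
  topo <- structure(list(participation = matrix(0.42, 6, 9),
                         module_z = matrix(1.3, 6, 9),
                         parcel_labels = sprintf("R%02d", 1:6)),
                    class = "topology_series")
  cp <- cartographic_profile(topo)
  expect_equal(sum(cp$counts), 6 * 9)
  expect_identical(sum(cp$counts > 0), 1L)      # constant values: one bin
  withr::with_seed(45, {
    topo$participation <- matrix(runif(54), 6, 9)
    topo$module_z <- matrix(rnorm(54, sd = 3), 6, 9)
    for (nb in c(5, 20, 100)) {
      cp2 <- cartographic_profile(topo, b_edges = seq(0, 1, length.out = nb + 1),
                                  z_edges = seq(-5, 5, length.out = nb + 1))
      expect_equal(sum(cp2$counts), 54)
    }
    cpn <- cartographic_profile(topo, normalise = TRUE)
    expect_equal(sum(cpn$counts), 1)
    expect_s3_class(autoplot(cpn), "ggplot")
  })
})

test_that("mean participation rises monotonically with between-module coupling", {
  mean_b <- function(btw, seed) {
    m <- preset_state_model("dlb", n_regions = 30, between_coupling = btw,
                            ambiguous_frac = 0)
    ts <- simulate_subject(m, 120, seed = seed)
    dc <- mtd_tensor(ts)
    topo <- topology_series(dc, detect_communities(dc, seed = seed))
    mean(topo$participation)
  }
  levels <- c(0.05, 0.15, 0.3)
  means <- vapply(levels, function(b)
    mean(vapply(1:20, function(s) mean_b(b, 4000 + s), numeric(1))), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_gt(means[3] - means[1], 0.02)
})

test_that("segregated occupancy recovers planted bimodal structure", {
  # half the windows at B ~ 0.1, half at B ~ 0.7, region-specific fractions
  withr::with_seed(46, {
    R <- 10; W <- 40
    frac <- seq(0.1, 1, length.out = R)  # planted per-region segregated fraction
    B <- matrix(0, R, W)
    for (i in seq_len(R)) {
      nseg <- round(frac[i] * W)
      B[i, ] <- c(rnorm(nseg, 0.1, 0.01), rnorm(W - nseg, 0.7, 0.01))
    }
    topo <- structure(list(participation = B, module_z = matrix(0, R, W),
                           parcel_labels = sprintf("R%02d", 1:R)),
                      class = "topology_series")
    occ <- segregated_occupancy(topo, seed = 1)
    expect_equal(occ$centroids, c(0.1, 0.7), tolerance = 0.05)
    expect_equal(occ$occupancy, round(frac * W) / W, tolerance = 0.01)
    expect_equal(max(occ$occupancy), 1)  # fully segregated region
    # window order is irrelevant
    topo2 <- topo
    topo2$participation <- B[, sample(W)]
    occ2 <- segregated_occupancy(topo2, seed = 1)
    expect_equal(occ2$occupancy, occ$occupancy, tolerance = 1e-12)
    expect_error(segregated_occupancy(structure(
      list(participation = matrix(0.5, 3, 4), module_z = matrix(0, 3, 4),
           parcel_labels = c("a", "b", "c")), class = "topology_series")),
      "distinct")
  })
})
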