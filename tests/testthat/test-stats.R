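test_that("permutation group test is calibrated under the null", {
  # identical generating process in both groups: p should be uniform;
  # type-I error at alpha = .05 inside the binomial 95% interval over 500 runs
  pvals <- vapply(1:500, function(s) {
    df <- withr::with_seed(s, tibble::tibble(
      y = rnorm(30), g = rep(c("a", "b"), 15), age = rnorm(30, 70, 5),
      sex = rbinom(30, 1, 0.5)))
    permutation_group_test(df, y, g, covariates = c("age", "sex"),
                           n_perm = 199, seed = s)$p_value
  }, numeric(1))
  rate <- mean(pvals <= 0.05)
  ci <- 0.05 + c(-1.96, 1.96) * sqrt(0.05 * 0.95 / 500)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
  expect_true(all(pvals >= 1 / 200))
})

test_that("permutation group test detects a one-SD planted shift", {
  hits <- vapply(1:200, function(s) {
    df <- withr::with_seed(10000 + s, tibble::tibble(
      y = c(rnorm(20, 1), rnorm(20, 0)), g = rep(c("a", "b"), each = 20)))
    permutation_group_test(df, y, g, n_perm = 199, seed = s)$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("covariate adjustment removes a pure age confound", {
  # group difference induced solely through age: adjusted test stays null
  sig <- vapply(1:200, function(s) {
    df <- withr::with_seed(20000 + s, {
      g <- rep(c("a", "b"), each = 15)
      age <- rnorm(30, ifelse(g == "a", 75, 65), 4)
      tibble::tibble(y = 0.1 * age + rnorm(30, sd = 0.3), g = g, age = age)
    })
    permutation_group_test(df, y, g, covariates = "age",
                           n_perm = 199, seed = s)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
  # sanity: without adjustment the same confound is detected almost always
  sig_raw <- vapply(1:50, function(s) {
    df <- withr::with_seed(20000 + s, {
      g <- rep(c("a", "b"), each = 15)
      age <- rnorm(30, ifelse(g == "a", 75, 65), 4)
      tibble::tibble(y = 0.1 * age + rnorm(30, sd = 0.3), g = g, age = age)
    })
    permutation_group_test(df, y, g, n_perm = 199, seed = s)$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(sig_raw), 0.9)
})

test_that("cohen's d equals the brute-force pooled formula", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(0, 2), c(-1, 1)), (1 - 0) / sqrt((2 + 2) / 2))
  withr::with_seed(71, {
    for (k in 1:10) {
      x <- rnorm(12); y <- rnorm(9, 0.5)
      pooled <- sqrt(((11) * var(x) + 8 * var(y)) / 19)
      expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / pooled, tolerance = 1e-12)
    }
  })
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "pooled SD")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("BH control matches hand-worked cases and the naive oracle", {
  r <- fdr_bh(rep(0.001, 10), q = 0.05)
  expect_true(all(r$significant))
  r2 <- fdr_bh(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_identical(r2$significant, c(TRUE, TRUE, TRUE, FALSE))
  withr::with_seed(72, {
    for (k in 1:10) {
      p <- runif(25)^1.5
      mine <- fdr_bh(p, q = 0.1)
      orc <- oracle_bh(p, q = 0.1)
      expect_equal(mine$q_values, orc$q_values, tolerance = 1e-12)
      expect_identical(mine$significant, orc$significant)
    }
  })
  empty <- fdr_bh(numeric(0))
  expect_length(empty$q_values, 0)
  expect_error(fdr_bh(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("BH keeps the realised false-discovery proportion at or below q", {
  fdp <- vapply(1:1000, function(s) {
    p <- withr::with_seed(30000 + s, runif(40))  # global null
    r <- fdr_bh(p, q = 0.05)
    sum(r$significant) > 0   # all discoveries are false under the global null
  }, logical(1))
  mc_slack <- 2 * sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(fdp), 0.05 + mc_slack)
})

test_that("Mann-Whitney U follows the stated convention and the exact oracle", {
  expect_equal(mannwhitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mannwhitney_u(c(4, 5, 6), c(1, 2, 3))$U, 9)
  same <- mannwhitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8)           # n1 n2 / 2
  withr::with_seed(73, {
    for (k in 1:10) {
      x <- rnorm(4); y <- rnorm(4)
      mine <- mannwhitney_u(x, y)
      orc <- oracle_mwu(x, y)
      expect_equal(mine$U, orc$U)
      expect_equal(mine$p_value, orc$p_value, tolerance = 1e-12)
    }
  })
  big <- mannwhitney_u(rnorm(30), rnorm(30) + 2)
  expect_lt(big$p_value, 0.001)
  expect_match(big$method, "normal")
})

test_that("permutation correlation is exact under identity and calibrated", {
  x <- c(0.3, 1.2, -0.5, 2.2, 0.7, -1.4, 0.1, 1.9)
  self <- permutation_correlation(x, x, n_perm = 999, seed = 1)
  expect_equal(self$estimate, 1, tolerance = 1e-12)
  # minimal attainable p up to chance re-draws of the identity permutation
  expect_lte(self$p_value, 2 / 1000)
  pvals <- vapply(1:500, function(s) {
    d <- withr::with_seed(40000 + s, list(x = rnorm(22), y = rnorm(22)))
    permutation_correlation(d$x, d$y, n_perm = 199, seed = s)$p_value
  }, numeric(1))
  rate <- mean(pvals <= 0.05)
  ci <- 0.05 + c(-1.96, 1.96) * sqrt(0.05 * 0.95 / 500)
  expect_gte(rate, ci[1]); expect_lte(rate, ci[2])
  # spearman path equals pearson-on-ranks
  withr::with_seed(74, {
    a <- rnorm(15); b <- a^3 + rnorm(15, sd = 0.5)
    sp <- permutation_correlation(a, b, n_perm = 99, seed = 2, rank = TRUE)
    expect_equal(sp$estimate, cor(rank(a), rank(b)), tolerance = 1e-12)
    expect_equal(sp$estimate, cor(a, b, method = "spearman"), tolerance = 1e-12)
  })
  expect_error(permutation_correlation(rep(1, 5), rnorm(5)), "constant")
})

test_that("bin-wise cartographic correlation finds constructed structure", {
  withr::with_seed(75, {
    mk_profile <- function(center) {
      B <- matrix(pmin(pmax(rnorm(200, center, 0.05), 0), 1), 10, 20)
      topo <- structure(list(participation = B, module_z = matrix(0, 10, 20),
                             parcel_labels = sprintf("R%02d", 1:10)),
                        class = "topology_series")
      cartographic_profile(topo, b_edges = seq(0, 1, length.out = 11),
                           z_edges = seq(-5, 5, length.out = 3))
    }
    centers <- seq(0.2, 0.8, length.out = 20)
    profiles <- lapply(centers, mk_profile)
    cm <- cartographic_binwise(profiles, centers, q = 0.05)
    # high-participation bins load positively on the outcome
    bmid <- (head(cm$b_edges, -1) + tail(cm$b_edges, -1)) / 2
    rmean <- rowMeans(cm$r, na.rm = TRUE)
    expect_gt(mean(rmean[bmid > 0.7], na.rm = TRUE), 0)
    expect_lt(mean(rmean[bmid < 0.3], na.rm = TRUE), 0)
    expect_true(any(cm$significant, na.rm = TRUE))
    expect_error(cartographic_binwise(profiles, rep(1, 20)), "constant")
  })
})

test_that("null cartographic maps survive FDR control", {
  empty <- vapply(1:200, function(s) {
    withr::with_seed(50000 + s, {
      profiles <- lapply(1:15, function(i) {
        topo <- structure(list(participation = matrix(runif(60), 6, 10),
                               module_z = matrix(rnorm(60), 6, 10),
                               parcel_labels = sprintf("R%02d", 1:6)),
                          class = "topology_series")
        cartographic_profile(topo, b_edges = seq(0, 1, length.out = 6),
                             z_edges = seq(-5, 5, length.out = 6))
      })
      outcome <- rnorm(15)
      cm <- cartographic_binwise(profiles, outcome, q = 0.05)
      !any(cm$significant, na.rm = TRUE)
    })
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("a planted brain-behavior link is recovered through the pipeline", {
  # subject-level local similarity drives the drift rate (log-linear, noisy);
  # rank correlation of S_L with RT variability should come back positive and
  # significant at n = 25 in at least 70% of seeds
  run_seed <- function(seed) {
    seeds <- derive_seeds(seed, 3)
    n <- 25
    subj_seeds <- derive_seeds(seeds[1], n)
    dwell <- withr::with_seed(seeds[2], 25 * exp(rnorm(n, 0, 0.25)))
    sl <- vapply(seq_len(n), function(i) {
      m <- preset_state_model("dlb", n_regions = 30, dwell_mean = max(1, dwell[i]))
      ts <- simulate_subject(m, 150, seed = subj_seeds[i])
      similarity(dc = mtd_tensor(ts), mode = "connectivity")$s_local
    }, numeric(1))
    eps <- withr::with_seed(seeds[3], rnorm(n))
    drift <- 0.2 * exp(-0.2 * scale(sl)[, 1] + 0.25 * eps)
    rtsd <- vapply(seq_len(n), function(i) {
      tr <- simulate_sart(diffusion_spec(drift = drift[i], n_trials = 500,
                                         seed = subj_seeds[i] %% 100000 + i))
      sqrt(summarise_trials(tr)$var_rt)
    }, numeric(1))
    pc <- permutation_correlation(sl, rtsd, n_perm = 999, seed = seeds[3],
                                  rank = TRUE)
    pc$estimate > 0 && pc$p_value <= 0.05
  }
  hits <- vapply(1:20, function(s) run_seed(123 + s), logical(1))
  expect_gte(mean(hits), 0.7)
})
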