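test_that("state_model validates couplings, partitions and dwell", {
  p <- list(rep(1:2, each = 5))
  expect_s3_class(state_model(10, p, 0.5, 0.2), "state_model")
  expect_error(state_model(10, p, 0.2, 0.5), "between_coupling")
  expect_error(state_model(10, p, 1.0, 0.2), "within_coupling")
  expect_error(state_model(10, list(rep(1, 9)), 0.5, 0.2), "partition")
  expect_error(state_model(10, p, 0.5, 0.2, dwell_mean = 0.5), "dwell_mean")
  expect_error(state_model(10, p, 0.5, 0.2, ambiguous_frac = 1.2), "ambiguous_frac")
})

test_that("simulate_subject is deterministic and returns ground truth", {
  m <- state_model(8, list(rep(1:2, each = 4)), 0.6, 0.1, dwell_mean = 5)
  a <- simulate_subject(m, 50, seed = 7)
  b <- simulate_subject(m, 50, seed = 7)
  expect_identical(a$data, b$data)
  expect_identical(attr(a, "states"), attr(b, "states"))
  expect_length(attr(a, "states"), 50)
  d <- simulate_subject(m, 50, seed = 8)
  expect_false(identical(a$data, d$data))
  expect_identical(dim(d$data), dim(a$data))
})

test_that("uncoupled single-state model gives independent regions", {
  m <- state_model(10, list(rep(1:2, each = 5)), 0, 0, noise_sd = 1)
  ts <- simulate_subject(m, 4000, seed = 3)
  r <- cor(t(ts$data))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.05)
})

test_that("sample correlations converge to the analytic coupling values", {
  # population within-module correlation = within / (1 + noise_sd^2)
  part <- rep(1:2, each = 10)
  m <- state_model(20, list(part), 0.8, 0, noise_sd = 1)
  ts <- simulate_subject(m, 2000, seed = 11)
  r <- cor(t(ts$data))
  same <- outer(part, part, "==") & upper.tri(r)
  diff <- (!outer(part, part, "==")) & upper.tri(r)
  expect_equal(mean(r[same]), 0.8 / (1 + 1), tolerance = 0.05)
  expect_lt(abs(mean(r[diff])), 0.05)
  expect_gt(mean(r[same]), mean(r[diff]))
})

test_that("unstable-allegiance regions carry retrievable host sequences", {
  m <- state_model(10, list(rep(1:2, each = 5)), 0.6, 0.1,
                   ambiguous_frac = 0.3, ambiguous_dwell = 4)
  expect_length(m$ambiguous_regions, 3)
  ts <- simulate_subject(m, 60, seed = 2)
  alg <- attr(ts, "allegiance")
  expect_identical(dim(alg), c(3L, 60L))
  expect_true(all(alg %in% 1:2))
  expect_gt(sum(alg[, -1] != alg[, -60]), 0)  # the hosts actually switch
})

test_that("simulate_cohort does the bookkeeping and is seed-stable", {
  spec <- cohort_spec(n_control = 5, n_dlb = 5, n_regions = 20,
                      n_timepoints = 40, window = 15)
  ch <- simulate_cohort(spec, seed = 1)
  expect_length(ch$subjects, 10)
  expect_equal(as.integer(table(ch$manifest$group)), c(5L, 5L))
  expect_true(all(c("subject_id", "group", "age", "sex") %in% names(ch$manifest)))
  ch2 <- simulate_cohort(spec, seed = 2)
  expect_false(identical(ch$subjects[[1]]$data, ch2$subjects[[1]]$data))
  expect_identical(dim(ch2$subjects[[1]]$data), dim(ch$subjects[[1]]$data))
  expect_identical(ch2$manifest$group, ch$manifest$group)
  expect_error(cohort_spec(n_control = 0, n_dlb = 5), "at least one subject")
  expect_error(cohort_spec(n_timepoints = 20, window = 15), "2 x window")
})

test_that("DLB-like preset dwells longer and couples between modules less", {
  ctrl <- preset_state_model("control")
  dlb <- preset_state_model("dlb")
  expect_gte(dlb$dwell_mean, 5 * ctrl$dwell_mean)
  expect_lt(dlb$between_coupling, ctrl$between_coupling)
  # realised dwell segments reflect the presets
  mean_dwell <- function(m, seed) {
    st <- attr(simulate_subject(m, 400, seed = seed), "states")
    mean(rle(st)$lengths)
  }
  expect_gt(mean_dwell(dlb, 5), 2.5 * mean_dwell(ctrl, 5))
})

test_that("simulate_motion stays quiet without spikes and flags exact frames", {
  m <- simulate_motion(120, seed = 4)
  expect_identical(dim(m), c(120L, 6L))
  expect_lt(max(framewise_displacement(m)), 0.25)
  m1 <- simulate_motion(120, spike_times = 57, spike_size = 1, seed = 4)
  fd <- framewise_displacement(m1)
  expect_identical(which(fd > 0.25), 57L)
  expect_gt(fd[57], 0.9)
  expect_error(simulate_motion(50, spike_times = 3, spike_size = -1), "non-negative")
  expect_error(simulate_motion(50, spike_times = 60), "spike_times")
  expect_identical(framewise_displacement(simulate_motion(1, seed = 1)), 0)
})

test_that("diffusion trials behave like the generating process", {
  # zero drift: symmetric boundaries, accuracy converges to 1/2
  tr0 <- simulate_sart(diffusion_spec(drift = 0, n_trials = 10000, seed = 5))
  acc0 <- mean(tr0$correct[!is.na(tr0$rt)])
  expect_lt(abs(acc0 - 0.5), 3 * sqrt(0.25 / 10000) + 0.005)
  # higher drift: more accurate and faster
  lo <- simulate_sart(diffusion_spec(drift = 0.1, n_trials = 10000, seed = 6))
  hi <- simulate_sart(diffusion_spec(drift = 0.4, n_trials = 10000, seed = 6))
  expect_gt(mean(hi$correct, na.rm = TRUE), mean(lo$correct, na.rm = TRUE))
  expect_lt(mean(hi$rt, na.rm = TRUE), mean(lo$rt, na.rm = TRUE))
  # nondecision is a pure additive shift at identical seed
  a <- simulate_sart(diffusion_spec(nondecision = 0, n_trials = 200, seed = 7))
  b <- simulate_sart(diffusion_spec(nondecision = 0.3, n_trials = 200, seed = 7))
  expect_equal(b$rt, a$rt + 0.3, tolerance = 1e-12)
  # everything omitted
  expect_error(simulate_sart(diffusion_spec(drift = 0, max_rt = 0.001, n_trials = 5)),
               "max_rt")
})

test_that("expression simulator plants the requested Spearman correlation", {
  target <- sin(seq_len(333) / 20) + seq_len(333) / 300
  e1 <- simulate_expression(333, 5, planted = list(target_map = target, rho = 1),
                            seed = 1)
  expect_equal(cor(e1$PLANTED, target, method = "spearman"), 1)
  e2 <- simulate_expression(333, 5, planted = list(target_map = target, rho = 0.6),
                            seed = 2)
  expect_gte(cor(e2$PLANTED, target, method = "spearman"), 0.55)
  expect_lte(cor(e2$PLANTED, target, method = "spearman"), 0.65)
  e3 <- simulate_expression(333, 5, planted = list(target_map = target, rho = -0.7),
                            seed = 3)
  expect_equal(cor(e3$PLANTED, target, method = "spearman"), -0.7, tolerance = 0.05)
  expect_error(simulate_expression(10, 3, planted = list(target_map = 1:5, rho = 0.5)),
               "target_map")
  expect_error(simulate_expression(10, 3, planted = list(target_map = 1:10, rho = 1.5)),
               "rho")
})

test_that("a rho = 0 plant is indistinguishable from background under FDR", {
  withr::with_seed(99, target <- rnorm(333))
  hits <- vapply(seq_len(200), function(s) {
    ex <- simulate_expression(333, 20,
                              planted = list(target_map = target, rho = 0),
                              seed = s)
    res <- gene_difference_correlation(
      ex, tibble::tibble(region_id = ex$region_id, difference = target), q = 0.1)
    res$significant[res$gene == "PLANTED"]
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
})
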