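#' Default study configuration
#'
#' All analysis defaults in one place: the 15-sample MTD window, the
#' 0.071-0.125 Hz band, Louvain settings, cartographic binning, permutation
#' count, FDR levels and diffusion scaling, plus the synthetic-study block
#' (cohort, behavior and expression generators). `demo_config()` is a small,
#' fast variant (2 x 8 subjects). Configurations round-trip through YAML via
#' [read_config()] / [write_config()].
#'
#' @param n_control,n_dlb subjects per group.
#' @param n_regions,n_timepoints scan geometry.
#' @param n_perm permutations for group tests and correlations.
#' @param region_n_perm permutations for the per-region maps.
#' @return nested list of class `fluctnet_config`.
#' @export
default_config <- function(n_control = 20, n_dlb = 20, n_regions = 60,
                           n_timepoints = 200, n_perm = 5000,
                           region_n_perm = 1000) {
  structure(list(
    cohort = list(n_control = n_control, n_dlb = n_dlb, n_regions = n_regions,
                  n_timepoints = n_timepoints, sampling_interval = 3,
                  dwell_jitter_sd = 0.25),
    analysis = list(window = 15, band = c(0.071, 0.125), filter = TRUE,
                    similarity_mode = "connectivity", gamma = 1,
                    louvain_restarts = 10, b_bins = 100, z_bins = 100,
                    n_perm = n_perm, region_n_perm = region_n_perm,
                    fdr_q = 0.05, region_q = 0.1, gene_q = 0.1),
    behavior = list(drift0 = 0.2, drift_slope = 0.2, drift_noise = 0.25,
                    boundary = 0.12, nondecision = 0.3, n_trials = 200,
                    max_rt = 10, noise_scale = 0.1),
    expression = list(n_genes = 20, planted_rho = 0.6, planted_name = "PLANTED")
  ), class = "fluctnet_config")
}

#' @rdname default_config
#' @export
demo_config <- function() default_config(n_control = 8, n_dlb = 8,
                                          n_perm = 2000, region_n_perm = 500)

#' @rdname default_config
#' @param path YAML file path.
#' @param config a `fluctnet_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$analysis$band <- as.numeric(cfg$analysis$band)
  structure(cfg, class = "fluctnet_config")
}

#' Run the full synthetic study end to end
#'
#' Simulates a two-group cohort, preprocesses every subject (motion QC,
#' nuisance regression, band-pass), computes MTD connectivity, temporal
#' similarity, time-resolved topology (communities, participation,
#' module-degree z, cartographic profile, segregated occupancy), matched-label
#' flexibility, diffusion-model behavior (per-subject drift tied to the
#' subject's realised dwell time, planting a brain-behavior correlation),
#' covariate-adjusted group inference, per-region difference maps, and the
#' gene-expression correlation with a planted gene. Optionally writes all
#' tabular intermediates plus a JSON manifest to `out_dir`.
#'
#' @param config a `fluctnet_config` (see [default_config()]) or YAML path.
#' @param seed master integer seed fanned out to all stages.
#' @param out_dir output directory (NULL: return results only).
#' @return object of class `study_result`: list with `subjects` (per-subject
#'   tibble of all derived measures), `group_tests` (tibble), `correlations`
#'   (tibble, DLB group), `region_diff` (per-region difference map with
#'   significance), `gene_results`, `regionset_tests`, `profiles` (per-subject
#'   cartographic profiles), `carto_map`, `config`, `seed`.
#' @export
run_study <- function(config = default_config(), seed = 1, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_fluctnet(sprintf("config file not found: %s", config))
    config <- read_config(config)
  }
  cf <- config
  an <- cf$analysis
  seeds <- derive_seeds(seed, 6)

  # --- simulate -------------------------------------------------------------
  spec <- cohort_spec(cf$cohort$n_control, cf$cohort$n_dlb, cf$cohort$n_regions,
                      cf$cohort$n_timepoints, cf$cohort$sampling_interval,
                      dwell_jitter_sd = cf$cohort$dwell_jitter_sd,
                      window = an$window)
  cohort <- simulate_cohort(spec, seed = seeds[1])
  man <- cohort$manifest
  n <- nrow(man)
  motion_seeds <- derive_seeds(seeds[2], n)
  sart_seeds <- derive_seeds(seeds[3], 2 * n)

  b_edges <- seq(0, 1, length.out = an$b_bins + 1)
  z_edges <- seq(-5, 5, length.out = an$z_bins + 1)

  per_subject <- vector("list", n)
  profiles <- vector("list", n)
  part_mat <- matrix(NA_real_, cf$cohort$n_regions, n)  # per-region mean B_T
  flex_mat <- matrix(NA_real_, cf$cohort$n_regions, n)  # per-region flexibility
  for (i in seq_len(n)) {
    ts <- cohort$subjects[[i]]
    motion <- simulate_motion(ncol(ts$data), seed = motion_seeds[i])
    pp <- preprocess_subject(ts, motion, filter = an$filter,
                             low = an$band[1], high = an$band[2])
    dc <- mtd_tensor(pp$ts, window = an$window)
    sim <- similarity(ts = pp$ts, dc = dc, mode = an$similarity_mode)
    assign <- detect_communities(dc, gamma = an$gamma, seed = seeds[4] + i,
                                 n_restarts = an$louvain_restarts)
    topo <- topology_series(dc, assign)
    profiles[[i]] <- cartographic_profile(topo, b_edges, z_edges, normalise = TRUE)
    occ <- segregated_occupancy(topo, seed = seeds[5] + i)
    flex <- regional_flexibility(match_labels(assign))
    part_mat[, i] <- rowMeans(topo$participation)
    flex_mat[, i] <- flex$flexibility
    per_subject[[i]] <- tibble::tibble(
      s_local = sim$s_local, s_global = sim$s_global,
      mean_bt = mean(topo$participation), mean_wt = mean(topo$module_z),
      flexibility = mean(flex$flexibility),
      occupancy = mean(occ$occupancy))
  }
  subjects <- dplyr::bind_cols(man, dplyr::bind_rows(per_subject))

  # --- behavior: attention depends on each subject's realised network
  # stationarity (the generative link the brain-behavior analyses probe):
  # more stationary dynamics (higher S_L, standardised within the cohort)
  # mean a lower drift rate, hence slower and more variable responding;
  # a lognormal idiosyncratic term keeps the link noisy, as real behavior is.
  # S_L is standardised within group so the link strength is comparable in
  # both cohorts despite their different dynamic ranges
  z_sl <- as.numeric(stats::ave(subjects$s_local, subjects$group,
                                FUN = function(x) as.numeric(scale(x))))
  behav <- purrr::map_dfr(seq_len(n), function(i) {
    eps_i <- withr::with_seed(sart_seeds[n + i], stats::rnorm(1))
    drift_i <- cf$behavior$drift0 *
      exp(-cf$behavior$drift_slope * z_sl[i] + cf$behavior$drift_noise * eps_i)
    trials <- simulate_sart(diffusion_spec(
      drift = drift_i, boundary = cf$behavior$boundary,
      nondecision = cf$behavior$nondecision, n_trials = cf$behavior$n_trials,
      max_rt = cf$behavior$max_rt, noise_scale = cf$behavior$noise_scale,
      seed = sart_seeds[i]))
    bs <- summarise_trials(trials)
    ddm <- fit_ddm(bs, noise_scale = cf$behavior$noise_scale)
    tibble::tibble(accuracy = bs$accuracy_raw, mean_rt = bs$mean_rt,
                   rt_sd = sqrt(bs$var_rt), true_drift = drift_i,
                   drift = ddm$drift, boundary = ddm$boundary,
                   nondecision = ddm$nondecision)
  })
  subjects <- dplyr::bind_cols(subjects, behav)

  # --- group inference ------------------------------------------------------
  measures <- c("s_local", "s_global", "mean_bt", "flexibility", "occupancy")
  group_tests <- purrr::map_dfr(measures, function(m) {
    pt <- permutation_group_test(subjects, !!rlang::sym(m), group,
                                 covariates = c("age", "sex"),
                                 n_perm = an$n_perm, seed = seeds[6])
    tibble::tibble(measure = m, dlb_minus_control = -pt$statistic,
                   cohens_d = -pt$cohens_d, p_value = pt$p_value)
  })

  dlb <- subjects[subjects$group == "dlb", ]
  correlations <- tibble::tibble(
    pair = c("s_local~rt_sd", "s_local~drift"),
    rho = NA_real_, p_value = NA_real_)
  if (nrow(dlb) >= 3) {
    c1 <- permutation_correlation(dlb$s_local, dlb$rt_sd,
                                  n_perm = an$n_perm, seed = seeds[6], rank = TRUE)
    c2 <- permutation_correlation(dlb$s_local, dlb$drift,
                                  n_perm = an$n_perm, seed = seeds[6] + 1, rank = TRUE)
    correlations$rho <- c(c1$estimate, c2$estimate)
    correlations$p_value <- c(c1$p_value, c2$p_value)
  }

  # --- regional maps --------------------------------------------------------
  is_ctrl <- subjects$group == "control"
  region_labels <- cohort$subjects[[1]]$parcel_labels
  region_p <- vapply(seq_len(nrow(part_mat)), function(r) {
    df <- tibble::tibble(v = part_mat[r, ], group = subjects$group,
                         age = subjects$age, sex = subjects$sex)
    permutation_group_test(df, v, group, covariates = c("age", "sex"),
                           n_perm = an$region_n_perm, seed = seeds[6] + r)$p_value
  }, numeric(1))
  fdr <- fdr_bh(region_p, an$region_q)
  region_diff <- tibble::tibble(
    region_id = region_labels,
    difference = rowMeans(part_mat[, is_ctrl, drop = FALSE]) -
      rowMeans(part_mat[, !is_ctrl, drop = FALSE]),   # control - DLB: positive = less integrated in DLB
    flex_difference = rowMeans(flex_mat[, !is_ctrl, drop = FALSE]) -
      rowMeans(flex_mat[, is_ctrl, drop = FALSE]),    # DLB - control
    p_value = region_p, q_value = fdr$q_values, significant = fdr$significant)

  # --- gene expression ------------------------------------------------------
  expr <- simulate_expression(
    cf$cohort$n_regions, n_genes = cf$expression$n_genes,
    planted = list(target_map = region_diff$difference,
                   rho = cf$expression$planted_rho,
                   name = cf$expression$planted_name),
    seed = seeds[2])
  gene_results <- gene_difference_correlation(
    expr, region_diff[, c("region_id", "difference")], q = an$gene_q)
  regionset_tests <- NULL
  sig_genes <- gene_results$gene[gene_results$significant]
  if (sum(region_diff$significant) >= 2 &&
      sum(!region_diff$significant) >= 2 && length(sig_genes)) {
    regionset_tests <- suppressWarnings(regionset_expression_test(
      expr, region_diff$region_id[region_diff$significant], genes = sig_genes))
  }

  # --- cartographic map vs behavior ----------------------------------------
  carto_map <- tryCatch(
    cartographic_binwise(profiles, subjects$drift, q = an$fdr_q),
    fluctnet_error = function(e) NULL)

  res <- structure(
    list(subjects = subjects, group_tests = group_tests,
         correlations = correlations, region_diff = region_diff,
         gene_results = gene_results, regionset_tests = regionset_tests,
         profiles = profiles, carto_map = carto_map,
         config = cf, seed = seed),
    class = "study_result")
  if (!is.null(out_dir)) write_study(res, out_dir)
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d subjects (%s), seed %d\n",
              nrow(x$subjects),
              paste(sprintf("%s n=%d", names(table(x$subjects$group)),
                            table(x$subjects$group)), collapse = ", "),
              x$seed))
  print(x$group_tests)
  invisible(x)
}

# write all tabular outputs plus a manifest
write_study <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$subjects, file.path(out_dir, "subjects.csv"))
  readr::write_csv(res$group_tests, file.path(out_dir, "group_tests.csv"))
  readr::write_csv(res$correlations, file.path(out_dir, "correlations.csv"))
  readr::write_csv(res$region_diff, file.path(out_dir, "region_difference_map.csv"))
  readr::write_csv(res$gene_results, file.path(out_dir, "gene_results.csv"))
  if (!is.null(res$regionset_tests))
    readr::write_csv(res$regionset_tests, file.path(out_dir, "regionset_tests.csv"))
  manifest <- list(
    package = "fluctnet",
    version = as.character(utils::packageVersion("fluctnet")),
    seed = res$seed,
    config = unclass(res$config),
    files = list.files(out_dir),
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
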