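#' Hidden-state model for modular BOLD dynamics
#'
#' Defines a small repertoire of connectivity "states". Each state is a
#' partition of regions into modules with compound-symmetric block correlation:
#' `within_coupling` between same-module regions, `between_coupling` between
#' modules, unit variance on the diagonal. A subject's scan switches between
#' states with geometric (memoryless) dwell times of mean `dwell_mean` samples;
#' observations are the state's multivariate-normal signal plus isotropic white
#' noise of standard deviation `noise_sd`.
#'
#' Each state's implied correlation matrix is checked for positive
#' semi-definiteness at construction.
#'
#' @param n_regions number of regions.
#' @param module_partitions list with one integer vector per state, mapping
#'   each region to a module id (each vector must cover all regions).
#' @param within_coupling correlation between same-module regions, in `[0, 1)`.
#' @param between_coupling correlation between regions in different modules,
#'   in `[0, 1)` and `<= within_coupling`.
#' A fraction of regions can be given *unstable module allegiance*
#' (`ambiguous_frac`): instead of a fixed module, each such region hosts in one
#' module at a time but re-draws its host with mean dwell `ambiguous_dwell`
#' samples, independently of the global state sequence. Such regions emulate
#' the unstable module membership the flexibility metric is designed to
#' detect: community detection keeps reassigning them over time.
#'
#' @param n_regions number of regions.
#' @param module_partitions list with one integer vector per state, mapping
#'   each region to a module id (each vector must cover all regions).
#' @param within_coupling correlation between same-module regions, in `[0, 1)`.
#' @param between_coupling correlation between regions in different modules,
#'   in `[0, 1)` and `<= within_coupling`.
#' @param dwell_mean mean state dwell time, in samples (>= 1).
#' @param noise_sd observation noise standard deviation.
#' @param ambiguous_frac fraction of regions (evenly spaced over the region
#'   index) given unstable module allegiance (default 0).
#' @param ambiguous_dwell mean dwell (samples) of an unstable region's host
#'   module (default 16, just above the usual 15-sample analysis window so
#'   host changes are resolvable).
#' @param ambiguous_loading attachment strength of an unstable region to its
#'   current host, in `(0, 1]`: 1 (default) = full member while hosted;
#'   smaller values spread the remaining attachment evenly over the other
#'   modules, making the region's allegiance harder to resolve.
#' @return an object of class `state_model`.
#' @export
state_model <- function(n_regions, module_partitions, within_coupling,
                        between_coupling, dwell_mean = 10, noise_sd = 1,
                        ambiguous_frac = 0, ambiguous_dwell = 16,
                        ambiguous_loading = 1) {
  if (!is.list(module_partitions)) module_partitions <- list(module_partitions)
  n_states <- length(module_partitions)
  stopifnot(n_states >= 1, n_regions >= 2)
  if (!(within_coupling >= 0 && within_coupling < 1))
    abort_fluctnet("within_coupling must be in [0, 1)")
  if (!(between_coupling >= 0 && between_coupling < 1))
    abort_fluctnet("between_coupling must be in [0, 1)")
  if (between_coupling > within_coupling)
    abort_fluctnet("between_coupling must not exceed within_coupling")
  if (dwell_mean < 1) abort_fluctnet("dwell_mean must be >= 1 sample")
  if (noise_sd < 0) abort_fluctnet("noise_sd must be non-negative")
  if (ambiguous_frac < 0 || ambiguous_frac >= 1)
    abort_fluctnet("ambiguous_frac must be in [0, 1)")
  if (ambiguous_dwell < 1) abort_fluctnet("ambiguous_dwell must be >= 1 sample")
  if (ambiguous_loading <= 0 || ambiguous_loading > 1)
    abort_fluctnet("ambiguous_loading must be in (0, 1]")
  n_amb <- floor(ambiguous_frac * n_regions)
  ambiguous <- if (n_amb > 0)
    unique(round(seq(1, n_regions, length.out = n_amb))) else integer(0)

  for (s in seq_len(n_states)) {
    part <- as.integer(module_partitions[[s]])
    if (length(part) != n_regions || anyNA(part))
      abort_fluctnet(sprintf("state %d: partition must assign every one of the %d regions",
                             s, n_regions))
    mods <- sort(unique(part))
    Wm <- outer(part, mods, "==") + 0
    C <- between_coupling + (within_coupling - between_coupling) * tcrossprod(Wm)
    diag(C) <- 1
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      abort_fluctnet(sprintf("state %d: implied covariance is not positive semi-definite (min eigenvalue %.3g)",
                             s, min(ev)))
    module_partitions[[s]] <- part
  }
  structure(
    list(n_regions = n_regions, n_states = n_states,
         module_partitions = module_partitions,
         within_coupling = within_coupling, between_coupling = between_coupling,
         dwell_mean = dwell_mean, noise_sd = noise_sd,
         ambiguous_frac = ambiguous_frac, ambiguous_dwell = ambiguous_dwell,
         ambiguous_loading = ambiguous_loading,
         ambiguous_regions = ambiguous),
    class = "state_model"
  )
}

# contiguous-block partition, circularly shifted; used to build state repertoires
shifted_partition <- function(n_regions, n_modules, shift = 0) {
  base <- ((seq_len(n_regions) - 1) %/% ceiling(n_regions / n_modules)) + 1L
  idx <- ((seq_len(n_regions) - 1 + shift) %% n_regions) + 1L
  base[idx]
}

#' Preset state models for the two synthetic study groups
#'
#' The "control"-like preset switches quickly between states (mean dwell 5
#' samples) with moderate between-module coupling (0.3, a relatively integrated
#' topology); the "dlb"-like preset dwells five times longer (mean 25 samples)
#' with weak between-module coupling (0.1, a segregated topology). Both share
#' `within_coupling = 0.6`, `noise_sd = 1`, three modules, and a repertoire of
#' three shifted modular states.
#'
#' The control-like preset mixes rapidly (mean dwell 5 samples) through a
#' larger repertoire of moderately integrated configurations (6 states,
#' within/between coupling 0.6/0.25); the DLB-like preset dwells five times
#' longer (mean 25 samples) in a smaller repertoire of more segregated
#' configurations (3 states, within/between coupling 0.7/0.1) and additionally
#' contains regions of unstable module allegiance (`ambiguous_frac = 0.2`),
#' emulating the unstable module membership reported in the patient group.
#'
#' @param group `"control"` or `"dlb"`.
#' @param n_regions,n_modules,n_states repertoire geometry (`n_states`
#'   defaults to 6 for control, 3 for dlb).
#' @param dwell_mean,between_coupling,within_coupling,noise_sd,ambiguous_frac
#'   optional overrides of the preset values.
#' @return a [state_model()].
#' @export
preset_state_model <- function(group = c("control", "dlb"), n_regions = 60,
                               n_modules = 3, n_states = NULL,
                               dwell_mean = NULL, between_coupling = NULL,
                               within_coupling = NULL, noise_sd = 1,
                               ambiguous_frac = NULL) {
  group <- match.arg(group)
  n_states <- n_states %||% if (group == "dlb") 3 else 6
  dwell_mean <- dwell_mean %||% if (group == "dlb") 25 else 5
  within_coupling <- within_coupling %||% if (group == "dlb") 0.7 else 0.6
  between_coupling <- between_coupling %||% if (group == "dlb") 0.1 else 0.25
  ambiguous_frac <- ambiguous_frac %||% if (group == "dlb") 0.2 else 0
  blk <- ceiling(n_regions / n_modules)
  shifts <- round(seq(0, blk - 1, length.out = n_states + 1))[seq_len(n_states)]
  parts <- lapply(shifts, function(s) shifted_partition(n_regions, n_modules, s))
  state_model(n_regions, parts, within_coupling, between_coupling,
              dwell_mean, noise_sd, ambiguous_frac)
}

#' Simulate one subject's parcellated BOLD time series
#'
#' Draws a hidden state sequence with geometric dwell times (stay probability
#' `1 - 1/dwell_mean`, switch uniformly to another state), then samples each
#' timepoint from the active state's modular correlation, adds white
#' observation noise, and offsets the whole series by `baseline` (arbitrary
#' BOLD units) so percentage-based QC metrics are defined.
#'
#' Sampling uses the equivalent latent-factor construction of the
#' compound-symmetric block correlation: a global factor (weight
#' `sqrt(between)`), one factor per module (weight `sqrt(within - between)` on
#' members) and an idiosyncratic residual, so that every sample is marginally
#' N(0, C_state). Regions with unstable allegiance load on their *current*
#' host module's factor, which re-draws with mean dwell `ambiguous_dwell`.
#' The hidden state sequence is attached as attribute `"states"`, and the
#' regions x time host-module matrix of unstable regions as attribute
#' `"allegiance"`, for ground-truth tests.
#'
#' @param model a [state_model()].
#' @param n_timepoints number of samples (>= 2).
#' @param sampling_interval TR in seconds.
#' @param seed integer seed; identical seed gives bit-identical output.
#' @param subject_id subject identifier.
#' @param baseline additive signal offset.
#' @return a [parcel_ts()] with attribute `states` (integer vector, length
#'   `n_timepoints`).
#' @export
simulate_subject <- function(model, n_timepoints, sampling_interval = 3,
                             seed = 1, subject_id = "sim", baseline = 1000) {
  stopifnot(inherits(model, "state_model"))
  if (n_timepoints < 2) abort_fluctnet("n_timepoints must be >= 2")
  R <- model$n_regions
  out <- withr::with_seed(as.integer(seed), {
    states <- integer(n_timepoints)
    states[1] <- sample.int(model$n_states, 1)
    if (n_timepoints > 1) {
      stay <- 1 - 1 / model$dwell_mean
      for (t in 2:n_timepoints) {
        if (model$n_states == 1 || stats::runif(1) < stay) {
          states[t] <- states[t - 1]
        } else {
          others <- setdiff(seq_len(model$n_states), states[t - 1])
          states[t] <- others[sample.int(length(others), 1)]
        }
      }
    }
    mods <- sort(unique(model$module_partitions[[1]]))
    M <- length(mods)
    # host-module matrix: partition of the active state, with unstable
    # regions following their own fast allegiance process
    host <- vapply(states, function(s)
      match(model$module_partitions[[s]], mods), integer(R))
    amb <- model$ambiguous_regions
    allegiance <- NULL
    if (length(amb)) {
      stay_a <- 1 - 1 / model$ambiguous_dwell
      allegiance <- matrix(0L, length(amb), n_timepoints)
      for (k in seq_along(amb)) {
        h <- integer(n_timepoints)
        h[1] <- sample.int(M, 1)
        for (t in seq_len(n_timepoints)[-1]) {
          h[t] <- if (M == 1 || stats::runif(1) < stay_a) h[t - 1] else
            setdiff(seq_len(M), h[t - 1])[sample.int(M - 1, 1)]
        }
        allegiance[k, ] <- h
      }
      host[amb, ] <- allegiance
    }
    b <- model$between_coupling
    w <- model$within_coupling
    g <- stats::rnorm(n_timepoints)                        # global factor
    f <- matrix(stats::rnorm(M * n_timepoints), M, n_timepoints)  # module factors
    eps <- matrix(stats::rnorm(R * n_timepoints), R, n_timepoints)
    fsel <- matrix(f[cbind(as.vector(host),
                           rep(seq_len(n_timepoints), each = R))], R, n_timepoints)
    l <- rep(1, R)
    l[amb] <- model$ambiguous_loading
    if (length(amb) && model$ambiguous_loading < 1 && M > 1) {
      # diluted attachment: loading l on the current host, the rest spread
      # evenly over the other module factors
      l_off <- (1 - model$ambiguous_loading) / (M - 1)
      fother <- (matrix(colSums(f), R, n_timepoints, byrow = TRUE) - fsel) * l_off
      fsel[amb, ] <- fsel[amb, , drop = FALSE] * model$ambiguous_loading +
        fother[amb, , drop = FALSE]
    }
    load2 <- l^2
    if (length(amb) && model$ambiguous_loading < 1 && M > 1)
      load2[amb] <- model$ambiguous_loading^2 +
        (1 - model$ambiguous_loading)^2 / (M - 1)
    x <- sqrt(b) * matrix(g, R, n_timepoints, byrow = TRUE) +
      sqrt(w - b) * fsel +
      sqrt(pmax(0, 1 - b - (w - b) * load2)) * eps
    x <- x + model$noise_sd * matrix(stats::rnorm(R * n_timepoints), R, n_timepoints)
    list(x = x + baseline, states = states, allegiance = allegiance)
  })
  ts <- parcel_ts(out$x, sampling_interval = sampling_interval,
                  subject_id = subject_id)
  attr(ts, "states") <- out$states
  attr(ts, "allegiance") <- out$allegiance
  ts
}

#' Specify a two-group synthetic cohort
#'
#' @param n_control,n_dlb subjects per group (>= 1 each).
#' @param n_regions,n_timepoints,sampling_interval scan geometry.
#' @param control_model,dlb_model optional [state_model()]s; defaults are the
#'   [preset_state_model()]s.
#' @param dwell_jitter_sd standard deviation of a per-subject lognormal jitter
#'   on `dwell_mean` (0 disables). Jitter creates within-group variation in
#'   dynamics that behavioral parameters can share, planting brain-behavior
#'   correlations.
#' @param age_mean,age_sd per-group age distributions (years),
#'   named `c(control = , dlb = )`.
#' @param p_male per-group probability of male sex.
#' @param window analysis window length used to validate `n_timepoints`
#'   (must be at least twice the window).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 20, n_dlb = 20, n_regions = 60,
                        n_timepoints = 200, sampling_interval = 3,
                        control_model = NULL, dlb_model = NULL,
                        dwell_jitter_sd = 0,
                        age_mean = c(control = 74, dlb = 70),
                        age_sd = c(control = 6, dlb = 6),
                        p_male = c(control = 0.5, dlb = 0.8),
                        window = 15) {
  if (n_control < 1 || n_dlb < 1)
    abort_fluctnet("each group needs at least one subject")
  if (n_timepoints < 2 * window)
    abort_fluctnet(sprintf("n_timepoints (%d) must be >= 2 x window (%d)",
                           n_timepoints, 2 * window))
  control_model <- control_model %||% preset_state_model("control", n_regions)
  dlb_model <- dlb_model %||% preset_state_model("dlb", n_regions)
  if (control_model$n_regions != n_regions || dlb_model$n_regions != n_regions)
    abort_fluctnet("group state models must share n_regions with the cohort spec")
  structure(
    list(n_control = n_control, n_dlb = n_dlb, n_regions = n_regions,
         n_timepoints = n_timepoints, sampling_interval = sampling_interval,
         models = list(control = control_model, dlb = dlb_model),
         dwell_jitter_sd = dwell_jitter_sd,
         age_mean = age_mean, age_sd = age_sd, p_male = p_male,
         window = window),
    class = "cohort_spec"
  )
}

#' Simulate a two-group cohort of parcel time series
#'
#' Each subject gets an independent RNG substream derived from the master
#' seed, a group label, and simulated covariates (age in years, sex with a
#' deliberate group imbalance, so covariate-adjusted inference can be
#' exercised). Per-subject dwell means are optionally jittered
#' (lognormal, see [cohort_spec()]); the realised dwell is recorded.
#'
#' @param spec a [cohort_spec()].
#' @param seed master integer seed.
#' @return list with `subjects` (list of `parcel_ts`, each with `states`
#'   attribute) and `manifest` (tibble: subject_id, group, age, sex,
#'   dwell_mean, seed).
#' @export
simulate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_control + spec$n_dlb
  groups <- rep(c("control", "dlb"), c(spec$n_control, spec$n_dlb))
  seeds <- derive_seeds(seed, n + 1)
  covs <- withr::with_seed(seeds[n + 1], {
    age <- stats::rnorm(n, spec$age_mean[groups], spec$age_sd[groups])
    sex <- stats::rbinom(n, 1, spec$p_male[groups])
    dwell_mult <- if (spec$dwell_jitter_sd > 0)
      stats::rlnorm(n, 0, spec$dwell_jitter_sd) else rep(1, n)
    list(age = round(age, 1), sex = sex, dwell_mult = dwell_mult)
  })
  subjects <- vector("list", n)
  dwell <- numeric(n)
  for (i in seq_len(n)) {
    m0 <- spec$models[[groups[i]]]
    dwell[i] <- max(1, m0$dwell_mean * covs$dwell_mult[i])
    m <- if (dwell[i] != m0$dwell_mean)
      state_model(m0$n_regions, m0$module_partitions, m0$within_coupling,
                  m0$between_coupling, dwell[i], m0$noise_sd,
                  m0$ambiguous_frac, m0$ambiguous_dwell) else m0
    subjects[[i]] <- simulate_subject(
      m, spec$n_timepoints, spec$sampling_interval, seed = seeds[i],
      subject_id = sprintf("%s_%02d", groups[i], i))
  }
  manifest <- tibble::tibble(
    subject_id = vapply(subjects, function(s) s$subject_id, character(1)),
    group = groups, age = covs$age, sex = covs$sex,
    dwell_mean = dwell, seed = seeds[seq_len(n)])
  list(subjects = subjects, manifest = manifest)
}

#' Simulate a 6-parameter head-motion trace
#'
#' Smooth, low-amplitude sinusoidal drift in all six rigid-body parameters
#' (translations in mm, rotations in radians), plus optional step displacements
#' ("spikes") of known size at known frames in the first translation axis. A
#' step at frame `k` produces framewise displacement of approximately
#' `spike_size` at frame `k` only.
#'
#' @param n_timepoints number of frames.
#' @param spike_times integer frame indices (2..n_timepoints) receiving steps.
#' @param spike_size step size in mm (>= 0).
#' @param seed integer seed.
#' @return frames x 6 numeric matrix with attribute `spike_times`.
#' @export
simulate_motion <- function(n_timepoints, spike_times = integer(0),
                            spike_size = 1, seed = 1) {
  if (length(spike_times) && any(spike_times > n_timepoints | spike_times < 2))
    abort_fluctnet("spike_times must lie in 2..n_timepoints")
  if (spike_size < 0) abort_fluctnet("spike_size must be non-negative")
  m <- withr::with_seed(as.integer(seed), {
    t <- seq_len(n_timepoints)
    amp <- c(rep(0.05, 3), rep(5e-4, 3))      # mm, rad
    period <- stats::runif(6, 60, 120)          # frames: slow drift
    phase <- stats::runif(6, 0, 2 * pi)
    sapply(1:6, function(j) amp[j] * sin(2 * pi * t / period[j] + phase[j]))
  })
  if (n_timepoints == 1) m <- matrix(m, nrow = 1)
  for (k in spike_times) m[k:n_timepoints, 1] <- m[k:n_timepoints, 1] + spike_size
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  attr(m, "spike_times") <- as.integer(spike_times)
  m
}

#' Specify a drift-diffusion process for reaction-time simulation
#'
#' A single-boundary-pair diffusion: evidence starts midway between boundaries
#' 0 and `boundary`, drifts at rate `drift` with diffusion coefficient
#' `noise_scale`, and a trial ends when a boundary is hit (upper = correct).
#' Reaction time = first-passage time + `nondecision`.
#'
#' @param drift drift rate, evidence units per second.
#' @param boundary boundary separation, evidence units (> 0).
#' @param nondecision non-decision time, seconds (>= 0).
#' @param n_trials number of trials.
#' @param max_rt maximum decision time, seconds; slower trials are omissions.
#' @param dt Euler-Maruyama step, seconds (> 0).
#' @param noise_scale diffusion coefficient (conventionally 0.1).
#' @param seed integer seed.
#' @return an object of class `diffusion_spec`.
#' @export
diffusion_spec <- function(drift = 0.2, boundary = 0.12, nondecision = 0.3,
                           n_trials = 1000, max_rt = 10, dt = 0.001,
                           noise_scale = 0.1, seed = 1) {
  if (boundary <= 0) abort_fluctnet("boundary must be > 0")
  if (nondecision < 0) abort_fluctnet("nondecision must be >= 0")
  if (dt <= 0) abort_fluctnet("dt must be > 0")
  if (n_trials < 1) abort_fluctnet("n_trials must be >= 1")
  structure(list(drift = drift, boundary = boundary, nondecision = nondecision,
                 n_trials = n_trials, max_rt = max_rt, dt = dt,
                 noise_scale = noise_scale, seed = seed),
            class = "diffusion_spec")
}

#' Simulate sustained-attention trials from a diffusion process
#'
#' Euler-Maruyama simulation of the process in [diffusion_spec()]. Trials whose
#' decision time exceeds `max_rt` are omissions: kept in the output with
#' `rt = NA` and excluded from downstream summaries.
#'
#' @param spec a [diffusion_spec()].
#' @return tibble with columns `rt` (seconds, NA for omissions) and `correct`
#'   (logical, NA for omissions); the true generating parameters are attached
#'   as attribute `truth`.
#' @export
simulate_sart <- function(spec) {
  stopifnot(inherits(spec, "diffusion_spec"))
  n <- spec$n_trials
  res <- withr::with_seed(as.integer(spec$seed), {
    a <- spec$boundary
    x <- rep(a / 2, n)
    alive <- rep(TRUE, n)
    dt_steps <- ceiling(spec$max_rt / spec$dt)
    sd_step <- spec$noise_scale * sqrt(spec$dt)
    drift_step <- spec$drift * spec$dt
    rt <- rep(NA_real_, n)
    correct <- rep(NA, n)
    for (step in seq_len(dt_steps)) {
      idx <- which(alive)
      if (!length(idx)) break
      x[idx] <- x[idx] + drift_step + sd_step * stats::rnorm(length(idx))
      hit <- idx[x[idx] >= a | x[idx] <= 0]
      if (length(hit)) {
        rt[hit] <- step * spec$dt + spec$nondecision
        correct[hit] <- x[hit] >= a
        alive[hit] <- FALSE
      }
    }
    list(rt = rt, correct = correct)
  })
  if (all(is.na(res$rt)))
    abort_fluctnet("all trials exceeded max_rt; increase max_rt or check parameters")
  out <- tibble::tibble(rt = res$rt, correct = res$correct)
  attr(out, "truth") <- spec[c("drift", "boundary", "nondecision", "noise_scale")]
  out
}

#' Simulate a region x gene expression matrix with an optional planted gene
#'
#' Background genes are smooth random fields over the region index (Gaussian
#' kernel smoothed white noise, rescaled to unit variance). When `planted` is
#' supplied, one extra gene is constructed by rank blending: the blend weight
#' between the target map's normal scores and independent noise is tuned by
#' bisection so the realised Spearman correlation with `target_map` lands
#' within `tol` of `rho` (exact rank copy when `rho = +/-1`, pure noise when
#' `rho = 0`).
#'
#' @param n_regions number of regions.
#' @param n_genes number of background genes.
#' @param planted optional list with elements `target_map` (numeric, length
#'   `n_regions`), `rho` (target Spearman, in `[-1, 1]`) and optionally `name`.
#' @param seed integer seed.
#' @param smooth_bw kernel bandwidth (regions) for background smoothness.
#' @param tol bisection tolerance on the realised Spearman.
#' @return tibble: `region_id` plus one column per gene; attribute
#'   `planted_gene` names the planted column (NULL if none).
#' @export
simulate_expression <- function(n_regions, n_genes = 20, planted = NULL,
                                seed = 1, smooth_bw = 5, tol = 0.02) {
  if (!is.null(planted)) {
    if (abs(planted$rho) > 1) abort_fluctnet("planted rho must be in [-1, 1]")
    if (length(planted$target_map) != n_regions)
      abort_fluctnet(sprintf("target_map has length %d; expected n_regions = %d",
                             length(planted$target_map), n_regions))
  }
  out <- withr::with_seed(as.integer(seed), {
    idx <- seq_len(n_regions)
    K <- exp(-0.5 * (outer(idx, idx, "-") / smooth_bw)^2)
    K <- K / rowSums(K)
    bg <- K %*% matrix(stats::rnorm(n_regions * n_genes), n_regions, n_genes)
    bg <- scale(bg)              # unit variance per gene
    colnames(bg) <- sprintf("GENE%02d", seq_len(n_genes))
    genes <- as.data.frame(bg)
    if (!is.null(planted)) {
      rho <- planted$rho
      target <- planted$target_map
      u <- stats::qnorm((rank(target, ties.method = "average") - 0.5) / n_regions)
      e <- stats::rnorm(n_regions)
      g <- if (rho == 0) {
        e
      } else if (abs(rho) == 1) {
        sign(rho) * u
      } else {
        sgn <- sign(rho)
        # bisection on the blend weight for the realised Spearman
        lo <- 0; hi <- 1
        for (it in 1:60) {
          mid <- (lo + hi) / 2
          r <- stats::cor(mid * sgn * u + (1 - mid) * e, target, method = "spearman")
          if (abs(r - rho) <= tol) { lo <- hi <- mid; break }
          if (sgn * r < sgn * rho) lo <- mid else hi <- mid
        }
        w <- (lo + hi) / 2
        w * sgn * u + (1 - w) * e
      }
      genes[[planted$name %||% "PLANTED"]] <- as.numeric(g)
    }
    genes
  })
  res <- tibble::as_tibble(cbind(
    data.frame(region_id = sprintf("R%03d", seq_len(n_regions))), out))
  attr(res, "planted_gene") <- if (is.null(planted)) NULL else planted$name %||% "PLANTED"
  res
}
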