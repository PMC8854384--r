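#' Summarise sustained-attention trials
#'
#' Computes the three summary statistics the diffusion-model fit consumes:
#' mean and variance of correct-trial reaction times, and accuracy
#' (correct / responded trials). Omissions (`rt = NA`) are excluded. Accuracy
#' of exactly 0, 0.5 or 1 is replaced by the standard edge correction
#' (a `1/(2n)` adjustment towards the interior) before model fitting; the raw
#' value is retained alongside.
#'
#' @param trials data frame with columns `rt` (seconds) and `correct`
#'   (logical/0-1); rows with `rt = NA` are omissions.
#' @return tibble of class `behavioral_summary` with columns `n_trials`,
#'   `accuracy_raw`, `accuracy`, `mean_rt`, `var_rt`.
#' @export
summarise_trials <- function(trials) {
  stopifnot(all(c("rt", "correct") %in% names(trials)))
  keep <- !is.na(trials$rt)
  rt <- trials$rt[keep]
  correct <- as.logical(trials$correct[keep])
  n <- length(rt)
  rt_c <- rt[correct]
  if (length(rt_c) < 2)
    abort_fluctnet("need at least 2 correct trials to summarise")
  acc_raw <- mean(correct)
  acc <- acc_raw
  if (acc == 1) acc <- 1 - 1 / (2 * n)
  if (acc == 0) acc <- 1 / (2 * n)
  if (acc == 0.5) acc <- 0.5 + 1 / (2 * n)
  out <- tibble::tibble(n_trials = n, accuracy_raw = acc_raw, accuracy = acc,
                        mean_rt = mean(rt_c), var_rt = stats::var(rt_c))
  class(out) <- c("behavioral_summary", class(out))
  out
}

#' Predicted moments of the simple diffusion model
#'
#' Closed-form accuracy, mean decision time and decision-time variance of the
#' three-parameter diffusion model (drift `v`, boundary separation `a`,
#' non-decision time `ter`, diffusion coefficient `s`), with the process
#' starting midway between the boundaries. Mean RT adds `ter` to the mean
#' decision time; RT variance equals the decision-time variance.
#'
#' @param drift,boundary,nondecision model parameters.
#' @param noise_scale diffusion coefficient (default 0.1).
#' @return tibble with `accuracy`, `mean_rt`, `var_rt`.
#' @export
ddm_moments <- function(drift, boundary, nondecision, noise_scale = 0.1) {
  s2 <- noise_scale^2
  y <- exp(-drift * boundary / s2)
  acc <- 1 / (1 + y)
  mdt <- (boundary / (2 * drift)) * (1 - y) / (1 + y)
  vdt <- (boundary * s2 / (2 * drift^3)) *
    (2 * (-drift * boundary / s2) * y - y^2 + 1) / (y + 1)^2
  tibble::tibble(accuracy = acc, mean_rt = nondecision + mdt, var_rt = vdt)
}

#' Closed-form diffusion-model fit from summary statistics
#'
#' Method-of-moments inversion of the simple diffusion model from accuracy,
#' RT variance and mean RT (the EZ-style solution): drift rate from accuracy
#' and RT variance, boundary separation from drift and accuracy, and
#' non-decision time as mean RT minus the model-implied mean decision time.
#' Deterministic; exactly inverts [ddm_moments()].
#'
#' @param summary a [summarise_trials()] result, or any data frame with
#'   columns `accuracy`, `mean_rt`, `var_rt` (one row per subject; extra
#'   identifier columns are carried through).
#' @param noise_scale diffusion coefficient (must match the scale convention
#'   of the data-generating process; default 0.1).
#' @return tibble of class `ddm_fit`: input identifier columns plus `drift`,
#'   `boundary`, `nondecision`.
#' @export
fit_ddm <- function(summary, noise_scale = 0.1) {
  stopifnot(all(c("accuracy", "mean_rt", "var_rt") %in% names(summary)))
  fit_one <- function(acc, mrt, vrt) {
    if (!is.finite(vrt) || vrt <= 0)
      abort_fluctnet("var_rt must be positive: drift is undefined at zero RT variance")
    if (acc <= 0 || acc >= 1 || acc == 0.5)
      abort_fluctnet("accuracy must be inside (0,1) and not exactly 0.5; use summarise_trials() edge correction")
    s <- noise_scale
    L <- stats::qlogis(acc)
    x <- L * (L * acc^2 - L * acc + acc - 0.5) / vrt
    v <- sign(acc - 0.5) * s * x^(1 / 4)
    a <- s^2 * L / v
    y <- exp(-v * a / s^2)
    mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
    c(drift = v, boundary = a, nondecision = mrt - mdt)
  }
  pars <- purrr::pmap(list(summary$accuracy, summary$mean_rt, summary$var_rt),
                      function(a, m, v) fit_one(a, m, v))
  pars <- do.call(rbind, pars)
  id_cols <- setdiff(names(summary),
                     c("accuracy", "accuracy_raw", "mean_rt", "var_rt", "n_trials"))
  out <- dplyr::bind_cols(
    tibble::as_tibble(summary)[, id_cols, drop = FALSE],
    tibble::as_tibble(pars))
  if (any(out$nondecision < -1e-8))
    warning("fitted non-decision time is negative for at least one subject")
  attr(out, "noise_scale") <- noise_scale
  class(out) <- c("ddm_fit", class(out))
  out
}

#' @rdname fit_ddm
#' @param x a `ddm_fit`.
#' @param ... unused.
#' @export
tidy.ddm_fit <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(c("drift", "boundary", "nondecision")),
                        names_to = "term", values_to = "estimate")
}

#' @rdname fit_ddm
#' @export
glance.ddm_fit <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x), noise_scale = attr(x, "noise_scale"))
}
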