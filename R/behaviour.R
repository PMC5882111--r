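#' Mean decision time in correct trials
#'
#' Converts the mean decision sample size (number of discrete observations
#' to threshold) into continuous decision time: each observation stands for
#' one inter-spike interval of the fastest-firing (preferred) channel, and
#' half an ISI is added for the wait from decision initiation to the first
#' spike, giving `tau_c = (mean_T + 0.5) * pref_mean_isi`.
#'
#' @param mean_T Mean decision sample size in steps (>= 0).
#' @param pref_mean_isi Mean preferred-channel ISI in ms (the unscaled,
#'   registry value `mu* n`).
#' @return Mean decision time in ms.
#' @examples
#' mean_decision_time_correct(7, 29.9)  # 224.25 ms
#' @export
mean_decision_time_correct <- function(mean_T, pref_mean_isi) {
  if (any(mean_T < 0)) stop("`mean_T` must be >= 0", call. = FALSE)
  (mean_T + 0.5) * pref_mean_isi
}

#' Mean decision time in error trials
#'
#' As [mean_decision_time_correct()], but an erroneous choice is driven by
#' a null-statistics channel that happened to fire fastest, so the null
#' mean ISI sets the time base: `tau_e = (mean_T + 0.5) * null_mean_isi`.
#'
#' @param mean_T Mean decision sample size in steps (>= 0).
#' @param null_mean_isi Mean null-channel ISI in ms (registry value
#'   `mu0 n`).
#' @return Mean decision time in ms.
#' @export
mean_decision_time_error <- function(mean_T, null_mean_isi) {
  if (any(mean_T < 0)) stop("`mean_T` must be >= 0", call. = FALSE)
  (mean_T + 0.5) * null_mean_isi
}

#' Mean decision sample size implied by a measured reaction time
#'
#' Inverse of [mean_decision_time_correct()]: strips the non-decision time
#' from a mean reaction time and converts the remaining decision time back
#' to observation counts,
#' `T_hat = (mean_rt - non_decision_time) / pref_mean_isi - 0.5`.
#'
#' @param mean_rt Mean reaction time in ms.
#' @param non_decision_time Sensory plus motor latency in ms (200-300 ms is
#'   plausible for macaques; 250 is the default elsewhere).
#' @param pref_mean_isi Mean preferred-channel ISI in ms.
#' @return Implied mean decision sample size in steps.
#' @export
monkey_decision_samples <- function(mean_rt, non_decision_time, pref_mean_isi) {
  dt <- mean_rt - non_decision_time
  if (any(dt <= 0)) {
    stop("reaction time must exceed the non-decision time", call. = FALSE)
  }
  dt / pref_mean_isi - 0.5
}

#' Information account for one condition
#'
#' The Wald-style link between decision time and evidence quality: the mean
#' total discrimination information needed for a decision at fixed error
#' rate and `N` is (approximately) constant, so the model's mean sample
#' size times the per-ISI discrimination information `K` estimates that
#' total, `I_hat = model_mean_T * K`. Dividing `I_hat` by the subject's
#' implied sample size gives the per-ISI information the subject actually
#' used, `K_hat = I_hat / monkey_T_hat`, and the information loss is
#' `(1 - K_hat / K) * 100` percent. `I_hat` inherits an upper-bound flavour
#' from the underlying inequality, so the loss is a minimum estimate.
#'
#' @param model_mean_T Model mean decision sample size (steps).
#' @param K Discrimination information in the evidence, bits per ISI.
#' @param monkey_T_hat Subject's implied mean decision sample size (steps).
#' @return A list with `K`, `I_hat`, `K_hat_monkey`, `loss_percent`.
#' @export
information_account <- function(model_mean_T, K, monkey_T_hat) {
  if (any(c(model_mean_T, K, monkey_T_hat) <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  I_hat <- model_mean_T * K
  K_hat <- I_hat / monkey_T_hat
  list(K = K, I_hat = I_hat, K_hat_monkey = K_hat,
       loss_percent = (1 - K_hat / K) * 100)
}

#' Deplete the discrimination information of an ISI pair
#'
#' Moves the null-channel statistics towards the preferred ones by a common
#' proportion `gamma`, `mu0' = mu* + gamma (mu0 - mu*)` and
#' `sd0' = sd* + gamma (sd0 - sd*)`, choosing `gamma` in `(0, 1]` by
#' bisection so that the Kullback-Leibler divergence from the preferred to
#' the adjusted null lognormal equals `K_target` bits. The preferred
#' channel is never modified.
#'
#' @param pref,null `isi_statistics` of the original pair.
#' @param K_target Target divergence in bits; must lie in
#'   `(0, K(pref, null)]`.
#' @param n Data scaling factor used when building shapes (the divergence
#'   does not depend on it).
#' @param tol Bisection tolerance on the divergence, bits (default 1e-9).
#' @return The adjusted null `isi_statistics`, with attribute `gamma`.
#' @export
deplete_information <- function(pref, null, K_target, n = 1, tol = 1e-9) {
  K_full <- kl_divergence_bits(lognormal_shape(pref, n), lognormal_shape(null, n))
  if (K_target <= 0) stop("`K_target` must be positive", call. = FALSE)
  if (K_target > K_full + 1e-12) {
    stop(sprintf(
      "infeasible depletion: K_target = %.4g bits exceeds the available %.4g bits",
      K_target, K_full), call. = FALSE)
  }
  pref_shape <- lognormal_shape(pref, n)
  k_of <- function(gamma) {
    nn <- isi_statistics(pref$mean_isi + gamma * (null$mean_isi - pref$mean_isi),
                         pref$sd_isi + gamma * (null$sd_isi - pref$sd_isi))
    kl_divergence_bits(pref_shape, lognormal_shape(nn, n))
  }
  if (abs(K_full - K_target) <= tol) {
    out <- isi_statistics(null$mean_isi, null$sd_isi)
    attr(out, "gamma") <- 1
    return(out)
  }
  lo <- 0
  hi <- 1
  # K is increasing in gamma (null moves away from pref); K(0+) -> 0
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    km <- k_of(mid)
    if (abs(km - K_target) <= tol) break
    if (km > K_target) hi <- mid else lo <- mid
  }
  gamma <- mid
  out <- isi_statistics(pref$mean_isi + gamma * (null$mean_isi - pref$mean_isi),
                        pref$sd_isi + gamma * (null$sd_isi - pref$sd_isi))
  attr(out, "gamma") <- gamma
  out
}

#' Build a depleted parameter set from per-condition information targets
#'
#' Applies [deplete_information()] at every coherence of a parameter set,
#' returning a new `isi_parameter_set` whose null channels carry the target
#' discrimination information while the preferred channels are unchanged.
#'
#' @param set Source `isi_parameter_set` (typically `Omega`).
#' @param K_targets Named numeric vector of target divergences in bits,
#'   keyed by coherence; coherences of the set without a target are left
#'   unchanged.
#' @param label Label for the new set.
#' @return An `isi_parameter_set`.
#' @export
deplete_parameter_set <- function(set, K_targets, label = "depleted") {
  stopifnot(inherits(set, "isi_parameter_set"))
  unknown <- setdiff(names(K_targets), rownames(set))
  if (length(unknown) > 0) {
    stop("K targets for coherences absent from the set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- set
  for (key in intersect(rownames(set), names(K_targets))) {
    kt <- K_targets[[key]]
    if (is.na(kt)) stop("NA K target for coherence ", key, call. = FALSE)
    st <- isi_stats(set, as.numeric(key))
    nn <- deplete_information(st$preferred, st$null, kt)
    out[key, "null_mean"] <- nn$mean_isi
    out[key, "null_sd"] <- nn$sd_isi
  }
  attr(out, "label") <- label
  .validate_parameter_set(out)
  out
}

#' Correct an information estimate for an enhanced reaction-time match
#'
#' The Wald inequality makes the first-pass `K_hat` a likely over-estimate,
#' leaving model reaction times slightly shorter than the subject's.
#' Multiplying `K_hat` per condition by the ratio of the model's decision
#' time to the subject's shrinks it accordingly; re-running depletion with
#' the corrected value lengthens model reaction times towards the
#' subject's.
#'
#' @param K_hat First-pass information estimate, bits per ISI.
#' @param model_rt Model mean decision (or reaction) time, ms.
#' @param monkey_rt Subject mean decision (or reaction) time on the same
#'   scale, ms.
#' @return Corrected estimate in bits per ISI.
#' @export
enhanced_loss_correction <- function(K_hat, model_rt, monkey_rt) {
  if (any(c(K_hat, model_rt, monkey_rt) <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  K_hat * (model_rt / monkey_rt)
}

#' Chebyshev confidence interval for a sample mean
#'
#' Distribution-free interval `mean +/- k * SD / sqrt(n)` with
#' `k = 1 / sqrt(1 - level)` (k = 10 at the 99% level), i.e. Chebyshev's
#' inequality applied to the standard error of the mean. Conservative:
#' coverage is at least `level` for any distribution with finite variance.
#'
#' @param samples Numeric vector, `n >= 2`.
#' @param level Coverage level in `(0, 1)` (default 0.99).
#' @return Named vector `c(low, high)`.
#' @export
chebyshev_interval <- function(samples, level = 0.99) {
  n <- length(samples)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)", call. = FALSE)
  k <- 1 / sqrt(1 - level)
  m <- mean(samples)
  half <- k * stats::sd(samples) / sqrt(n)
  c(low = m - half, high = m + half)
}
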