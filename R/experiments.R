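#' Define a Monte Carlo experiment plan
#'
#' Fixes the condition grid (parameter set, numbers of alternatives,
#' coherences), the trial budget, seeding, and the reaction-time
#' conversion. Trials are divided equally across the coherences (the
#' standard totals of 3200 and 4800 trials per experiment for `N = 2` and
#' `N = 4` give 640 and 960 trials per coherence).
#'
#' @param parameter_set Label: `"Omega"` or `"Omega_d"` (resolved per `N`),
#'   or an explicit registry label.
#' @param n_alternatives Integer vector of `N` values (default `c(2, 4)`).
#' @param coherences Coherence percentages (default the registry levels).
#' @param trials_per_experiment Total trials per experiment, one entry per
#'   `N` (default `c(3200, 4800)`).
#' @param n_experiments Number of repeated Monte Carlo experiments
#'   (default 1).
#' @param seed Root seed; every child simulation derives from it.
#' @param non_decision_time Sensory-plus-motor latency added to decision
#'   times, ms (default 250).
#' @param scaling_n Data scaling factor (default 40).
#' @param Delta Feedback delay (default 3).
#' @param calibration_trials Trials per error-rate evaluation during
#'   threshold calibration (default 2000).
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(parameter_set = "Omega_d",
                            n_alternatives = c(2L, 4L),
                            coherences = coherence_levels(),
                            trials_per_experiment = c(3200L, 4800L),
                            n_experiments = 1L, seed = 1L,
                            non_decision_time = 250,
                            scaling_n = 40, Delta = 3L,
                            calibration_trials = 2000L) {
  if (length(trials_per_experiment) == 1L) {
    trials_per_experiment <- rep(trials_per_experiment, length(n_alternatives))
  }
  stopifnot(length(trials_per_experiment) == length(n_alternatives))
  per_coh <- trials_per_experiment / length(coherences)
  if (any(per_coh != round(per_coh))) {
    stop("`trials_per_experiment` must divide equally across the coherences",
         call. = FALSE)
  }
  structure(list(parameter_set = parameter_set,
                 n_alternatives = as.integer(n_alternatives),
                 coherences = as.numeric(coherences),
                 trials_per_experiment = as.integer(trials_per_experiment),
                 n_experiments = as.integer(n_experiments),
                 seed = as.integer(seed),
                 non_decision_time = as.numeric(non_decision_time),
                 scaling_n = as.numeric(scaling_n),
                 Delta = as.integer(Delta),
                 calibration_trials = as.integer(calibration_trials)),
            class = "experiment_plan")
}

# canonical condition index over the standard grid (N in {2, 4} by the
# packaged coherences); the behavioural pipeline keys its child seeds on it
# so that fixture generation and recovery runs of the same condition share
# evidence streams (a paired, common-random-numbers design)
.pipeline_condition_index <- function(N, coherence) {
  iN <- match(N, c(2L, 4L))
  ic <- match(.coherence_key(coherence), .coherence_key(coherence_levels()))
  if (is.na(iN) || is.na(ic)) return(NA_integer_)
  (iN - 1L) * length(coherence_levels()) + ic
}

# per-condition child seeds: condition index for calibration, plus one per
# experiment for the measurement runs
.condition_index <- function(plan, N, coherence) {
  iN <- match(N, plan$n_alternatives)
  ic <- match(coherence, plan$coherences)
  (iN - 1L) * length(plan$coherences) + ic
}

#' Run the Monte Carlo experiment grid
#'
#' For every condition of the plan: calibrates the threshold to the
#' coherence-dependent target error rate, runs the planned trials, and
#' summarizes behaviour. Decision sample sizes are converted to decision
#' times with the preferred-channel mean ISI for correct trials and the
#' null-channel mean for error trials, then to reaction times by adding the
#' non-decision time. With `n_experiments > 1` the summary is the mean of
#' per-experiment summaries. Everything is reproducible from the plan's
#' root seed.
#'
#' @param plan An [experiment_plan()].
#' @param registry Registry from [load_parameter_table()] (loaded on demand).
#' @param keep_trials If `TRUE`, attach the per-trial records (with
#'   reaction times) as attribute `trials`.
#' @return A data.frame with one row per condition: `parameter_set`, `N`,
#'   `coherence`, `theta`, `target_error`, `error_rate`, `n_trials`,
#'   `mean_T_correct`, `mean_T_error`, `mean_dt_correct_ms`,
#'   `mean_dt_error_ms`, `mean_rt_correct_ms`, `mean_rt_error_ms`.
#' @export
run_experiment_grid <- function(plan, registry = NULL, keep_trials = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (is.null(registry)) registry <- load_parameter_table()
  rows <- list()
  trial_rows <- list()
  for (iN in seq_along(plan$n_alternatives)) {
    N <- plan$n_alternatives[iN]
    per_coh <- plan$trials_per_experiment[iN] %/% length(plan$coherences)
    for (coh in plan$coherences) {
      cond <- decision_condition(N, coh, plan$parameter_set,
                                 scaling_n = plan$scaling_n)
      ci <- .condition_index(plan, N, coh)
      target <- error_rate_target(coh, N)
      theta <- calibrate_threshold(cond, target,
                                   mc_trials = plan$calibration_trials,
                                   seed = .child_seed(plan$seed, ci, 1L),
                                   Delta = plan$Delta, registry = registry)
      st <- isi_stats(registry[[.resolve_set_label(plan$parameter_set, N)]], coh)
      per_exp <- vector("list", plan$n_experiments)
      for (e in seq_len(plan$n_experiments)) {
        res <- run_trials(cond, as.numeric(theta), per_coh,
                          seed = .child_seed(plan$seed, ci, 1L + e),
                          Delta = plan$Delta, registry = registry)
        ok <- res$correct
        mTc <- mean(res$T[ok])
        mTe <- if (any(!ok)) mean(res$T[!ok]) else NA_real_
        per_exp[[e]] <- data.frame(
          error_rate = mean(!ok),
          mean_T_correct = mTc,
          mean_T_error = mTe,
          mean_dt_correct_ms = mean_decision_time_correct(mTc, st$preferred$mean_isi),
          mean_dt_error_ms = if (is.na(mTe)) NA_real_ else
            mean_decision_time_error(mTe, st$null$mean_isi)
        )
        if (keep_trials) {
          res$experiment <- e
          res$N <- N
          res$coherence <- coh
          res$rt_ms <- ifelse(
            res$correct,
            mean_decision_time_correct(res$T, st$preferred$mean_isi),
            mean_decision_time_error(res$T, st$null$mean_isi)
          ) + plan$non_decision_time
          trial_rows[[length(trial_rows) + 1L]] <- res
        }
      }
      pe <- do.call(rbind, per_exp)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter_set = .resolve_set_label(plan$parameter_set, N),
        N = N, coherence = coh, theta = as.numeric(theta),
        target_error = target,
        error_rate = mean(pe$error_rate),
        n_trials = per_coh * plan$n_experiments,
        mean_T_correct = mean(pe$mean_T_correct),
        mean_T_error = mean(pe$mean_T_error, na.rm = TRUE),
        mean_dt_correct_ms = mean(pe$mean_dt_correct_ms),
        mean_dt_error_ms = mean(pe$mean_dt_error_ms, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$mean_rt_correct_ms <- out$mean_dt_correct_ms + plan$non_decision_time
  out$mean_rt_error_ms <- out$mean_dt_error_ms + plan$non_decision_time
  if (keep_trials) attr(out, "trials") <- do.call(rbind, trial_rows)
  out
}

.sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Reaction-time histograms per condition and outcome
#'
#' Bins per-trial reaction times (from [run_experiment_grid()] with
#' `keep_trials = TRUE`) and reports a sample skewness per group.
#'
#' @param trials Per-trial data.frame with columns `N`, `coherence`,
#'   `correct`, `rt_ms`.
#' @param bin_width Bin width in ms (default 50).
#' @return A data.frame of bin counts (`N`, `coherence`, `outcome`,
#'   `bin_start`, `count`) with a `skewness` data.frame attached as an
#'   attribute.
#' @export
rt_histograms <- function(trials, bin_width = 50) {
  stopifnot(nrow(trials) > 0, all(c("N", "coherence", "correct", "rt_ms") %in%
                                    names(trials)))
  groups <- unique(trials[, c("N", "coherence", "correct")])
  hists <- list()
  skews <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- trials$N == groups$N[g] & trials$coherence == groups$coherence[g] &
      trials$correct == groups$correct[g]
    rt <- trials$rt_ms[sel]
    if (length(rt) == 0) next
    bins <- floor(rt / bin_width) * bin_width
    tab <- table(bins)
    outc <- if (groups$correct[g]) "correct" else "error"
    hists[[length(hists) + 1L]] <- data.frame(
      N = groups$N[g], coherence = groups$coherence[g], outcome = outc,
      bin_start = as.numeric(names(tab)), count = as.integer(tab),
      stringsAsFactors = FALSE)
    skews[[length(skews) + 1L]] <- data.frame(
      N = groups$N[g], coherence = groups$coherence[g], outcome = outc,
      skewness = .sample_skewness(rt), q95 = unname(stats::quantile(rt, 0.95)),
      n = length(rt), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hists)
  attr(out, "skewness") <- do.call(rbind, skews)
  out
}

#' Trace experiment: averaged circuit traces per condition
#'
#' Runs trials with full circuit traces for each condition of the plan and
#' returns initiation- and termination-aligned selected/non-selected mean
#' series per mapped region.
#'
#' @param plan An [experiment_plan()] (the per-coherence trial counts set
#'   how many traced trials are run per condition).
#' @param config A [circuit_config()].
#' @param registry Registry (loaded on demand).
#' @param correct_only Average correct trials only (default `TRUE`, the
#'   usual display convention).
#' @return A long data.frame with `parameter_set`, `N`, `coherence`,
#'   `alignment`, `step`, `region`, `class`, `value`, `n`.
#' @export
trace_experiment <- function(plan, config = circuit_config(), registry = NULL,
                             correct_only = TRUE) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (is.null(registry)) registry <- load_parameter_table()
  out <- list()
  for (iN in seq_along(plan$n_alternatives)) {
    N <- plan$n_alternatives[iN]
    per_coh <- plan$trials_per_experiment[iN] %/% length(plan$coherences)
    for (coh in plan$coherences) {
      cond <- decision_condition(N, coh, plan$parameter_set,
                                 scaling_n = plan$scaling_n)
      ci <- .condition_index(plan, N, coh)
      target <- error_rate_target(coh, N)
      theta <- calibrate_threshold(cond, target,
                                   mc_trials = plan$calibration_trials,
                                   seed = .child_seed(plan$seed, ci, 1L),
                                   Delta = config$latencies$Delta,
                                   registry = registry)
      seed_run <- .child_seed(plan$seed, ci, 2L)
      traces <- vector("list", per_coh)
      for (k in seq_len(per_coh)) {
        traces[[k]] <- run_trial_with_traces(cond, as.numeric(theta), seed_run,
                                             trial = k, config = config,
                                             registry = registry)
      }
      if (correct_only) {
        traces <- Filter(function(tr) tr$choice == tr$correct_channel, traces)
      }
      for (al in c("initiation", "termination")) {
        avg <- align_and_average_traces(traces, al)
        avg$parameter_set <- .resolve_set_label(plan$parameter_set, N)
        avg$N <- N
        avg$coherence <- coh
        avg$alignment <- al
        out[[length(out) + 1L]] <- avg
      }
    }
  }
  do.call(rbind, out)
}

#' Estimate discrimination-information loss from behavioural data
#'
#' The full estimation pipeline: per condition, the rMSPRT is calibrated on
#' the full-information `Omega` statistics to the coherence-dependent error
#' rate, giving the model mean decision sample size and thus the total
#' information estimate `I_hat`; the behavioural mean reaction time gives
#' the subject's implied sample size; their ratio gives the information
#' the subject used and the percentage lost (see [information_account()]).
#'
#' @param behaviour_table Data.frame with columns `N`, `coherence`,
#'   `outcome`, `mean_rt_ms`; only `outcome == "correct"` rows are used.
#' @param seed Root seed for the model runs.
#' @param mc_trials Trials for measuring the model mean sample size
#'   (default 10000).
#' @param calibration_trials Trials per calibration evaluation.
#' @param non_decision_time ms subtracted from reaction times (default 250).
#' @param scaling_n Data scaling factor.
#' @param Delta Feedback delay.
#' @param registry Registry (loaded on demand).
#' @return A data.frame with one row per condition: `N`, `coherence`, `K`,
#'   `model_mean_T`, `I_hat`, `monkey_T_hat`, `K_hat_monkey`,
#'   `loss_percent`.
#' @export
estimate_information_loss <- function(behaviour_table, seed = 1L,
                                      mc_trials = 10000L,
                                      calibration_trials = 2000L,
                                      non_decision_time = 250,
                                      scaling_n = 40, Delta = 3L,
                                      registry = NULL) {
  if (is.null(registry)) registry <- load_parameter_table()
  tab <- behaviour_table[behaviour_table$outcome == "correct", ]
  if (nrow(tab) == 0) stop("behaviour table has no correct-trial rows", call. = FALSE)
  rows <- list()
  for (r in seq_len(nrow(tab))) {
    N <- tab$N[r]
    coh <- tab$coherence[r]
    cond <- decision_condition(N, coh, "Omega", scaling_n = scaling_n)
    target <- error_rate_target(coh, N)
    ci <- .pipeline_condition_index(N, coh)
    if (is.na(ci)) ci <- 100L + r
    theta <- calibrate_threshold(cond, target, mc_trials = calibration_trials,
                                 seed = .child_seed(seed, ci, 11L),
                                 Delta = Delta, registry = registry)
    res <- run_trials(cond, as.numeric(theta), mc_trials,
                      seed = .child_seed(seed, ci, 12L), Delta = Delta,
                      registry = registry)
    mTc <- mean(res$T[res$correct])
    st <- isi_stats(registry$Omega, coh)
    K <- set_discrimination_bits(registry$Omega, coh)
    That <- monkey_decision_samples(tab$mean_rt_ms[r], non_decision_time,
                                    st$preferred$mean_isi)
    acc <- information_account(mTc, K, That)
    rows[[length(rows) + 1L]] <- data.frame(
      N = N, coherence = coh, K = K, model_mean_T = mTc, I_hat = acc$I_hat,
      monkey_T_hat = That, K_hat_monkey = acc$K_hat_monkey,
      loss_percent = acc$loss_percent, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Depleted parameter sets implied by an information-loss account
#'
#' Converts the per-condition `K_hat_monkey` estimates of
#' [estimate_information_loss()] into depleted parameter sets, one per `N`,
#' by shrinking the `Omega` null channels until each pair carries the
#' estimated information (capped at the available information when the
#' estimate exceeds it).
#'
#' @param account Output of [estimate_information_loss()].
#' @param registry Registry (loaded on demand).
#' @return A named list of `isi_parameter_set` objects, one per `N` in the
#'   account (names like `"N2"`, `"N4"`).
#' @export
depleted_sets_from_account <- function(account, registry = NULL) {
  if (is.null(registry)) registry <- load_parameter_table()
  out <- list()
  for (N in sort(unique(account$N))) {
    sub <- account[account$N == N, ]
    targets <- pmin(sub$K_hat_monkey, sub$K)
    names(targets) <- .coherence_key(sub$coherence)
    out[[paste0("N", N)]] <- deplete_parameter_set(
      registry$Omega, targets, label = paste0("depleted_N", N))
  }
  out
}

#' Iteratively recover depleted statistics from behavioural data
#'
#' Full estimation-plus-matching pipeline. The first-pass information
#' account inherits an upward bias from the Wald-style product
#' `I_hat = T * K`: the accumulated information overshoots the threshold
#' by a per-step excess, which matters most when decisions take few steps.
#' The enhanced-match correction removes it empirically: simulate the
#' rMSPRT on the currently recovered depleted statistics, compare its mean
#' correct decision time with the behavioural one, shrink or grow
#' `K_hat` by the decision-time ratio (see [enhanced_loss_correction()]),
#' and re-deplete. Because the recovered sets live in the one-parameter
#' depletion family, iterating converges to the statistics whose simulated
#' reaction times match the behavioural table.
#'
#' @inheritParams estimate_information_loss
#' @param iterations Number of enhanced-match iterations after the first
#'   pass (default 2).
#' @return A list with `account` (as [estimate_information_loss()], with
#'   `K_hat_monkey` and `loss_percent` corrected) and `sets` (named list of
#'   recovered `isi_parameter_set`s per `N`).
#' @export
recover_information_loss <- function(behaviour_table, seed = 1L,
                                     mc_trials = 10000L,
                                     calibration_trials = 2000L,
                                     non_decision_time = 250,
                                     scaling_n = 40, Delta = 3L,
                                     iterations = 2L, registry = NULL) {
  if (is.null(registry)) registry <- load_parameter_table()
  account <- estimate_information_loss(
    behaviour_table, seed = seed, mc_trials = mc_trials,
    calibration_trials = calibration_trials,
    non_decision_time = non_decision_time, scaling_n = scaling_n,
    Delta = Delta, registry = registry)
  tab <- behaviour_table[behaviour_table$outcome == "correct", ]
  for (it in seq_len(iterations)) {
    sets <- depleted_sets_from_account(account, registry)
    for (r in seq_len(nrow(account))) {
      N <- account$N[r]
      coh <- account$coherence[r]
      set <- sets[[paste0("N", N)]]
      cond <- decision_condition(N, coh, set, scaling_n = scaling_n)
      target <- error_rate_target(coh, N)
      # seed tags match generate_fixture's per-condition tags: when the
      # behavioural table is a fixture built from the same root seed, the
      # model and "monkey" runs share evidence streams and the
      # decision-time ratio is a paired comparison
      ci <- .pipeline_condition_index(N, coh)
      if (is.na(ci)) ci <- 100L + r
      theta <- calibrate_threshold(cond, target,
                                   mc_trials = calibration_trials,
                                   seed = .child_seed(seed, ci, 21L),
                                   Delta = Delta, registry = registry)
      res <- run_trials(cond, as.numeric(theta), mc_trials,
                        seed = .child_seed(seed, ci, 22L),
                        Delta = Delta, registry = registry)
      st <- isi_stats(set, coh)
      tau_model <- mean_decision_time_correct(mean(res$T[res$correct]),
                                              st$preferred$mean_isi)
      bt_row <- tab[tab$N == N & tab$coherence == coh, ]
      tau_monkey <- bt_row$mean_rt_ms[1] - non_decision_time
      account$K_hat_monkey[r] <- enhanced_loss_correction(
        account$K_hat_monkey[r], tau_model, tau_monkey)
    }
    account$K_hat_monkey <- pmin(account$K_hat_monkey, account$K)
    account$loss_percent <- (1 - account$K_hat_monkey / account$K) * 100
  }
  list(account = account, sets = depleted_sets_from_account(account, registry))
}
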