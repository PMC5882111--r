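#' Coefficients of the simplified lognormal log-likelihood
#'
#' The per-observation log density ratio between the preferred and null
#' lognormal ISI distributions is a quadratic in `log(u)`:
#' `log f*(u) - log f0(u) = g0 + g1 (log u)^2 + g2 log u`, with
#' `g1 = 1/(2 T0^2) - 1/(2 T*^2)`, `g2 = k*/T*^2 - k0/T0^2`, and
#' `g0 = k0^2/(2 T0^2) - k*^2/(2 T*^2) + log(T0/T*)` where `k` is `kappa`
#' and `T^2` is `theta2`. Only `g1` and `g2` enter inference: the `g0`
#' terms are hypothesis-independent and cancel in the posterior
#' normalization, so they are dropped from the simplified log-likelihood
#' (`g0` is carried for oracle checks).
#'
#' @param pref,null `lognormal_shape` objects for the two channels.
#' @return A list of class `likelihood_coefficients` with `g0`, `g1`, `g2`.
#' @export
likelihood_coefficients <- function(pref, null) {
  stopifnot(inherits(pref, "lognormal_shape"), inherits(null, "lognormal_shape"))
  t2p <- pref$theta2
  t2n <- null$theta2
  structure(list(
    g0 = null$kappa^2 / (2 * t2n) - pref$kappa^2 / (2 * t2p) +
      0.5 * log(t2n / t2p),
    g1 = 1 / (2 * t2n) - 1 / (2 * t2p),
    g2 = pref$kappa / t2p - null$kappa / t2n
  ), class = "likelihood_coefficients")
}

#' Simplified log-likelihood over an observation window
#'
#' For each channel `i`, sums the quadratic evidence terms over the active
#' window: `y_i = g1 * sum(log(x_i)^2) + g2 * sum(log(x_i))`. The window is
#' all observations so far while `t <= Delta`, and the last `Delta`
#' observations afterwards; the caller supplies the windowed observations.
#' The hypothesis-independent `g0 * Delta` term of the full log-likelihood
#' is dropped.
#'
#' @param window_obs Matrix of scaled observations, channels x window steps
#'   (a vector is treated as one step).
#' @param coeffs A [likelihood_coefficients()] object.
#' @return Numeric vector `y`, one entry per channel.
#' @export
simplified_log_likelihood <- function(window_obs, coeffs) {
  if (is.vector(window_obs)) window_obs <- matrix(window_obs, ncol = 1)
  if (any(window_obs <= 0)) stop("observations must be positive", call. = FALSE)
  lx <- log(window_obs)
  coeffs$g1 * rowSums(lx * lx) + coeffs$g2 * rowSums(lx)
}

#' Initialize a posterior state
#'
#' Holds the negative log-posteriors over the `N` hypotheses, the feedback
#' buffer of the last `Delta` posterior vectors, and the step counter.
#' Before any evidence the negative log-posteriors equal the negative log
#' priors.
#'
#' @param n_alternatives Number of hypotheses `N`.
#' @param priors Prior probabilities (default flat); must sum to 1.
#' @param Delta Feedback delay in steps (>= 1).
#' @return An object of class `posterior_state`.
#' @export
posterior_state <- function(n_alternatives, priors = NULL, Delta = 3L) {
  N <- as.integer(n_alternatives)
  if (is.null(priors)) priors <- rep(1 / N, N)
  if (length(priors) != N || any(priors < 0) || abs(sum(priors) - 1) > 1e-10) {
    stop("`priors` must be a length-N probability vector", call. = FALSE)
  }
  Delta <- as.integer(Delta)
  if (Delta < 1L) stop("`Delta` must be >= 1", call. = FALSE)
  structure(list(
    neglog_posteriors = -log(priors),
    posterior_buffer = list(),
    priors = priors,
    Delta = Delta,
    t = 0L
  ), class = "posterior_state")
}

.logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' One recursive Bayes update of the posterior state
#'
#' Applies the delayed-feedback form of Bayes' rule in the negative-log
#' domain. With `z_i = y_i + c`: while `t <= Delta` the fixed log priors are
#' used, `-log P_i(t) = -z_i - log P(H_i) + logsumexp_j(z_j + log P(H_j))`;
#' for `t > Delta` the fed-back posterior from `Delta` steps ago replaces
#' the prior. The baseline `c` is hypothesis-independent, so it cancels in
#' the normalization and never affects the posteriors.
#'
#' @param state A [posterior_state()].
#' @param y Simplified log-likelihood vector for the current window.
#' @param baseline_c Hypothesis-independent scalar baseline added to every
#'   `y_i` (default 0).
#' @return The updated `posterior_state`.
#' @export
recursive_update <- function(state, y, baseline_c = 0) {
  stopifnot(inherits(state, "posterior_state"))
  N <- length(state$priors)
  if (length(y) != N) stop("`y` must have one entry per hypothesis", call. = FALSE)
  t <- state$t + 1L
  z <- y + baseline_c
  if (t <= state$Delta) {
    lp <- log(state$priors)
  } else {
    if (length(state$posterior_buffer) < state$Delta) {
      stop("internal-state error: posterior buffer underrun at t = ", t,
           call. = FALSE)
    }
    lp <- -state$posterior_buffer[[1L]]
  }
  m <- z + lp
  nlp <- .logsumexp(m) - m
  buf <- c(state$posterior_buffer, list(nlp))
  if (length(buf) > state$Delta) buf <- buf[-1L]
  state$neglog_posteriors <- nlp
  state$posterior_buffer <- buf
  state$t <- t
  state
}

#' Apply the decision rule to a posterior state
#'
#' Decides for the hypothesis with the smallest negative log-posterior if
#' that minimum is at or below the threshold `theta`; otherwise sampling
#' continues. Exact ties at the minimum (a measure-zero event under
#' continuous evidence) are broken uniformly with a seeded draw so the
#' outcome is reproducible.
#'
#' @param state A [posterior_state()].
#' @param theta Threshold in `(0, log N]`.
#' @param seed Seed for the tie-break draw.
#' @return A list of class `decision_outcome` with `status`
#'   (`"decided"`/`"continue"`), `choice` (hypothesis index or `NA`) and
#'   `T` (the state's step count, or `NA` if continuing).
#' @export
decide <- function(state, theta, seed = 1L) {
  stopifnot(inherits(state, "posterior_state"))
  N <- length(state$priors)
  if (!is.numeric(theta) || theta <= 0 || theta > log(N) + 1e-12) {
    stop("`theta` must lie in (0, log N]", call. = FALSE)
  }
  nlp <- state$neglog_posteriors
  if (min(nlp) <= theta) {
    structure(list(status = "decided",
                   choice = .argmin_tiebreak(nlp, seed, state$t),
                   T = state$t),
              class = "decision_outcome")
  } else {
    structure(list(status = "continue", choice = NA_integer_, T = NA_integer_),
              class = "decision_outcome")
  }
}

.argmin_tiebreak <- function(v, seed, id) {
  w <- which(v == min(v))
  if (length(w) == 1L) return(w)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(.child_seed(seed, id, 999983L))
  w[sample.int(length(w), 1L)]
}

# Core simulation engine, vectorized across trials. All trials advance in
# lockstep; a trial leaves the active set when its minimum negative
# log-posterior crosses theta. Evidence is drawn per trial from
# counter-based child seeds so batch and single-trial runs see identical
# streams. `recursive = FALSE` gives the non-recursive MSPRT (cumulative
# sums, fixed priors throughout). `record = TRUE` (single trial only)
# stores the per-step negative log-posteriors and y, and keeps updating
# `post_steps` beyond threshold crossing.
.run_batch <- function(condition, theta, n_trials, seed, Delta = 3L,
                       recursive = TRUE, max_steps = 100000L, registry = NULL,
                       trial_ids = NULL, record = FALSE, post_steps = 0L) {
  stopifnot(inherits(condition, "decision_condition"), n_trials >= 1)
  if (record && n_trials != 1L) {
    stop("`record` requires a single trial", call. = FALSE)
  }
  spec <- .condition_spec(condition, registry)
  N <- condition$n_alternatives
  if (!is.numeric(theta) || theta <= 0 || theta > log(N) + 1e-12) {
    stop("`theta` must lie in (0, log N]", call. = FALSE)
  }
  co <- likelihood_coefficients(spec$pref_shape, spec$null_shape)
  g1 <- co$g1
  g2 <- co$g2
  Delta <- as.integer(Delta)
  if (recursive && Delta < 1L) stop("`Delta` must be >= 1", call. = FALSE)
  if (is.null(trial_ids)) trial_ids <- seq_len(n_trials)
  stopifnot(length(trial_ids) == n_trials)
  correct <- .draw_correct_channels(condition, max(trial_ids), seed)[trial_ids]
  lprior <- -log(N)
  cs <- .EVIDENCE_CHUNK

  act <- seq_len(n_trials)
  S1 <- matrix(0, N, n_trials)
  S2 <- matrix(0, N, n_trials)
  if (recursive) {
    R1 <- array(0, c(N, n_trials, Delta))
    R2 <- array(0, c(N, n_trials, Delta))
    PR <- array(0, c(N, n_trials, Delta))
  }
  T_out <- rep(NA_integer_, n_trials)
  choice <- rep(NA_integer_, n_trials)
  E <- NULL
  hist_nlp <- if (record) vector("list", 64L) else NULL
  hist_y <- if (record) vector("list", 64L) else NULL
  decided_at <- NA_integer_
  t <- 0L
  while (length(act) > 0L) {
    t <- t + 1L
    if (t > max_steps) {
      stop(sprintf(
        paste0("non-termination: %d trial(s) undecided after %d steps ",
               "(theta = %.4g, set %s, coherence %s, N = %d)"),
        length(act), max_steps, theta,
        if (is.character(condition$parameter_set)) condition$parameter_set else attr(condition$parameter_set, "label"),
        .coherence_key(condition$coherence), N), call. = FALSE)
    }
    na <- length(act)
    ci <- (t - 1L) %/% cs
    off <- t - ci * cs
    if (off == 1L) {
      E <- array(0, c(N, na, cs))
      for (j in seq_len(na)) {
        E[, j, ] <- .log_evidence_chunk(spec$kappa, spec$theta, N,
                                        correct[act[j]], seed,
                                        trial_ids[act[j]], ci, cs)
      }
    }
    v1 <- E[, , off, drop = FALSE]
    dim(v1) <- c(N, na)
    v2 <- v1 * v1
    if (recursive) {
      slot <- ((t - 1L) %% Delta) + 1L
      if (t <= Delta) {
        S1 <- S1 + v1
        S2 <- S2 + v2
        lp <- matrix(lprior, N, na)
      } else {
        o1 <- R1[, , slot, drop = FALSE]; dim(o1) <- c(N, na)
        o2 <- R2[, , slot, drop = FALSE]; dim(o2) <- c(N, na)
        S1 <- S1 + v1 - o1
        S2 <- S2 + v2 - o2
        lp <- PR[, , slot, drop = FALSE]; dim(lp) <- c(N, na)
        lp <- -lp
      }
      R1[, , slot] <- v1
      R2[, , slot] <- v2
    } else {
      S1 <- S1 + v1
      S2 <- S2 + v2
      lp <- matrix(lprior, N, na)
    }
    y <- g1 * S2 + g2 * S1
    m <- y + lp
    cm <- m[1, ]
    for (r in 2:N) cm <- pmax(cm, m[r, ])
    lse <- log(.colSums(exp(m - rep(cm, each = N)), N, na)) + cm
    nlp <- rep(lse, each = N) - m
    if (recursive) PR[, , slot] <- nlp
    if (record) {
      hist_nlp[[t]] <- nlp[, 1]
      hist_y[[t]] <- y[, 1]
      if (is.na(decided_at) && min(nlp[, 1]) <= theta) {
        decided_at <- t
        T_out[1] <- t
        choice[1] <- .argmin_tiebreak(nlp[, 1], seed, trial_ids[1])
      }
      if (!is.na(decided_at) && t >= decided_at + post_steps) break
      next
    }
    mn <- nlp[1, ]
    for (r in 2:N) mn <- pmin(mn, nlp[r, ])
    done <- mn <= theta
    if (any(done)) {
      for (j in which(done)) {
        id <- act[j]
        T_out[id] <- t
        choice[id] <- .argmin_tiebreak(nlp[, j], seed, trial_ids[id])
      }
      keep <- !done
      act <- act[keep]
      if (length(act) > 0L) {
        S1 <- S1[, keep, drop = FALSE]
        S2 <- S2[, keep, drop = FALSE]
        if (recursive) {
          R1 <- R1[, keep, , drop = FALSE]
          R2 <- R2[, keep, , drop = FALSE]
          PR <- PR[, keep, , drop = FALSE]
        }
        E <- E[, keep, , drop = FALSE]
      }
    }
  }
  res <- data.frame(trial = trial_ids, correct_channel = correct,
                    choice = choice, T = T_out)
  res$correct <- res$choice == res$correct_channel
  if (record) {
    keep_t <- seq_len(t)
    attr(res, "neglog_history") <- do.call(cbind, hist_nlp[keep_t])
    attr(res, "y_history") <- do.call(cbind, hist_y[keep_t])
  }
  res
}

#' Run one rMSPRT trial
#'
#' Iterates evidence sampling, simplified log-likelihoods, the recursive
#' posterior update, and the decision rule until a posterior crosses the
#' threshold. Initial priors are flat.
#'
#' @param condition A [decision_condition()].
#' @param theta Decision threshold in `(0, log N]`; see
#'   [calibrate_threshold()].
#' @param seed Root seed.
#' @param trial Trial index (child seeds make any trial of a batch
#'   reproducible in isolation).
#' @param Delta Feedback delay in steps (default 3).
#' @param registry Parameter registry (loaded on demand when `NULL`).
#' @param max_steps Step cap; exceeding it raises a non-termination error.
#' @param record If `TRUE`, attach the per-step negative log-posterior and
#'   `y` histories as attributes.
#' @param post_decision_steps With `record`, number of updates to continue
#'   past threshold crossing.
#' @return A one-row data.frame with `trial`, `correct_channel`, `choice`,
#'   `T`, `correct`.
#' @export
run_trial <- function(condition, theta, seed, trial = 1L, Delta = 3L,
                      registry = NULL, max_steps = 100000L, record = FALSE,
                      post_decision_steps = 0L) {
  .run_batch(condition, theta, 1L, seed, Delta = Delta, recursive = TRUE,
             max_steps = max_steps, registry = registry,
             trial_ids = as.integer(trial), record = record,
             post_steps = as.integer(post_decision_steps))
}

#' Run one non-recursive MSPRT trial
#'
#' Identical to [run_trial()] but the priors are never updated: the
#' likelihood always accumulates over the full history (the `Delta -> Inf`
#' behaviour). On the same evidence stream the posterior sequence is
#' mathematically identical to the rMSPRT's, so decisions and decision
#' times agree.
#'
#' @inheritParams run_trial
#' @export
run_msprt_trial <- function(condition, theta, seed, trial = 1L,
                            registry = NULL, max_steps = 100000L,
                            record = FALSE, post_decision_steps = 0L) {
  .run_batch(condition, theta, 1L, seed, recursive = FALSE,
             max_steps = max_steps, registry = registry,
             trial_ids = as.integer(trial), record = record,
             post_steps = as.integer(post_decision_steps))
}

#' Run a batch of rMSPRT trials
#'
#' Vectorized Monte Carlo driver: all trials advance in lockstep, each
#' reading its own deterministic evidence stream, so results are identical
#' to running [run_trial()] once per trial id.
#'
#' @inheritParams run_trial
#' @param n_trials Number of trials.
#' @param recursive `FALSE` gives the non-recursive MSPRT.
#' @return A data.frame with one row per trial: `trial`, `correct_channel`,
#'   `choice`, `T`, `correct`.
#' @export
run_trials <- function(condition, theta, n_trials, seed, Delta = 3L,
                       recursive = TRUE, registry = NULL,
                       max_steps = 100000L) {
  .run_batch(condition, theta, as.integer(n_trials), seed, Delta = Delta,
             recursive = recursive, max_steps = max_steps,
             registry = registry)
}

# Error-rate curve over a decreasing grid of thresholds, from a single
# lockstep simulation: every trial runs until it has crossed the smallest
# threshold, recording the choice it would have made at each level on the
# way down. Returns the Monte Carlo error rate per level. Far cheaper than
# re-simulating per candidate threshold, and all levels share the same
# evidence streams (common random numbers by construction).
.error_curve <- function(condition, thetas, n_trials, seed, Delta = 3L,
                         registry = NULL, max_steps = 100000L) {
  stopifnot(all(diff(thetas) < 0))
  spec <- .condition_spec(condition, registry)
  N <- condition$n_alternatives
  co <- likelihood_coefficients(spec$pref_shape, spec$null_shape)
  g1 <- co$g1
  g2 <- co$g2
  Delta <- as.integer(Delta)
  K <- length(thetas)
  trial_ids <- seq_len(n_trials)
  correct <- .draw_correct_channels(condition, n_trials, seed)
  lprior <- -log(N)
  cs <- .EVIDENCE_CHUNK
  act <- seq_len(n_trials)
  next_lvl <- rep(1L, n_trials)
  S1 <- matrix(0, N, n_trials)
  S2 <- matrix(0, N, n_trials)
  R1 <- array(0, c(N, n_trials, Delta))
  R2 <- array(0, c(N, n_trials, Delta))
  PR <- array(0, c(N, n_trials, Delta))
  err <- integer(K)
  E <- NULL
  t <- 0L
  while (length(act) > 0L) {
    t <- t + 1L
    if (t > max_steps) {
      stop("non-termination during threshold calibration", call. = FALSE)
    }
    na <- length(act)
    ci <- (t - 1L) %/% cs
    off <- t - ci * cs
    if (off == 1L) {
      E <- array(0, c(N, na, cs))
      for (j in seq_len(na)) {
        E[, j, ] <- .log_evidence_chunk(spec$kappa, spec$theta, N,
                                        correct[act[j]], seed,
                                        trial_ids[act[j]], ci, cs)
      }
    }
    v1 <- E[, , off, drop = FALSE]
    dim(v1) <- c(N, na)
    v2 <- v1 * v1
    slot <- ((t - 1L) %% Delta) + 1L
    if (t <= Delta) {
      S1 <- S1 + v1
      S2 <- S2 + v2
      lp <- matrix(lprior, N, na)
    } else {
      o1 <- R1[, , slot, drop = FALSE]; dim(o1) <- c(N, na)
      o2 <- R2[, , slot, drop = FALSE]; dim(o2) <- c(N, na)
      S1 <- S1 + v1 - o1
      S2 <- S2 + v2 - o2
      lp <- PR[, , slot, drop = FALSE]; dim(lp) <- c(N, na)
      lp <- -lp
    }
    R1[, , slot] <- v1
    R2[, , slot] <- v2
    y <- g1 * S2 + g2 * S1
    m <- y + lp
    cm <- m[1, ]
    for (r in 2:N) cm <- pmax(cm, m[r, ])
    lse <- log(.colSums(exp(m - rep(cm, each = N)), N, na)) + cm
    nlp <- rep(lse, each = N) - m
    PR[, , slot] <- nlp
    mn <- nlp[1, ]
    for (r in 2:N) mn <- pmin(mn, nlp[r, ])
    nl <- next_lvl[act]
    repeat {
      adv <- nl <= K & mn <= thetas[pmin(nl, K)]
      if (!any(adv)) break
      sub <- which(adv)
      ch <- max.col(-t(nlp[, sub, drop = FALSE]), ties.method = "first")
      wrong <- ch != correct[act[sub]]
      if (any(wrong)) {
        err <- err + tabulate(nl[sub][wrong], nbins = K)
      }
      nl[sub] <- nl[sub] + 1L
    }
    next_lvl[act] <- nl
    done <- nl > K
    if (any(done)) {
      keep <- !done
      act <- act[keep]
      if (length(act) > 0L) {
        S1 <- S1[, keep, drop = FALSE]
        S2 <- S2[, keep, drop = FALSE]
        R1 <- R1[, keep, , drop = FALSE]
        R2 <- R2[, keep, , drop = FALSE]
        PR <- PR[, keep, , drop = FALSE]
        E <- E[, keep, , drop = FALSE]
      }
    }
  }
  err / n_trials
}

#' Calibrate the decision threshold to a target error rate
#'
#' Finds `theta` in `(0, log N]` such that the Monte Carlo error-rate
#' estimate matches `epsilon_target`. The error rate is a monotonically
#' increasing function of `theta`; rather than re-simulating per candidate,
#' a single lockstep simulation evaluates the whole error-rate curve on a
#' fine log-spaced threshold grid (every trial records the choice it would
#' have made at each level as its posterior descends), and the calibrated
#' threshold is read off by monotone interpolation at the target. All grid
#' levels therefore share the same evidence streams, and the calibration
#' residual is set by the binomial sampling error at `mc_trials`.
#'
#' @inheritParams run_trial
#' @param epsilon_target Target error probability in `(0, 1 - 1/N]`; at the
#'   chance boundary `1 - 1/N` the loosest admissible threshold `log N`
#'   (immediate guessing) is returned.
#' @param mc_trials Trials in the calibration simulation (default 2000).
#' @param grid_points Number of threshold levels on the grid (default 140).
#' @return The calibrated `theta`, with attributes `achieved_error` (the
#'   interpolated curve value at `theta`) and `mc_trials`.
#' @export
calibrate_threshold <- function(condition, epsilon_target, mc_trials = 2000L,
                                seed = 1L, Delta = 3L, registry = NULL,
                                grid_points = 140L) {
  N <- condition$n_alternatives
  chance <- 1 - 1 / N
  if (!is.numeric(epsilon_target) || epsilon_target <= 0 ||
      epsilon_target > chance + 1e-12) {
    stop("`epsilon_target` must lie in (0, 1 - 1/N]", call. = FALSE)
  }
  if (is.null(registry)) registry <- load_parameter_table()
  hi <- log(N)
  if (abs(epsilon_target - chance) < 1e-12) {
    # the loosest admissible threshold: decisions fire on the first
    # observation (which still carries information, so the achieved error
    # rate is at most the chance level)
    return(structure(hi, achieved_error = NA_real_, mc_trials = 0L))
  }
  theta_min <- epsilon_target / 6
  for (attempt in 1:3) {
    thetas <- exp(seq(log(hi), log(theta_min), length.out = grid_points))
    eps <- .error_curve(condition, thetas, mc_trials, seed, Delta = Delta,
                        registry = registry)
    if (eps[1] <= epsilon_target) {
      # even immediate guessing errs less often than the target
      return(structure(hi, achieved_error = eps[1], mc_trials = mc_trials))
    }
    # cumulative minimum enforces monotonicity against sampling jitter
    eps_mono <- cummin(eps)
    if (min(eps_mono) <= epsilon_target) {
      k <- which(eps_mono <= epsilon_target)[1]
      if (k == 1L) {
        theta_hat <- thetas[1]
        achieved <- eps_mono[1]
      } else {
        e1 <- eps_mono[k - 1L]
        e2 <- eps_mono[k]
        w <- if (e1 > e2) (e1 - epsilon_target) / (e1 - e2) else 1
        theta_hat <- exp((1 - w) * log(thetas[k - 1L]) + w * log(thetas[k]))
        achieved <- epsilon_target
      }
      return(structure(theta_hat, achieved_error = achieved,
                       mc_trials = mc_trials))
    }
    theta_min <- theta_min / 16
  }
  stop("calibration error: target error rate ", epsilon_target,
       " unattainable within theta in (0, log N]", call. = FALSE)
}
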