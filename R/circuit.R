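#' Loop latencies of the cortico-basal-ganglia-thalamo-cortical circuit
#'
#' Integer signal latencies (in time steps) between the mapped stations:
#' `delta_yb` cortex to basal ganglia, `delta_bu` basal ganglia to thalamus,
#' `delta_uy` thalamus to cortex, and `delta_yu` cortex to thalamus (the
#' diffuse baseline projection). The recursion delay is
#' `Delta = delta_yb + delta_bu + delta_uy`, required to be at least 1.
#'
#' @param delta_yb,delta_bu,delta_uy,delta_yu Nonnegative integers
#'   (defaults all 1, so `Delta = 3`).
#' @return An object of class `loop_latencies` with a `Delta` field.
#' @export
loop_latencies <- function(delta_yb = 1L, delta_bu = 1L, delta_uy = 1L,
                           delta_yu = 1L) {
  v <- c(delta_yb = delta_yb, delta_bu = delta_bu, delta_uy = delta_uy,
         delta_yu = delta_yu)
  if (any(v < 0) || any(v != round(v))) {
    stop("latencies must be nonnegative integers", call. = FALSE)
  }
  Delta <- as.integer(delta_yb + delta_bu + delta_uy)
  if (Delta < 1L) stop("Delta = delta_yb + delta_bu + delta_uy must be >= 1",
                       call. = FALSE)
  structure(list(delta_yb = as.integer(delta_yb), delta_bu = as.integer(delta_bu),
                 delta_uy = as.integer(delta_uy), delta_yu = as.integer(delta_yu),
                 Delta = Delta), class = "loop_latencies")
}

#' Circuit configuration
#'
#' Free parameters of the circuit mapping. None of them affects inference:
#' `l` is the constant sensorimotor-cortex baseline, `w_yu` the weight of
#' the diffuse cortico-thalamic projection (kept below 1 so the positive
#' cortico-thalamo-cortical feedback does not blow up), and
#' `post_decision_steps` the number of updates simulated past threshold
#' crossing for termination-aligned averaging.
#'
#' @param latencies A [loop_latencies()] object.
#' @param l Nonnegative baseline (default 15).
#' @param w_yu Cortico-thalamic weight in `[0, 1)` (default 0.4).
#' @param post_decision_steps Integer (default 3).
#' @return An object of class `circuit_config`.
#' @export
circuit_config <- function(latencies = loop_latencies(), l = 15, w_yu = 0.4,
                           post_decision_steps = 3L) {
  stopifnot(inherits(latencies, "loop_latencies"))
  if (l < 0) stop("`l` must be nonnegative", call. = FALSE)
  if (w_yu < 0 || w_yu >= 1) stop("`w_yu` must lie in [0, 1)", call. = FALSE)
  structure(list(latencies = latencies, l = as.numeric(l),
                 w_yu = as.numeric(w_yu),
                 post_decision_steps = as.integer(post_decision_steps)),
            class = "circuit_config")
}

#' Baseline basal-ganglia output before evidence
#'
#' Before any task-related signal reaches the model basal ganglia, its
#' output codes the negative log priors: `-log P(H_i)` per hypothesis, so
#' the baseline inhibition grows with the number of alternatives (`log N`
#' under flat priors).
#'
#' @param priors Probability vector summing to 1.
#' @return Vector of negative log priors; a zero prior yields `Inf` with a
#'   warning.
#' @export
baseline_bg_output <- function(priors) {
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-10) {
    stop("`priors` must be a probability vector", call. = FALSE)
  }
  if (any(priors == 0)) {
    warning("zero prior gives infinite baseline basal-ganglia output")
  }
  -log(priors)
}

# Compute the circuit-mapped series from recorded per-step posterior and
# likelihood histories. The basal-ganglia output is the recorded negative
# log-posterior path itself (the mapping is a re-arrangement of the same
# arithmetic, not a new algorithm); cortex, thalamus and the baselines
# c(t), h(t) are assembled around it with the configured latencies.
# Requires delta_yb <= delta_yu and delta_uy + delta_yu >= 1 so every term
# is causally available.
.circuit_pass <- function(nlp_hist, y_hist, priors, config) {
  lat <- config$latencies
  Delta <- lat$Delta
  N <- length(priors)
  S <- ncol(nlp_hist)
  if (lat$delta_yb > lat$delta_yu || (lat$delta_uy + lat$delta_yu) < 1L) {
    stop("trace computation requires delta_yb <= delta_yu and delta_uy + delta_yu >= 1",
         call. = FALSE)
  }
  lprior <- log(priors)
  logP <- function(idx) if (idx >= 1L && idx <= S) -nlp_hist[, idx] else lprior
  h <- rep(NA_real_, S)
  h_at <- function(idx) {
    if (idx <= 0L) 0 else if (idx <= S && !is.na(h[idx])) h[idx] else NA_real_
  }
  cvec <- rep(NA_real_, S)
  z <- matrix(NA_real_, N, S)
  cortex <- matrix(NA_real_, N, S)
  thal <- matrix(NA_real_, N, S)
  for (t in seq_len(S)) {
    hv <- h_at(t - Delta)
    cvec[t] <- hv + config$l
    z[, t] <- y_hist[, t] + cvec[t]
    rho <- if (t <= Delta) lprior else logP(t - Delta)
    cortex[, t] <- z[, t] + rho
    # h at index v becomes computable once z(t) with t = v + dbu + dyb - dyu
    # is known
    v <- t - lat$delta_bu - lat$delta_yb + lat$delta_yu
    if (v >= 1L && v <= S) {
      h[v] <- (config$w_yu / N) *
        sum(z[, t] + logP(v - lat$delta_uy - lat$delta_yu))
    }
  }
  for (t in seq_len(S)) {
    thal[, t] <- h_at(t) + logP(t - lat$delta_bu)
  }
  list(c = cvec, h = h, z = z, cortex = cortex, striatum = cortex,
       thalamus = thal, bg_output = nlp_hist)
}

#' Initialize an incremental circuit state
#'
#' State for [step_circuit()]: wraps a [posterior_state()] together with the
#' observation window, the likelihood coefficients, and the delayed-signal
#' buffers of the circuit mapping. All buffers start at their pre-evidence
#' values (no likelihood input, posteriors equal to priors, `h = 0`,
#' `c = l`).
#'
#' @param coeffs [likelihood_coefficients()] of the active condition.
#' @param n_alternatives Number of hypotheses.
#' @param config A [circuit_config()].
#' @param priors Prior probabilities (default flat).
#' @return An object of class `circuit_state`.
#' @export
circuit_state <- function(coeffs, n_alternatives, config = circuit_config(),
                          priors = NULL) {
  N <- as.integer(n_alternatives)
  if (is.null(priors)) priors <- rep(1 / N, N)
  structure(list(
    coeffs = coeffs,
    config = config,
    posterior = posterior_state(N, priors, config$latencies$Delta),
    obs_window = list(),
    nlp_hist = list(),
    y_hist = list(),
    t = 0L
  ), class = "circuit_state")
}

#' Advance the circuit mapping by one observation
#'
#' Feeds one vector of scaled observations through the mapped loop:
#' sensorimotor cortex adds the simplified log-likelihood, the baseline
#' `c(t)` and the fed-back log-prior term; the striatum carries a copy of
#' the cortical signal; the basal-ganglia output is the updated negative
#' log-posterior vector (identical to the inference core's, since the
#' hypothesis-independent baselines cancel in the normalization); the
#' thalamus relays the delayed posterior plus the cortico-thalamic baseline
#' `h(t)`.
#'
#' @param state A [circuit_state()].
#' @param new_observation_vector Positive scaled observations, one per
#'   channel.
#' @return A list with the updated `state` and `row`, the trace row for this
#'   step (fields `step`, `cortex`, `striatum`, `bg_output`, `thalamus`,
#'   `c`, `h`; `thalamus` and `h` entries may be `NA` until their delayed
#'   inputs exist).
#' @export
step_circuit <- function(state, new_observation_vector) {
  stopifnot(inherits(state, "circuit_state"))
  N <- length(state$posterior$priors)
  Delta <- state$config$latencies$Delta
  if (length(new_observation_vector) != N || any(new_observation_vector <= 0)) {
    stop("observation vector must hold one positive value per channel",
         call. = FALSE)
  }
  state$t <- state$t + 1L
  state$obs_window <- c(state$obs_window, list(new_observation_vector))
  if (length(state$obs_window) > Delta) {
    state$obs_window <- state$obs_window[-1L]
  }
  W <- do.call(cbind, state$obs_window)
  y <- simplified_log_likelihood(W, state$coeffs)
  state$posterior <- recursive_update(state$posterior, y)
  state$nlp_hist[[state$t]] <- state$posterior$neglog_posteriors
  state$y_hist[[state$t]] <- y
  pass <- .circuit_pass(do.call(cbind, state$nlp_hist),
                        do.call(cbind, state$y_hist),
                        state$posterior$priors, state$config)
  t <- state$t
  row <- list(step = t - 1L,
              cortex = pass$cortex[, t], striatum = pass$striatum[, t],
              bg_output = pass$bg_output[, t], thalamus = pass$thalamus[, t],
              c = pass$c[t], h = pass$h[t])
  list(state = state, row = row)
}

#' Run one trial and return its circuit-mapped traces
#'
#' Runs the rMSPRT trial exactly as [run_trial()] (same seed, same decision
#' and decision time) while recording the per-step series of every mapped
#' station, continuing `post_decision_steps` updates past threshold
#' crossing. Display steps count observations from 0, so with the default
#' latencies the feedforward phase is steps 0 to `Delta - 1` and the
#' posterior feedback first reaches cortex at step `Delta` (the fork). A
#' pre-evidence row at step -1, determined only by the initial priors and
#' baselines, is prepended.
#'
#' @inheritParams run_trial
#' @param config A [circuit_config()].
#' @return A list of class `circuit_traces`: `steps` (display steps,
#'   starting at -1), matrices `cortex`, `striatum`, `bg_output`,
#'   `thalamus` (hypotheses x steps), vectors `c` and `h`, markers
#'   `initiation` (display step 0) and `termination` (display step of
#'   threshold crossing), `choice`, `correct_channel`, `T`, and the
#'   one-row `outcome` data.frame.
#' @export
run_trial_with_traces <- function(condition, theta, seed, trial = 1L,
                                  config = circuit_config(), registry = NULL,
                                  max_steps = 100000L) {
  Delta <- config$latencies$Delta
  res <- .run_batch(condition, theta, 1L, seed, Delta = Delta,
                    recursive = TRUE, max_steps = max_steps,
                    registry = registry, trial_ids = as.integer(trial),
                    record = TRUE, post_steps = config$post_decision_steps)
  N <- condition$n_alternatives
  priors <- rep(1 / N, N)
  nlp_hist <- attr(res, "neglog_history")
  y_hist <- attr(res, "y_history")
  pass <- .circuit_pass(nlp_hist, y_hist, priors, config)
  # pre-evidence column (display step -1): no likelihood input, posteriors
  # equal priors, h = 0, c = l
  pre_cortex <- config$l + log(priors)
  pre <- list(cortex = pre_cortex, striatum = pre_cortex,
              bg_output = -log(priors), thalamus = 0 + log(priors))
  S <- ncol(nlp_hist)
  structure(list(
    steps = c(-1L, seq_len(S) - 1L),
    cortex = cbind(pre$cortex, pass$cortex),
    striatum = cbind(pre$striatum, pass$striatum),
    bg_output = cbind(pre$bg_output, pass$bg_output),
    thalamus = cbind(pre$thalamus, pass$thalamus),
    c = c(config$l, pass$c),
    h = c(0, pass$h),
    initiation = 0L,
    termination = res$T[1] - 1L,
    choice = res$choice[1],
    correct_channel = res$correct_channel[1],
    T = res$T[1],
    outcome = res
  ), class = "circuit_traces")
}

#' Average circuit traces across trials
#'
#' Aggregates a list of [run_trial_with_traces()] results into mean
#' selected/non-selected series per region. `selected` is the hypothesis the
#' trial chose; `nonselected` is the mean over the remaining hypotheses.
#' Initiation alignment indexes display steps from -1 and truncates at the
#' median termination step plus 3; termination alignment indexes steps
#' relative to each trial's threshold crossing (0 at crossing).
#'
#' @param traces List of `circuit_traces`.
#' @param alignment `"initiation"` or `"termination"`.
#' @return A long data.frame with `step`, `region`, `class`
#'   (`selected` / `nonselected` / `baseline` for the scalar `c` and `h`
#'   series), `value` (mean over trials valid at that step) and `n` (number
#'   of contributing trials).
#' @export
align_and_average_traces <- function(traces,
                                     alignment = c("initiation", "termination")) {
  alignment <- match.arg(alignment)
  if (length(traces) == 0) stop("no traces supplied", call. = FALSE)
  regions <- c("cortex", "striatum", "bg_output", "thalamus")
  rows <- list()
  med_term <- stats::median(vapply(traces, function(tr) tr$termination, numeric(1)))
  for (tr in traces) {
    sel <- tr$choice
    steps <- if (alignment == "initiation") tr$steps else tr$steps - tr$termination
    for (rg in regions) {
      M <- tr[[rg]]
      nonsel <- if (nrow(M) > 2) colMeans(M[-sel, , drop = FALSE]) else M[-sel, ]
      rows[[length(rows) + 1L]] <- data.frame(
        step = steps, region = rg,
        class = "selected", value = M[sel, ], stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        step = steps, region = rg,
        class = "nonselected", value = nonsel, stringsAsFactors = FALSE)
    }
    for (rg in c("c", "h")) {
      rows[[length(rows) + 1L]] <- data.frame(
        step = steps, region = rg,
        class = "baseline", value = tr[[rg]], stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  long <- long[!is.na(long$value), ]
  agg <- stats::aggregate(value ~ step + region + class, data = long, FUN = mean)
  cnt <- stats::aggregate(value ~ step + region + class, data = long, FUN = length)
  agg$n <- cnt$value
  if (alignment == "initiation") {
    agg <- agg[agg$step <= med_term + 3, ]
  }
  agg[order(agg$region, agg$class, agg$step), ]
}
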