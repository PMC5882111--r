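# Deterministic child-seed derivation: one root seed per run, one child per
# (trial, chunk), so any trial is reproducible in isolation and batch runs
# draw the exact same evidence as single-trial runs.
.SEED_MOD <- 2147483647

.child_seed <- function(root, trial, chunk = 0L) {
  h <- as.numeric(root) %% .SEED_MOD
  step <- function(h, k) (((h * 48271) %% .SEED_MOD) + k) %% .SEED_MOD
  h <- step(h, as.numeric(trial))
  h <- step(h, as.numeric(chunk))
  h <- (h * 48271) %% .SEED_MOD
  as.integer(h)
}

# log-evidence (log of scaled ISIs) for one trial and one chunk of steps:
# a C x chunk_size matrix of normal draws with the preferred channel's
# (kappa, sqrt(theta2)) on row `correct_channel` and the null channel's
# elsewhere. The draw layout (standard normals filled column-major, then
# located/scaled per channel) is fixed: it is part of the determinism
# contract shared by all simulation paths.
.log_evidence_chunk <- function(kappa, theta, C, correct_channel, root_seed,
                                trial, chunk_index, chunk_size) {
  kap <- rep(kappa["null"], C)
  th <- rep(theta["null"], C)
  kap[correct_channel] <- kappa["pref"]
  th[correct_channel] <- theta["pref"]
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(.child_seed(root_seed, trial, chunk_index))
  z <- matrix(stats::rnorm(C * chunk_size), nrow = C)
  kap + th * z
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Define a simulated decision condition
#'
#' A condition fixes the number of alternatives `N`, the motion coherence,
#' the parameter set supplying the ISI statistics, the data scaling factor
#' `n`, and (optionally) which channel carries the preferred-direction
#' evidence. The minimum-input configuration is used throughout: as many
#' evidence channels as hypotheses (`C = N`).
#'
#' @param n_alternatives Integer number of hypotheses `N >= 2` (the task
#'   variants modelled use 2 and 4).
#' @param coherence Motion coherence percentage; must be a registry key.
#' @param parameter_set Label: `"Omega"`, `"Omega_d"` (resolved to
#'   `"Omega_d_N2"` or `"Omega_d_N4"` by `N`), `"Omega_d_N2"` or
#'   `"Omega_d_N4"`.
#' @param scaling_n Positive data scaling factor `n` (default 40). It is
#'   hypothesis-independent and never affects inference; it shapes the
#'   dynamic range of circuit-mapped signals.
#' @param correct_channel Integer in `[1, N]` fixing the channel driven by
#'   the preferred-direction statistics, or `NULL` (default) to draw it
#'   uniformly per trial.
#' @return An object of class `decision_condition`.
#' @export
decision_condition <- function(n_alternatives, coherence,
                               parameter_set = "Omega",
                               scaling_n = 40, correct_channel = NULL) {
  N <- as.integer(n_alternatives)
  if (is.na(N) || N < 2L) stop("`n_alternatives` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(scaling_n) || scaling_n <= 0) {
    stop("`scaling_n` must be positive", call. = FALSE)
  }
  label <- .resolve_set_label(parameter_set, N)
  if (!is.null(correct_channel)) {
    correct_channel <- as.integer(correct_channel)
    if (correct_channel < 1L || correct_channel > N) {
      stop("`correct_channel` must lie in [1, N]", call. = FALSE)
    }
  }
  structure(list(n_alternatives = N, coherence = as.numeric(coherence),
                 parameter_set = label, scaling_n = as.numeric(scaling_n),
                 correct_channel = correct_channel),
            class = "decision_condition")
}

.resolve_set_label <- function(label, N) {
  if (inherits(label, "isi_parameter_set")) return(label)
  label <- as.character(label)
  if (label == "Omega_d") label <- if (N == 4L) "Omega_d_N4" else "Omega_d_N2"
  if (!label %in% .registry_labels) {
    stop("unknown parameter set label '", label, "'; expected one of ",
         paste(c(.registry_labels, "Omega_d"), collapse = ", "), call. = FALSE)
  }
  label
}

# resolve the condition's parameter set against a registry and return the
# per-channel lognormal shapes plus the raw (Table-style) statistics
.condition_spec <- function(condition, registry = NULL) {
  stopifnot(inherits(condition, "decision_condition"))
  set <- condition$parameter_set
  if (!inherits(set, "isi_parameter_set")) {
    if (is.null(registry)) registry <- load_parameter_table()
    set <- registry[[set]]
    if (is.null(set)) stop("registry lacks set ", condition$parameter_set, call. = FALSE)
  }
  st <- isi_stats(set, condition$coherence)
  pref <- lognormal_shape(st$preferred, condition$scaling_n)
  null <- lognormal_shape(st$null, condition$scaling_n)
  list(stats = st,
       kappa = c(pref = pref$kappa, null = null$kappa),
       theta = c(pref = sqrt(pref$theta2), null = sqrt(null$theta2)),
       pref_shape = pref, null_shape = null)
}

.draw_correct_channels <- function(condition, n_trials, root_seed) {
  if (!is.null(condition$correct_channel)) {
    return(rep(condition$correct_channel, n_trials))
  }
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(.child_seed(root_seed, 0L, 0L))
  sample.int(condition$n_alternatives, n_trials, replace = TRUE)
}

#' Sample a block of scaled ISI evidence
#'
#' Draws `steps` i.i.d. lognormal scaled inter-spike intervals for each of
#' the `C = N` channels of a condition. The channel carrying the correct
#' hypothesis is driven by the preferred-direction statistics; all others by
#' the null-direction statistics. All values are divided by the condition's
#' scaling factor `n`.
#'
#' @param condition A [decision_condition()].
#' @param steps Number of time steps (>= 1).
#' @param seed Root seed; with `trial`, fully determines the draws.
#' @param trial Trial index used for child-seed derivation (default 1).
#' @param registry Registry from [load_parameter_table()]; loaded on demand
#'   when `NULL`.
#' @return A list of class `evidence_block` with `observations` (a
#'   `C x steps` matrix of positive scaled ISIs) and `correct_channel`.
#' @export
sample_evidence <- function(condition, steps, seed, trial = 1L, registry = NULL) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("`steps` must be >= 1", call. = FALSE)
  spec <- .condition_spec(condition, registry)
  # drawing `trial` values and keeping the last matches the batch runner's
  # per-trial assignment of correct channels
  correct <- .draw_correct_channels(condition, max(1L, as.integer(trial)), seed)[[as.integer(trial)]]
  C <- condition$n_alternatives
  cs <- .EVIDENCE_CHUNK
  n_chunks <- ceiling(steps / cs)
  logx <- matrix(0, C, n_chunks * cs)
  for (k in seq_len(n_chunks)) {
    logx[, ((k - 1L) * cs + 1L):(k * cs)] <-
      .log_evidence_chunk(spec$kappa, spec$theta, C, correct, seed, trial, k - 1L, cs)
  }
  structure(list(observations = exp(logx[, seq_len(steps), drop = FALSE]),
                 correct_channel = correct),
            class = "evidence_block")
}

.EVIDENCE_CHUNK <- 32L

#' Render a continuous-time spike train from an ISI sequence
#'
#' @param isi_sequence Positive inter-spike intervals in ms.
#' @return Event times in ms (cumulative sums); empty input gives an empty
#'   vector.
#' @examples
#' render_spike_train(c(10, 10, 10))
#' @export
render_spike_train <- function(isi_sequence) {
  if (length(isi_sequence) == 0) return(numeric(0))
  if (any(!is.finite(isi_sequence)) || any(isi_sequence <= 0)) {
    stop("ISIs must be positive", call. = FALSE)
  }
  cumsum(as.numeric(isi_sequence))
}

#' Moving mean and variance of firing rate across spike trains
#'
#' Counts spikes in a sliding window (default 20 ms, advanced every 1 ms)
#' for each train, converts counts to rates (spikes/s), and returns the mean
#' and variance across trains per bin. Only bins whose window lies entirely
#' within `[0, duration]` are reported (valid bins).
#'
#' @param spike_trains List of numeric vectors of event times in ms.
#' @param window Window width in ms (default 20).
#' @param step Window step in ms (default 1).
#' @param duration Observation span in ms; defaults to the latest spike time
#'   over all trains.
#' @return A data.frame with `time` (window start, ms), `mean_rate` and
#'   `var_rate` (spikes/s and its variance across trains).
#' @export
moving_rate_statistics <- function(spike_trains, window = 20, step = 1,
                                   duration = NULL) {
  if (!is.list(spike_trains)) spike_trains <- list(spike_trains)
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  if (is.null(duration)) {
    duration <- suppressWarnings(max(0, unlist(lapply(spike_trains, function(s) {
      if (length(s)) max(s) else 0
    }))))
  }
  starts <- seq(0, duration - window, by = step)
  if (length(starts) == 0 || duration < window) {
    return(data.frame(time = numeric(0), mean_rate = numeric(0),
                      var_rate = numeric(0)))
  }
  counts <- vapply(spike_trains, function(s) {
    if (length(s) == 0) return(numeric(length(starts)))
    # count events in [start, start + window)
    findInterval(starts + window - 1e-9, s) - findInterval(starts - 1e-9, s)
  }, numeric(length(starts)))
  counts <- matrix(counts, nrow = length(starts))
  rates <- counts / (window / 1000)
  data.frame(
    time = starts,
    mean_rate = rowMeans(rates),
    var_rate = if (ncol(rates) > 1) apply(rates, 1, stats::var) else rep(NA_real_, length(starts))
  )
}

#' Gaussian smoothing of a time series
#'
#' Convolves the series with a discrete Gaussian kernel (default SD 10
#' samples/ms) truncated at 4 SD. At the edges the kernel is renormalized
#' over the available samples, so a constant series passes through
#' unchanged and the output has the same length as the input.
#'
#' @param series Numeric series.
#' @param sd Kernel standard deviation in samples (default 10).
#' @return Smoothed series of the same length.
#' @export
gaussian_smooth <- function(series, sd = 10) {
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  n <- length(series)
  if (n == 0) return(numeric(0))
  half <- ceiling(4 * sd)
  kern <- stats::dnorm(-half:half, sd = sd)
  kern <- kern / sum(kern)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    w <- kern[(lo - i + half + 1L):(hi - i + half + 1L)]
    out[i] <- sum(series[lo:hi] * w) / sum(w)
  }
  out
}

#' Target error rate as a function of coherence
#'
#' The calibration target used to set decision thresholds: an exponential
#' decay of error rate with motion coherence `s` (in %), fitted to monkey
#' psychometric data. For `N = 2` it is `0.50 * exp(-0.11 s)`; for `N = 4`,
#' `0.75 * exp(-0.08 s)`.
#'
#' @param coherence Coherence percentage (>= 0).
#' @param n_alternatives 2 or 4.
#' @return Error probability.
#' @examples
#' error_rate_target(0, 2)    # 0.50
#' error_rate_target(51.2, 4)
#' @export
error_rate_target <- function(coherence, n_alternatives) {
  if (any(coherence < 0)) stop("`coherence` must be >= 0", call. = FALSE)
  N <- as.integer(n_alternatives)
  if (identical(N, 2L)) return(0.50 * exp(-0.11 * coherence))
  if (identical(N, 4L)) return(0.75 * exp(-0.08 * coherence))
  stop("error-rate targets are defined for N = 2 or 4 only", call. = FALSE)
}

#' Export spike trains as delimited text
#'
#' Two-column CSV (`train_id`, `event_time_ms`), one row per spike.
#'
#' @param spike_trains List of numeric vectors of event times in ms.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_spike_trains <- function(spike_trains, path) {
  if (!is.list(spike_trains)) spike_trains <- list(spike_trains)
  df <- do.call(rbind, lapply(seq_along(spike_trains), function(i) {
    if (length(spike_trains[[i]]) == 0) return(NULL)
    data.frame(train_id = i, event_time_ms = spike_trains[[i]])
  }))
  if (is.null(df)) df <- data.frame(train_id = integer(0),
                                    event_time_ms = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
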