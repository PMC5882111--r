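test_that("loop latencies compose into the recursion delay", {
  lat <- loop_latencies()
  expect_identical(lat$Delta, 3L)
  expect_identical(loop_latencies(1, 0, 0, 1)$Delta, 1L)
  expect_error(loop_latencies(-1, 1, 1, 1), "nonnegative")
  expect_error(loop_latencies(0, 0, 0, 1), "Delta")
  expect_error(circuit_config(w_yu = 1), "w_yu")
})

test_that("baseline basal-ganglia output codes the negative log priors", {
  expect_equal(baseline_bg_output(c(0.5, 0.5)), c(log(2), log(2)))
  expect_equal(baseline_bg_output(rep(0.25, 4)), rep(log(4), 4))
  expect_gt(log(4), log(2))  # baseline grows with the number of alternatives
  expect_warning(out <- baseline_bg_output(c(1, 0)), "infinite")
  expect_equal(out, c(0, Inf))
})

test_that("incremental circuit stepping mirrors the inference core", {
  sh <- shapes_at("Omega", 25.6, n = 40)
  co <- likelihood_coefficients(sh$pref, sh$null)
  cond <- decision_condition(2, 25.6, "Omega", correct_channel = 1)
  obs <- sample_evidence(cond, 8, seed = 41)$observations
  st_c <- circuit_state(co, 2)
  st_p <- posterior_state(2, Delta = 3)
  for (t in 1:8) {
    step <- step_circuit(st_c, obs[, t])
    st_c <- step$state
    win <- if (t <= 3) 1:t else (t - 2):t
    y <- simplified_log_likelihood(obs[, win, drop = FALSE], co)
    st_p <- recursive_update(st_p, y)
    expect_equal(step$row$bg_output, st_p$neglog_posteriors, tolerance = 1e-12)
  }
  # baseline-free configuration reduces cortex to likelihood plus prior
  cfg0 <- circuit_config(l = 0, w_yu = 0)
  st0 <- circuit_state(co, 2, cfg0)
  s1 <- step_circuit(st0, obs[, 1])
  y1 <- simplified_log_likelihood(obs[, 1], co)
  expect_equal(s1$row$cortex, y1 + log(0.5), tolerance = 1e-12)
  expect_equal(s1$row$c, 0)
})

test_that("traced trials agree with plain runs and expose the pre-evidence row", {
  cond <- decision_condition(2, 25.6, "Omega_d")
  tr <- run_trial_with_traces(cond, 0.1, seed = 51, trial = 3)
  plain <- run_trial(cond, 0.1, seed = 51, trial = 3, record = TRUE,
                     post_decision_steps = 3)
  expect_identical(tr$T, plain$T[1])
  expect_identical(tr$choice, plain$choice[1])
  expect_equal(tr$bg_output[, -1], attr(plain, "neglog_history"))
  expect_equal(tr$striatum, tr$cortex)  # striatum relays the cortical signal
  # pre-evidence display step -1: priors and baselines only
  expect_identical(tr$steps[1], -1L)
  expect_equal(tr$cortex[, 1], 15 + log(c(0.5, 0.5)))
  expect_equal(tr$bg_output[, 1], c(log(2), log(2)))
  expect_equal(tr$c[1], 15)
  expect_equal(tr$h[1], 0)
})

test_that("inference is invariant to the circuit free parameters", {
  cond <- decision_condition(2, 25.6, "Omega_d")
  base <- run_trial_with_traces(cond, 0.1, seed = 61, trial = 1)
  variants <- list(
    circuit_config(l = 0, w_yu = 0),
    circuit_config(l = 7.5, w_yu = 0.2),
    circuit_config(l = 22.5, w_yu = 0.6)
  )
  for (cfg in variants) {
    tr <- run_trial_with_traces(cond, 0.1, seed = 61, trial = 1, config = cfg)
    expect_equal(tr$bg_output, base$bg_output, tolerance = 1e-10)
    expect_identical(tr$T, base$T)
    expect_identical(tr$choice, base$choice)
  }
  # data scaling factor n: co-scaled statistics and evidence cancel
  for (n in c(1, 20, 60)) {
    cond_n <- decision_condition(2, 25.6, "Omega_d", scaling_n = n)
    tr <- run_trial_with_traces(cond_n, 0.1, seed = 61, trial = 1)
    expect_equal(tr$bg_output, base$bg_output, tolerance = 1e-9)
    expect_identical(tr$T, base$T)
  }
  # recursion delay: posterior path is Delta-invariant
  lat_sets <- list(loop_latencies(1, 0, 0, 1), loop_latencies(1, 1, 0, 1),
                   loop_latencies(1, 1, 1, 1), loop_latencies(2, 2, 1, 2))
  Ts <- vapply(lat_sets, function(lat) {
    run_trial_with_traces(cond, 0.1, seed = 61, trial = 1,
                          config = circuit_config(latencies = lat))$T
  }, integer(1))
  expect_true(all(Ts == base$T))
})

test_that("trace averaging respects identity and alignment arithmetic", {
  cond <- decision_condition(2, 25.6, "Omega_d")
  tr <- run_trial_with_traces(cond, 0.1, seed = 71, trial = 2)
  avg1 <- align_and_average_traces(list(tr), "initiation")
  sel <- avg1[avg1$region == "cortex" & avg1$class == "selected", ]
  keep <- tr$steps <= tr$termination + 3
  expect_equal(sel$value, unname(tr$cortex[tr$choice, keep]))
  avg2 <- align_and_average_traces(list(tr, tr), "initiation")
  expect_equal(avg2$value, avg1$value)
  expect_true(all(avg2$n == 2 * avg1$n))
  # termination alignment is the initiation alignment shifted by T
  term <- align_and_average_traces(list(tr), "termination")
  ts <- term[term$region == "cortex" & term$class == "selected", ]
  expect_equal(ts$step, tr$steps - tr$termination)
  expect_error(align_and_average_traces(list()), "no traces")
})

test_that("correct-trial cortical traces ramp, then fork after the loop delay", {
  cond <- decision_condition(2, 25.6, "Omega_d")
  target <- error_rate_target(25.6, 2)
  th <- calibrate_threshold(cond, target, mc_trials = 2000, seed = 81)
  traces <- lapply(1:800, function(k) {
    run_trial_with_traces(cond, as.numeric(th), seed = 82, trial = k)
  })
  correct <- Filter(function(tr) tr$choice == tr$correct_channel, traces)
  avg <- align_and_average_traces(correct, "initiation")
  sel <- avg[avg$region == "cortex" & avg$class == "selected", ]
  non <- avg[avg$region == "cortex" & avg$class == "nonselected", ]
  gap <- function(s) sel$value[sel$step == s] - non$value[non$step == s]
  # ramp: the selected trace rises through the feedforward phase
  expect_gt(sel$value[sel$step == 2], sel$value[sel$step == 0])
  # fork: the selected/non-selected gap keeps widening once fed-back
  # posteriors arrive (step Delta = 3)...
  expect_gt(gap(3), gap(2))
  expect_gt(gap(4), gap(3))
  # ... and the non-selected trace rises more slowly than the selected one
  post_sel <- sel$value[sel$step == 5] - sel$value[sel$step == 3]
  post_non <- non$value[non$step == 5] - non$value[non$step == 3]
  expect_gt(post_sel, post_non)
  # the thalamo-cortical baseline h rises early in the trial
  hb <- avg[avg$region == "h" & avg$step %in% -1:2, ]
  hb <- hb[order(hb$step), ]
  expect_gt((hb$value[4] - hb$value[1]) / 3, 0)
  # delay-locked slope change: the rMSPRT gap slope breaks at the fork,
  # whereas the non-recursive MSPRT gap (cumulative evidence, fixed
  # priors; identical decisions, hence identical trial survivorship)
  # grows steadily from the first step with no break at the delay
  gap_series <- function(recursive) {
    per_trial <- sapply(seq_along(traces), function(k) {
      tr <- traces[[k]]
      if (tr$choice != tr$correct_channel) return(rep(NA_real_, 6))
      if (recursive) {
        g <- tr$cortex[tr$choice, -1] - tr$cortex[3 - tr$choice, -1]
      } else {
        r <- run_msprt_trial(cond, as.numeric(th), seed = 82, trial = k,
                             record = TRUE, post_decision_steps = 3)
        y <- attr(r, "y_history")
        g <- y[r$choice[1], ] - y[3 - r$choice[1], ]
      }
      length(g) <- 6
      g
    })
    rowMeans(per_trial, na.rm = TRUE)
  }
  rg <- gap_series(TRUE)   # display steps 0..5
  mg <- gap_series(FALSE)
  expect_true(all(diff(mg) > 0))  # MSPRT separation grows from step 1
  slope_break <- function(g) abs((g[6] - g[4]) / (g[3] - g[1]) - 1)
  expect_lt(slope_break(mg), slope_break(rg))
  # termination-aligned selected cortical peak does not precede the crossing
  term <- align_and_average_traces(correct, "termination")
  ts <- term[term$region == "cortex" & term$class == "selected" &
               term$n >= length(correct) / 2, ]
  expect_gte(ts$step[which.max(ts$value)], 0)
})
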