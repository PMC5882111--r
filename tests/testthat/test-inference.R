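test_that("likelihood coefficients reproduce the per-observation density ratio", {
  sh <- shapes_at("Omega", 51.2, n = 40)
  co <- likelihood_coefficients(sh$pref, sh$null)
  u <- exp(seq(-4, 3, length.out = 50))
  lhs <- co$g0 + co$g1 * log(u)^2 + co$g2 * log(u)
  rhs <- stats::dlnorm(u, sh$pref$kappa, sqrt(sh$pref$theta2), log = TRUE) -
    stats::dlnorm(u, sh$null$kappa, sqrt(sh$null$theta2), log = TRUE)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # indistinguishable hypotheses give zero coefficients
  co0 <- likelihood_coefficients(sh$pref, sh$pref)
  expect_equal(unlist(co0[c("g0", "g1", "g2")]), c(g0 = 0, g1 = 0, g2 = 0))
  # swapping channels negates g1
  sw <- likelihood_coefficients(sh$null, sh$pref)
  expect_equal(sw$g1, -co$g1)
  expect_equal(sw$g2, -co$g2)
})

test_that("simplified log-likelihood matches direct density evaluation", {
  sh <- shapes_at("Omega", 25.6, n = 40)
  co <- likelihood_coefficients(sh$pref, sh$null)
  cond <- decision_condition(2, 25.6, "Omega", correct_channel = 1)
  W <- sample_evidence(cond, 6, seed = 5)$observations
  y <- simplified_log_likelihood(W, co)
  direct <- rowSums(stats::dlnorm(W, sh$pref$kappa, sqrt(sh$pref$theta2),
                                  log = TRUE) -
                      stats::dlnorm(W, sh$null$kappa, sqrt(sh$null$theta2),
                                    log = TRUE))
  expect_equal(y + co$g0 * ncol(W), direct, tolerance = 1e-10)
  expect_equal(simplified_log_likelihood(matrix(1, 2, 4), co), c(0, 0))
  expect_error(simplified_log_likelihood(matrix(-1, 2, 1), co), "positive")
})

test_that("one-step recursive update has the closed form and ignores baselines", {
  st <- posterior_state(2, Delta = 3)
  a <- 1.3
  b <- -0.4
  st1 <- recursive_update(st, c(a, b), baseline_c = 17.2)
  expect_equal(st1$neglog_posteriors[1], -a + log(exp(a) + exp(b)))
  expect_equal(sum(exp(-st1$neglog_posteriors)), 1, tolerance = 1e-12)
  # equal evidence with flat priors leaves posteriors flat
  stf <- recursive_update(posterior_state(2), c(a, a))
  expect_equal(stf$neglog_posteriors, c(log(2), log(2)))
  # arbitrary baseline sequence never changes the posteriors
  set.seed(31)
  ys <- matrix(stats::rnorm(40), 2)
  s_plain <- posterior_state(2, Delta = 2)
  s_base <- posterior_state(2, Delta = 2)
  for (t in 1:20) {
    s_plain <- recursive_update(s_plain, ys[, t])
    s_base <- recursive_update(s_base, ys[, t], baseline_c = stats::rnorm(1, 0, 50))
    expect_equal(s_base$neglog_posteriors, s_plain$neglog_posteriors,
                 tolerance = 1e-10)
    expect_equal(sum(exp(-s_plain$neglog_posteriors)), 1, tolerance = 1e-10)
  }
  # buffer underrun is an internal-state error
  broken <- posterior_state(2, Delta = 3)
  broken$t <- 5L
  expect_error(recursive_update(broken, c(0, 0)), "buffer underrun")
})

test_that("recursive, batch, and non-recursive posteriors coincide", {
  # module-surface check across random conditions and delays
  set.seed(77)
  for (rep in 1:30) {
    N <- sample(c(2L, 4L), 1)
    coh <- sample(coherence_levels(), 1)
    Delta <- sample(1:5, 1)
    lbl <- sample(c("Omega", "Omega_d_N2"), 1)
    cond <- decision_condition(N, coh, lbl, scaling_n = 40)
    sh <- shapes_at(lbl, coh, n = 40)
    co <- likelihood_coefficients(sh$pref, sh$null)
    obs <- sample_evidence(cond, 40, seed = 1000 + rep)$observations
    lx <- log(obs)
    st <- posterior_state(N, Delta = Delta)
    for (t in 1:40) {
      win <- if (t <= Delta) 1:t else (t - Delta + 1):t
      y <- co$g1 * rowSums(lx[, win, drop = FALSE]^2) +
        co$g2 * rowSums(lx[, win, drop = FALSE])
      st <- recursive_update(st, y)
      # single-shot batch posterior from the full history and flat priors
      yb <- co$g1 * rowSums(lx[, 1:t, drop = FALSE]^2) +
        co$g2 * rowSums(lx[, 1:t, drop = FALSE])
      m <- yb + log(1 / N)
      batch <- (max(m) + log(sum(exp(m - max(m))))) - m
      expect_lt(max(abs(st$neglog_posteriors - batch)), 1e-10)
    }
  }
  # engine check: same streams through the recursive and non-recursive paths
  cond <- decision_condition(2, 12.8, "Omega")
  ra <- run_trial(cond, 1e-4, seed = 55, trial = 4, record = TRUE)
  rb <- run_msprt_trial(cond, 1e-4, seed = 55, trial = 4, record = TRUE)
  expect_lt(max(abs(attr(ra, "neglog_history") - attr(rb, "neglog_history"))),
            1e-10)
  expect_identical(ra$T, rb$T)
  expect_identical(ra$choice, rb$choice)
})

test_that("two-hypothesis posteriors reduce to the Wald SPRT statistic", {
  cond <- decision_condition(2, 25.6, "Omega", correct_channel = 1)
  sh <- shapes_at("Omega", 25.6, n = 40)
  co <- likelihood_coefficients(sh$pref, sh$null)
  r <- run_msprt_trial(cond, 1e-5, seed = 6, trial = 2, record = TRUE)
  h <- attr(r, "neglog_history")
  lx <- log(sample_evidence(cond, ncol(h), seed = 6, trial = 2)$observations)
  # cumulative log-likelihood ratio of channel 1 vs channel 2
  llr <- cumsum((co$g1 * lx[1, ]^2 + co$g2 * lx[1, ]) -
                  (co$g1 * lx[2, ]^2 + co$g2 * lx[2, ]))
  expect_equal(h[2, ] - h[1, ], llr, tolerance = 1e-10)
})

test_that("the decision rule respects the threshold and breaks ties reproducibly", {
  st <- posterior_state(2)
  st <- recursive_update(st, c(0.1, 0.1))  # posteriors stay flat at log 2
  # at the admissible boundary theta = log N the rule fires immediately
  out <- decide(st, log(2), seed = 5)
  expect_identical(out$status, "decided")
  expect_identical(out$T, 1L)
  out2 <- decide(st, log(2), seed = 5)
  expect_identical(out$choice, out2$choice)  # seeded tie-break repeats
  # strictly above threshold: continue
  expect_identical(decide(st, 0.3)$status, "continue")
  expect_error(decide(st, 2), "log N")
  expect_error(decide(st, 0), "log N")
})

test_that("decisions at the loosest threshold are immediate", {
  cond <- decision_condition(4, 12.8, "Omega")
  res <- run_trials(cond, log(4), 2000, seed = 12)
  expect_true(all(res$T == 1L))
  # the single observation consumed still carries information
  expect_gt(mean(res$correct), 0.25)
})

test_that("information-free evidence yields uniform seeded guessing", {
  eq <- equal_stats_set()
  cond <- decision_condition(4, 12.8, eq)
  # posteriors stay exactly flat, so at theta = log N every trial decides
  # at t = 1 through the uniform tie-break
  res <- run_trials(cond, log(4), 2000, seed = 13)
  expect_true(all(res$T == 1L))
  acc <- mean(res$correct)
  expect_lt(abs(acc - 0.25), 2.58 * sqrt(0.25 * 0.75 / 2000))
  res2 <- run_trials(cond, log(4), 2000, seed = 13)
  expect_identical(res$choice, res2$choice)  # tie-breaks repeat under seed
})

test_that("single trials reproduce their batch counterparts exactly", {
  cond <- decision_condition(4, 12.8, "Omega_d")
  batch <- run_trials(cond, 0.2, 30, seed = 91)
  for (k in c(1L, 13L, 30L)) {
    solo <- run_trial(cond, 0.2, seed = 91, trial = k)
    expect_identical(solo$T, batch$T[k])
    expect_identical(solo$choice, batch$choice[k])
    expect_identical(solo$correct_channel, batch$correct_channel[k])
  }
})

test_that("a degenerate parameter set triggers the non-termination guard", {
  dg <- near_degenerate_set("Omega", K_bits = 1e-12)
  cond <- decision_condition(2, 25.6, dg)
  expect_error(run_trials(cond, 0.05, 5, seed = 1, max_steps = 200),
               "non-termination")
})

test_that("threshold calibration closes on its target error rate", {
  cond <- decision_condition(2, 25.6, "Omega")
  target <- error_rate_target(25.6, 2)
  th <- calibrate_threshold(cond, target, mc_trials = 4000, seed = 301)
  expect_gt(as.numeric(th), 0)
  expect_lte(as.numeric(th), log(2))
  res <- run_trials(cond, as.numeric(th), 4000, seed = 302)
  eps <- mean(!res$correct)
  expect_lt(abs(eps - target),
            2.58 * sqrt(target * (1 - target) / 4000) + 0.004)
  # chance-level target maps to the loosest admissible threshold
  th_chance <- calibrate_threshold(cond, 0.5, seed = 1)
  expect_equal(as.numeric(th_chance), log(2))
  expect_error(calibrate_threshold(cond, 0.7, seed = 1), "1 - 1/N")
})

test_that("tighter error targets require more evidence (speed-accuracy trade-off)", {
  cond <- decision_condition(2, 12.8, "Omega")
  th_loose <- calibrate_threshold(cond, 0.25, mc_trials = 2000, seed = 311)
  th_tight <- calibrate_threshold(cond, 0.05, mc_trials = 2000, seed = 311)
  expect_lt(as.numeric(th_tight), as.numeric(th_loose))
  r_loose <- run_trials(cond, as.numeric(th_loose), 1500, seed = 312)
  r_tight <- run_trials(cond, as.numeric(th_tight), 1500, seed = 312)
  expect_gt(mean(r_tight$T), mean(r_loose$T))
})

test_that("mean sample sizes respect the Wald bound", {
  cond <- decision_condition(2, 12.8, "Omega")
  target <- error_rate_target(12.8, 2)
  th <- calibrate_threshold(cond, target, mc_trials = 4000, seed = 321)
  res <- run_trials(cond, as.numeric(th), 4000, seed = 322)
  sh <- shapes_at("Omega", 12.8, n = 40)
  eps <- mean(!res$correct)
  bound <- wald_bound_T(eps, sh$pref, sh$null)
  se_T <- stats::sd(res$T) / sqrt(nrow(res))
  expect_gt(mean(res$T), bound - 3 * se_T)
})
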