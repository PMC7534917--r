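test_that("Gaussian smoothing matches the direct kernel computation", {
  x <- rep(0, 31); x[16] <- 1
  y <- smooth_binary(x)
  r <- ceiling(4 * 2.25)
  w <- dnorm((-r):r, 0, 2.25); w <- w / sum(w)
  expect_equal(y[16], max(w)) # impulse response peaks at the kernel peak
  expect_equal(y, oracle_smooth(x))
  expect_equal(sum(y), 1) # mass conserved away from edges
  # random sequences, including ones short relative to the kernel
  set.seed(3)
  for (n in c(5, 12, 80)) {
    x <- rbinom(n, 1, 0.4)
    y <- smooth_binary(x)
    expect_equal(y, oracle_smooth(x))
    expect_true(all(y >= 0 & y <= 1))
  }
  expect_equal(smooth_binary(rep(1, 20)), rep(1, 20))
  expect_equal(smooth_binary(rep(0, 20)), rep(0, 20))
  expect_error(smooth_binary(numeric(0)), "empty")
})

test_that("reward curves average per-trace smoothed outcomes with SEM", {
  perfect <- scripted_log(list(rep(c(2, 3, 2, 1), 10)))
  cv <- reward_curve(perfect)
  expect_equal(cv$values, rep(1, 40))
  expect_equal(cv$sem, rep(0, 40))
  # two identical logs: SEM exactly zero
  cv2 <- reward_curve(list(perfect, perfect))
  expect_equal(cv2$sem, rep(0, 40))
  expect_equal(cv2$n_traces, 2L)
  # short logs are excluded with a warning
  short <- scripted_log(c(2, 3, 2))
  expect_warning(cv3 <- reward_curve(list(perfect, short), window = 40),
                 "excluded")
  expect_equal(cv3$n_traces, 1L)
})

test_that("frozen uniform ensemble reward curve sits at the Markov-chain value", {
  p <- agent_params("memory", alpha = 0, gamma = 0, init_bias = 0, seed = 1)
  oracle <- oracle_stationary_reward(p)
  spec <- fit_spec("max_reward", "memory", n_repeats = 200, window = 800,
                   session_lengths = rep(800L, 1L), base_seed = 10)
  ens <- simulate_ensemble(agent_params("memory", 0, 0, init_bias = 0), spec)
  mid <- 100:800 # past the session-start transient
  dev <- abs(ens$reward$values[mid] - oracle)
  expect_true(all(dev < 4 * pmax(ens$reward$sem[mid], 1e-3)))
})

test_that("error curves match a hand computation on a known log", {
  lg <- scripted_log(c(2, 3, 1, 2, 3, 2, 3, 1, 3, 2, 1, 2, 3, 2, 1, 2, 3,
                       1, 2, 3))
  ec <- error_curves(lg, window = 20)
  # manual pipeline: subsequence -> kernel smoothing -> interpolation
  ann <- as.data.frame(lg)
  for (ty in c("inbound", "outbound")) {
    idx <- which(ann$trial_type == ty)
    manual <- approx(x = idx - 1, y = oracle_smooth(ann$is_error[idx]),
                     xout = 0:19, rule = 2)$y
    got <- if (ty == "inbound") ec$inbound$values else ec$outbound$values
    expect_equal(got, manual)
  }
  # error-free logs give all-zero curves
  ok <- scripted_log(rep(c(2, 3, 2, 1), 5))
  ec0 <- error_curves(ok, window = 20)
  expect_equal(ec0$inbound$values, rep(0, 20))
  expect_equal(ec0$outbound$values, rep(0, 20))
})

test_that("every trial is exactly one of inbound or outbound", {
  lg <- run_agent(agent_params("full", seed = 8), 3, 40)
  expect_equal(sum(lg$trial_type == "inbound") +
                 sum(lg$trial_type == "outbound"), nrow(lg))
  # session starts are classed inbound and bump the inbound error curve
  expect_equal(lg$trial_type[lg$session_start], rep("inbound", 3))
})

test_that("ensemble curves from the compiled path equal the R metrics pipeline", {
  p <- agent_params("full", 0.15, 0.95, seed = 1)
  spec <- fit_spec("max_reward", "full", n_repeats = 8, window = 200,
                   session_lengths = rep(50L, 5L), base_seed = 100)
  ens <- simulate_ensemble(p, spec)
  logs <- lapply(wtrack:::ensemble_seeds(spec), function(s) {
    p$seed <- s
    run_agent(p, 5, 50)
  })
  rc <- reward_curve(lapply(logs, function(l) l[1:200, ]), window = 200)
  expect_equal(ens$reward$values, rc$values, tolerance = 1e-12)
  expect_equal(ens$reward$sem, rc$sem, tolerance = 1e-12)
  ec <- error_curves(lapply(logs, function(l) l[1:200, ]), window = 200)
  expect_equal(ens$inbound$values, ec$inbound$values, tolerance = 1e-12)
  expect_equal(ens$outbound$values, ec$outbound$values, tolerance = 1e-12)
})

test_that("first-visit arm probabilities count the deterministic sequences", {
  alt <- scripted_log(rep(c(2, 1, 2, 3), length.out = 12))
  expect_equal(unname(first_visits_probability(alt, k = 10)$prob),
               c(0.3, 0.5, 0.2))
  pair <- scripted_log(rep(c(1, 2), length.out = 10))
  expect_equal(unname(first_visits_probability(pair, k = 10)$prob),
               c(0.5, 0.5, 0))
  # uniform-random agents visit all arms equally often
  coh <- generate_cohort(cohort_spec(n_subjects = 40, n_sessions = 1,
                                     trials_per_session = 12,
                                     generator = "uniform_random", seed = 2))
  pr <- first_visits_probability(coh, k = 10)
  expect_equal(sum(pr$prob), 1)
  expect_true(all(abs(pr$prob - 1 / 3) < 3 * pmax(pr$sem, 0.01)))
})

test_that("exponential fits recover noiseless time constants within 2%", {
  t <- 0:299
  for (tau in c(10, 40, 150, 500)) {
    y <- 0.5 + 0.3 * exp(-t / tau)
    f <- fit_exponential(y)
    expect_true(f$converged)
    expect_lt(abs(f$tau - tau) / tau, 0.02)
    expect_true(f$tau_ci99[1] <= f$tau && f$tau <= f$tau_ci99[2])
  }
  # rising curves (negative scale) fit equally well
  f <- fit_exponential(0.9 - 0.7 * exp(-t / 55))
  expect_equal(f$tau, 55, tolerance = 1e-3)
  expect_equal(f$scale, -0.7, tolerance = 1e-3)
  # constrained refit: only tau free
  fc <- fit_exponential(0.5 + 0.3 * exp(-t / 40),
                        constrain = c(scale = 0.3, offset = 0.5))
  expect_equal(fc$tau, 40, tolerance = 1e-4)
})

test_that("degenerate exponential fits are flagged, never silent", {
  expect_warning(f <- fit_exponential(rep(0.7, 300)), "degenerate")
  expect_false(f$converged)
  expect_true(is.na(f$tau))
})

test_that("parametric 99% CIs cover the true tau at close to nominal rate", {
  set.seed(99)
  t <- 0:299
  hits <- 0
  for (i in 1:50) {
    y <- 0.6 - 0.4 * exp(-t / 60) + rnorm(300, 0, 0.02)
    f <- fit_exponential(y)
    if (f$converged && f$tau_ci99[1] <= 60 && 60 <= f$tau_ci99[2])
      hits <- hits + 1
  }
  expect_gte(hits, 46) # Bin(50, 0.99) leaves this essentially certain
})

test_that("tau comparison follows the 99% CI non-overlap rule", {
  mk <- function(tau, half) structure(
    list(scale = -0.5, offset = 0.8, tau = tau, tau_se = half / qt(0.995, 297),
         tau_ci99 = c(tau - half, tau + half), converged = TRUE, n = 300,
         ci_method = "covariance"), class = "exp_fit")
  # the separation reported for rats versus the memory-only agent
  expect_equal(compare_tau(mk(38.1, 3.3), mk(52.3, 3.2)), "different")
  expect_equal(compare_tau(mk(40, 3), mk(40, 3)), "not_distinguished")
  # one tau inside the other's interval: not distinguishable
  expect_equal(compare_tau(mk(40, 10), mk(45, 2)), "not_distinguished")
  bad <- mk(40, 3); bad$converged <- FALSE
  expect_warning(res <- compare_tau(bad, mk(45, 2)), "degenerate")
  expect_equal(res, "not_distinguished")
})
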