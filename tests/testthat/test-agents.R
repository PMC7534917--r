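test_that("initialization places the outer-arm bias where the variant carries it", {
  p0 <- init_propensities(agent_params("full", init_bias = 0))
  expect_true(all(p0$b == 0) && all(p0$bi == 0) && p0$bn1 == 0 &&
                all(p0$V == 0))
  pm <- init_propensities(agent_params("memory", init_bias = 1.7))
  expect_equal(unname(pm$b[, c(1, 3)]), matrix(1.7, 13, 2))
  expect_equal(unname(pm$b[, 2]), rep(0, 13))
  expect_equal(pm$bi, c(0, 0, 0)) # memory variant has no arm preference
  pf <- init_propensities(agent_params("full", init_bias = 0.8))
  expect_equal(pf$bi, c(0.8, 0, 0.8))
  expect_equal(pf$bn1, 0)
  expect_error(agent_params("full", init_bias = -1), "non-negative")
})

test_that("softmax policy zeroes the current arm and is correctly normalized", {
  expect_equal(action_distribution(c(0, 0, 0), 2), c(0.5, 0, 0.5))
  expect_equal(action_distribution(c(0, 0, 0), START), rep(1 / 3, 3))
  expect_equal(action_distribution(c(log(2), 0, 0), 2), c(2 / 3, 0, 1 / 3))
  # symmetric outer bias: equal outer probabilities at the center, any c
  for (c0 in c(0.5, 2, 5)) {
    m <- total_propensity(init_propensities(agent_params("memory",
                                                         init_bias = c0)),
                          1, 2)
    p <- action_distribution(m, 2)
    expect_equal(p[1], p[3])
  }
  # full-variant start state: center is least likely, outers tie
  m <- total_propensity(init_propensities(agent_params("full",
                                                       init_bias = 1)),
                        START, START)
  p <- action_distribution(m, START)
  expect_equal(p, exp(c(2, 0, 2)) / sum(exp(c(2, 0, 2)))) # b + bi = 2c
  expect_lt(p[2], p[1])
  # numerically stable at extreme propensities
  p <- action_distribution(c(1e3, -1e3, 900), 2)
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1)
})

test_that("propensity composition adds the neighbor term only where arms adjoin", {
  prop <- init_propensities(agent_params("full", init_bias = 0))
  prop$bn1 <- 0.7
  # at a track end only the center neighbors
  expect_equal(total_propensity(prop, 2, 1), c(0, 0.7, 0))
  expect_equal(total_propensity(prop, 2, 3), c(0, 0.7, 0))
  # from the center the preference applies in both directions
  expect_equal(total_propensity(prop, 1, 2), c(0.7, 0, 0.7))
  # no neighbor contribution at the session start
  expect_equal(total_propensity(prop, START, START), c(0, 0, 0))
  # memory variant: the propensity is exactly the transition row
  pm <- init_propensities(agent_params("memory", init_bias = 1.2))
  pm$b[state_index(1, 2), ] <- c(0.1, 0.2, 0.3)
  expect_equal(total_propensity(pm, 1, 2), c(0.1, 0.2, 0.3))
})

test_that("TD error takes its canonical form", {
  expect_equal(td_error(1, 0, 0, 0.9), 1)
  expect_equal(td_error(1, 0.1, 0.2, 0.5), 1)
  expect_equal(td_error(0, 0.4, 0.4, 0.999), 0.4 * (0.999 - 1))
})

test_that("a single REINFORCE step matches hand-computed component deltas", {
  # uniform start, state (START, arm 1), choose the center, r = 1, gamma = 0
  prop <- init_propensities(agent_params("full", init_bias = 0))
  pol <- action_distribution(total_propensity(prop, START, 1), 1)
  expect_equal(pol, c(0, 0.5, 0.5))
  delta <- td_error(1, 0, 0, 0)
  up <- update_propensities(prop, START, 1, 2, pol, delta, alpha = 0.1)
  s <- state_index(START, 1)
  expect_equal(unname(up$b[s, ]), c(0, 0.05, -0.05))
  expect_equal(unname(up$b[-s, ]), unname(prop$b[-s, ])) # only current row
  expect_equal(up$bi, c(0, 0.05, -0.05))
  expect_equal(up$bn1, 0.05) # only the center neighbors arm 1
  expect_equal(up$V[s], 0.1)
  # zero learning rate changes nothing
  same <- update_propensities(prop, START, 1, 2, pol, delta, alpha = 0)
  expect_equal(same, prop)
  # saturated policy: zero policy gradient, critic still moves
  sat <- prop
  sat$b[s, 2] <- 50
  pol2 <- action_distribution(total_propensity(sat, START, 1), 1)
  up2 <- update_propensities(sat, START, 1, 2, pol2, delta, alpha = 0.1)
  expect_lt(max(abs(up2$b[s, ] - sat$b[s, ])), 1e-10)
  expect_equal(up2$V[s], 0.1)
})

test_that("REINFORCE increments are mean-zero over the policy at frozen delta", {
  set.seed(11)
  prop <- init_propensities(agent_params("full", init_bias = 0.6))
  pol <- action_distribution(total_propensity(prop, 3, 2), 2)
  n <- 20000
  chosen <- sample(1:3, n, replace = TRUE, prob = pol)
  dbi <- matrix(0, n, 3)
  dbn <- numeric(n)
  for (i in seq_len(n)) {
    up <- update_propensities(prop, 3, 2, chosen[i], pol, delta = 1,
                              alpha = 1)
    dbi[i, ] <- up$bi - prop$bi
    dbn[i] <- up$bn1 - prop$bn1
  }
  expect_lt(max(abs(colMeans(dbi))), 4 / sqrt(n))
  expect_lt(abs(mean(dbn)), 4 / sqrt(n))
})

test_that("compiled and reference simulation loops are bit-identical", {
  for (v in c("memory", "full")) {
    p <- agent_params(v, alpha = 0.2, gamma = 0.95, seed = 123)
    a <- run_agent(p, n_sessions = 4, trials_per_session = 25)
    b <- run_agent(p, n_sessions = 4, trials_per_session = 25, engine = "r")
    expect_identical(a$arm, b$arm)
    expect_identical(a$reward, b$reward)
    expect_equal(attr(a, "propensities")$b, attr(b, "propensities")$b,
                 ignore_attr = TRUE)
    expect_equal(attr(a, "propensities")$bn1, attr(b, "propensities")$bn1)
  }
})

test_that("simulation is deterministic given a seed and logs are valid", {
  p <- agent_params("full", seed = 77)
  a <- run_agent(p, 3, 40)
  b <- run_agent(p, 3, 40)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(validate_log(a))
  expect_equal(a$visit_index, 0:119)
})

test_that("full variant with frozen extras reproduces the memory variant exactly", {
  pf <- agent_params("full", alpha = 0.15, gamma = 0.9, init_bias = 0,
                     seed = 31)
  pm <- agent_params("memory", alpha = 0.15, gamma = 0.9, init_bias = 0,
                     seed = 31)
  a <- run_agent(pf, 3, 50, frozen = c("bi", "bn1"))
  b <- run_agent(pm, 3, 50)
  expect_identical(a$arm, b$arm)
  expect_identical(a$reward, b$reward)
})

test_that("frozen uniform policy matches the exact Markov-chain reward rate", {
  p <- agent_params("memory", alpha = 0, gamma = 0, init_bias = 0, seed = 5)
  oracle <- oracle_stationary_reward(p)
  lg <- run_agent(p, n_sessions = 1, trials_per_session = 20000)
  emp <- mean(lg$reward[1001:20000])
  se <- sd(lg$reward[1001:20000]) / sqrt(19000)
  expect_lt(abs(emp - oracle), 4 * se)
  # and empirical arm frequencies are uniform under the frozen policy
  freq <- tabulate(lg$arm, 3) / nrow(lg)
  expect_lt(max(abs(freq - 1 / 3)), 0.02)
})

test_that("agents with sensible parameters improve with training", {
  spec <- fit_spec("max_reward", "full", n_repeats = 50, base_seed = 42)
  for (al in c(0.05, 0.12, 0.3)) {
    ens <- simulate_ensemble(agent_params("full", al, 0.99), spec,
                             what = "none")
    expect_gt(mean(ens$raw_reward[200:300]), mean(ens$raw_reward[1:100]))
  }
})

test_that("init-bias calibration hits the target center share and orders variants", {
  cm <- calibrate_init_bias("memory")
  cf <- calibrate_init_bias("full")
  expect_equal(expected_center_share("memory", cm), 0.1, tolerance = 1e-6)
  expect_equal(expected_center_share("full", cf), 0.1, tolerance = 1e-6)
  # sharing the value with the arm preference halves the raw bias needed
  expect_lt(cf, cm)
  expect_equal(cf / cm, 0.5, tolerance = 0.01)
})
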