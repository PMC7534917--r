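# Independent oracles used across the suite.  Each is written from the task
# definition in a different formulation than the package code paths.

# Reward truth table: tracks the last visit time of each outer arm; the
# correct outbound choice is the outer arm visited least recently (never
# visited counts as least recent).
oracle_reward <- function(visits_so_far, choice) {
  cur <- if (length(visits_so_far) > 0) visits_so_far[length(visits_so_far)]
  else 0L
  if (cur != 2L) return(as.integer(choice == 2L))
  t1 <- max(c(0L, which(visits_so_far == 1L)))
  t3 <- max(c(0L, which(visits_so_far == 3L)))
  if (t1 == 0L && t3 == 0L) return(1L)
  correct <- if (t1 < t3) 1L else 3L
  as.integer(choice == correct)
}

# All within-session arm sequences up to a given length with no immediate
# repeats.
oracle_sequences <- function(max_len) {
  out <- list()
  grow <- function(prefix) {
    if (length(prefix) > 0) out[[length(out) + 1L]] <<- prefix
    if (length(prefix) == max_len) return()
    for (a in 1:3) {
      if (length(prefix) == 0 || prefix[length(prefix)] != a)
        grow(c(prefix, a))
    }
  }
  grow(integer())
  out
}

# Exact long-run reward probability of a frozen-policy agent, by stationary
# analysis of the 6-state (previous, current) chain; within a long session
# the last-visited outer arm is implied by the state (the current arm if it
# is outer, else the arm the agent came from).
oracle_stationary_reward <- function(params) {
  prop <- init_propensities(params)
  sts <- list()
  for (prev in 1:3) for (cur in 1:3) if (prev != cur)
    sts[[length(sts) + 1L]] <- c(prev, cur)
  key <- vapply(sts, function(s) paste(s, collapse = "-"), character(1))
  k <- length(sts)
  P <- matrix(0, k, k)
  r_exp <- numeric(k)
  for (i in seq_len(k)) {
    prev <- sts[[i]][1]; cur <- sts[[i]][2]
    last_outer <- if (cur != 2L) cur else prev
    p <- action_distribution(total_propensity(prop, prev, cur), cur)
    for (a in 1:3) {
      if (p[a] == 0) next
      rwd <- if (cur != 2L) as.integer(a == 2L) else
        as.integer(a == if (last_outer == 1L) 3L else 1L)
      r_exp[i] <- r_exp[i] + p[a] * rwd
      j <- match(paste(c(cur, a), collapse = "-"), key)
      P[i, j] <- P[i, j] + p[a]
    }
  }
  pi <- rep(1 / k, k)
  for (it in 1:5000) pi <- as.numeric(pi %*% P)
  sum(pi * r_exp)
}

# Gaussian smoothing written directly from the kernel definition (dnorm
# weights, edge-inclusive reflection), independent of smooth_binary's
# vectorized indexing.
oracle_smooth <- function(x, sd = 2.25) {
  n <- length(x)
  r <- max(1L, ceiling(4 * sd))
  w <- dnorm((-r):r, 0, sd)
  w <- w / sum(w)
  vapply(seq_len(n), function(i) {
    acc <- 0
    for (k in (-r):r) {
      j <- i - 1L + k
      while (j < 0L || j >= n) {
        if (j < 0L) j <- -j - 1L
        if (j >= n) j <- 2L * n - 1L - j
      }
      acc <- acc + w[k + r + 1L] * x[j + 1L]
    }
    acc
  }, numeric(1))
}
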