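# Parameter estimation: objective variants, seeded simulated annealing with
# restarts, common-random-number ensembles, average and individual fits.

OBJECTIVES <- c("avg_reward_rms", "max_reward", "avg_error_rms",
                "individual_error_rms")

#' Fitting specification
#'
#' Bundles the objective, agent variant, ensemble size, analysis window,
#' annealing configuration and seeds. The same seed vector
#' `base_seed + 0..n_repeats-1` is reused for every candidate parameter
#' vector (common random numbers), so the objective is a deterministic
#' function of the candidate and differences between candidates reflect the
#' parameters, not sampling noise.
#'
#' @param objective one of `"avg_reward_rms"` (RMS distance between the
#'   ensemble-average smoothed reward curve and a target reward curve),
#'   `"max_reward"` (negative ensemble-mean total reward; no target),
#'   `"avg_error_rms"` / `"individual_error_rms"` (sum of the inbound and
#'   outbound error-curve RMS distances, equally weighted).
#' @param variant agent variant to fit.
#' @param n_repeats ensemble size (default 200).
#' @param window analysis window in well visits (default 1012, the span all
#'   rats completed).
#' @param n_restarts independent annealing restarts (at least 4).
#' @param n_evals objective evaluations per restart.
#' @param base_seed first ensemble seed; also seeds the annealer.
#' @param sd smoothing SD in well visits.
#' @param session_lengths trials per session for ensemble runs (default 68
#'   trials x 15 sessions, covering the 1012-visit window).
#' @param bounds named list of `c(lower, upper)` for `alpha`, `gamma` and
#'   (individual mode) `init_bias`.
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(objective = "avg_reward_rms", variant = "full",
                     n_repeats = 200, window = 1012, n_restarts = 4,
                     n_evals = 400, base_seed = 1L, sd = 2.25,
                     session_lengths = rep(68L, 15L),
                     bounds = list(alpha = c(0, 1), gamma = c(0, 0.9999),
                                   init_bias = c(0, 8))) {
  objective <- match.arg(objective, OBJECTIVES)
  variant <- match.arg(variant, VARIANTS)
  stopifnot(n_repeats >= 1, window >= 1, n_restarts >= 1, n_evals >= 10)
  structure(list(objective = objective, variant = variant,
                 n_repeats = as.integer(n_repeats),
                 window = as.integer(min(window, sum(session_lengths))),
                 n_restarts = as.integer(n_restarts),
                 n_evals = as.integer(n_evals),
                 base_seed = as.integer(base_seed), sd = sd,
                 session_lengths = as.integer(session_lengths),
                 bounds = bounds),
            class = "fit_spec")
}

ensemble_seeds <- function(spec) spec$base_seed + seq_len(spec$n_repeats) - 1L

#' Common-random-number ensemble curves for a candidate parameter vector
#'
#' Runs `n_repeats` agents with the spec's fixed seed set and returns the
#' ensemble-averaged smoothed reward curve, inbound/outbound error curves,
#' the unsmoothed mean reward trace and the mean total reward over the
#' window. Deterministic given the spec.
#'
#' @param params an [agent_params()] object (its `seed` is ignored; the
#'   spec's seed set is used).
#' @param spec a [fit_spec()].
#' @param what which curves to compute: `"all"`, `"reward"`, `"errors"` or
#'   `"none"` (totals only); skipped curves are `NULL`.
#' @return list with `behavior_curve` elements `reward`, `inbound`,
#'   `outbound`, plus `raw_reward` (numeric) and `total_reward` (scalar).
#' @export
simulate_ensemble <- function(params, spec,
                              what = c("all", "reward", "errors", "none")) {
  stopifnot(inherits(params, "agent_params"), inherits(spec, "fit_spec"))
  what <- match.arg(what)
  code <- match(what, c("all", "reward", "errors", "none")) - 1L
  fl <- variant_flags(params$variant)
  res <- cpp_ensemble_curves(params$alpha, params$gamma, params$init_bias,
                             fl$has_bi, fl$has_bn, ensemble_seeds(spec),
                             spec$session_lengths, spec$sd, spec$window, 500,
                             code)
  list(reward = if (what %in% c("all", "reward"))
         new_behavior_curve(res$reward_mean, res$reward_sem, "reward",
                            spec$n_repeats),
       inbound = if (what %in% c("all", "errors"))
         new_behavior_curve(res$inbound_mean, res$inbound_sem,
                            "inbound_error", res$n_inbound_traces),
       outbound = if (what %in% c("all", "errors"))
         new_behavior_curve(res$outbound_mean, res$outbound_sem,
                            "outbound_error", res$n_outbound_traces),
       raw_reward = res$raw_reward_mean,
       total_reward = res$total_reward)
}

rms <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(mean((a - b)^2))
}

#' Objective value of a candidate parameter vector
#'
#' @param candidate named numeric vector with `alpha`, `gamma` and, when the
#'   spec fits it, `init_bias` (otherwise `init_bias` must be supplied).
#' @param target for RMS objectives, a list with `behavior_curve` elements
#'   (`reward` for `avg_reward_rms`; `inbound` and `outbound` for the error
#'   objectives) computed from the target logs over the spec's window;
#'   `NULL` for `max_reward`.
#' @param spec a [fit_spec()].
#' @param init_bias initialization value used when the candidate does not
#'   carry one.
#' @return scalar objective (lower is better; `max_reward` returns the
#'   negated mean total reward).
#' @export
objective_value <- function(candidate, target, spec, init_bias = NULL) {
  ib <- if ("init_bias" %in% names(candidate)) candidate[["init_bias"]] else
    init_bias
  if (is.null(ib)) stop("init_bias neither fitted nor supplied", call. = FALSE)
  params <- agent_params(spec$variant, alpha = candidate[["alpha"]],
                         gamma = candidate[["gamma"]], init_bias = ib,
                         seed = spec$base_seed)
  ens <- simulate_ensemble(params, spec,
                           what = switch(spec$objective,
                                         max_reward = "none",
                                         avg_reward_rms = "reward",
                                         "errors"))
  switch(spec$objective,
    max_reward = -ens$total_reward,
    avg_reward_rms = {
      stopifnot(!is.null(target$reward))
      rms(ens$reward$values, target$reward$values[seq_len(spec$window)])
    },
    avg_error_rms = ,
    individual_error_rms = {
      stopifnot(!is.null(target$inbound), !is.null(target$outbound))
      rms(ens$inbound$values, target$inbound$values[seq_len(spec$window)]) +
        rms(ens$outbound$values, target$outbound$values[seq_len(spec$window)])
    })
}

#' Simulated annealing with restarts
#'
#' Minimizes a deterministic objective over a box by Metropolis annealing:
#' Gaussian proposals scaled to the box, temperature and proposal width both
#' decaying geometrically from their initial values to 1/1000 of them over
#' the evaluation budget. At least `n_restarts` independent runs start from
#' distinct seeded positions; the best evaluation ever seen wins. Fully
#' reproducible given `seed`.
#'
#' @param fn objective function of a named parameter vector.
#' @param lower,upper named numeric bounds (same names, same order).
#' @param n_restarts,n_evals restarts and evaluations per restart.
#' @param seed integer seed for the annealer's RNG.
#' @return object of class `fit_result`: `par` (best parameters), `value`,
#'   `restarts` (per-restart best par/value), `converged` (all restarts
#'   produced finite values), `n_evals_total`.
#' @export
anneal <- function(fn, lower, upper, n_restarts = 4, n_evals = 400,
                   seed = 1L) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  nm <- names(lower)
  span <- upper - lower
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  best_par <- NULL; best_val <- Inf
  restarts <- vector("list", n_restarts)
  decay <- 1e-3^(1 / max(1, n_evals - 1))
  for (rs in seq_len(n_restarts)) {
    set.seed(seed + 1000L * rs)
    x <- lower + runif(length(lower)) * span
    names(x) <- nm
    fx <- fn(x)
    if (!is.finite(fx)) fx <- Inf # degenerate candidates are rejected
    rbest_par <- x; rbest_val <- fx
    temp <- max(abs(fx[is.finite(fx)]), 1e-6, 0.01) * 0.1
    width <- 0.25
    for (i in seq_len(n_evals - 1L)) {
      prop <- x + rnorm(length(x), 0, width * span)
      prop <- pmin(pmax(prop, lower), upper)
      names(prop) <- nm
      fp <- fn(prop)
      if (!is.finite(fp)) fp <- Inf
      accept <- fp < fx ||
        (is.finite(fp) && is.finite(fx) &&
           runif(1) < exp(-(fp - fx) / temp))
      if (accept) {
        x <- prop; fx <- fp
      }
      if (fp < rbest_val) {
        rbest_par <- prop; rbest_val <- fp
      }
      temp <- temp * decay
      width <- width * decay^(1 / 3)
    }
    restarts[[rs]] <- list(par = rbest_par, value = rbest_val)
    if (rbest_val < best_val) {
      best_val <- rbest_val; best_par <- rbest_par
    }
  }
  if (!is.finite(best_val))
    stop("all annealing restarts produced non-finite objectives",
         call. = FALSE)
  structure(list(par = best_par, value = best_val, restarts = restarts,
                 converged = all(vapply(restarts,
                                        function(r) is.finite(r$value),
                                        logical(1))),
                 n_evals_total = n_restarts * n_evals),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result: objective =", format(x$value, digits = 6), "\n")
  cat("  par:", paste(sprintf("%s = %.4g", names(x$par), x$par),
                      collapse = ", "), "\n")
  cat("  ", length(x$restarts), "restarts,", x$n_evals_total,
      "evaluations\n")
  invisible(x)
}

# Calibrate init_bias by bisection so the ensemble's mean reward over the
# first `k` visits matches the target's (average-mode fitting rule).
calibrate_init_bias_reward <- function(alpha, gamma, target_rate, spec,
                                       k = 25, tol = 0.005) {
  f <- function(ib) {
    params <- agent_params(spec$variant, alpha = alpha, gamma = gamma,
                           init_bias = ib, seed = spec$base_seed)
    mean(simulate_ensemble(params, spec, what = "none")$raw_reward[seq_len(k)]) -
      target_rate
  }
  lo <- spec$bounds$init_bias[1]; hi <- spec$bounds$init_bias[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) return(if (abs(flo) < abs(fhi)) lo else hi)
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm * flo <= 0) { hi <- mid } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

target_curves_for <- function(logs, spec) {
  switch(spec$objective,
    max_reward = NULL,
    avg_reward_rms = list(reward = reward_curve(logs, spec$window, spec$sd)),
    error_curves(logs, spec$window, spec$sd))
}

#' Fit agent parameters to average behavior
#'
#' Fits `(alpha, gamma)` by simulated annealing against curves averaged
#' across the target logs over the spec's window. For each candidate the
#' initialization value is calibrated so the ensemble's mean reward over the
#' first 25 visits matches the target's (the initial condition is matched,
#' not fitted). For `max_reward` no target logs are needed and the
#' initialization is held at `init_bias` (default: the variant's
#' outer-arm-preference calibration).
#'
#' @param target_logs logs (cohort data.frame, list, or single log); ignored
#'   for the `max_reward` objective.
#' @param spec a [fit_spec()] with objective `"avg_reward_rms"`,
#'   `"avg_error_rms"` or `"max_reward"`.
#' @param init_bias fixed initialization for `max_reward` (default
#'   [calibrate_init_bias()] of the variant).
#' @return a `fit_result`; `par` carries `alpha`, `gamma` and the
#'   initialization actually used as `init_bias`.
#' @export
fit_average <- function(target_logs = NULL, spec, init_bias = NULL) {
  stopifnot(inherits(spec, "fit_spec"))
  if (spec$objective == "individual_error_rms")
    stop("use fit_individual() for the individual objective", call. = FALSE)
  if (spec$objective == "max_reward") {
    ib <- if (is.null(init_bias)) calibrate_init_bias(spec$variant) else
      init_bias
    fn <- function(x) objective_value(x, NULL, spec, init_bias = ib)
    res <- anneal(fn,
                  lower = c(alpha = spec$bounds$alpha[1],
                            gamma = spec$bounds$gamma[1]),
                  upper = c(alpha = spec$bounds$alpha[2],
                            gamma = spec$bounds$gamma[2]),
                  n_restarts = spec$n_restarts, n_evals = spec$n_evals,
                  seed = spec$base_seed)
    res$par <- c(res$par, init_bias = ib)
    return(res)
  }
  target <- target_curves_for(target_logs, spec)
  target_rate <- if (!is.null(target$reward))
    mean(target$reward$values[1:25]) else {
      raw <- vapply(as_log_list(target_logs),
                    function(lg) mean(lg$reward[1:25]), numeric(1))
      mean(raw)
    }
  ib_cache <- new.env(parent = emptyenv())
  fn <- function(x) {
    key <- paste(signif(x, 8), collapse = "_")
    ib <- ib_cache[[key]]
    if (is.null(ib)) {
      ib <- calibrate_init_bias_reward(x[["alpha"]], x[["gamma"]],
                                       target_rate, spec)
      ib_cache[[key]] <- ib
    }
    objective_value(x, target, spec, init_bias = ib)
  }
  res <- anneal(fn,
                lower = c(alpha = spec$bounds$alpha[1],
                          gamma = spec$bounds$gamma[1]),
                upper = c(alpha = spec$bounds$alpha[2],
                          gamma = spec$bounds$gamma[2]),
                n_restarts = spec$n_restarts, n_evals = spec$n_evals,
                seed = spec$base_seed)
  key <- paste(signif(res$par, 8), collapse = "_")
  ib <- ib_cache[[key]]
  if (is.null(ib))
    ib <- calibrate_init_bias_reward(res$par[["alpha"]], res$par[["gamma"]],
                                     target_rate, spec)
  res$par <- c(res$par, init_bias = ib)
  res
}

#' Fit agent parameters to one subject's behavior
#'
#' Fits `(alpha, gamma, init_bias)` — the initial condition is a third free
#' parameter — by minimizing the summed inbound and outbound error-curve RMS
#' distance over all of the subject's visits. Ensemble session lengths are
#' matched to the subject's per-session visit counts.
#'
#' @param subject_log a single subject's visit log.
#' @param spec a [fit_spec()] with objective `"individual_error_rms"`.
#' @return a `fit_result` with `par` = (`alpha`, `gamma`, `init_bias`).
#' @export
fit_individual <- function(subject_log, spec) {
  stopifnot(inherits(spec, "fit_spec"),
            spec$objective == "individual_error_rms")
  logs <- as_log_list(subject_log)
  stopifnot(length(logs) == 1L)
  lg <- logs[[1]]
  sl <- as.integer(table(factor(lg$session, levels = unique(lg$session))))
  spec$session_lengths <- sl
  spec$window <- nrow(lg)
  target <- target_curves_for(lg, spec)
  fn <- function(x) objective_value(x, target, spec)
  anneal(fn,
         lower = c(alpha = spec$bounds$alpha[1], gamma = spec$bounds$gamma[1],
                   init_bias = spec$bounds$init_bias[1]),
         upper = c(alpha = spec$bounds$alpha[2], gamma = spec$bounds$gamma[2],
                   init_bias = spec$bounds$init_bias[2]),
         n_restarts = spec$n_restarts, n_evals = spec$n_evals,
         seed = spec$base_seed)
}
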