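# Behavioral analysis: Gaussian smoothing of binary outcome sequences,
# reward and error curves with SEM, first-visit arm probabilities,
# exponential learning-curve fits with 99% CIs, CI-overlap comparison.

#' Gaussian smoothing of a binary outcome sequence
#'
#' Convolves the sequence with a normalized Gaussian kernel of the given SD
#' in sequence-index units (kernel radius `ceil(4*sd)`), using
#' edge-inclusive reflection padding. Output length equals input length and
#' values stay within the input's range.
#'
#' @param x numeric sequence (typically 0/1 outcomes).
#' @param sd kernel standard deviation in index units; the behavioral
#'   analyses all use 2.25.
#' @return numeric vector the same length as `x`.
#' @export
smooth_binary <- function(x, sd = 2.25) {
  n <- length(x)
  if (n == 0L) stop("cannot smooth an empty sequence", call. = FALSE)
  r <- max(1L, as.integer(ceiling(4 * sd)))
  k <- (-r):r
  w <- exp(-0.5 * k^2 / sd^2)
  w <- w / sum(w)
  j <- outer(seq_len(n) - 1L, k, "+") # 0-based with reflection
  while (any(j < 0L | j >= n)) {
    j[j < 0L] <- -j[j < 0L] - 1L
    j[j >= n] <- 2L * n - 1L - j[j >= n]
  }
  as.vector(matrix(x[j + 1L], n) %*% w)
}

new_behavior_curve <- function(values, sem, kind, n_traces) {
  structure(list(values = as.numeric(values), sem = as.numeric(sem),
                 kind = kind, n_traces = as.integer(n_traces)),
            class = "behavior_curve")
}

#' @export
print.behavior_curve <- function(x, ...) {
  cat("Behavior curve [", x$kind, "]: ", length(x$values),
      " well visits, ", x$n_traces, " traces\n", sep = "")
  cat(sprintf("  start %.3f, end %.3f, mean %.3f\n",
              x$values[1], x$values[length(x$values)], mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.behavior_curve <- function(x, ...) {
  data.frame(visit = seq_along(x$values) - 1L, value = x$values,
             sem = x$sem, kind = x$kind)
}

#' @export
plot.behavior_curve <- function(x, col = "black", add = FALSE,
                                ylab = x$kind, ...) {
  t <- seq_along(x$values) - 1L
  if (!add)
    plot(t, x$values, type = "n", xlab = "well visit", ylab = ylab,
         ylim = c(0, 1), ...)
  graphics::polygon(c(t, rev(t)),
                    c(x$values + x$sem, rev(x$values - x$sem)),
                    border = NA,
                    col = grDevices::adjustcolor(col, alpha.f = 0.3))
  graphics::lines(t, x$values, col = col)
  invisible(x)
}

# Coerce the accepted log containers (single log, list of logs, cohort
# data.frame with subject_id) to a list of per-subject logs.
as_log_list <- function(logs) {
  if (is.data.frame(logs)) {
    if ("subject_id" %in% names(logs))
      return(split(logs, logs$subject_id))
    return(list(logs))
  }
  stopifnot(is.list(logs), all(vapply(logs, is.data.frame, logical(1))))
  logs
}

#' Reward probability curve across subjects or repeats
#'
#' Each subject's (or repeat's) binary reward sequence over its first
#' `window` well visits is smoothed individually ([smooth_binary()]); the
#' smoothed traces are then averaged, with the across-trace SEM.
#'
#' @param logs a visit log, a list of logs, or a cohort data.frame.
#' @param window number of well visits to analyze; defaults to the shortest
#'   log. Logs shorter than the window are excluded with a warning.
#' @param sd smoothing SD in well visits.
#' @return a `behavior_curve` of kind `"reward"`.
#' @export
reward_curve <- function(logs, window = NULL, sd = 2.25) {
  logs <- as_log_list(logs)
  lens <- vapply(logs, nrow, integer(1))
  if (is.null(window)) window <- min(lens)
  keep <- lens >= window
  if (!all(keep)) {
    warning(sum(!keep), " log(s) shorter than the ", window,
            "-visit window excluded", call. = FALSE)
    logs <- logs[keep]
  }
  if (length(logs) == 0L) stop("no log covers the window", call. = FALSE)
  traces <- vapply(logs, function(lg) smooth_binary(lg$reward[1:window], sd),
                   numeric(window))
  traces <- matrix(traces, nrow = window)
  m <- rowMeans(traces)
  s <- if (ncol(traces) > 1) apply(traces, 1, sd) / sqrt(ncol(traces)) else
    rep(0, window)
  new_behavior_curve(m, s, "reward", ncol(traces))
}

# Smooth one subject's error indicator for one trial type in units of that
# type's trial index, then place the values at the trials' global well-visit
# indices and linearly interpolate onto visits 0..window-1 (ends held flat).
error_trace <- function(log, type, window, sd) {
  idx <- which(log$trial_type == type)
  idx <- idx[idx <= window]
  if (length(idx) < 3L) return(NULL)
  sm <- smooth_binary(log$is_error[idx], sd)
  approx(x = idx - 1L, y = sm, xout = seq_len(window) - 1L, rule = 2)$y
}

#' Inbound and outbound error curves on the well-visit axis
#'
#' Per subject, the binary error indicator of each trial type is smoothed
#' with a Gaussian of SD `sd` in units of that type's trial index, placed at
#' the trials' global well-visit indices, and linearly interpolated onto the
#' full well-visit axis (held flat beyond the first/last trial of the
#' type); traces are then averaged with across-subject SEM. Subjects with
#' fewer than 3 trials of a type are excluded from that curve with a
#' warning.
#'
#' @inheritParams reward_curve
#' @return list with `behavior_curve` elements `inbound` and `outbound`.
#' @export
error_curves <- function(logs, window = NULL, sd = 2.25) {
  logs <- as_log_list(logs)
  logs <- lapply(logs, function(lg)
    if ("trial_type" %in% names(lg)) lg else annotate_log(lg))
  lens <- vapply(logs, nrow, integer(1))
  if (is.null(window)) window <- min(lens)
  out <- lapply(c(inbound = "inbound", outbound = "outbound"), function(ty) {
    traces <- lapply(logs, error_trace, type = ty, window = window, sd = sd)
    drop <- vapply(traces, is.null, logical(1))
    if (any(drop))
      warning(sum(drop), " subject(s) with < 3 ", ty,
              " trials excluded from the ", ty, " curve", call. = FALSE)
    traces <- do.call(cbind, traces[!drop])
    if (is.null(traces)) stop("no subject has >= 3 ", ty, " trials",
                              call. = FALSE)
    m <- rowMeans(traces)
    s <- if (ncol(traces) > 1) apply(traces, 1, sd) / sqrt(ncol(traces)) else
      rep(0, window)
    new_behavior_curve(m, s, paste0(ty, "_error"), ncol(traces))
  })
  out
}

#' Probability of visiting each arm within the first k well visits
#'
#' Empirical per-arm frequency among each subject's first `k` visits,
#' averaged across subjects, with across-subject SEM. Captures the initial
#' spatial preferences expressed before the task contingencies are learned.
#'
#' @inheritParams reward_curve
#' @param k number of initial visits (default 10).
#' @return list with `prob` (named length-3 vector summing to 1) and `sem`.
#' @export
first_visits_probability <- function(logs, k = 10) {
  logs <- as_log_list(logs)
  short <- vapply(logs, nrow, integer(1)) < k
  if (any(short)) stop("log(s) with fewer than ", k, " visits", call. = FALSE)
  per <- vapply(logs, function(lg)
    tabulate(lg$arm[1:k], nbins = 3) / k, numeric(3))
  per <- matrix(per, nrow = 3)
  prob <- rowMeans(per)
  s <- if (ncol(per) > 1) apply(per, 1, sd) / sqrt(ncol(per)) else rep(0, 3)
  list(prob = setNames(prob, paste0("arm", 1:3)),
       sem = setNames(s, paste0("arm", 1:3)))
}

#' Exponential fit to a learning curve
#'
#' Least-squares fit of `y(t) = offset + scale * exp(-t / tau)` over the
#' first `window` well visits (t = 0, 1, ...), with a 99% confidence
#' interval on the time constant tau. The parametric CI uses the fit
#' covariance and a t quantile on the residual degrees of freedom; a
#' residual-bootstrap CI is available via `ci_method = "bootstrap"`. With
#' `constrain`, offset and scale are held fixed and only tau is free.
#'
#' @param curve a `behavior_curve` or a plain numeric vector.
#' @param window number of leading visits fitted (default 300, capped at the
#'   curve length).
#' @param constrain optional named numeric `c(scale = , offset = )` holding
#'   those parameters fixed.
#' @param ci_method `"covariance"` (default) or `"bootstrap"`.
#' @param boot_n bootstrap replicates when `ci_method = "bootstrap"`.
#' @return object of class `exp_fit` with elements `scale`, `offset`, `tau`,
#'   `tau_se`, `tau_ci99`, `converged`, `n`. A degenerate fit (no curvature,
#'   non-convergence) is flagged `converged = FALSE` with a warning, never
#'   silently.
#' @export
#' @examples
#' y <- 0.5 + 0.3 * exp(-(0:299) / 40)
#' fit_exponential(y)$tau  # recovers 40
fit_exponential <- function(curve, window = 300, constrain = NULL,
                            ci_method = c("covariance", "bootstrap"),
                            boot_n = 200) {
  ci_method <- match.arg(ci_method)
  y <- if (inherits(curve, "behavior_curve")) curve$values else
    as.numeric(curve)
  window <- min(window, length(y))
  y <- y[seq_len(window)]
  t <- seq_len(window) - 1
  dat <- data.frame(t = t, y = y)

  degenerate <- function(msg) {
    warning("degenerate exponential fit: ", msg, call. = FALSE)
    structure(list(scale = NA_real_, offset = mean(y), tau = NA_real_,
                   tau_se = NA_real_, tau_ci99 = c(NA_real_, NA_real_),
                   converged = FALSE, n = window, ci_method = ci_method),
              class = "exp_fit")
  }
  if (sd(y) < 1e-10) return(degenerate("constant curve, tau unidentifiable"))

  tail_m <- mean(y[max(1, window - 49):window])
  tau_starts <- window / c(6, 20, 2, 60) # several basins; first success wins
  if (is.null(constrain)) {
    fit <- NULL
    for (tau0 in tau_starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ offset + scale * exp(-t / tau), data = dat,
                          start = list(offset = tail_m,
                                       scale = y[1] - tail_m, tau = tau0),
                          lower = c(-Inf, -Inf, 1e-3),
                          upper = c(Inf, Inf, 1e7),
                          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) return(degenerate("no starting point converged"))
    cf <- coef(fit)
    offset <- cf[["offset"]]; scale <- cf[["scale"]]; tau <- cf[["tau"]]
  } else {
    stopifnot(all(c("scale", "offset") %in% names(constrain)))
    offset <- constrain[["offset"]]; scale <- constrain[["scale"]]
    fit <- NULL
    for (tau0 in tau_starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ offset + scale * exp(-t / tau), data = dat,
                          start = list(tau = tau0),
                          lower = 1e-3, upper = 1e7,
                          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) return(degenerate("no starting point converged"))
    tau <- coef(fit)[["tau"]]
  }
  if (abs(scale) < 1e-8) return(degenerate("scale ~ 0, tau unidentifiable"))

  dof <- window - length(coef(fit))
  if (ci_method == "covariance") {
    se <- tryCatch(sqrt(vcov(fit)["tau", "tau"]), error = function(e) NA_real_)
    if (!is.finite(se)) return(degenerate("singular covariance"))
    half <- qt(0.995, dof) * se
    ci <- c(tau - half, tau + half)
  } else {
    res <- y - (offset + scale * exp(-t / tau))
    taus <- rep(NA_real_, boot_n)
    for (bidx in seq_len(boot_n)) {
      yb <- (offset + scale * exp(-t / tau)) +
        sample(res, window, replace = TRUE)
      fb <- tryCatch(
        minpack.lm::nlsLM(yb ~ o + s * exp(-t / tb),
                          data = data.frame(t = t, yb = yb),
                          start = list(o = offset, s = scale, tb = tau),
                          lower = c(-Inf, -Inf, 1e-3), upper = c(Inf, Inf, 1e7)),
        error = function(e) NULL)
      if (!is.null(fb)) taus[bidx] <- coef(fb)[["tb"]]
    }
    taus <- taus[is.finite(taus)]
    if (length(taus) < boot_n / 2)
      return(degenerate("bootstrap refits mostly failed"))
    se <- sd(taus)
    ci <- unname(quantile(taus, c(0.005, 0.995)))
  }
  structure(list(scale = unname(scale), offset = unname(offset),
                 tau = unname(tau), tau_se = unname(se),
                 tau_ci99 = unname(ci), converged = TRUE, n = window,
                 ci_method = ci_method),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Exponential fit: degenerate (not converged)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Exponential fit over %d visits: tau = %.1f trials (99%% CI %.1f-%.1f)\n",
    x$n, x$tau, x$tau_ci99[1], x$tau_ci99[2]))
  cat(sprintf("  offset = %.3f, scale = %.3f\n", x$offset, x$scale))
  invisible(x)
}

#' Compare two learning time constants by 99% CI overlap
#'
#' Declares the fits `"different"` (p < 0.01) if and only if each fit's tau
#' lies outside the other's 99% confidence interval; otherwise
#' `"not_distinguished"`. Degenerate fits compare as not distinguished, with
#' a warning.
#'
#' @param fit_a,fit_b `exp_fit` objects.
#' @return `"different"` or `"not_distinguished"`.
#' @export
#' @examples
#' a <- list(tau = 38.1, tau_ci99 = c(34.8, 41.4), converged = TRUE)
#' b <- list(tau = 52.3, tau_ci99 = c(49.1, 55.5), converged = TRUE)
#' class(a) <- class(b) <- "exp_fit"
#' compare_tau(a, b)  # "different"
compare_tau <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "exp_fit"), inherits(fit_b, "exp_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    warning("degenerate fit; taus cannot be distinguished", call. = FALSE)
    return("not_distinguished")
  }
  outside <- function(tau, ci) tau < ci[1] || tau > ci[2]
  if (outside(fit_a$tau, fit_b$tau_ci99) && outside(fit_b$tau, fit_a$tau_ci99))
    "different" else "not_distinguished"
}
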