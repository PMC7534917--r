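# Synthetic cohort generator: rat-like behavioral logs with the statistical
# structure the analyses assume (initial outer-arm preference, fast inbound
# learning, slow incomplete outbound learning, session-start inbound-error
# bumps), plus scripted reference logs for hand-verifiable fixtures.

GENERATORS <- c("full_agent", "memory_agent", "perfect_alternator",
                "uniform_random", "scripted")

#' Cohort specification
#'
#' Defaults emulate the study conditions the analyses assume: 10 subjects,
#' 15 sessions, session lengths drawn uniformly from 64-72 visits (topped up
#' so every subject reaches at least 1012 total visits, the analysis
#' window), and a full-variant agent at the learning parameters that
#' reproduce rat-like behavior (`alpha = 0.120`, `gamma = 0.997`) with the
#' outer-arm-preference initialization of [calibrate_init_bias()].
#'
#' @param n_subjects number of subjects.
#' @param n_sessions sessions per subject.
#' @param trials_per_session `NULL` (draw 64-72 per session), a single
#'   count, or a length-`n_sessions` vector.
#' @param generator one of `"full_agent"`, `"memory_agent"`,
#'   `"perfect_alternator"`, `"uniform_random"`, `"scripted"`.
#' @param generator_params [agent_params()] for the agent generators
#'   (default: full/memory variant at alpha 0.120, gamma 0.997).
#' @param arm_sequences for `"scripted"`: list (one per subject) of lists of
#'   per-session arm vectors.
#' @param seed cohort seed; per-subject simulation seeds are derived from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10, n_sessions = 15,
                        trials_per_session = NULL, generator = "full_agent",
                        generator_params = NULL, arm_sequences = NULL,
                        seed = 1L) {
  generator <- match.arg(generator, GENERATORS)
  stopifnot(n_subjects >= 1, n_sessions >= 1)
  if (is.null(generator_params) &&
      generator %in% c("full_agent", "memory_agent")) {
    variant <- if (generator == "full_agent") "full" else "memory"
    generator_params <- agent_params(variant, alpha = 0.120, gamma = 0.997)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 trials_per_session = trials_per_session,
                 generator = generator,
                 generator_params = generator_params,
                 arm_sequences = arm_sequences,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

draw_session_lengths <- function(spec, subject) {
  if (!is.null(spec$trials_per_session)) {
    sl <- if (length(spec$trials_per_session) == 1L)
      rep(spec$trials_per_session, spec$n_sessions) else
        spec$trials_per_session
    return(as.integer(sl))
  }
  set.seed(subject_seed(spec$seed, subject) %% 100000L)
  sl <- sample(64:72, spec$n_sessions, replace = TRUE)
  # guarantee the 1012-visit analysis window when 15 sessions are emulated
  if (spec$n_sessions >= 15L && sum(sl) < 1012L)
    sl[spec$n_sessions] <- sl[spec$n_sessions] + (1012L - sum(sl))
  as.integer(sl)
}

#' Generate a synthetic cohort of visit logs
#'
#' @param spec a [cohort_spec()].
#' @return a `wtrack_cohort` data.frame: per-subject logs stacked, with a
#'   `subject_id` column prepended; every log satisfies [validate_log()].
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 2, seed = 7))
#' table(coh$subject_id)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  logs <- lapply(seq_len(spec$n_subjects), function(i) {
    sl <- draw_session_lengths(spec, i)
    sid <- subject_seed(spec$seed, i)
    log <- switch(spec$generator,
      full_agent = ,
      memory_agent = {
        p <- spec$generator_params
        p$seed <- sid
        run_agent(p, n_sessions = length(sl), trials_per_session = sl)
      },
      uniform_random = {
        p <- agent_params("memory", alpha = 0, gamma = 0, init_bias = 0,
                          seed = sid)
        run_agent(p, n_sessions = length(sl), trials_per_session = sl)
      },
      perfect_alternator = {
        arms <- lapply(sl, perfect_session)
        scripted_log(arms)
      },
      scripted = {
        stopifnot(!is.null(spec$arm_sequences))
        scripted_log(spec$arm_sequences[[i]])
      })
    cbind(subject_id = sprintf("S%02d", i), as.data.frame(log))
  })
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  class(out) <- c("wtrack_cohort", "data.frame")
  out
}

# one session of flawless alternation: 2, 3, 2, 1, 2, 3, ...
perfect_session <- function(len) {
  outer <- rep(c(3L, 1L), length.out = len)
  arms <- integer(len)
  arms[seq(1, len, by = 2)] <- 2L
  arms[seq(2, len, by = 2)] <- outer[seq_len(floor(len / 2))]
  arms
}

#' Build a visit log from scripted arm sequences
#'
#' Rewards, trial types and error flags are filled in by the task rules;
#' used for hand-verifiable fixtures and reference policies.
#'
#' @param arm_sequences list of integer vectors, one per session, or a
#'   single vector (one session).
#' @return a `wtrack_log` data.frame.
#' @export
#' @examples
#' scripted_log(c(2, 3, 2, 1, 2))$reward  # all 1: a correct cycle
scripted_log <- function(arm_sequences) {
  if (!is.list(arm_sequences)) arm_sequences <- list(arm_sequences)
  rows <- list()
  v <- 0L
  for (si in seq_along(arm_sequences)) {
    arms <- as.integer(arm_sequences[[si]])
    if (any(!(arms %in% ARMS)))
      stop("session ", si, ": arm outside {1,2,3}", call. = FALSE)
    if (any(diff(arms) == 0L))
      stop("session ", si, ": immediate arm repeat at position ",
           which(diff(arms) == 0L)[1] + 1L, call. = FALSE)
    visits <- integer()
    cur <- 0L
    for (a in arms) {
      r <- reward_rule(cur, a, visits)
      rows[[length(rows) + 1L]] <- data.frame(
        session = si, visit_index = v, arm = a, reward = r)
      visits <- c(visits, a)
      cur <- a
      v <- v + 1L
    }
  }
  log <- annotate_log(do.call(rbind, rows))
  class(log) <- c("wtrack_log", "data.frame")
  log
}
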