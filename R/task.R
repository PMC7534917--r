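# Task environment: 13-state space, reward-delivery algorithm, trial taxonomy.

ARMS <- 1:3
OUTER_ARMS <- c(1L, 3L)
CENTER_ARM <- 2L

#' Is an arm an outer arm?
#' @param arm integer arm code (1, 2 or 3).
#' @return logical
#' @export
is_outer <- function(arm) arm %in% OUTER_ARMS

check_arm_or_start <- function(x, what = "arm") {
  if (length(x) != 1L || is.na(x) || !(x %in% c(0L, ARMS)))
    stop(what, " must be an arm (1, 2, 3) or START (0), got: ", deparse(x),
         call. = FALSE)
  as.integer(x)
}

#' Index of a (previous, current) task state
#'
#' The agent's state is the pair of its previous and current arm locations.
#' The propensity table has 13 rows: 9 arm/arm pairs (rows 1-9, row
#' `(previous-1)*3 + current`), 3 session-start pairs (rows 10-12,
#' `previous = START`, current an arm) and the session-start state itself
#' (row 13, both `START`). Three of the arm/arm rows have
#' `previous == current`; such states are never visited because revisiting
#' the current arm is forbidden, and with `strict = TRUE` (the default)
#' requesting them is an error. `strict = FALSE` indexes any of the 13 rows.
#'
#' @param previous,current arm codes (1-3) or [START] (0).
#' @param strict reject `previous == current` arm pairs (unreachable states)?
#' @return integer state index in 1..13.
#' @export
#' @examples
#' state_index(START, START)  # 13, the session-start state
#' state_index(1, 2)          # arrived at center from arm 1
state_index <- function(previous, current, strict = TRUE) {
  previous <- check_arm_or_start(previous, "previous")
  current <- check_arm_or_start(current, "current")
  if (previous == 0L && current == 0L) return(13L)
  if (current == 0L)
    stop("current = START requires previous = START", call. = FALSE)
  if (previous == 0L) return(9L + current)
  if (strict && previous == current)
    stop("inadmissible state: previous == current (arm ", previous,
         "); revisits are forbidden", call. = FALSE)
  (previous - 1L) * 3L + current
}

#' Enumerate all 13 rows of the state space
#'
#' @return data.frame with columns `index`, `previous`, `current`,
#'   `reachable` (FALSE for the three same-arm rows).
#' @export
enumerate_states <- function() {
  prev <- c(rep(ARMS, each = 3L), rep(0L, 3L), 0L)
  cur <- c(rep(ARMS, 3L), ARMS, 0L)
  data.frame(
    index = vapply(seq_along(prev), function(i)
      state_index(prev[i], cur[i], strict = FALSE), integer(1)),
    previous = prev, current = cur,
    reachable = !(prev == cur & prev != 0L)
  )
}

#' Reward-delivery algorithm of the spatial alternation task
#'
#' From any arm other than the center (including the session-start
#' position), reward is delivered for going to the center arm. From the
#' center arm, reward is delivered for going to the less recently visited
#' outer arm this session, whether or not that arm was previously rewarded;
#' if the center arm was the session's first visit, either outer arm is
#' rewarded.
#'
#' @param current arm the subject is at (1-3) or [START] (0).
#' @param choice arm chosen next (1-3); must differ from `current`.
#' @param visits integer vector of arms already visited this session, in
#'   order (the last entry must equal `current` unless `current` is START).
#' @param start_center_rewarded is a session-start visit to the center arm
#'   itself rewarded? Default `TRUE` (it satisfies the go-to-center rule
#'   from the start position; the first-visit exception is read as governing
#'   the next, outbound trial). The simulation engine uses the default; the
#'   flag exists so the alternative reading of the session-start rule can be
#'   examined.
#' @return 0 or 1.
#' @export
#' @examples
#' reward_rule(3, 2, visits = c(2, 3))       # return to center: rewarded
#' reward_rule(2, 3, visits = c(1, 2))       # correct alternation: rewarded
#' reward_rule(2, 1, visits = c(1, 2))       # returning to arm 1: not rewarded
reward_rule <- function(current, choice, visits = integer(),
                        start_center_rewarded = TRUE) {
  current <- check_arm_or_start(current, "current")
  choice <- check_arm_or_start(choice, "choice")
  if (choice == 0L) stop("choice must be an arm, not START", call. = FALSE)
  if (choice == current)
    stop("choice equals the current arm; revisits are forbidden", call. = FALSE)
  visits <- as.integer(visits)
  if (current == 0L) {
    if (length(visits) > 0L)
      stop("current = START implies no visits yet this session", call. = FALSE)
  } else if (length(visits) == 0L || visits[length(visits)] != current) {
    stop("session history must end at the current arm", call. = FALSE)
  }
  if (current != CENTER_ARM) {
    if (current == 0L && choice == CENTER_ARM && !start_center_rewarded)
      return(0L)
    return(as.integer(choice == CENTER_ARM))
  }
  outer_seen <- visits[visits != CENTER_ARM]
  if (length(outer_seen) == 0L) return(1L) # center was the session's first visit
  last_outer <- outer_seen[length(outer_seen)]
  as.integer(choice == if (last_outer == 1L) 3L else 1L)
}

#' Classify a trial as inbound or outbound and flag errors
#'
#' A trial beginning at an outer arm (or at the session start) is inbound:
#' the correct response is the center arm. A trial beginning at the center
#' arm is outbound: the correct response is the less recently visited outer
#' arm. Session-start trials are classed inbound (a session's first visit
#' that is not the center arm is an inbound error) and additionally flagged.
#'
#' @param current arm the trial begins at (1-3) or [START] (0).
#' @param choice arm visited (1-3).
#' @param reward 0/1 outcome delivered by [reward_rule()].
#' @return list with `trial_type` ("inbound" or "outbound"), `is_error`
#'   (integer 0/1) and `session_start` (logical).
#' @export
classify_trial <- function(current, choice, reward) {
  current <- check_arm_or_start(current, "current")
  choice <- check_arm_or_start(choice, "choice")
  if (choice == current)
    stop("choice equals the current arm; revisits are forbidden", call. = FALSE)
  type <- if (current == CENTER_ARM) "outbound" else "inbound"
  list(trial_type = type, is_error = as.integer(reward == 0L),
       session_start = current == 0L)
}

# Add trial_type / is_error / session_start columns to a log that has
# session, arm, reward.  The arm a trial departs from is the previous
# visit's arm within the session (START for a session's first visit).
annotate_log <- function(log) {
  stopifnot(all(c("session", "arm", "reward") %in% names(log)))
  n <- nrow(log)
  from <- c(0L, log$arm[-n])
  first_of_session <- c(TRUE, log$session[-1] != log$session[-n])
  from[first_of_session] <- 0L
  log$trial_type <- ifelse(from == CENTER_ARM, "outbound", "inbound")
  log$is_error <- as.integer(log$reward == 0L)
  log$session_start <- first_of_session
  log
}

#' Validate a visit log against the task rules
#'
#' Checks arm and reward codings, per-session absence of immediate arm
#' repeats, and (when `recompute = TRUE`) that the recorded rewards match
#' the reward-delivery algorithm replayed over the log.
#'
#' @param log data.frame with columns `session`, `visit_index`, `arm`,
#'   `reward`.
#' @param recompute also replay the reward rule and compare? Logs from live
#'   animals trivially satisfy this; it guards synthetic or edited logs.
#' @return invisibly `TRUE`; stops with a diagnostic on the first violation.
#' @export
validate_log <- function(log, recompute = TRUE) {
  stopifnot(is.data.frame(log))
  need <- c("session", "visit_index", "arm", "reward")
  miss <- setdiff(need, names(log))
  if (length(miss) > 0L)
    stop("log lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(log$arm %in% ARMS))
    stop("row ", which(!(log$arm %in% ARMS))[1], ": arm outside {1,2,3}",
         call. = FALSE)
  if (!all(log$reward %in% 0:1))
    stop("row ", which(!(log$reward %in% 0:1))[1], ": reward outside {0,1}",
         call. = FALSE)
  if (is.unsorted(log$session))
    stop("session numbers must be non-decreasing", call. = FALSE)
  if (any(diff(log$visit_index) <= 0))
    stop("row ", which(diff(log$visit_index) <= 0)[1] + 1L,
         ": visit_index not strictly increasing", call. = FALSE)
  n <- nrow(log)
  same_sess <- log$session[-1] == log$session[-n]
  rep_rows <- which(same_sess & log$arm[-1] == log$arm[-n])
  if (length(rep_rows) > 0L)
    stop("row ", rep_rows[1] + 1L,
         ": immediate arm repeat within a session", call. = FALSE)
  if (recompute) {
    for (s in unique(log$session)) {
      rows <- which(log$session == s)
      visits <- integer()
      cur <- 0L
      for (i in rows) {
        r <- reward_rule(cur, log$arm[i], visits)
        if (r != log$reward[i])
          stop("row ", i, ": recorded reward ", log$reward[i],
               " disagrees with the task rules (expected ", r, ")",
               call. = FALSE)
        visits <- c(visits, log$arm[i])
        cur <- log$arm[i]
      }
    }
  }
  invisible(TRUE)
}
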