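# Readers/writers: visit-log CSV schema, curve export, fit-result JSON,
# YAML fitting configuration.

LOG_COLUMNS <- c("subject_id", "session", "visit_index", "arm", "reward")

#' Read a visit-log CSV
#'
#' The shared schema has header columns `subject_id`, `session`,
#' `visit_index`, `arm`, `reward` (optional `trial_type`, `is_error`,
#' `session_start`, which are recomputed from the task rules and
#' cross-checked). Violations are reported with their row number.
#' Accidental immediate arm repeats within a session are collapsed to a
#' single visit with a warning, since the environment forbids revisits.
#'
#' @param path CSV file path.
#' @return a `wtrack_cohort` data.frame.
#' @export
read_visit_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(LOG_COLUMNS, names(df))
  if (length(miss) > 0L)
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!(df$arm %in% 1:3))
  if (length(bad) > 0L)
    stop("row ", bad[1], ": arm = ", df$arm[bad[1]],
         " outside {1,2,3}", call. = FALSE)
  bad <- which(!(df$reward %in% 0:1))
  if (length(bad) > 0L)
    stop("row ", bad[1], ": reward outside {0,1}", call. = FALSE)

  provided <- intersect(c("trial_type", "is_error"), names(df))
  parts <- lapply(split(df, df$subject_id), function(sub) {
    sub <- sub[order(sub$visit_index), ]
    if (is.unsorted(sub$session))
      stop("subject ", sub$subject_id[1],
           ": session numbers decrease", call. = FALSE)
    n <- nrow(sub)
    rep_rows <- which(sub$session[-1] == sub$session[-n] &
                        sub$arm[-1] == sub$arm[-n]) + 1L
    if (length(rep_rows) > 0L) {
      warning("subject ", sub$subject_id[1], ": collapsed ",
              length(rep_rows), " immediate repeat visit(s)", call. = FALSE)
      sub <- sub[-rep_rows, ]
      sub$visit_index <- seq_len(nrow(sub)) - 1L
    }
    ann <- annotate_log(sub[c("session", "visit_index", "arm", "reward")])
    for (col in provided) {
      if (!isTRUE(all(ann[[col]] == sub[[col]][seq_len(nrow(ann))])))
        warning("subject ", sub$subject_id[1], ": provided ", col,
                " disagrees with the task rules; recomputed values used",
                call. = FALSE)
    }
    cbind(subject_id = sub$subject_id, ann)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("wtrack_cohort", "data.frame")
  out
}

#' Write visit logs to the shared CSV schema
#'
#' @param logs a cohort data.frame, list of logs, or single log (a lone log
#'   gets `subject_id` `"S01"`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_visit_log <- function(logs, path) {
  if (is.data.frame(logs) && !("subject_id" %in% names(logs)))
    logs <- list(S01 = logs)
  if (!is.data.frame(logs)) {
    nm <- names(logs)
    if (is.null(nm)) nm <- sprintf("S%02d", seq_along(logs))
    logs <- do.call(rbind, Map(function(lg, id)
      cbind(subject_id = id, as.data.frame(lg)), logs, nm))
  }
  write.csv(as.data.frame(logs), path, row.names = FALSE)
  invisible(path)
}

#' Export a behavior curve as tidy CSV
#'
#' Columns `visit`, `value`, `sem`, `kind`.
#'
#' @param curve a `behavior_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_behavior_curve <- function(curve, path) {
  stopifnot(inherits(curve, "behavior_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fit result (with its reproducibility manifest) to JSON
#'
#' @param fit a `fit_result`.
#' @param path output JSON path.
#' @param spec optional [fit_spec()]; its seeds, bounds, window and ensemble
#'   size are embedded so the fit can be regenerated exactly.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path, spec = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  manifest <- if (!is.null(spec)) list(
    objective = spec$objective, variant = spec$variant,
    n_repeats = spec$n_repeats, window = spec$window,
    n_restarts = spec$n_restarts, n_evals = spec$n_evals,
    base_seed = spec$base_seed, sd = spec$sd,
    session_lengths = spec$session_lengths, bounds = spec$bounds) else NULL
  obj <- list(par = as.list(fit$par), value = fit$value,
              converged = fit$converged,
              restarts = lapply(fit$restarts, function(r)
                list(par = as.list(r$par), value = r$value)),
              manifest = manifest,
              package_version = as.character(utils::packageVersion("wtrack")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fit result written by [write_fit_result()]
#'
#' @param path JSON path.
#' @return a `fit_result` (manifest attached as attribute `"manifest"`).
#' @export
read_fit_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- structure(list(par = unlist(obj$par), value = obj$value,
                        restarts = obj$restarts,
                        converged = obj$converged,
                        n_evals_total = NA_integer_),
                   class = "fit_result")
  attr(res, "manifest") <- obj$manifest
  res
}

#' Read a fitting configuration from YAML
#'
#' Recognized keys mirror the [fit_spec()] arguments.
#'
#' @param path YAML path.
#' @return a [fit_spec()].
#' @export
read_fit_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("objective", "variant", "n_repeats", "window", "n_restarts",
             "n_evals", "base_seed", "sd", "session_lengths", "bounds")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$bounds)) cfg$bounds <- lapply(cfg$bounds, as.numeric)
  do.call(fit_spec, cfg)
}
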