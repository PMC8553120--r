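#' Sample one press outcome
#'
#' A press resolves sequentially: an injury occurs with probability
#' `p_injury`; otherwise a reward occurs with probability `p_reward`;
#' otherwise the press is neutral (no points gained, no health lost). The
#' three outcomes are therefore exclusive even though the configured
#' marginal probabilities (1/5 injury, 9/10 reward at the high levels) would
#' overlap if drawn disjointly. Magnitudes are drawn uniformly over the
#' trial's inclusive integer range, independently per event.
#'
#' @param spec one trial row of an [generate_design()] design (or any list
#'   with `p_injury`, `p_reward` and the four magnitude-bound fields).
#' @return a list `(kind, magnitude)` with `kind` one of `"reward"`,
#'   `"neutral"`, `"injury"`; neutral magnitude is 0. Uses the current RNG
#'   stream.
#' @export
sample_press_outcome <- function(spec) {
  if (stats::runif(1) < spec$p_injury) {
    list(kind = "injury",
         magnitude = sample_magnitude(spec$injury_mag_min, spec$injury_mag_max))
  } else if (stats::runif(1) < spec$p_reward) {
    list(kind = "reward",
         magnitude = sample_magnitude(spec$reward_mag_min, spec$reward_mag_max))
  } else {
    list(kind = "neutral", magnitude = 0L)
  }
}

# uniform over the inclusive integer range [lo, hi]
sample_magnitude <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Initial trial state
#'
#' @param config an [aprt_config()]; every trial starts at its
#'   `initial_health` (100) and `initial_points` (0).
#' @return a list `(health, points, presses, terminated_by)` with
#'   `terminated_by = "ongoing"`.
#' @export
new_trial_state <- function(config = aprt_config()) {
  list(health = config$initial_health, points = config$initial_points,
       presses = 0L, terminated_by = "ongoing")
}

#' Apply an outcome to a trial state
#'
#' Rewards add their magnitude to the trial's points. Neutral outcomes
#' change nothing. Injuries subtract their magnitude from *both* health and
#' points (points clamped at zero under the default floor). If health falls
#' to zero or below the trial terminates by death and all trial points are
#' forfeited.
#'
#' @param state a trial state as from [new_trial_state()].
#' @param event an outcome list `(kind, magnitude)`.
#' @param config an [engine_config()] (controls the points floor).
#' @return the updated state; `terminated_by` becomes `"death"` on a fatal
#'   injury.
#' @export
apply_outcome <- function(state, event, config = engine_config()) {
  if (state$terminated_by != "ongoing")
    stop("cannot apply an outcome to a terminated trial state")
  state$presses <- state$presses + 1L
  if (event$kind == "reward") {
    state$points <- state$points + event$magnitude
  } else if (event$kind == "injury") {
    state$health <- state$health - event$magnitude
    state$points <- state$points - event$magnitude
    if (config$points_floor_at_zero) state$points <- max(state$points, 0L)
    if (state$health <= 0L) {
      state$terminated_by <- "death"
      state$points <- 0L
    }
  } else if (event$kind != "neutral") {
    stop("unknown outcome kind: ", event$kind)
  }
  state
}

#' Run one trial under a decision policy
#'
#' Repeatedly queries the policy (press or quit). On press, an outcome is
#' sampled (or taken from the policy's outcome script) and applied; on quit
#' the current points are banked; on death the trial banks 0. Every press
#' and the terminating quit are recorded with simulated timestamps: press k
#' occurs at `k * delay_ms` in cool mode and `k * response_latency_ms` in
#' hot mode.
#'
#' @param spec one trial row.
#' @param policy a policy from [make_policy()].
#' @param config an [engine_config()].
#' @param factor_config the [aprt_config()] supplying initial health/points.
#' @return a list with `record` (banked_points, go_presses, injuries,
#'   remaining_health, died, terminated_by) and `events` (one data.frame row
#'   per press/quit).
#' @export
run_trial <- function(spec, policy, config = engine_config(),
                      factor_config = aprt_config()) {
  raw <- run_trial_raw(spec, policy, config, factor_config)
  list(record = raw$record, events = trial_events_df(raw))
}

# engine core: accumulates the event log in preallocated vectors so whole
# cohorts simulate quickly; run_trial/run_session shape it into data.frames
run_trial_raw <- function(spec, policy, config, factor_config) {
  state <- new_trial_state(factor_config)
  step_ms <- if (config$mode == "cool") config$delay_ms else config$response_latency_ms
  policy_reset(policy)
  cap <- 32L
  ev_action <- character(cap); ev_outcome <- character(cap)
  ev_mag <- integer(cap); ev_points <- integer(cap); ev_health <- integer(cap)
  n_ev <- 0L
  injuries <- 0L
  grow <- function() {
    ev_action <<- c(ev_action, character(cap)); ev_outcome <<- c(ev_outcome, character(cap))
    ev_mag <<- c(ev_mag, integer(cap)); ev_points <<- c(ev_points, integer(cap))
    ev_health <<- c(ev_health, integer(cap)); cap <<- 2L * cap
  }
  repeat {
    if (state$presses >= config$press_cap)
      stop("runaway policy: press cap (", config$press_cap, ") exceeded on trial ",
           spec$trial_index)
    action <- policy$decide(state, spec)
    n_ev <- n_ev + 1L
    if (n_ev > cap) grow()
    if (identical(action, "quit")) {
      ev_action[n_ev] <- "quit"; ev_outcome[n_ev] <- NA_character_
      ev_mag[n_ev] <- NA_integer_
      ev_points[n_ev] <- state$points; ev_health[n_ev] <- state$health
      state$terminated_by <- "quit"
      break
    }
    event <- policy_next_outcome(policy) %||% sample_press_outcome(spec)
    state <- apply_outcome(state, event, config)
    if (event$kind == "injury") injuries <- injuries + 1L
    ev_action[n_ev] <- "press"; ev_outcome[n_ev] <- event$kind
    ev_mag[n_ev] <- as.integer(event$magnitude)
    ev_points[n_ev] <- state$points; ev_health[n_ev] <- state$health
    if (state$terminated_by == "death") break
  }
  keep <- seq_len(n_ev)
  record <- list(
    trial_index = spec$trial_index,
    practice = isTRUE(spec$practice),
    banked_points = if (state$terminated_by == "death") 0L else state$points,
    go_presses = state$presses,
    injuries = injuries,
    remaining_health = max(state$health, 0L),
    died = state$terminated_by == "death",
    terminated_by = state$terminated_by
  )
  list(record = record,
       trial_index = rep(spec$trial_index, n_ev),
       press_index = keep,
       action = ev_action[keep], outcome = ev_outcome[keep],
       magnitude = ev_mag[keep], points_after = ev_points[keep],
       health_after = ev_health[keep],
       timestamp_ms = keep * step_ms)
}

trial_events_df <- function(raw) {
  data.frame(trial_index = raw$trial_index, press_index = raw$press_index,
             action = raw$action, outcome = raw$outcome,
             magnitude = raw$magnitude, points_after = raw$points_after,
             health_after = raw$health_after, timestamp_ms = raw$timestamp_ms,
             stringsAsFactors = FALSE)
}

#' Run a full session
#'
#' Runs every row of `design` (practice rows included but flagged) under one
#' policy and engine configuration, seeding the session RNG from
#' `config$seed` so the whole event log is reproducible. The grand total is
#' the sum of banked points over non-practice trials.
#'
#' @param design an `aprt_design`, optionally with practice rows prepended
#'   (see [with_practice()]).
#' @param policy a policy from [make_policy()].
#' @param config an [engine_config()].
#' @param factor_config the [aprt_config()] used to build the design.
#' @param participant_id identifier stored in the log.
#' @return an object of class `aprt_session`: list with `participant_id`,
#'   `mode`, `delay_ms`, `seed`, `events` (per-press rows), `trials`
#'   (per-trial records) and `grand_total_points`.
#' @export
run_session <- function(design, policy, config = engine_config(),
                        factor_config = attr(design, "config") %||% aprt_config(),
                        participant_id = "p0") {
  d <- as.data.frame(design)
  if (nrow(d) == 0L) {
    empty_events <- data.frame(
      trial_index = integer(), press_index = integer(), action = character(),
      outcome = character(), magnitude = integer(), points_after = integer(),
      health_after = integer(), timestamp_ms = numeric(),
      session_time_ms = numeric(), stringsAsFactors = FALSE)
    empty_trials <- data.frame(
      trial_index = integer(), practice = logical(), banked_points = integer(),
      go_presses = integer(), injuries = integer(), remaining_health = integer(),
      died = logical(), terminated_by = character(), stringsAsFactors = FALSE)
    return(structure(
      list(participant_id = participant_id, mode = config$mode,
           delay_ms = config$delay_ms, seed = config$seed,
           events = empty_events, trials = empty_trials,
           grand_total_points = 0L),
      class = "aprt_session"))
  }
  # row lists are cheap to index; d[i, ] inside the loop is not
  drows <- lapply(seq_len(nrow(d)), function(i) lapply(d, `[[`, i))
  out <- with_seed(config$seed, {
    lapply(drows, function(row) run_trial_raw(row, policy, config, factor_config))
  })
  trials <- do.call(rbind, lapply(out, function(x) as.data.frame(x$record)))
  cat_field <- function(f) unlist(lapply(out, `[[`, f), use.names = FALSE)
  events <- data.frame(
    trial_index = cat_field("trial_index"), press_index = cat_field("press_index"),
    action = cat_field("action"), outcome = cat_field("outcome"),
    magnitude = cat_field("magnitude"), points_after = cat_field("points_after"),
    health_after = cat_field("health_after"), timestamp_ms = cat_field("timestamp_ms"),
    stringsAsFactors = FALSE)
  # session-global clock: trials run back to back, each press offset by its
  # within-trial timestamp
  trial_durations <- vapply(out, function(x) max(x$timestamp_ms), numeric(1))
  trial_starts <- c(0, cumsum(trial_durations))
  offset <- rep(trial_starts[seq_along(out)],
                vapply(out, function(x) length(x$timestamp_ms), integer(1)))
  events$session_time_ms <- events$timestamp_ms + offset
  rownames(trials) <- rownames(events) <- NULL
  structure(
    list(participant_id = participant_id, mode = config$mode,
         delay_ms = config$delay_ms, seed = config$seed,
         events = events, trials = trials,
         grand_total_points = sum(trials$banked_points[!trials$practice])),
    class = "aprt_session"
  )
}

#' @export
print.aprt_session <- function(x, ...) {
  cat(sprintf("<aprt_session> participant %s, %s mode (%d trials, %d practice)\n",
              x$participant_id, x$mode, sum(!x$trials$practice),
              sum(x$trials$practice)))
  cat(sprintf("  grand total points: %d | presses: %d | deaths: %d\n",
              x$grand_total_points, sum(x$trials$go_presses),
              sum(x$trials$died)))
  invisible(x)
}

#' Write / read a session log
#'
#' Serializes a session losslessly to three plain-text files in `dir`:
#' `events.csv` (per-press rows), `trials.csv` (per-trial records) and
#' `session.json` (scalar metadata).
#'
#' @param session an `aprt_session`.
#' @param dir directory to write into (created if needed).
#' @return `read_session` returns the reconstructed `aprt_session`.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$events, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  meta <- session[c("participant_id", "mode", "delay_ms", "seed",
                    "grand_total_points")]
  jsonlite::write_json(meta, file.path(dir, "session.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  for (f in c("events.csv", "trials.csv", "session.json"))
    if (!file.exists(file.path(dir, f)))
      stop("session directory ", dir, " is missing ", f)
  events <- read_checked_csv(
    file.path(dir, "events.csv"),
    c("trial_index", "press_index", "action", "outcome", "magnitude",
      "points_after", "health_after", "timestamp_ms", "session_time_ms"),
    numeric_cols = c("trial_index", "press_index", "magnitude", "points_after",
                     "health_after", "timestamp_ms", "session_time_ms"))
  trials <- read_checked_csv(
    file.path(dir, "trials.csv"),
    c("trial_index", "practice", "banked_points", "go_presses", "injuries",
      "remaining_health", "died", "terminated_by"),
    numeric_cols = c("trial_index", "banked_points", "go_presses", "injuries",
                     "remaining_health"))
  trials$practice <- as.logical(trials$practice)
  trials$died <- as.logical(trials$died)
  meta <- jsonlite::read_json(file.path(dir, "session.json"), simplifyVector = TRUE)
  structure(
    list(participant_id = meta$participant_id, mode = meta$mode,
         delay_ms = meta$delay_ms, seed = meta$seed,
         events = events, trials = trials,
         grand_total_points = as.integer(meta$grand_total_points)),
    class = "aprt_session"
  )
}

# read.csv wrapper that validates schema and flags malformed rows by number
read_checked_csv <- function(path, required_cols, numeric_cols = character()) {
  df <- tryCatch(suppressWarnings(utils::read.csv(path, stringsAsFactors = FALSE)),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e)))
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("parse error in ", path, ": missing columns ",
         paste(missing, collapse = ", "))
  for (cl in numeric_cols) {
    v <- df[[cl]]
    bad <- which(!is.na(as.character(v)) & is.na(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric value in column '", cl,
           "' at data row ", bad[1])
    df[[cl]] <- suppressWarnings(as.numeric(v))
  }
  df
}
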