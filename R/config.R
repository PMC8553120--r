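#' Task factor configuration
#'
#' Defines the factorial structure of the risk-taking task: the picture
#' categories and, for each low/high level, the per-press injury and reward
#' probabilities and the inclusive integer magnitude ranges. The defaults are
#' the task's published parameterization: injury probability 1/15 (low) vs
#' 1/5 (high); reward probability 2/3 vs 9/10; injury magnitude 5--35 vs
#' 60--90 health points per injury; reward magnitude 5--25 vs 50--250 points
#' per reward; trials start at 100 health and 0 points.
#'
#' @param picture_categories character vector of scenario category labels.
#' @param injury_prob named numeric `c(low=, high=)` per-press injury
#'   probabilities, each in (0, 1).
#' @param reward_prob named numeric `c(low=, high=)` reward probabilities
#'   conditional on no injury, each in (0, 1).
#' @param injury_mag_range list with `low` and `high` integer `c(min, max)`
#'   bounds of health/points lost per injury.
#' @param reward_mag_range list with `low` and `high` integer `c(min, max)`
#'   bounds of points gained per reward.
#' @param initial_health starting health of every trial.
#' @param initial_points starting points of every trial.
#' @return an object of class `aprt_config`.
#' @examples
#' cfg <- aprt_config()
#' cfg$injury_prob
#' @export
aprt_config <- function(picture_categories = c("animal", "cliff", "disaster", "hero"),
                        injury_prob = c(low = 1 / 15, high = 1 / 5),
                        reward_prob = c(low = 2 / 3, high = 9 / 10),
                        injury_mag_range = list(low = c(5L, 35L), high = c(60L, 90L)),
                        reward_mag_range = list(low = c(5L, 25L), high = c(50L, 250L)),
                        initial_health = 100L,
                        initial_points = 0L) {
  cfg <- structure(
    list(picture_categories = as.character(picture_categories),
         injury_prob = injury_prob,
         reward_prob = reward_prob,
         injury_mag_range = lapply(injury_mag_range, as.integer),
         reward_mag_range = lapply(reward_mag_range, as.integer),
         initial_health = as.integer(initial_health),
         initial_points = as.integer(initial_points)),
    class = "aprt_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (length(cfg$picture_categories) < 1L || anyDuplicated(cfg$picture_categories))
    abort_config("picture_categories", "must be a non-empty set of distinct labels")
  for (nm in c("injury_prob", "reward_prob")) {
    p <- cfg[[nm]]
    if (!all(c("low", "high") %in% names(p)))
      abort_config(nm, "needs named entries 'low' and 'high'")
    # degenerate 0/1 allowed so tests can force outcomes; >1 or <0 is an error
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      abort_config(nm, "probabilities must lie in [0, 1]")
  }
  if (cfg$injury_prob[["high"]] < cfg$injury_prob[["low"]])
    abort_config("injury_prob", "high level must be >= low level")
  for (nm in c("injury_mag_range", "reward_mag_range")) {
    r <- cfg[[nm]]
    if (!all(c("low", "high") %in% names(r)))
      abort_config(nm, "needs named entries 'low' and 'high'")
    for (lev in c("low", "high")) {
      b <- r[[lev]]
      if (length(b) != 2L || anyNA(b) || b[1] > b[2])
        abort_config(sprintf("%s$%s", nm, lev), "must be c(min, max) with min <= max")
      if (b[1] < 1L)
        abort_config(sprintf("%s$%s", nm, lev), "magnitudes must be positive integers")
    }
  }
  if (is.na(cfg$initial_health) || cfg$initial_health < 1L)
    abort_config("initial_health", "must be a positive integer")
  if (is.na(cfg$initial_points) || cfg$initial_points < 0L)
    abort_config("initial_points", "must be a nonnegative integer")
  cfg
}

#' @export
print.aprt_config <- function(x, ...) {
  cat("<aprt_config>\n")
  cat("  categories:", paste(x$picture_categories, collapse = ", "), "\n")
  cat(sprintf("  injury prob   low %.4f  high %.4f\n",
              x$injury_prob[["low"]], x$injury_prob[["high"]]))
  cat(sprintf("  reward prob   low %.4f  high %.4f\n",
              x$reward_prob[["low"]], x$reward_prob[["high"]]))
  cat(sprintf("  injury mag    low [%d, %d]  high [%d, %d]\n",
              x$injury_mag_range$low[1], x$injury_mag_range$low[2],
              x$injury_mag_range$high[1], x$injury_mag_range$high[2]))
  cat(sprintf("  reward mag    low [%d, %d]  high [%d, %d]\n",
              x$reward_mag_range$low[1], x$reward_mag_range$low[2],
              x$reward_mag_range$high[1], x$reward_mag_range$high[2]))
  cat(sprintf("  initial health %d, initial points %d\n",
              x$initial_health, x$initial_points))
  invisible(x)
}

#' Engine execution configuration
#'
#' Controls how a session is executed: "hot" mode responds immediately (an
#' agent response latency stands in for human inter-press time), "cool" mode
#' enforces a fixed delay between consecutive presses within a trial
#' (1500 ms by default, the task's delay manipulation).
#'
#' @param mode `"hot"` or `"cool"`.
#' @param delay_ms enforced inter-press delay in milliseconds; defaults to 0
#'   in hot mode and 1500 in cool mode. Cool mode requires a positive delay.
#' @param seed integer seed for the session random stream.
#' @param points_floor_at_zero if `TRUE` (default) an injury can not push the
#'   trial's point balance below zero.
#' @param press_cap guard against non-terminating policies; exceeding it is
#'   an error.
#' @param response_latency_ms simulated hot-mode inter-press latency used for
#'   event timestamps (plumbing only; no behavioral consequence).
#' @return an object of class `aprt_engine_config`.
#' @export
engine_config <- function(mode = c("hot", "cool"), delay_ms = NULL, seed = 1L,
                          points_floor_at_zero = TRUE, press_cap = 10000L,
                          response_latency_ms = 600L) {
  mode <- match.arg(mode)
  if (is.null(delay_ms)) delay_ms <- if (mode == "cool") 1500L else 0L
  delay_ms <- as.integer(delay_ms)
  if (is.na(delay_ms) || delay_ms < 0L)
    abort_config("delay_ms", "must be a nonnegative integer")
  if (mode == "cool" && delay_ms <= 0L)
    abort_config("delay_ms", "cool mode requires delay_ms > 0")
  structure(
    list(mode = mode, delay_ms = delay_ms, seed = as.integer(seed),
         points_floor_at_zero = isTRUE(points_floor_at_zero),
         press_cap = as.integer(press_cap),
         response_latency_ms = as.integer(response_latency_ms)),
    class = "aprt_engine_config"
  )
}
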