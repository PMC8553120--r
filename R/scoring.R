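OUTCOMES <- c("points", "go_presses", "injuries", "remaining_health")
BINARY_FACTORS <- c("injury_mag", "injury_prob", "reward_mag", "reward_prob")
DIFF_FACTORS <- c(BINARY_FACTORS, "animal_cliff", "disaster_hero")

factor_level_col <- function(f) paste0(f, "_level")

#' Per-trial scores of one session
#'
#' Joins the session's per-trial records to the design's factor levels and
#' returns one score row per non-practice trial: banked points (0 on
#' death), go presses, injuries and remaining health (floored at 0).
#'
#' @param session an `aprt_session`.
#' @param design the `aprt_design` the session was run on.
#' @return a data.frame with participant id, trial index, the five factor
#'   levels and the four outcome columns. Trials present in the design but
#'   absent from the log are flagged via the `missing_trials` attribute and
#'   a warning.
#' @export
score_session <- function(session, design) {
  d <- as.data.frame(design)
  d <- d[!d$practice, c("trial_index", "picture_category",
                        "injury_prob_level", "injury_mag_level",
                        "reward_prob_level", "reward_mag_level")]
  tr <- session$trials
  tr <- tr[!tr$practice, c("trial_index", "banked_points", "go_presses",
                           "injuries", "remaining_health")]
  miss <- setdiff(d$trial_index, tr$trial_index)
  if (length(miss))
    warning("session ", session$participant_id, " is missing ",
            length(miss), " design trial(s)")
  out <- merge(d, tr, by = "trial_index", sort = TRUE)
  names(out)[names(out) == "banked_points"] <- "points"
  out <- cbind(participant_id = session$participant_id, out)
  attr(out, "missing_trials") <- miss
  out
}

#' Per-level condition means
#'
#' @param trial_scores per-trial rows from [score_session()].
#' @param factor one of `injury_mag`, `injury_prob`, `reward_mag`,
#'   `reward_prob` (levels low/high) or `picture_category`.
#' @param outcome one of `points`, `go_presses`, `injuries`,
#'   `remaining_health`.
#' @return named numeric vector of the mean outcome per factor level.
#' @export
condition_means <- function(trial_scores, factor, outcome) {
  stopifnot(outcome %in% OUTCOMES)
  col <- if (factor == "picture_category") "picture_category" else factor_level_col(factor)
  if (!col %in% names(trial_scores)) stop("unknown factor: ", factor)
  g <- split(trial_scores[[outcome]], trial_scores[[col]])
  if (any(!lengths(g)))
    stop("design error: empty level for factor ", factor)
  vapply(g, mean, numeric(1))
}

#' Low-minus-high difference scores
#'
#' One value per manipulated factor and outcome: the mean outcome over the
#' factor's low-level trials minus the mean over its high-level trials. The
#' picture factor is split into two contrasts, Animal - Cliff and
#' Disaster - Hero (animal and disaster play the "low" role). Small
#' difference scores index insensitivity to the manipulation, i.e. higher
#' risk taking.
#'
#' @param trial_scores per-trial rows from [score_session()] (one
#'   participant).
#' @param outcome outcome column name.
#' @return named numeric vector over `injury_mag`, `injury_prob`,
#'   `reward_mag`, `reward_prob`, `animal_cliff`, `disaster_hero`.
#' @export
difference_scores <- function(trial_scores, outcome) {
  out <- numeric(0)
  for (f in BINARY_FACTORS) {
    m <- condition_means(trial_scores, f, outcome)
    out[f] <- m[["low"]] - m[["high"]]
  }
  pm <- condition_means(trial_scores, "picture_category", outcome)
  # contrasts defined for the default category set only
  if (all(c("animal", "cliff") %in% names(pm)))
    out["animal_cliff"] <- pm[["animal"]] - pm[["cliff"]]
  if (all(c("disaster", "hero") %in% names(pm)))
    out["disaster_hero"] <- pm[["disaster"]] - pm[["hero"]]
  out
}

#' Participant-by-score table
#'
#' Aggregates a list of session logs into the wide score table used by the
#' statistical pipeline: for each of the four outcomes, the per-trial mean
#' (`<outcome>__total`), the grand point sum (`points__grand_total`), each
#' factor-level condition mean (`<outcome>__<factor>_<level>`), and the six
#' low-minus-high difference scores (`<outcome>__diff_<factor>`).
#'
#' @param sessions list of `aprt_session` logs.
#' @param design the common `aprt_design`.
#' @return a data.frame of class `aprt_scores`, one row per participant,
#'   with `participant_id` and `arm` (mode) leading columns.
#' @export
score_table <- function(sessions, design) {
  rows <- lapply(sessions, function(s) {
    ts <- score_session(s, design)
    row <- list(participant_id = s$participant_id, arm = s$mode)
    for (oc in OUTCOMES) {
      row[[paste0(oc, "__total")]] <- mean(ts[[oc]])
      for (f in BINARY_FACTORS) {
        m <- condition_means(ts, f, oc)
        row[[paste0(oc, "__", f, "_low")]] <- m[["low"]]
        row[[paste0(oc, "__", f, "_high")]] <- m[["high"]]
      }
      pm <- condition_means(ts, "picture_category", oc)
      for (lv in names(pm)) row[[paste0(oc, "__picture_", lv)]] <- pm[[lv]]
      dv <- difference_scores(ts, oc)
      for (f in names(dv)) row[[paste0(oc, "__diff_", f)]] <- dv[[f]]
    }
    row$points__grand_total <- s$grand_total_points
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("aprt_scores", "data.frame"))
}

#' Cronbach's alpha
#'
#' Internal consistency of a participants x items score matrix:
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of item sums)`.
#'
#' @param item_matrix numeric matrix or data.frame, rows = participants,
#'   columns = items (here: trials within a condition).
#' @return alpha (scalar, <= 1).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  k <- ncol(m)
  if (k < 2L) stop("Cronbach's alpha needs at least 2 items")
  if (nrow(m) < 2L) stop("Cronbach's alpha needs at least 2 participants")
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) stop("Cronbach's alpha undefined: zero total variance")
  item_vars <- apply(m, 2L, stats::var)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}

#' Reliability of a difference score
#'
#' Classical psychometric reliability of `X - Y` from the component
#' reliabilities, their correlation and standard deviations:
#' `(r_xx sd_x^2 + r_yy sd_y^2 - 2 r_xy sd_x sd_y) /
#'  (sd_x^2 + sd_y^2 - 2 r_xy sd_x sd_y)`.
#'
#' @param r_xx,r_yy component reliabilities in \[0, 1\].
#' @param r_xy correlation between the components, |r_xy| <= 1.
#' @param sd_x,sd_y component standard deviations (> 0).
#' @return the difference-score reliability.
#' @export
difference_score_reliability <- function(r_xx, r_yy, r_xy, sd_x, sd_y) {
  stopifnot(r_xx >= 0, r_xx <= 1, r_yy >= 0, r_yy <= 1,
            abs(r_xy) <= 1, sd_x > 0, sd_y > 0)
  denom <- sd_x^2 + sd_y^2 - 2 * r_xy * sd_x * sd_y
  if (denom <= 0) stop("degenerate difference score: denominator <= 0")
  (r_xx * sd_x^2 + r_yy * sd_y^2 - 2 * r_xy * sd_x * sd_y) / denom
}

#' Internal-consistency report
#'
#' For every outcome and every factor condition (low/high of the four
#' binary factors), Cronbach's alpha over that condition's trials treated
#' as items across participants, plus the resulting difference-score
#' reliability per factor (components = the low and high condition means).
#'
#' @param sessions list of `aprt_session` logs.
#' @param design the common `aprt_design`.
#' @return list with `alpha` (outcome, factor, level, k_items, alpha) and
#'   `difference` (outcome, factor, reliability) data.frames.
#' @export
reliability_report <- function(sessions, design) {
  ts_list <- lapply(sessions, score_session, design = design)
  # align trials across participants by trial_index
  idx <- sort(ts_list[[1]]$trial_index)
  alpha_rows <- list()
  diff_rows <- list()
  for (oc in OUTCOMES) {
    item <- do.call(rbind, lapply(ts_list, function(ts) {
      ts[match(idx, ts$trial_index), oc]
    }))
    levels_of <- ts_list[[1]][match(idx, ts_list[[1]]$trial_index), ]
    for (f in BINARY_FACTORS) {
      lv <- levels_of[[factor_level_col(f)]]
      a <- list()
      comp <- list()
      for (l in c("low", "high")) {
        m <- item[, lv == l, drop = FALSE]
        a[[l]] <- tryCatch(cronbach_alpha(m), error = function(e) NA_real_)
        comp[[l]] <- rowMeans(m)
        alpha_rows[[length(alpha_rows) + 1L]] <- data.frame(
          outcome = oc, factor = f, level = l, k_items = ncol(m),
          alpha = a[[l]], stringsAsFactors = FALSE)
      }
      rel <- tryCatch(
        difference_score_reliability(
          max(min(a$low, 1), 0), max(min(a$high, 1), 0),
          stats::cor(comp$low, comp$high),
          stats::sd(comp$low), stats::sd(comp$high)),
        error = function(e) NA_real_)
      diff_rows[[length(diff_rows) + 1L]] <- data.frame(
        outcome = oc, factor = f, reliability = rel, stringsAsFactors = FALSE)
    }
  }
  list(alpha = do.call(rbind, alpha_rows),
       difference = do.call(rbind, diff_rows))
}

#' Write a score table as CSV
#'
#' @param scores an `aprt_scores` table.
#' @param path output CSV path.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}
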