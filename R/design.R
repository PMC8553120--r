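#' Generate the counterbalanced factorial trial set
#'
#' Builds one full factorial replicate of Picture Category x Injury
#' Probability x Injury Magnitude x Reward Probability x Reward Magnitude
#' (4 x 2^4 = 64 unique trials at the default configuration), resolves each
#' trial's numeric parameters from the configuration, attaches the border
#' cues, and shuffles the presentation order deterministically from `seed`.
#'
#' @param config an [aprt_config()].
#' @param seed integer; controls the presentation order only.
#' @return a `data.frame` of class `aprt_design`, one row per trial, with
#'   factor-level columns, resolved probabilities and magnitude bounds,
#'   border cues and a `practice` flag (all `FALSE` here). The generating
#'   `config` and `seed` are stored as attributes.
#' @examples
#' d <- generate_design(aprt_config(), seed = 1)
#' nrow(d)            # 64
#' table(d$picture_category)
#' @export
generate_design <- function(config = aprt_config(), seed = 1L) {
  config <- validate_config(config)
  lv <- c("low", "high")
  grid <- expand.grid(
    picture_category = config$picture_categories,
    injury_prob_level = lv, injury_mag_level = lv,
    reward_prob_level = lv, reward_mag_level = lv,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  ord <- with_seed(derive_seed(seed, "design-order"), sample.int(nrow(grid)))
  grid <- grid[ord, , drop = FALSE]
  design <- resolve_trials(grid, config)
  design$trial_index <- seq_len(nrow(design)) - 1L
  design$practice <- FALSE
  design <- design[, design_columns(), drop = FALSE]
  rownames(design) <- NULL
  structure(design, class = c("aprt_design", "data.frame"),
            seed = as.integer(seed), config = config)
}

design_columns <- function() {
  c("trial_index", "practice", "picture_category",
    "injury_prob_level", "injury_mag_level",
    "reward_prob_level", "reward_mag_level",
    "p_injury", "p_reward",
    "injury_mag_min", "injury_mag_max", "reward_mag_min", "reward_mag_max",
    "border_pattern", "border_color", "description_text")
}

# fill in resolved numeric parameters + cues + description for level rows
resolve_trials <- function(grid, config) {
  grid$p_injury <- unname(config$injury_prob[grid$injury_prob_level])
  grid$p_reward <- unname(config$reward_prob[grid$reward_prob_level])
  imr <- config$injury_mag_range
  rmr <- config$reward_mag_range
  grid$injury_mag_min <- vapply(grid$injury_mag_level, function(l) imr[[l]][1], integer(1))
  grid$injury_mag_max <- vapply(grid$injury_mag_level, function(l) imr[[l]][2], integer(1))
  grid$reward_mag_min <- vapply(grid$reward_mag_level, function(l) rmr[[l]][1], integer(1))
  grid$reward_mag_max <- vapply(grid$reward_mag_level, function(l) rmr[[l]][2], integer(1))
  cues <- cue_encoding(grid)
  grid$border_pattern <- cues$border_pattern
  grid$border_color <- cues$border_color
  grid$description_text <- description_text(grid$picture_category)
  grid
}

# fixed per-category template strings; photographic stimuli are out of scope
description_text <- function(category) {
  templates <- c(
    animal = "You are encountering a dangerous animal.",
    cliff = "You are standing along a steep cliff face.",
    disaster = "You are attempting to photograph a natural disaster.",
    hero = "You are attempting to rescue someone in physical peril."
  )
  out <- templates[category]
  out[is.na(out)] <- sprintf("You are engaging in a risky activity (%s).",
                             category[is.na(out)])
  unname(out)
}

#' Border cue encoding
#'
#' Participants are cued about each trial's probabilities by the picture
#' border: a solid border signals high reward probability (striped = low),
#' and a yellow border signals high injury probability (blue = low).
#'
#' @param spec a trial spec row, design, or any data.frame with
#'   `reward_prob_level` and `injury_prob_level` columns.
#' @return a data.frame with columns `border_pattern` (`solid`/`striped`)
#'   and `border_color` (`yellow`/`blue`).
#' @seealso [cue_decoding()] for the inverse map.
#' @export
cue_encoding <- function(spec) {
  stopifnot(all(c("reward_prob_level", "injury_prob_level") %in% names(spec)))
  data.frame(
    border_pattern = ifelse(spec$reward_prob_level == "high", "solid", "striped"),
    border_color = ifelse(spec$injury_prob_level == "high", "yellow", "blue"),
    stringsAsFactors = FALSE
  )
}

#' @rdname cue_encoding
#' @param cues a data.frame with `border_pattern` and `border_color` columns.
#' @export
cue_decoding <- function(cues) {
  stopifnot(all(c("border_pattern", "border_color") %in% names(cues)))
  data.frame(
    reward_prob_level = ifelse(cues$border_pattern == "solid", "high", "low"),
    injury_prob_level = ifelse(cues$border_color == "yellow", "high", "low"),
    stringsAsFactors = FALSE
  )
}

#' Generate practice trials
#'
#' One practice trial per picture category, with the four binary factor
#' levels drawn seed-deterministically. Practice trials carry
#' `practice = TRUE` and are excluded from scoring.
#'
#' @inheritParams generate_design
#' @return a data.frame shaped like [generate_design()] rows.
#' @export
generate_practice <- function(config = aprt_config(), seed = 1L) {
  config <- validate_config(config)
  lv <- c("low", "high")
  k <- length(config$picture_categories)
  grid <- with_seed(derive_seed(seed, "practice"), data.frame(
    picture_category = config$picture_categories,
    injury_prob_level = sample(lv, k, replace = TRUE),
    injury_mag_level = sample(lv, k, replace = TRUE),
    reward_prob_level = sample(lv, k, replace = TRUE),
    reward_mag_level = sample(lv, k, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  practice <- resolve_trials(grid, config)
  practice$trial_index <- -seq_len(k)  # negative indices mark practice rows
  practice$practice <- TRUE
  practice <- practice[, design_columns(), drop = FALSE]
  rownames(practice) <- NULL
  practice
}

#' Prepend practice trials to a design
#'
#' @param design an `aprt_design`.
#' @param seed seed for the practice-trial level draws; defaults to the
#'   design's own seed.
#' @return the design with the practice block in front, attributes kept.
#' @export
with_practice <- function(design, seed = attr(design, "seed")) {
  config <- attr(design, "config") %||% aprt_config()
  practice <- generate_practice(config, seed = seed)
  out <- rbind(practice, as.data.frame(design)[, design_columns()])
  rownames(out) <- NULL
  structure(out, class = c("aprt_design", "data.frame"),
            seed = attr(design, "seed"), config = config)
}

#' Design balance report
#'
#' Tabulates one-way and two-way factor-level cell counts of a design and
#' checks trial uniqueness. At the default full factorial every binary level
#' appears 32 times, every picture category 16 times, every binary x binary
#' cell 16 times and every picture x binary cell 8 times.
#'
#' @param design an `aprt_design` (practice rows are ignored).
#' @return a list with `one_way` and `two_way` count tables (data.frames),
#'   `n_trials`, and `duplicates`, the duplicated 5-tuples (empty when the
#'   design is valid).
#' @export
design_balance_report <- function(design) {
  d <- as.data.frame(design)
  d <- d[!d$practice, , drop = FALSE]
  fac <- c("picture_category", "injury_prob_level", "injury_mag_level",
           "reward_prob_level", "reward_mag_level")
  one <- do.call(rbind, lapply(fac, function(f) {
    tb <- table(d[[f]])
    data.frame(factor = f, level = names(tb), n = as.integer(tb),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(fac, 2L, simplify = FALSE)
  two <- do.call(rbind, lapply(pairs, function(p) {
    tb <- as.data.frame(table(d[[p[1]]], d[[p[2]]]), stringsAsFactors = FALSE)
    names(tb) <- c("level_1", "level_2", "n")
    cbind(data.frame(factor_1 = p[1], factor_2 = p[2], stringsAsFactors = FALSE), tb)
  }))
  key <- do.call(paste, c(d[fac], sep = "\r"))
  dup <- unique(d[key %in% key[duplicated(key)], fac, drop = FALSE])
  rownames(one) <- rownames(two) <- rownames(dup) <- NULL
  list(n_trials = nrow(d), one_way = one, two_way = two, duplicates = dup)
}

#' Write / read a design as CSV
#'
#' @param design an `aprt_design`.
#' @param path file path of the CSV artifact.
#' @return `read_design` returns the design data.frame (class restored;
#'   `config`/`seed` attributes are not serialized).
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design)[, design_columns()], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(design_columns(), names(d))
  if (length(missing))
    stop("design file ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  d$practice <- as.logical(d$practice)
  structure(d[, design_columns()], class = c("aprt_design", "data.frame"))
}
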