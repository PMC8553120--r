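# shared fixtures, all generated in code

default_design <- function(seed = 11L) generate_design(aprt_config(), seed = seed)

# config with forced outcome probabilities (degenerate levels are allowed
# precisely so tests can isolate one outcome branch)
forced_config <- function(p_injury = NULL, p_reward = NULL,
                          injury_mag = NULL, base = aprt_config()) {
  if (!is.null(p_injury)) base$injury_prob[] <- p_injury
  if (!is.null(p_reward)) base$reward_prob[] <- p_reward
  if (!is.null(injury_mag)) {
    base$injury_mag_range$low <- as.integer(c(injury_mag, injury_mag))
    base$injury_mag_range$high <- as.integer(c(injury_mag, injury_mag))
  }
  validate_config(base)
}

# one resolved trial row without going through a whole design
trial_spec <- function(config = aprt_config(), picture = "animal",
                       injury_prob = "low", injury_mag = "low",
                       reward_prob = "low", reward_mag = "low",
                       trial_index = 0L, practice = FALSE) {
  grid <- data.frame(picture_category = picture,
                     injury_prob_level = injury_prob,
                     injury_mag_level = injury_mag,
                     reward_prob_level = reward_prob,
                     reward_mag_level = reward_mag,
                     stringsAsFactors = FALSE)
  row <- aprt:::resolve_trials(grid, config)
  row$trial_index <- trial_index
  row$practice <- practice
  row
}

# the published walk-through trial: win 63, injury 64, fatal injury 40
fig1_policy <- function() {
  make_policy("scripted", actions = rep("press", 3),
              outcomes = list(list(kind = "reward", magnitude = 63L),
                              list(kind = "injury", magnitude = 64L),
                              list(kind = "injury", magnitude = 40L)))
}

# direct-formula Cronbach alpha oracle, independent of the implementation
alpha_oracle <- function(m) {
  k <- ncol(m)
  covm <- stats::cov(m)
  (k / (k - 1)) * (1 - sum(diag(covm)) / sum(covm))
}

# brute-force Holm-Sidak step-down oracle: explicit loop over ordered
# hypotheses using the per-step critical values 1 - (1-alpha)^(1/(m-i+1))
holm_sidak_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    crit <- 1 - (1 - alpha)^(1 / (m - i + 1))
    if (p[ord[i]] <= crit) reject[ord[i]] <- TRUE else break
  }
  reject
}

# factorial panel with known ground truth: cell value = participant random
# intercept + injected effects + iid noise (the spec's "simulated panel")
synth_panel <- function(n, effects = list(), sd_b = 1, sd_e = 1, seed = 1L) {
  cells <- expand.grid(
    picture_type = c("animal", "cliff", "disaster", "hero"),
    injury_mag = c("low", "high"), injury_prob = c("low", "high"),
    reward_mag = c("low", "high"), reward_prob = c("low", "high"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    panel <- do.call(rbind, lapply(seq_len(n), function(i) {
      d <- cells
      d$participant <- sprintf("p%03d", i)
      d$delay <- if (i %% 2 == 0) "delay" else "no_delay"
      d$value <- rnorm(1, 0, sd_b) + rnorm(nrow(d), 0, sd_e)
      for (f in names(effects)) {
        d$value <- d$value + effects[[f]] * (d[[f]] == "high")
      }
      d
    }))
  })
  panel <- panel[order(panel$participant, panel$picture_type, panel$injury_mag,
                       panel$injury_prob, panel$reward_mag, panel$reward_prob), ]
  rownames(panel) <- NULL
  structure(panel, class = c("aprt_panel", "data.frame"), outcome = "synthetic")
}
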