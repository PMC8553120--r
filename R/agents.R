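#' Latent trait profile of a simulated agent
#'
#' The decision model translates five latent traits into press/quit
#' behavior:
#' * `theta` in \[0,1\]: baseline press drive (risk propensity).
#' * `cue_sensitivity` (s >= 0): down-weighting of the press drive when the
#'   trial's injury cues are high. `s = 0` is the task's operationalization
#'   of maximal risk taking -- complete insensitivity to injury-condition
#'   changes.
#' * `satisficing_target` (T > 0): the agent quits a trial once its points
#'   reach T, mirroring the satisficing pattern in the points scores.
#' * `health_caution` (h >= 0): press drive scales with the current health
#'   fraction raised to h.
#' * `delay_attenuation` (a in \[0,1\]): in cool (delayed) mode the press
#'   drive shrinks toward a cautious baseline: theta_eff = (1-a) theta +
#'   a theta_cool.
#'
#' @param theta,cue_sensitivity,satisficing_target,health_caution,
#'   delay_attenuation numeric scalars in the domains above.
#' @param theta_cool the cautious cool-mode baseline drive.
#' @return a list of class `aprt_trait_profile`.
#' @export
trait_profile <- function(theta, cue_sensitivity = 0, satisficing_target = Inf,
                          health_caution = 0, delay_attenuation = 0,
                          theta_cool = 0.3) {
  stopifnot(theta >= 0, theta <= 1, cue_sensitivity >= 0,
            satisficing_target > 0, health_caution >= 0,
            delay_attenuation >= 0, delay_attenuation <= 1,
            theta_cool >= 0, theta_cool <= 1)
  structure(list(theta = theta, cue_sensitivity = cue_sensitivity,
                 satisficing_target = satisficing_target,
                 health_caution = health_caution,
                 delay_attenuation = delay_attenuation,
                 theta_cool = theta_cool),
            class = "aprt_trait_profile")
}

# number of high injury cues on this trial, in {0, 1, 2}
injury_cue_count <- function(spec) {
  (spec$injury_prob_level == "high") + (spec$injury_mag_level == "high")
}

#' Press probability of the trait policy
#'
#' pi = clip(theta_eff * exp(-s * I) * (health/100)^h, 0, 1) where I counts
#' the trial's high injury cues (probability and magnitude, so I in
#' \{0,1,2\}) and theta_eff is the (possibly delay-attenuated) press drive.
#'
#' @param state trial state (uses `health` and `points`).
#' @param spec trial row (uses the injury levels).
#' @param profile an [trait_profile()].
#' @param mode `"hot"` or `"cool"`.
#' @param initial_health the health a trial starts with (denominator of the
#'   health fraction).
#' @return the press probability; exactly 0 when the satisficing target is
#'   reached (the agent quits).
#' @export
press_probability <- function(state, spec, profile, mode = "hot",
                              initial_health = 100L) {
  if (state$points >= profile$satisficing_target) return(0)
  theta_eff <- if (identical(mode, "cool")) {
    (1 - profile$delay_attenuation) * profile$theta +
      profile$delay_attenuation * profile$theta_cool
  } else {
    profile$theta
  }
  frac <- max(state$health, 0L) / initial_health
  pi <- theta_eff * exp(-profile$cue_sensitivity * injury_cue_count(spec)) *
    frac^profile$health_caution
  min(max(pi, 0), 1)
}

#' Trait-policy decision
#'
#' Quit if the satisficing target is reached, otherwise press with
#' probability [press_probability()] (drawn from the session RNG stream).
#'
#' @inheritParams press_probability
#' @return `"press"` or `"quit"`.
#' @export
policy_decide <- function(state, spec, profile, mode = "hot",
                          initial_health = 100L) {
  pi <- press_probability(state, spec, profile, mode, initial_health)
  if (pi <= 0) return("quit")
  if (stats::runif(1) < pi) "press" else "quit"
}

#' Construct a decision policy
#'
#' @param kind one of `"never_quit"`, `"always_quit"`, `"satisficer"`,
#'   `"cue_sensitive"`, `"scripted"`.
#' @param ... parameters by kind: `satisficer` takes `target`;
#'   `cue_sensitive` takes `profile` (a [trait_profile()]), `mode` and
#'   optionally `initial_health`; `scripted` takes `actions` (character
#'   vector of `"press"`/`"quit"`) and optionally `outcomes`, a list of
#'   `(kind, magnitude)` events replayed in order instead of sampling
#'   (used e.g. to replay a published example trial).
#' @return an `aprt_policy`; pass to [run_trial()]/[run_session()].
#' @examples
#' p <- make_policy("satisficer", target = 50)
#' @export
make_policy <- function(kind = c("never_quit", "always_quit", "satisficer",
                                 "cue_sensitive", "scripted"), ...) {
  kind <- match.arg(kind)
  params <- list(...)
  env <- new.env(parent = emptyenv())
  env$outcome_pos <- 0L
  env$action_pos <- 0L
  decide <- switch(kind,
    never_quit = function(state, spec) "press",
    always_quit = function(state, spec) "quit",
    satisficer = {
      target <- params$target
      stopifnot(is.numeric(target), target > 0)
      function(state, spec) if (state$points >= target) "quit" else "press"
    },
    cue_sensitive = {
      profile <- params$profile
      stopifnot(inherits(profile, "aprt_trait_profile"))
      mode <- params$mode %||% "hot"
      ih <- params$initial_health %||% 100L
      function(state, spec) policy_decide(state, spec, profile, mode, ih)
    },
    scripted = {
      actions <- params$actions
      stopifnot(is.character(actions), all(actions %in% c("press", "quit")))
      function(state, spec) {
        env$action_pos <- env$action_pos + 1L
        if (env$action_pos > length(actions)) "quit" else actions[env$action_pos]
      }
    }
  )
  structure(list(kind = kind, decide = decide, params = params, env = env),
            class = "aprt_policy")
}

# scripted policies replay per-trial state; others are stateless
policy_reset <- function(policy) {
  policy$env$outcome_pos <- 0L
  policy$env$action_pos <- 0L
  invisible(policy)
}

# next scripted outcome, or NULL to sample from the trial's distribution
policy_next_outcome <- function(policy) {
  outs <- policy$params$outcomes
  if (is.null(outs)) return(NULL)
  policy$env$outcome_pos <- policy$env$outcome_pos + 1L
  if (policy$env$outcome_pos > length(outs))
    stop("scripted policy ran out of outcomes")
  outs[[policy$env$outcome_pos]]
}

#' Cohort specification
#'
#' Trait distributions for a synthetic cohort plus the generative model of
#' its self-report scale scores. Defaults are calibrated once for trait
#' identifiability of the simulation design (see the methods vignette):
#' theta ~ Beta(4, 1.5), cue sensitivity ~ Gamma(0.6, rate 4), satisficing
#' target ~ Lognormal(log 45, 0.2); health caution (0), delay attenuation
#' (0.6) and the cool baseline drive (0.3) are fixed cohort-wide; scale
#' loading lambda = 0.35 with 3 convergent and 3 divergent scales.
#'
#' @param n number of participants (>= 1).
#' @param seed cohort seed; per-participant engine seeds derive from it.
#' @param lambda target trait-scale loading of convergent scales, in
#'   \[-1, 1\].
#' @param n_convergent,n_divergent numbers of synthetic scale scores.
#' @param theta_shape1,theta_shape2 Beta parameters of the propensity.
#' @param s_shape,s_rate Gamma parameters of the cue sensitivity.
#' @param target_meanlog,target_sdlog Lognormal parameters of the
#'   satisficing target (points).
#' @param health_caution fixed health-caution exponent shared by the whole
#'   cohort (not a heterogeneity source, which keeps the cue-sensitivity
#'   difference score identifiable).
#' @param delay_attenuation,theta_cool cool-mode shrinkage weight and
#'   baseline shared by all agents.
#' @return a list of class `aprt_cohort_spec`.
#' @export
cohort_spec <- function(n, seed = 1L, lambda = 0.35, n_convergent = 3L,
                        n_divergent = 3L, theta_shape1 = 4, theta_shape2 = 1.5,
                        s_shape = 0.6, s_rate = 4,
                        target_meanlog = log(45), target_sdlog = 0.2,
                        health_caution = 0,
                        delay_attenuation = 0.6, theta_cool = 0.3) {
  stopifnot(n >= 1, lambda >= -1, lambda <= 1,
            delay_attenuation >= 0, delay_attenuation <= 1)
  structure(as.list(environment()), class = "aprt_cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws a trait profile per participant and synthetic self-report scale
#' scores: each convergent scale is `lambda * z(theta) +
#' sqrt(1 - lambda^2) * noise` (standardized), each divergent scale is
#' independent standard normal noise. Participants get 0-based ids; even
#' ids are assigned to the cool (delayed) arm and odd ids to the hot arm,
#' matching the task's even/odd delay-assignment rule.
#'
#' @param spec an [cohort_spec()].
#' @return a data.frame of class `aprt_cohort`: id, arm, trait columns,
#'   `conv_*` and `div_*` scale columns; the spec is kept as an attribute.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "aprt_cohort_spec"))
  n <- spec$n
  ch <- with_seed(derive_seed(spec$seed, "cohort-traits"), {
    df <- data.frame(
      id = seq_len(n) - 1L,
      theta = stats::rbeta(n, spec$theta_shape1, spec$theta_shape2),
      cue_sensitivity = stats::rgamma(n, shape = spec$s_shape, rate = spec$s_rate),
      satisficing_target = stats::rlnorm(n, spec$target_meanlog, spec$target_sdlog),
      health_caution = spec$health_caution
    )
    df$delay_attenuation <- spec$delay_attenuation
    df$theta_cool <- spec$theta_cool
    df$arm <- ifelse(df$id %% 2L == 0L, "cool", "hot")
    z <- if (n > 1 && stats::sd(df$theta) > 0) {
      (df$theta - mean(df$theta)) / stats::sd(df$theta)
    } else {
      rep(0, n)
    }
    lam <- spec$lambda
    for (j in seq_len(spec$n_convergent)) {
      raw <- lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
      df[[paste0("conv_", j)]] <- if (n > 1 && stats::sd(raw) > 0)
        (raw - mean(raw)) / stats::sd(raw) else raw
    }
    for (j in seq_len(spec$n_divergent)) {
      df[[paste0("div_", j)]] <- stats::rnorm(n)
    }
    df
  })
  structure(ch, class = c("aprt_cohort", "data.frame"), spec = spec)
}

#' Simulate sessions for a whole cohort
#'
#' Runs each cohort member through the design under their trait policy.
#' Even-id participants run in cool mode (1500 ms delay), odd-id in hot
#' mode; per-participant engine seeds derive deterministically from the
#' cohort seed.
#'
#' @param cohort an `aprt_cohort` from [generate_cohort()].
#' @param design an `aprt_design`.
#' @param delay_ms cool-arm inter-press delay (ms).
#' @param include_practice prepend the design's practice block (flagged,
#'   excluded from scoring).
#' @param mode_override force every participant into `"hot"` or `"cool"`
#'   regardless of id (used e.g. for parameter-recovery checks); `NULL`
#'   (default) keeps the even/odd assignment.
#' @return list of `aprt_session` logs, one per cohort row.
#' @export
simulate_cohort <- function(cohort, design, delay_ms = 1500L,
                            include_practice = TRUE, mode_override = NULL) {
  stopifnot(inherits(cohort, "aprt_cohort"))
  spec <- attr(cohort, "spec")
  factor_config <- attr(design, "config") %||% aprt_config()
  d <- if (include_practice) with_practice(design) else design
  lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    mode <- mode_override %||% row$arm
    profile <- trait_profile(
      theta = row$theta, cue_sensitivity = row$cue_sensitivity,
      satisficing_target = row$satisficing_target,
      health_caution = row$health_caution,
      delay_attenuation = row$delay_attenuation,
      theta_cool = row$theta_cool
    )
    policy <- make_policy("cue_sensitive", profile = profile, mode = mode,
                          initial_health = factor_config$initial_health)
    eng <- engine_config(mode = mode,
                         delay_ms = if (mode == "cool") delay_ms else 0L,
                         seed = derive_seed(spec$seed, paste0("engine-", row$id)))
    run_session(d, policy, eng, factor_config,
                participant_id = paste0("p", row$id))
  })
}

#' Write a cohort table as CSV
#'
#' @param cohort an `aprt_cohort`.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
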