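test_that("press outcomes honor degenerate probabilities and magnitude bounds", {
  spec0 <- trial_spec(forced_config(p_injury = 0))
  withr::with_seed(1, {
    kinds <- replicate(500, sample_press_outcome(spec0)$kind)
  })
  expect_false(any(kinds == "injury"))

  spec1 <- trial_spec(forced_config(p_injury = 1), injury_mag = "high")
  withr::with_seed(2, {
    ev <- replicate(2000, sample_press_outcome(spec1), simplify = FALSE)
  })
  expect_true(all(vapply(ev, `[[`, character(1), "kind") == "injury"))
  mags <- vapply(ev, `[[`, numeric(1), "magnitude")
  expect_true(all(mags >= 60 & mags <= 90))

  # reward magnitudes respect the low range
  specr <- trial_spec(forced_config(p_injury = 0, p_reward = 1))
  withr::with_seed(3, {
    mr <- replicate(2000, sample_press_outcome(specr)$magnitude)
  })
  expect_true(all(mr >= 5 & mr <= 25))
  expect_setequal(range(mr), c(5, 25))
})

test_that("the sequential outcome scheme yields the closed-form neutral rate", {
  # low reward (2/3), high injury (1/5): P(neutral) = (1-1/5)(1-2/3) = 4/15
  spec <- trial_spec(aprt_config(), injury_prob = "high", reward_prob = "low")
  n <- 30000
  withr::with_seed(4, {
    kinds <- replicate(n, sample_press_outcome(spec)$kind)
  })
  p_neutral <- 4 / 15
  se <- sqrt(p_neutral * (1 - p_neutral) / n)
  expect_lt(abs(mean(kinds == "neutral") - p_neutral), 3 * se)
  # exhaustive enumeration of the two-stage scheme as the oracle
  p_inj <- 1 / 5; p_rew <- 2 / 3
  probs <- c(injury = p_inj, reward = (1 - p_inj) * p_rew,
             neutral = (1 - p_inj) * (1 - p_rew))
  expect_equal(sum(probs), 1)
  se_i <- sqrt(probs[["injury"]] * (1 - probs[["injury"]]) / n)
  expect_lt(abs(mean(kinds == "injury") - probs[["injury"]]), 3 * se_i)
})

test_that("apply_outcome follows the published trial walk-through", {
  cfg <- engine_config("hot")
  st <- new_trial_state()
  expect_equal(st$health, 100L); expect_equal(st$points, 0L)
  st <- apply_outcome(st, list(kind = "reward", magnitude = 63L), cfg)
  expect_equal(c(st$points, st$health), c(63L, 100L))
  st <- apply_outcome(st, list(kind = "injury", magnitude = 64L), cfg)
  expect_equal(c(st$points, st$health), c(0L, 36L))   # points clamped at 0
  expect_equal(st$terminated_by, "ongoing")
  st <- apply_outcome(st, list(kind = "injury", magnitude = 40L), cfg)
  expect_equal(st$terminated_by, "death")
  expect_equal(st$points, 0L)
  expect_error(apply_outcome(st, list(kind = "reward", magnitude = 5L), cfg),
               "terminated")
  # without the floor, points may go negative but death still zeroes them
  cfg_nf <- engine_config("hot", points_floor_at_zero = FALSE)
  st2 <- apply_outcome(new_trial_state(),
                       list(kind = "injury", magnitude = 30L), cfg_nf)
  expect_equal(st2$points, -30L)
})

test_that("run_trial handles quitting, scripts and runaway policies", {
  spec <- trial_spec()
  out <- run_trial(spec, make_policy("always_quit"))
  expect_equal(out$record$go_presses, 0L)
  expect_equal(out$record$banked_points, 0L)
  expect_equal(out$record$remaining_health, 100L)
  expect_equal(out$events$action, "quit")

  fig1 <- run_trial(spec, fig1_policy())
  expect_equal(fig1$record$go_presses, 3L)
  expect_equal(fig1$record$injuries, 2L)
  expect_true(fig1$record$died)
  expect_equal(fig1$record$banked_points, 0L)
  expect_equal(fig1$events$points_after, c(63L, 0L, 0L))
  expect_equal(fig1$events$health_after, c(100L, 36L, -4L))

  # a policy that never quits under a no-injury config hits the press cap
  spec_safe <- trial_spec(forced_config(p_injury = 0))
  expect_error(
    withr::with_seed(1, run_trial(spec_safe, make_policy("never_quit"),
                                  engine_config("hot", press_cap = 50))),
    "runaway policy")
})

test_that("mean presses-to-death matches the negative-binomial oracle", {
  # fixed injury magnitude m, health h: death at the r-th injury,
  # r = ceiling(h / m); presses to death ~ NegBin, mean r / p_injury
  cases <- list(list(health = 10L, mag = 5L, p = 0.5),
                list(health = 20L, mag = 7L, p = 0.3))
  for (cs in cases) {
    cfg <- forced_config(p_injury = cs$p, injury_mag = cs$mag)
    cfg$initial_health <- cs$health
    spec <- trial_spec(cfg)
    n <- 4000
    presses <- withr::with_seed(7, {
      replicate(n, run_trial(spec, make_policy("never_quit"),
                             engine_config("hot"), cfg)$record$go_presses)
    })
    r <- ceiling(cs$health / cs$mag)
    mu <- r / cs$p
    sd_th <- sqrt(r * (1 - cs$p) / cs$p^2)
    expect_lt(abs(mean(presses) - mu), 3 * sd_th / sqrt(n))
  }
})

test_that("sessions are reproducible and conserve health and points", {
  d <- default_design()
  profile <- trait_profile(theta = 0.8, cue_sensitivity = 0.3,
                           satisficing_target = 60)
  pol <- make_policy("cue_sensitive", profile = profile)
  s1 <- run_session(d, pol, engine_config("hot", seed = 9))
  s2 <- run_session(d, pol, engine_config("hot", seed = 9))
  expect_identical(s1$events, s2$events)
  expect_identical(s1$trials, s2$trials)
  expect_equal(s1$grand_total_points,
               sum(s1$trials$banked_points[!s1$trials$practice]))

  # conservation: within a trial, health = 100 - cumulative injury and
  # points follow the reward/injury ledger with the zero clamp
  ev <- s1$events
  for (ti in unique(ev$trial_index)) {
    e <- ev[ev$trial_index == ti & ev$action == "press", ]
    if (!nrow(e)) next
    inj <- ifelse(e$outcome == "injury", e$magnitude, 0)
    expect_equal(e$health_after, 100 - cumsum(inj))
    pts <- 0
    for (j in seq_len(nrow(e))) {
      if (e$outcome[j] == "reward") pts <- pts + e$magnitude[j]
      if (e$outcome[j] == "injury") pts <- max(pts - e$magnitude[j], 0)
      if (e$health_after[j] <= 0) pts <- 0
      expect_equal(e$points_after[j], pts)
    }
  }
})

test_that("cool mode spaces consecutive presses by the configured delay", {
  d <- default_design()
  pol <- make_policy("satisficer", target = 40)
  s <- run_session(d, pol, engine_config("cool", seed = 5))
  ev <- s$events
  gaps <- unlist(lapply(split(ev$timestamp_ms, ev$trial_index), diff))
  expect_true(all(gaps >= 1500))
  expect_equal(min(gaps), 1500)
  expect_true(all(diff(ev$session_time_ms) >= 0))  # global clock nondecreasing
  expect_error(engine_config("cool", delay_ms = 0), "delay_ms")
})

test_that("session logs round-trip losslessly through CSV", {
  d <- generate_design(seed = 2)
  s <- run_session(d[1:6, ], make_policy("satisficer", target = 30),
                   engine_config("hot", seed = 3))
  dir <- withr::local_tempdir()
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(s2$events$points_after, s$events$points_after)
  expect_equal(s2$trials$banked_points, s$trials$banked_points)
  expect_equal(s2$grand_total_points, s$grand_total_points)
  expect_equal(s2$participant_id, s$participant_id)

  # malformed numeric cell is reported with its row
  ev_path <- file.path(dir, "events.csv")
  lines <- readLines(ev_path)
  lines[2] <- sub("^[0-9]+", "not_a_number", lines[2])
  writeLines(lines, ev_path)
  expect_error(read_session(dir), "parse error.*row 1")

  # truncated file (header cut mid-way, columns missing) is a parse error
  writeLines(substr(lines[1], 1, 30), ev_path)
  expect_error(read_session(dir), "parse error")

  # a 0-trial session still writes valid files with headers
  s0 <- run_session(d[0, ], make_policy("always_quit"),
                    engine_config("hot", seed = 1))
  dir0 <- withr::local_tempdir()
  write_session(s0, dir0)
  s0b <- read_session(dir0)
  expect_equal(nrow(s0b$events), 0L)
  expect_equal(s0b$grand_total_points, 0L)
})
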