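test_that("winsorize_upper caps only the upper tail at mean + k SD", {
  expect_equal(winsorize_upper(rep(4, 10)), rep(4, 10))
  x <- c(rep(0, 10), 10)
  cap <- mean(x) + 3 * sd(x)
  out <- winsorize_upper(x)
  expect_equal(out, c(rep(0, 10), cap))
  # property: max(output) <= cap of the input, lower tail untouched
  for (seed in 1:5) {
    v <- withr::with_seed(seed, rlnorm(200, 0, 1.5))
    w <- winsorize_upper(v)
    expect_lte(max(w), mean(v) + 3 * sd(v))
    expect_equal(w[v <= mean(v)], v[v <= mean(v)])
  }
  expect_error(winsorize_upper(3), "at least 2")
})

test_that("log_shift_transform is the zero-preserving monotone log(x+1)", {
  expect_equal(log_shift_transform(0), 0)
  expect_equal(log_shift_transform(exp(1) - 1), 1)
  v <- withr::with_seed(2, rpois(100, 3))
  expect_equal(order(log_shift_transform(v)), order(v))
  expect_error(log_shift_transform(c(1, -0.1)), ">= 0")
})

test_that("holm_sidak_adjust reproduces the brute-force step-down procedure", {
  # single hypothesis: adjusted p equals p
  expect_equal(holm_sidak_adjust(0.03)$p_adj, 0.03)
  # all p = 1: nothing rejected
  res1 <- holm_sidak_adjust(rep(1, 5))
  expect_true(all(res1$p_adj == 1) && !any(res1$reject))
  # m = 3: first critical value is 1 - 0.95^(1/3)
  crit1 <- 1 - 0.95^(1 / 3)
  expect_true(holm_sidak_adjust(c(crit1 - 1e-6, 0.9, 0.9))$reject[1])
  expect_false(holm_sidak_adjust(c(crit1 + 1e-6, 0.9, 0.9))$reject[1])
  # adjusted p of the smallest of m is 1-(1-p)^m
  p <- c(0.011, 0.2, 0.04, 0.9)
  expect_equal(holm_sidak_adjust(p)$p_adj[1], 1 - (1 - 0.011)^4)
  # random p-vectors against the explicit ordered-loop oracle
  withr::with_seed(42, {
    for (i in 1:200) {
      m <- sample(1:20, 1)
      pv <- runif(m)  # continuous: tie-free, so both tie conventions agree
      expect_identical(holm_sidak_adjust(pv)$reject, holm_sidak_oracle(pv),
                       label = paste("case", i))
    }
  })
})

test_that("build_model_terms counts the factorial term structure", {
  terms <- build_model_terms()
  expect_equal(nrow(terms), 21L)
  expect_equal(terms$df[terms$term == "picture_type"], 3L)
  expect_equal(sum(grepl(":", terms$term)), 15L)
  expect_equal(sum(grepl("delay", terms$term)), 6L)
  expect_true(all(terms$df[grepl("picture_type", terms$term)] == 3L))
  small <- build_model_terms(c(a = 2L, b = 2L), delay = FALSE)
  expect_equal(nrow(small), 3L)
  expect_equal(small$term, c("a", "b", "a:b"))
})

test_that("the estimating-equation solver matches independent oracles", {
  # fixture regenerated deterministically; frozen reference values computed
  # with an external GEE implementation (statsmodels 0.14, exchangeable and
  # independence working correlations) on the identical CSV payload
  set.seed(12345)
  n <- 30; k <- 8
  id <- rep(1:n, each = k)
  x1 <- rep(rep(c(-1, 1), each = 4), n)
  x2 <- rep(rep(c(-1, 1), 4), n)
  b_i <- rep(rnorm(n, 0, 0.8), each = k)
  y <- 1 + 0.5 * x1 - 0.3 * x2 + 0.2 * x1 * x2 + b_i + rnorm(n * k, 0, 0.6)
  X <- cbind(1, x1, x2, x1 * x2)

  fit <- aprt:::gee_fit(X, y, id, corstr = "exchangeable")
  expect_equal(unname(fit$beta),
               c(1.1319743884, 0.4868221167, -0.3426999953, 0.1905950025),
               tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(fit$vbeta))),
               c(0.1489248842, 0.0422830315, 0.0300545748, 0.0463169079),
               tolerance = 1e-8)

  # independence working correlation: beta is OLS and the sandwich can be
  # assembled from first principles right here
  fi <- aprt:::gee_fit(X, y, id, corstr = "independence")
  beta_ols <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fi$beta), unname(drop(beta_ols)), tolerance = 1e-10)
  res <- y - X %*% beta_ols
  B <- crossprod(X)
  M <- matrix(0, 4, 4)
  for (i in 1:n) {
    sel <- id == i
    u <- crossprod(X[sel, ], res[sel])
    M <- M + tcrossprod(u)
  }
  V <- solve(B) %*% M %*% solve(B)
  expect_equal(unname(fi$vbeta), unname(V), tolerance = 1e-10)

  # contract errors
  expect_error(aprt:::gee_fit(cbind(X, x1), y, id), "singular")
  expect_error(aprt:::gee_fit(X[1:8, ], y[1:8], id[1:8]), "2 clusters")
  expect_warning(aprt:::gee_fit(X[1:32, ], y[1:32], id[1:32],
                                corstr = "unstructured"),
                 "falling back to exchangeable")
})

test_that("fit_factorial_effects detects an injected effect and keeps 21 terms", {
  panel <- synth_panel(60, effects = list(injury_prob = 0.6), seed = 31)
  fit <- fit_factorial_effects(panel, corstr = "exchangeable")
  eff <- fit$effects
  expect_equal(nrow(eff), 21L)
  expect_equal(eff$df[eff$term == "picture_type"], 3L)
  ip <- eff[eff$term == "injury_prob", ]
  expect_true(ip$reject_adj)
  expect_lt(ip$p_adj, 1e-6)
  # the injected effect dwarfs every null term
  expect_gt(ip$wald, max(eff$wald[eff$term != "injury_prob"]))
  # transforms change statistics, never the term count
  panel_t <- panel
  panel_t$value <- winsorize_upper(panel_t$value - min(panel_t$value))
  fit_t <- fit_factorial_effects(panel_t, corstr = "exchangeable")
  expect_equal(nrow(fit_t$effects), 21L)
  # single participant is an error
  one <- panel[panel$participant == "p001", ]
  expect_error(fit_factorial_effects(one, corstr = "exchangeable"),
               "at least 2 participants")
})

test_that("unstructured requests fall back for small panels with a warning", {
  panel <- synth_panel(20, seed = 7)
  expect_warning(fit <- fit_factorial_effects(panel, corstr = "unstructured"),
                 "falling back to exchangeable")
  expect_equal(fit$fit$corstr, "exchangeable")
})

test_that("decompose_interaction recovers simple effects with correct signs", {
  # crossover: injury_prob effect +1 when injury_mag low, -1 when high
  panel <- synth_panel(80, seed = 13)
  hi_im <- panel$injury_mag == "high"
  hi_ip <- panel$injury_prob == "high"
  panel$value <- panel$value + ifelse(hi_im, -1, 1) * ifelse(hi_ip, 1, 0)
  fit <- fit_factorial_effects(panel, corstr = "exchangeable")
  expect_true(fit$effects$reject_adj[fit$effects$term ==
                                      "injury_mag:injury_prob"])
  dec <- decompose_interaction(fit, "injury_mag:injury_prob")
  im_rows <- dec[dec$within == "injury_mag", ]
  expect_equal(nrow(im_rows), 2L)
  d_low <- im_rows[im_rows$within_level == "low", ]
  d_high <- im_rows[im_rows$within_level == "high", ]
  expect_true(d_low$reject && d_high$reject)
  # opposite-signed simple effects (mean_2 - mean_1 for high-vs-low contrast)
  expect_gt(d_low$mean_2 - d_low$mean_1, 0.5)
  expect_lt(d_high$mean_2 - d_high$mean_1, -0.5)

  # additive panel: simple effects agree within Monte-Carlo error
  pan_add <- synth_panel(80, effects = list(injury_prob = 0.5), seed = 14)
  fit_add <- fit_factorial_effects(pan_add, corstr = "exchangeable")
  dec_add <- decompose_interaction(fit_add, "injury_mag:injury_prob")
  rows <- dec_add[dec_add$within == "injury_mag", ]
  est <- rows$mean_2 - rows$mean_1
  expect_lt(abs(diff(est)), 4 * sqrt(sum(rows$se_1^2 + rows$se_2^2)))

  # term-name ordering is free; main effects and absent terms are errors
  expect_equal(nrow(decompose_interaction(fit, "injury_prob:injury_mag")), 4L)
  expect_error(decompose_interaction(fit, "injury_mag"), "two-way interaction")
  expect_error(decompose_interaction(fit, "injury_mag:banana"), "not in the fitted model")
})

test_that("interactions with the picture factor decompose into the two contrasts", {
  panel <- synth_panel(60, seed = 17)
  # hero trials respond to injury_prob, others do not
  sel <- panel$picture_type == "hero" & panel$injury_prob == "high"
  panel$value[sel] <- panel$value[sel] + 1.2
  fit <- fit_factorial_effects(panel, corstr = "exchangeable")
  dec <- decompose_interaction(fit, "picture_type:injury_prob")
  # conditioning on injury_prob level, contrasts are animal-cliff and
  # disaster-hero
  byp <- dec[dec$within == "injury_prob", ]
  expect_setequal(unique(byp$contrast), c("animal_cliff", "disaster_hero"))
  dh_high <- byp[byp$contrast == "disaster_hero" &
                   byp$within_level == "high", ]
  expect_true(dh_high$reject)
  expect_gt(dh_high$mean_2 - dh_high$mean_1, 0.6)  # hero exceeds disaster
  dh_low <- byp[byp$contrast == "disaster_hero" & byp$within_level == "low", ]
  expect_false(dh_low$reject)
})

test_that("correlation screens adjust within (score, family, arm) families", {
  ch <- generate_cohort(cohort_spec(n = 60, seed = 23))
  scores <- data.frame(
    participant_id = paste0("p", ch$id),
    arm = ch$arm,
    go_presses__total = ch$theta * 2 + withr::with_seed(3, rnorm(60, 0, 0.1)),
    stringsAsFactors = FALSE)
  scores$self_copy <- scores$go_presses__total
  fams <- list(convergent = c("conv_1", "conv_2", "conv_3"),
               divergent = c("div_1", "div_2", "div_3"))
  rep <- correlation_families(scores, ch, fams,
                              score_cols = "go_presses__total")
  expect_equal(nrow(rep), 12L)  # 6 scales x 2 arms
  expect_true(all(rep$n >= 4))
  # adjustment happens within each (score, family, arm) cell
  for (key in split(rep, paste(rep$score, rep$family, rep$arm))) {
    manual <- holm_sidak_adjust(key$p)
    expect_equal(key$p_adj, manual$p_adj)
    expect_equal(key$reject, manual$reject)
  }
  # a scale identical to the score correlates perfectly
  ch2 <- ch
  ch2$conv_1 <- scores$go_presses__total
  rep2 <- correlation_families(scores, ch2, fams,
                               score_cols = "go_presses__total")
  expect_equal(rep2$r[rep2$scale == "conv_1"], c(1, 1), tolerance = 1e-12)
  # constant columns are flagged, not dropped silently
  ch3 <- ch
  ch3$div_1 <- 1
  rep3 <- correlation_families(scores, ch3, fams,
                               score_cols = "go_presses__total")
  expect_true(all(rep3$flag[rep3$scale == "div_1"] == "constant"))
  # families must partition the scales
  expect_error(correlation_families(scores, ch,
                                    list(a = "conv_1", b = "conv_1")),
               "partition")
  # too-small arms are rejected
  expect_error(correlation_families(scores[1:5, ], ch[1:5, ], fams,
                                    score_cols = "go_presses__total"),
               "n >= 4")
})

test_that("panels built from sessions are balanced and transform correctly", {
  d <- default_design()
  ch <- generate_cohort(cohort_spec(n = 6, seed = 29))
  sessions <- simulate_cohort(ch, d)
  panel <- build_panel(sessions, d, "go_presses", log_transform = TRUE)
  expect_equal(nrow(panel), 6 * 64)
  expect_true(all(table(panel$participant) == 64))
  expect_true(all(panel$value >= 0))
  counts <- table(panel$participant, panel$injury_prob)
  expect_true(all(counts == 32))
  # each participant sits in exactly one arm
  expect_equal(nrow(unique(panel[, c("participant", "delay")])), 6L)
})
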