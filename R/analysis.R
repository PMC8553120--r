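WITHIN_FACTORS <- c("picture_type", "injury_mag", "injury_prob",
                    "reward_mag", "reward_prob")

#' Build the long-format analysis panel
#'
#' One row per participant x design cell (the unit entering the marginal
#' model), carrying the five within-subject factors, the between-subject
#' delay arm and the chosen outcome.
#'
#' @param sessions list of `aprt_session` logs.
#' @param design the common `aprt_design`.
#' @param outcome one of `points`, `go_presses`, `injuries`,
#'   `remaining_health`.
#' @param winsorize_k Winsorize the outcome (upper tail, mean + k SD across
#'   all rows) before modeling; `NULL` skips.
#' @param log_transform apply [log_shift_transform()] after Winsorizing
#'   (used for the skewed press and injury counts).
#' @return a data.frame of class `aprt_panel` with columns `participant`,
#'   `delay`, the five factors and `value`, ordered by participant and
#'   cell.
#' @export
build_panel <- function(sessions, design, outcome,
                        winsorize_k = 3, log_transform = FALSE) {
  stopifnot(outcome %in% OUTCOMES)
  rows <- lapply(sessions, function(s) {
    ts <- score_session(s, design)
    data.frame(
      participant = s$participant_id,
      delay = if (s$mode == "cool") "delay" else "no_delay",
      picture_type = ts$picture_category,
      injury_mag = ts$injury_mag_level,
      injury_prob = ts$injury_prob_level,
      reward_mag = ts$reward_mag_level,
      reward_prob = ts$reward_prob_level,
      value = ts[[outcome]],
      stringsAsFactors = FALSE
    )
  })
  panel <- do.call(rbind, rows)
  if (isTRUE(log_transform)) panel$value <- log_shift_transform(panel$value)
  if (!is.null(winsorize_k)) panel$value <- winsorize_upper(panel$value, winsorize_k)
  panel <- panel[order(panel$participant, panel$picture_type, panel$injury_mag,
                       panel$injury_prob, panel$reward_mag, panel$reward_prob), ]
  rownames(panel) <- NULL
  structure(panel, class = c("aprt_panel", "data.frame"), outcome = outcome)
}

#' Model term list of the factorial analysis
#'
#' All main effects, all two-way interactions among the within-subject
#' factors, and each within-subject factor's interaction with the
#' between-subject delay factor: 6 + choose(5, 2) + 5 = 21 terms at the
#' default design. Term df is the product of (levels - 1) over the factors
#' involved (picture terms have df 3).
#'
#' @param factors named integer vector of within-subject factor level
#'   counts (defaults to the five task factors).
#' @param delay include the between-subject delay factor and its
#'   interactions.
#' @return data.frame with `term` and `df`, in model order.
#' @export
build_model_terms <- function(factors = c(picture_type = 4L, injury_mag = 2L,
                                          injury_prob = 2L, reward_mag = 2L,
                                          reward_prob = 2L),
                              delay = TRUE) {
  nm <- names(factors)
  terms <- data.frame(term = nm, df = unname(factors) - 1L,
                      stringsAsFactors = FALSE)
  if (delay) terms <- rbind(terms, data.frame(term = "delay", df = 1L))
  if (length(nm) >= 2L) {
    for (pair in utils::combn(nm, 2L, simplify = FALSE)) {
      terms <- rbind(terms, data.frame(
        term = paste(pair, collapse = ":"),
        df = (factors[[pair[1]]] - 1L) * (factors[[pair[2]]] - 1L)))
    }
  }
  if (delay) {
    for (f in nm) {
      terms <- rbind(terms, data.frame(term = paste(f, "delay", sep = ":"),
                                       df = factors[[f]] - 1L))
    }
  }
  rownames(terms) <- NULL
  terms
}

# panel -> model matrix with sum-to-zero coding + term/column bookkeeping
panel_design <- function(panel, delay = NULL) {
  if (is.null(delay)) delay <- length(unique(panel$delay)) > 1L
  fac <- WITHIN_FACTORS[WITHIN_FACTORS %in% names(panel)]
  d <- panel
  d$picture_type <- factor(d$picture_type,
                           levels = sort(unique(d$picture_type)))
  for (f in setdiff(fac, "picture_type"))
    d[[f]] <- factor(d[[f]], levels = c("low", "high"))
  rhs <- sprintf("(%s)^2", paste(fac, collapse = " + "))
  if (delay) {
    d$delay <- factor(d$delay, levels = c("no_delay", "delay"))
    rhs <- sprintf("%s + delay + delay:(%s)", rhs, paste(fac, collapse = " + "))
  }
  fml <- stats::as.formula(paste("value ~", rhs))
  contr <- stats::setNames(rep(list("contr.sum"), length(fac) + delay),
                           c(fac, if (delay) "delay"))
  mf <- stats::model.frame(fml, d)
  mm <- stats::model.matrix(fml, mf, contrasts.arg = contr)
  tt <- stats::terms(fml)
  labels <- attr(tt, "term.labels")
  asgn <- attr(mm, "assign")
  term_cols <- lapply(seq_along(labels), function(i) which(asgn == i))
  names(term_cols) <- labels
  list(X = mm, term_cols = term_cols, labels = labels, data = d,
       formula = fml, contrasts = contr, delay = delay)
}

# canonical term name: same factors in any order
match_term <- function(term, labels) {
  want <- sort(strsplit(term, ":", fixed = TRUE)[[1]])
  hit <- which(vapply(labels, function(l)
    identical(sort(strsplit(l, ":", fixed = TRUE)[[1]]), want), logical(1)))
  if (!length(hit)) return(NA_integer_)
  hit[[1]]
}

#' Fit the factorial effect table
#'
#' Fits the marginal model of the outcome on all main effects, within
#' two-way interactions and within x delay interactions, with participants
#' as clusters, and reports a robust Wald chi-square per term, the raw
#' p-value and the Holm-Sidak adjusted p-value across all terms.
#'
#' The paper-analysis default is an unstructured working correlation over
#' the 64 repeated cells, which requires more participants than cells;
#' with fewer the fit falls back to an exchangeable structure (warning).
#'
#' @param panel an `aprt_panel` from [build_panel()] (already transformed).
#' @param corstr working correlation passed to the solver.
#' @param alpha nominal family-wise error rate of the adjusted decisions.
#' @return an object of class `aprt_effects`: the effect table
#'   (`$effects`: term, df, wald, p, p_adj, reject_raw, reject_adj) plus
#'   the underlying fit and design, for decomposition.
#' @export
fit_factorial_effects <- function(panel, corstr = c("unstructured",
                                                    "exchangeable",
                                                    "independence"),
                                  alpha = 0.05) {
  corstr <- match.arg(corstr)
  pd <- panel_design(panel)
  n_per <- table(panel$participant)
  if (length(n_per) < 2L)
    stop("factorial analysis needs at least 2 participants")
  if (pd$delay) {
    arm_n <- table(unique(panel[, c("participant", "delay")])$delay)
    if (any(arm_n < 2L))
      stop("factorial analysis needs at least 2 participants per delay arm")
  }
  fit <- gee_fit(pd$X, pd$data$value, pd$data$participant, corstr = corstr)
  rows <- lapply(pd$labels, function(l) {
    w <- gee_wald(fit, pd$term_cols[[l]])
    data.frame(term = l, df = w$df, wald = w$wald, p = w$p,
               stringsAsFactors = FALSE)
  })
  eff <- do.call(rbind, rows)
  adj <- holm_sidak_adjust(eff$p, alpha = alpha)
  eff$p_adj <- adj$p_adj
  eff$reject_raw <- eff$p < alpha
  eff$reject_adj <- adj$reject
  rownames(eff) <- NULL
  structure(list(effects = eff, fit = fit, design = pd, alpha = alpha,
                 outcome = attr(panel, "outcome")),
            class = "aprt_effects")
}

#' @export
print.aprt_effects <- function(x, ...) {
  cat(sprintf("<aprt_effects> outcome: %s | working correlation: %s | %d clusters\n",
              x$outcome %||% "?", x$fit$corstr, x$fit$n_clusters))
  df <- x$effects
  df$wald <- round(df$wald, 2)
  df$p <- signif(df$p, 3)
  df$p_adj <- signif(df$p_adj, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

# estimated marginal mean row vector for fixed factor settings, averaging
# the model matrix over a full reference grid of the remaining factors
emm_vector <- function(pd, at) {
  grid <- list(picture_type = levels(pd$data$picture_type),
               injury_mag = c("low", "high"), injury_prob = c("low", "high"),
               reward_mag = c("low", "high"), reward_prob = c("low", "high"))
  if (pd$delay) grid$delay <- c("no_delay", "delay")
  for (nm in names(at)) grid[[nm]] <- at[[nm]]
  ref <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (f in names(grid)) {
    lev <- if (f == "picture_type") levels(pd$data$picture_type)
           else if (f == "delay") c("no_delay", "delay") else c("low", "high")
    ref[[f]] <- factor(ref[[f]], levels = lev)
  }
  ref$value <- 0
  mm <- stats::model.matrix(pd$formula, stats::model.frame(pd$formula, ref),
                            contrasts.arg = pd$contrasts)
  colMeans(mm)
}

# contrast pairs used when one side of an interaction is the picture factor
picture_contrasts <- function() {
  list(animal_cliff = c("animal", "cliff"), disaster_hero = c("disaster", "hero"))
}

#' Decompose a fitted two-way interaction into simple effects
#'
#' For each level of one factor of the interaction, tests the df-1 Wald
#' contrast of the other factor's levels (for the picture factor, the
#' Animal-Cliff and Disaster-Hero contrasts), with means and robust SEs of
#' the marginal cells and a Holm-Sidak adjustment within the decomposition
#' family.
#'
#' @param effects an `aprt_effects` fit.
#' @param term the interaction term, e.g. `"injury_mag:injury_prob"`
#'   (factor order free).
#' @param alpha family-wise error rate within the decomposition.
#' @return data.frame, one row per simple effect: the conditioning factor
#'   and level, the contrasted pair with marginal means and SEs, Wald
#'   chi-square (df 1), raw and adjusted p, reject flag.
#' @export
decompose_interaction <- function(effects, term, alpha = 0.05) {
  stopifnot(inherits(effects, "aprt_effects"))
  pd <- effects$design
  i <- match_term(term, pd$labels)
  if (is.na(i)) stop("term '", term, "' is not in the fitted model")
  label <- pd$labels[[i]]
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("'", term, "' is not a two-way interaction term")
  fit <- effects$fit
  rows <- list()
  level_sets <- function(f) {
    if (f == "picture_type") picture_contrasts()
    else if (f == "delay") list(delay = c("no_delay", "delay"))
    else stats::setNames(list(c("low", "high")), f)
  }
  cond_levels <- function(f) {
    if (f == "picture_type") levels(pd$data$picture_type)
    else if (f == "delay") c("no_delay", "delay") else c("low", "high")
  }
  for (ord in list(parts, rev(parts))) {
    v1 <- ord[1]; v2 <- ord[2]
    for (l1 in cond_levels(v1)) {
      for (cname in names(level_sets(v2))) {
        pair <- level_sets(v2)[[cname]]
        at1 <- stats::setNames(list(l1, pair[1]), c(v1, v2))
        at2 <- stats::setNames(list(l1, pair[2]), c(v1, v2))
        L1 <- emm_vector(pd, at1)
        L2 <- emm_vector(pd, at2)
        m1 <- drop(L1 %*% fit$beta); m2 <- drop(L2 %*% fit$beta)
        se1 <- sqrt(drop(t(L1) %*% fit$vbeta %*% L1))
        se2 <- sqrt(drop(t(L2) %*% fit$vbeta %*% L2))
        cc <- L2 - L1
        W <- drop(cc %*% fit$beta)^2 / drop(t(cc) %*% fit$vbeta %*% cc)
        rows[[length(rows) + 1L]] <- data.frame(
          term = label, within = v1, within_level = l1,
          contrast = if (v2 == "picture_type") cname else v2,
          level_1 = pair[1], mean_1 = m1, se_1 = se1,
          level_2 = pair[2], mean_2 = m2, se_2 = se2,
          wald = W, df = 1L, p = stats::pchisq(W, 1, lower.tail = FALSE),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  adj <- holm_sidak_adjust(out$p, alpha = alpha)
  out$p_adj <- adj$p_adj
  out$reject <- adj$reject
  rownames(out) <- NULL
  out
}

#' Family-wise correlation screen
#'
#' Pearson correlations between task score columns and self-report scale
#' columns, computed within each delay arm, with a Holm-Sidak correction
#' applied separately within each (score column, family, arm) family of
#' correlations (the convergent/divergent-validity screen).
#'
#' @param scores an `aprt_scores` table (has `participant_id`, `arm`).
#' @param participants a cohort table with `id` and the scale columns
#'   (participant `p<id>` matches score rows).
#' @param families named list partitioning the scale columns into
#'   correlation families, e.g. `list(convergent = ..., divergent = ...)`.
#' @param score_cols score columns to screen (default: the six Go-Press
#'   difference scores and the Go-Press total).
#' @param by_arm compute within each arm (default) or pooled.
#' @param alpha family-wise error rate per family.
#' @return data.frame of class `aprt_correlations`: score, scale, family,
#'   arm, n, r, p, p_adj, reject, flag (`"constant"` when r is undefined).
#' @export
correlation_families <- function(scores, participants, families,
                                 score_cols = c(paste0("go_presses__diff_",
                                                       DIFF_FACTORS),
                                                "go_presses__total"),
                                 by_arm = TRUE, alpha = 0.05) {
  sc <- as.data.frame(scores)
  pt <- as.data.frame(participants)
  scales <- unlist(families, use.names = FALSE)
  if (anyDuplicated(scales))
    stop("correlation families must partition the scale list")
  missing <- setdiff(scales, names(pt))
  if (length(missing))
    stop("scale columns not found: ", paste(missing, collapse = ", "))
  missing_sc <- setdiff(score_cols, names(sc))
  if (length(missing_sc))
    stop("score columns not found: ", paste(missing_sc, collapse = ", "))
  pt$participant_id <- paste0("p", pt$id)
  # keep only the id key and the scales so shared columns (arm, traits)
  # cannot collide in the merge
  pt <- pt[, c("participant_id", scales), drop = FALSE]
  merged <- merge(sc, pt, by = "participant_id")
  arms <- if (by_arm) unique(merged$arm) else "all"
  rows <- list()
  for (arm in arms) {
    sub <- if (by_arm) merged[merged$arm == arm, ] else merged
    if (nrow(sub) < 4L)
      stop("correlation screen needs n >= 4 per arm (arm '", arm, "' has ",
           nrow(sub), ")")
    for (col in score_cols) {
      for (fam in names(families)) {
        for (scale in families[[fam]]) {
          x <- sub[[col]]; yv <- sub[[scale]]
          if (stats::sd(x) == 0 || stats::sd(yv) == 0) {
            rows[[length(rows) + 1L]] <- data.frame(
              score = col, scale = scale, family = fam, arm = arm,
              n = nrow(sub), r = NA_real_, p = NA_real_,
              flag = "constant", stringsAsFactors = FALSE)
          } else {
            ct <- stats::cor.test(x, yv, method = "pearson")
            rows[[length(rows) + 1L]] <- data.frame(
              score = col, scale = scale, family = fam, arm = arm,
              n = nrow(sub), r = unname(ct$estimate), p = ct$p.value,
              flag = "", stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  out$reject <- FALSE
  for (key in unique(paste(out$score, out$family, out$arm))) {
    sel <- paste(out$score, out$family, out$arm) == key
    adj <- holm_sidak_adjust(out$p[sel], alpha = alpha)
    out$p_adj[sel] <- adj$p_adj
    out$reject[sel] <- adj$reject
  }
  rownames(out) <- NULL
  structure(out, class = c("aprt_correlations", "data.frame"))
}
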