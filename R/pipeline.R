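#' Load a pipeline configuration file
#'
#' JSON or YAML with up to three sections: `factors` (task factor
#' configuration; fields of [aprt_config()]), `engine` (fields of
#' [engine_config()] except `mode`/`seed`) and `cohort` (fields of
#' [cohort_spec()] except `seed`). Missing sections and fields take the
#' task's published defaults; unknown keys are rejected with their path.
#'
#' @param path config file (`.json`, `.yaml`/`.yml`); an empty or absent
#'   body yields all defaults.
#' @return list of class `aprt_run_config` with `factors` (an
#'   `aprt_config`), `engine` (named list of overrides) and `cohort`
#'   (named list of overrides).
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  parse_run_config(raw)
}

parse_run_config <- function(raw) {
  known_top <- c("factors", "engine", "cohort")
  extra <- setdiff(names(raw), known_top)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))

  fa <- raw$factors %||% list()
  extra <- setdiff(names(fa), names(formals(aprt_config)))
  if (length(extra))
    stop("unknown config key(s): ", paste0("factors.", extra, collapse = ", "))
  # nested magnitude ranges may arrive as lists; coerce shape then validate
  for (nm in c("injury_mag_range", "reward_mag_range"))
    if (!is.null(fa[[nm]])) fa[[nm]] <- lapply(fa[[nm]], unlist)
  for (nm in c("injury_prob", "reward_prob"))
    if (!is.null(fa[[nm]])) fa[[nm]] <- unlist(fa[[nm]])
  factors <- do.call(aprt_config, fa)

  en <- raw$engine %||% list()
  allowed <- c("delay_ms", "points_floor_at_zero", "press_cap",
               "response_latency_ms")
  extra <- setdiff(names(en), allowed)
  if (length(extra))
    stop("unknown config key(s): ", paste0("engine.", extra, collapse = ", "))

  co <- raw$cohort %||% list()
  allowed <- setdiff(names(formals(cohort_spec)), "seed")
  extra <- setdiff(names(co), allowed)
  if (length(extra))
    stop("unknown config key(s): ", paste0("cohort.", extra, collapse = ", "))
  if (!is.null(co$n) && co$n < 1) stop("cohort.n must be >= 1")

  structure(list(factors = factors, engine = en, cohort = co),
            class = "aprt_run_config")
}

#' @rdname load_config
#' @param config an `aprt_run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "aprt_run_config"))
  factors <- unclass(config$factors)
  # jsonlite drops names of atomic vectors; store prob levels as objects
  for (nm in c("injury_prob", "reward_prob"))
    factors[[nm]] <- as.list(factors[[nm]])
  payload <- list(factors = factors,
                  engine = config$engine, cohort = config$cohort)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead")
    yaml::write_yaml(payload, path, precision = 15L)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Run the full pipeline
#'
#' design -> cohort -> simulate -> score -> analyze, writing every CSV
#' artifact plus a JSON run manifest into `out_dir`. Analysis failures
#' (e.g. too few participants) do not destroy the earlier simulation
#' artifacts: the error is recorded in the manifest and raised as a
#' warning.
#'
#' @param config an `aprt_run_config` (default: all published defaults).
#' @param out_dir output directory (created).
#' @param seed master seed; design, cohort and engine seeds derive from it.
#' @param n cohort size (overrides `config$cohort$n`; default 20).
#' @return the run manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config = parse_run_config(list()), out_dir, seed,
                         n = NULL) {
  stopifnot(inherits(config, "aprt_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "design"
  files <- character(0)
  errors <- list()
  emit <- function(f) files[[length(files) + 1L]] <<- f

  design <- generate_design(config$factors, seed = derive_seed(seed, "design"))
  write_design(design, file.path(out_dir, "design.csv")); emit("design.csv")

  stage <- "cohort"
  co_args <- config$cohort
  co_args$n <- n %||% co_args$n %||% 20L
  co_args$seed <- derive_seed(seed, "cohort")
  cohort <- generate_cohort(do.call(cohort_spec, co_args))
  write_cohort(cohort, file.path(out_dir, "participants.csv")); emit("participants.csv")

  stage <- "simulate"
  delay_ms <- config$engine$delay_ms %||% 1500L
  sessions <- simulate_cohort(cohort, design, delay_ms = delay_ms)
  events <- do.call(rbind, lapply(sessions, function(s)
    cbind(participant_id = s$participant_id, s$events)))
  trials <- do.call(rbind, lapply(sessions, function(s)
    cbind(participant_id = s$participant_id, s$trials)))
  utils::write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
  emit("events.csv")
  utils::write.csv(trials, file.path(out_dir, "trials.csv"), row.names = FALSE)
  emit("trials.csv")

  stage <- "score"
  scores <- score_table(sessions, design)
  write_scores(scores, file.path(out_dir, "scores.csv")); emit("scores.csv")

  stage <- "analyze"
  analysis_status <- "ok"
  tryCatch({
    eff_all <- do.call(rbind, lapply(OUTCOMES, function(oc) {
      panel <- build_panel(sessions, design, oc,
                           log_transform = oc %in% c("go_presses", "injuries"))
      fit <- withCallingHandlers(
        fit_factorial_effects(panel),
        warning = function(w) {
          message("[analyze] ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      cbind(outcome = oc, fit$effects)
    }))
    utils::write.csv(eff_all, file.path(out_dir, "effects.csv"),
                     row.names = FALSE)
    emit("effects.csv")
    spec <- attr(cohort, "spec")
    fams <- list(convergent = paste0("conv_", seq_len(spec$n_convergent)),
                 divergent = paste0("div_", seq_len(spec$n_divergent)))
    cors <- correlation_families(
      scores, cohort, fams,
      score_cols = c(paste0("go_presses__diff_", DIFF_FACTORS), "go_presses__total",
                     paste0("points__diff_", DIFF_FACTORS), "points__total"))
    utils::write.csv(cors, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    emit("correlations.csv")
  }, error = function(e) {
    analysis_status <<- paste0("failed: ", conditionMessage(e))
    errors[["analyze"]] <<- conditionMessage(e)
  })

  stage <- "manifest"
  cfg_path <- file.path(out_dir, "config.json")
  save_config(config, cfg_path); emit("config.json")
  inventory <- lapply(files, function(f) {
    list(file = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("aprt")),
    r_version = R.version.string,
    seed = seed,
    seeds = list(design = derive_seed(seed, "design"),
                 cohort = derive_seed(seed, "cohort")),
    n = co_args$n,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = list(analyze = analysis_status),
    files = inventory,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(errors))
    warning("pipeline stage 'analyze' failed: ", errors[["analyze"]])
  invisible(manifest)
}
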