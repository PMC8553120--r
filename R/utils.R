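# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

# Deterministic sub-stream seeds. Keeps every derived seed inside the 32-bit
# signed-integer range R requires of set.seed().
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(salt))) {
    s <- (s * 31 + ch) %% 2147483629
  }
  as.integer(s %% 2147483647)
}

# run `expr` with the global RNG seeded, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

abort_config <- function(field, msg) {
  stop(structure(
    class = c("aprt_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field '%s': %s", field, msg),
         call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
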