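#' Upper one-sided Winsorizing at mean + k SD
#'
#' Single pass: the cap `mean(x) + k * sd(x)` is computed on the input
#' vector and every value above it is replaced by the cap. The lower tail
#' is untouched; a zero-variance vector is returned unchanged.
#'
#' @param values numeric vector (finite).
#' @param k number of standard deviations above the mean (default 3).
#' @return the capped vector.
#' @export
winsorize_upper <- function(values, k = 3) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (length(values) < 2L) stop("winsorize_upper needs at least 2 values")
  s <- stats::sd(values)
  if (s == 0) return(values)
  cap <- mean(values) + k * s
  pmin(values, cap)
}

#' Shifted log transform
#'
#' `log(x + 1)`: monotone, zero-preserving, defined for the zero-inflated
#' press and injury counts.
#'
#' @param values nonnegative numeric vector.
#' @return transformed vector.
#' @export
log_shift_transform <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop("log_shift_transform requires values >= 0")
  log1p(values)
}

#' Holm-Sidak (sequential Sidak) step-down adjustment
#'
#' Orders the m p-values ascending and adjusts the i-th smallest to
#' `1 - (1 - p_(i))^(m - i + 1)`, enforcing monotonicity by a running
#' maximum; hypotheses are rejected step-down while the adjusted p-value
#' stays at or below `alpha`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha nominal family-wise error rate (default 0.05).
#' @return a data.frame (input order) with `p`, `p_adj`, `reject`.
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_sidak_adjust <- function(p, alpha = 0.05) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  out <- data.frame(p = p, p_adj = NA_real_, reject = FALSE)
  if (!m) return(out)
  ok <- which(!is.na(p))
  ord <- ok[order(p[ok])]
  mm <- length(ord)
  # 1 - (1 - p)^k computed stably for tiny p
  adj <- -expm1((mm - seq_len(mm) + 1) * log1p(-p[ord]))
  adj <- cummax(pmin(adj, 1))
  rej <- logical(mm)
  for (i in seq_len(mm)) {
    if (adj[i] <= alpha) rej[i] <- TRUE else break
  }
  out$p_adj[ord] <- adj
  out$reject[ord] <- rej
  out
}
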