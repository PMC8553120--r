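# Gaussian marginal-model (estimating-equation) solver.
#
# Identity link, balanced clusters, working correlation shared across
# clusters. Coefficients solve the weighted estimating equations by
# iterated generalized least squares; inference uses the robust sandwich
# covariance, so Wald tests stay valid when the working correlation is
# misspecified.

gee_control <- function(maxit = 50L, tol = 1e-8) list(maxit = maxit, tol = tol)

#' Fit a Gaussian marginal model with a working correlation
#'
#' @param X model matrix (all clusters stacked; rows of one cluster must be
#'   contiguous and in a common within-cluster order).
#' @param y response vector.
#' @param id cluster identifier, one per row.
#' @param corstr working correlation: `"independence"`, `"exchangeable"`
#'   or `"unstructured"`. An unstructured matrix needs more clusters than
#'   cluster cells; otherwise (or if the estimate is not positive
#'   definite) the fit falls back to exchangeable with a warning.
#' @param control list from `gee_control()`.
#' @return list of class `aprt_gee`: `beta`, `vbeta` (robust), `R`,
#'   `corstr` (the structure actually used), `phi`, `n_clusters`,
#'   `cluster_size`, `iterations`, `converged`.
#' @keywords internal
gee_fit <- function(X, y, id, corstr = c("exchangeable", "unstructured",
                                         "independence"),
                    control = gee_control()) {
  corstr <- match.arg(corstr)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(id) == length(y))
  idx <- split(seq_along(y), factor(id, levels = unique(id)))
  n <- length(idx)
  if (n < 2L) stop("marginal model needs at least 2 clusters (participants)")
  k <- lengths(idx)
  if (length(unique(k)) != 1L)
    stop("unbalanced clusters are not supported; aggregate to a common cell grid")
  k <- k[[1]]
  p <- ncol(X)
  if (qr(X)$rank < p) stop("singular design matrix")
  if (corstr == "unstructured" && n <= k) {
    warning("unstructured working correlation needs more clusters (", n,
            ") than cells (", k, "); falling back to exchangeable")
    corstr <- "exchangeable"
  }

  beta <- qr.solve(X, y)
  R <- diag(k)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    res <- y - drop(X %*% beta)
    E <- matrix(res[unlist(idx)], nrow = n, byrow = TRUE)
    phi <- mean(E^2)
    R_new <- switch(corstr,
      independence = diag(k),
      exchangeable = {
        alpha <- (sum(rowSums(E)^2) - sum(E^2)) / (n * k * (k - 1) * phi)
        alpha <- min(max(alpha, -1 / (k - 1) + 1e-8), 1 - 1e-8)
        matrix(alpha, k, k) + diag(1 - alpha, k)
      },
      unstructured = {
        Rm <- crossprod(E) / (n * phi)
        Rm <- (Rm + t(Rm)) / 2
        diag(Rm) <- 1
        ch <- tryCatch(chol(Rm), error = function(e) NULL)
        if (is.null(ch)) {
          warning("estimated unstructured correlation is not positive ",
                  "definite; falling back to exchangeable")
          corstr <- "exchangeable"
          alpha <- (sum(rowSums(E)^2) - sum(E^2)) / (n * k * (k - 1) * phi)
          alpha <- min(max(alpha, -1 / (k - 1) + 1e-8), 1 - 1e-8)
          matrix(alpha, k, k) + diag(1 - alpha, k)
        } else Rm
      })
    R <- R_new
    Rinv <- chol2inv(chol(R))
    B <- matrix(0, p, p)
    z <- numeric(p)
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]
      XtR <- crossprod(Xi, Rinv)
      B <- B + XtR %*% Xi
      z <- z + drop(XtR %*% y[ii])
    }
    beta_new <- solve(B, z)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (corstr == "independence" && iter >= 1L) { converged <- TRUE; break }
    if (delta < control$tol) { converged <- TRUE; break }
    if (iter >= control$maxit) break
  }

  # robust sandwich covariance
  res <- y - drop(X %*% beta)
  Rinv <- chol2inv(chol(R))
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ii in idx) {
    Xi <- X[ii, , drop = FALSE]
    XtR <- crossprod(Xi, Rinv)
    B <- B + XtR %*% Xi
    u <- drop(XtR %*% res[ii])
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  vbeta <- Binv %*% M %*% Binv
  dimnames(vbeta) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(beta = beta, vbeta = vbeta, R = R, corstr = corstr,
                 phi = mean(res^2), n_clusters = n, cluster_size = k,
                 iterations = iter, converged = converged),
            class = "aprt_gee")
}

# Wald chi-square for a coefficient block
gee_wald <- function(fit, cols) {
  b <- fit$beta[cols]
  V <- fit$vbeta[cols, cols, drop = FALSE]
  W <- drop(crossprod(b, solve(V, b)))
  df <- length(cols)
  list(wald = W, df = df, p = stats::pchisq(W, df, lower.tail = FALSE))
}
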