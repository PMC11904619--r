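#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' A standard (mu/mu_w, lambda)-CMA-ES minimiser following Hansen's tutorial
#' formulation: rank-based recombination of the best half of each sampled
#' population, cumulative step-size adaptation, and rank-one plus rank-mu
#' covariance updates. This is the stochastic optimiser used for
#' maximum-likelihood fitting of the IKr models; bound constraints are
#' handled by the objective (repair plus quadratic penalty), not here.
#'
#' @param fn Objective function of a numeric vector; must return a finite
#'   scalar or `Inf`.
#' @param x0 Initial mean.
#' @param sigma0 Initial step size (in the units of `x0`).
#' @param popsize Population size lambda (default `floor(4 + 3*log(n))`).
#' @param max_evals Budget of function evaluations.
#' @param tol_fun Stop when the spread of the population's objective values
#'   and the recent best-value improvement both fall below this (relative to
#'   `1 + |best|`).
#' @param seed Optional integer seed for the internal sampling.
#' @return A list: `par`, `value`, `n_evals`, `converged`, `sigma`.
#' @export
cma_es <- function(fn, x0, sigma0 = 0.3, popsize = NULL,
                   max_evals = 10000, tol_fun = 1e-7, seed = NULL) {
  run <- function() {
    n <- length(x0)
    lambda <- popsize %||% as.integer(floor(4 + 3 * log(n)))
    lambda <- max(lambda, 4L)
    mu <- floor(lambda / 2)
    w <- log(mu + 0.5) - log(seq_len(mu))
    w <- w / sum(w)
    mu_eff <- 1 / sum(w^2)

    cc <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
    cs <- (mu_eff + 2) / (n + mu_eff + 5)
    c1 <- 2 / ((n + 1.3)^2 + mu_eff)
    cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
    damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + cs
    chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

    xmean <- x0
    sigma <- sigma0
    pc <- ps <- numeric(n)
    C <- diag(n)
    B <- diag(n)
    D <- rep(1, n)
    inv_sqrt_C <- diag(n)
    eigen_stale <- 0

    best_x <- x0
    best_f <- fn(x0)
    n_evals <- 1
    prev_best <- Inf
    converged <- FALSE

    while (n_evals + lambda <= max_evals) {
      Z <- matrix(stats::rnorm(n * lambda), n, lambda)
      Y <- B %*% (D * Z)                       # N(0, C) draws
      X <- xmean + sigma * Y
      f <- apply(X, 2, fn)
      f[!is.finite(f)] <- .Machine$double.xmax
      n_evals <- n_evals + lambda
      ord <- order(f)
      if (f[ord[1]] < best_f) {
        best_f <- f[ord[1]]
        best_x <- X[, ord[1]]
      }

      sel <- ord[seq_len(mu)]
      y_w <- as.vector(Y[, sel, drop = FALSE] %*% w)
      xmean <- xmean + sigma * y_w

      ps <- (1 - cs) * ps +
        sqrt(cs * (2 - cs) * mu_eff) * as.vector(inv_sqrt_C %*% y_w)
      hsig <- sqrt(sum(ps^2)) /
        sqrt(1 - (1 - cs)^(2 * n_evals / lambda)) / chiN < 1.4 + 2 / (n + 1)
      pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mu_eff) * y_w

      Ysel <- Y[, sel, drop = FALSE]
      C <- (1 - c1 - cmu) * C +
        c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
        cmu * (Ysel %*% (w * t(Ysel)))
      sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

      eigen_stale <- eigen_stale + lambda
      if (eigen_stale > lambda / (c1 + cmu) / n / 10) {
        eigen_stale <- 0
        C <- (C + t(C)) / 2
        eig <- eigen(C, symmetric = TRUE)
        D <- sqrt(pmax(eig$values, 1e-20))
        B <- eig$vectors
        inv_sqrt_C <- B %*% ((1 / D) * t(B))
      }

      f_spread <- f[ord[lambda]] - f[ord[1]]
      improve <- prev_best - best_f
      scale <- 1 + abs(best_f)
      if (f_spread < tol_fun * scale && improve < tol_fun * scale) {
        converged <- TRUE
        break
      }
      prev_best <- best_f
      if (sigma * max(D) < 1e-12) {
        converged <- TRUE
        break
      }
    }
    list(par = best_x, value = best_f, n_evals = n_evals,
         converged = converged, sigma = sigma)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
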