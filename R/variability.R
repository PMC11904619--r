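#' Well- and protocol-dependence of parameter estimates
#'
#' Tables of per-sweep kinetic-parameter estimates (on the `a = log(A)` and
#' `b` scales; the conductance is excluded because cell-to-cell conductance
#' variability is expected) are analysed with the two-way fixed-effects
#' linear model `Y = mu + Xd bd + Xw bw + E`, with sum-to-zero constraints
#' on both effect matrices and independent IID Gaussian errors per column.
#' Nested variants (`M0`, `Mw`, `Md`, `Mwd`) are compared by log-likelihood
#' differences: `LLD(-w) = l(Mwd) - l(Md)` measures well-dependence,
#' `LLD(-d) = l(Mwd) - l(Mw)` protocol-dependence.
#'
#' @name variability_stats
NULL

#' Build an estimate table from fitted sweeps
#'
#' Transforms each fit's kinetic parameters to the linear-model scale:
#' A-type pre-factors become `a = log(A)`, b-type exponents pass through,
#' and the maximal conductance is dropped.
#'
#' @param fits List of `ikr_fit` objects, all from the same model structure.
#' @param model The model structure.
#' @return A tibble with `well`, `protocol`, `sweep`, then one numeric
#'   column per transformed kinetic parameter (`a_*`, `b_*`).
#' @export
transform_estimates <- function(fits, model) {
  kin_names <- model$param_names[seq_len(model$n_kinetic_params)]
  is_a <- startsWith(kin_names, "A_")
  out_names <- ifelse(is_a, sub("^A_", "a_", kin_names), kin_names)
  rows <- lapply(fits, function(f) {
    if (f$model != model$name) {
      stop("All fits must come from model '", model$name, "'.", call. = FALSE)
    }
    kin <- f$theta[seq_len(model$n_kinetic_params)]
    if (any(kin[is_a] <= 0)) {
      stop("Non-positive A-type estimate cannot be log-transformed.",
           call. = FALSE)
    }
    vals <- ifelse(is_a, log(kin), kin)
    c(list(well = f$well, protocol = f$protocol, sweep = f$sweep),
      stats::setNames(as.list(unname(vals)), out_names))
  })
  tbl <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  dplyr::arrange(tbl, .data$well, .data$protocol, .data$sweep)
}

#' Sum-to-zero design matrices for well and protocol effects
#'
#' Effects (deviation) coding with one column per level minus one; the
#' dropped level is represented by -1 in every column, so expanded effects
#' sum to zero across levels by construction.
#'
#' @param wells,protocols Factors (or character vectors) of row labels.
#' @return A list: `X_w`, `X_d` (matrices, possibly zero-column),
#'   `well_levels`, `protocol_levels`.
#' @export
build_design_matrices <- function(wells, protocols) {
  one <- function(x, prefix) {
    f <- factor(x)
    lv <- levels(f)
    if (any(table(f) == 0)) stop("Level with no rows.", call. = FALSE)
    if (length(lv) < 2) {
      return(list(X = matrix(0, length(x), 0), levels = lv))
    }
    X <- stats::model.matrix(~f, contrasts.arg = list(f = "contr.sum"))[, -1,
                                                                        drop = FALSE]
    colnames(X) <- paste0(prefix, lv[-length(lv)])
    list(X = X, levels = lv)
  }
  w <- one(wells, "w_")
  d <- one(protocols, "d_")
  list(X_w = w$X, X_d = d$X,
       well_levels = w$levels, protocol_levels = d$levels)
}

# Expand reduced (contr.sum) coefficients to all levels (sum-to-zero rows).
expand_effects <- function(B_reduced, levels) {
  if (nrow(B_reduced) == 0) {
    out <- matrix(0, length(levels), ncol(B_reduced))
  } else {
    out <- rbind(B_reduced, -colSums(B_reduced))
  }
  rownames(out) <- levels
  out
}

#' Fit a variant of the two-way fixed-effects model
#'
#' Per-column ordinary least squares of the estimate table on the intercept
#' plus (depending on the variant) protocol and well effect design matrices;
#' error SDs are maximum-likelihood (`sqrt(RSS / N)`), and the total
#' log-likelihood is the sum of the per-column Gaussian log-likelihoods at
#' the MLE.
#'
#' @param table An estimate table from [transform_estimates()] (columns
#'   `well`, `protocol`, `sweep`, then numeric parameter columns).
#' @param variant One of `"M0"`, `"Mw"`, `"Md"`, `"Mwd"`.
#' @return An `ikr_effects_fit`: `mu`, `beta_w`, `beta_d` (full-level,
#'   sum-to-zero), `sigma_k`, `loglik`, `variant`, dimensions.
#' @export
fit_linear_model <- function(table, variant = c("Mwd", "Mw", "Md", "M0")) {
  variant <- match.arg(variant)
  param_cols <- setdiff(names(table), c("well", "protocol", "sweep"))
  Y <- as.matrix(table[, param_cols])
  if (anyNA(Y)) stop("Estimate table has missing cells.", call. = FALSE)
  n <- nrow(Y)
  dm <- build_design_matrices(table$well, table$protocol)
  use_w <- variant %in% c("Mw", "Mwd") && ncol(dm$X_w) > 0
  use_d <- variant %in% c("Md", "Mwd") && ncol(dm$X_d) > 0
  X <- cbind(`(mu)` = rep(1, n),
             if (use_d) dm$X_d, if (use_w) dm$X_w)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("Rank-deficient design; aliased columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrX, Y)
  resid <- Y - X %*% coefs
  rss <- colSums(resid^2)
  sigma_k <- sqrt(rss / n)
  sigma_k <- pmax(sigma_k, 1e-300)
  loglik <- sum(-n / 2 * (log(2 * pi * sigma_k^2) + 1))

  idx <- 1L
  mu <- coefs[idx, , drop = FALSE]
  rownames(mu) <- "mu"
  take <- function(k) {
    if (k == 0) return(matrix(0, 0, ncol(Y)))
    block <- coefs[seq(idx + 1L, idx + k), , drop = FALSE]
    idx <<- idx + k
    block
  }
  bd_red <- take(if (use_d) ncol(dm$X_d) else 0L)
  bw_red <- take(if (use_w) ncol(dm$X_w) else 0L)
  beta_d <- if (use_d) expand_effects(bd_red, dm$protocol_levels) else
    matrix(0, length(dm$protocol_levels), ncol(Y),
           dimnames = list(dm$protocol_levels, NULL))
  beta_w <- if (use_w) expand_effects(bw_red, dm$well_levels) else
    matrix(0, length(dm$well_levels), ncol(Y),
           dimnames = list(dm$well_levels, NULL))
  colnames(beta_d) <- colnames(beta_w) <- param_cols

  structure(list(variant = variant, mu = mu, beta_w = beta_w,
                 beta_d = beta_d, sigma_k = sigma_k, loglik = loglik,
                 n_trace = n, n_params = ncol(Y), param_names = param_cols,
                 residuals = resid),
            class = "ikr_effects_fit")
}

#' @export
print.ikr_effects_fit <- function(x, ...) {
  cat("<ikr_effects_fit> variant ", x$variant, ": ", x$n_trace,
      " estimates x ", x$n_params, " parameters, loglik = ",
      round(x$loglik, 2), "\n", sep = "")
  invisible(x)
}

#' Tidy a linear effects fit
#'
#' One row per term (intercept, well effect, protocol effect) and parameter
#' column.
#' @param x An `ikr_effects_fit`.
#' @param ... Unused.
#' @export
tidy.ikr_effects_fit <- function(x, ...) {
  stack <- function(M, type) {
    if (nrow(M) == 0) return(NULL)
    df <- tibble::as_tibble(M, rownames = "level")
    df <- tidyr::pivot_longer(df, -"level", names_to = "parameter",
                              values_to = "estimate")
    df$term <- type
    df
  }
  dplyr::bind_rows(stack(x$mu, "intercept"),
                   stack(x$beta_w, "well"),
                   stack(x$beta_d, "protocol"))[
                     , c("term", "level", "parameter", "estimate")]
}

#' One-row summary of a linear effects fit
#' @param x An `ikr_effects_fit`.
#' @param ... Unused.
#' @export
glance.ikr_effects_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant, loglik = x$loglik,
                 n_trace = x$n_trace, n_params = x$n_params,
                 mean_sigma = mean(x$sigma_k))
}

nested_pairs <- list(Mwd = c("Mw", "Md", "M0"), Mw = "M0", Md = "M0",
                     M0 = character(0))

#' Log-likelihood difference between nested variants
#'
#' `lld(full, reduced) = loglik(full) - loglik(reduced)`; `LLD(-w)` is
#' `lld(Mwd, Md)` and `LLD(-d)` is `lld(Mwd, Mw)`. Always non-negative for
#' nested least-squares fits.
#'
#' @param full,reduced `ikr_effects_fit` objects; `reduced` must be nested
#'   in `full`.
#' @return Scalar log-likelihood difference.
#' @export
lld <- function(full, reduced) {
  if (!(reduced$variant %in% nested_pairs[[full$variant]]) &&
      reduced$variant != full$variant) {
    stop("Model '", reduced$variant, "' is not nested in '",
         full$variant, "'.", call. = FALSE)
  }
  full$loglik - reduced$loglik
}

#' Full variability analysis of an estimate table
#'
#' Fits all four variants and reports their log-likelihoods and the two
#' headline LLD statistics, one row per call (rows from different model
#' structures can be bound into the standard summary table).
#'
#' @param table An estimate table from [transform_estimates()].
#' @param model_name Label for the row.
#' @return A tibble: `model`, `loglik_M0`, `loglik_Mw`, `loglik_Md`,
#'   `loglik_Mwd`, `lld_w`, `lld_d`.
#' @export
variability_analysis <- function(table, model_name = "model") {
  fits <- lapply(c("M0", "Mw", "Md", "Mwd"),
                 function(v) fit_linear_model(table, v))
  names(fits) <- c("M0", "Mw", "Md", "Mwd")
  tibble::tibble(
    model = model_name,
    loglik_M0 = fits$M0$loglik, loglik_Mw = fits$Mw$loglik,
    loglik_Md = fits$Md$loglik, loglik_Mwd = fits$Mwd$loglik,
    lld_w = lld(fits$Mwd, fits$Md),
    lld_d = lld(fits$Mwd, fits$Mw))
}
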