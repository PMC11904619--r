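#' Cross-protocol validation metrics
#'
#' Predictive accuracy is scored with the normalised root-mean-square error
#' NRMSE(y, z) = sqrt(sum((z - y)^2)) / sqrt(sum(z^2)) (RMS convention in
#' numerator and denominator, so traces of different lengths and current
#' magnitudes are comparable). Fits and predictions are collected into a
#' cross-validation table (fitting sweep x validation sweep); `E_fit`
#' averages the diagonal and `E_predict` the off-diagonal under the
#' `1/(N_d - 1)^2` normalisation. Time-resolved discrepancy is summarised by
#' noise-weighted residuals and the ensemble-consistency statistic T.
#'
#' @name validation_metrics
NULL

#' Normalised root-mean-square error
#'
#' @param y Model output.
#' @param z Data (must not be identically zero).
#' @return `sqrt(sum((z - y)^2)) / sqrt(sum(z^2))`; scale-invariant.
#' @export
nrmse <- function(y, z) {
  stopifnot(length(y) == length(z))
  denom <- sqrt(sum(z^2))
  if (denom == 0) stop("Data trace is identically zero.", call. = FALSE)
  sqrt(sum((z - y)^2)) / denom
}

#' Cross-validation table of NRMSE values
#'
#' Rows index the fitting sweeps (one fitted parameter set each; repeats of
#' the staircase protocol are distinct rows), columns index every validation
#' sweep in the postprocessed set (including the validation-only protocol).
#' Entry (d, d~) is the NRMSE between the current simulated from the row's
#' parameter estimate under the column's protocol (using the column sweep's
#' voltage offset) and that sweep's data.
#'
#' @param fits List of `ikr_fit` objects for one well.
#' @param pp The [postprocess_dataset()] result holding validation traces.
#' @param model The fitted model structure.
#' @param well Well id (defaults to the first fit's well).
#' @return A `crossval_table`: tibble with `fit_protocol`, `fit_sweep`,
#'   one numeric column per validation sweep (named `protocol.sweep`), and
#'   attribute `diag_keys` mapping rows to their own-column keys.
#' @export
cross_validation_table <- function(fits, pp, model, well = NULL) {
  well <- well %||% fits[[1]]$well
  val_rows <- pp$design[pp$design$drug_state == "pre" &
                          pp$design$well == well, ]
  val_keys <- paste0(val_rows$protocol, ".", val_rows$sweep)
  sim_cache <- new.env()

  entry <- function(fit, vrow) {
    key <- trace_key(well, vrow$protocol, vrow$sweep, "pre")
    ztr <- pp$traces[[key]]
    if (is.null(ztr)) return(NA_real_)
    v_off <- (attr(ztr, "meta") %||% list())$V_off %||% 0
    if (is.na(v_off)) v_off <- 0
    cache_key <- paste(paste(signif(fit$theta, 12), collapse = ","),
                       vrow$protocol, signif(v_off, 8), sep = "@")
    y <- sim_cache[[cache_key]]
    if (is.null(y)) {
      y <- simulate_current(model, fit$theta, pp$protocols[[vrow$protocol]],
                            E_Kr = pp$E_Nernst, V_off = v_off)$trace$current_pA
      sim_cache[[cache_key]] <- y
    }
    nrmse(y, ztr$current_pA)
  }

  rows <- lapply(fits, function(fit) {
    vals <- vapply(seq_len(nrow(val_rows)),
                   function(j) entry(fit, val_rows[j, ]), numeric(1))
    c(list(fit_protocol = fit$protocol, fit_sweep = fit$sweep),
      stats::setNames(as.list(vals), val_keys))
  })
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  attr(out, "diag_keys") <- paste0(out$fit_protocol, ".", out$fit_sweep)
  attr(out, "well") <- well
  class(out) <- c("crossval_table", class(out))
  out
}

cv_matrix <- function(table) {
  keys <- setdiff(names(table), c("fit_protocol", "fit_sweep"))
  m <- as.matrix(table[, keys])
  rownames(m) <- attr(table, "diag_keys")
  m
}

#' Mean fitting error over the diagonal
#'
#' Average NRMSE of each fit evaluated on its own sweep, over the fitting
#' sweeps (the validation-only protocol contributes no row). In the study
#' design the number of fitting sweeps is `N_d - 1` with `N_d` the number of
#' validation sweeps, so this equals the `1/(N_d - 1)` normalisation.
#'
#' @param table A [cross_validation_table()].
#' @return Scalar `E_fit`.
#' @export
e_fit <- function(table) {
  m <- cv_matrix(table)
  diag_vals <- vapply(seq_len(nrow(m)),
                      function(i) m[i, rownames(m)[i]], numeric(1))
  mean(diag_vals, na.rm = TRUE)
}

#' Mean prediction error over the off-diagonal
#'
#' Double sum of NRMSE over fitting sweeps and validation sweeps other than
#' the fitting sweep itself, normalised by `(N_d - 1)^2`.
#'
#' @param table A [cross_validation_table()].
#' @return Scalar `E_predict`.
#' @export
e_predict <- function(table) {
  m <- cv_matrix(table)
  n_d <- ncol(m)
  total <- 0
  for (i in seq_len(nrow(m))) {
    own <- rownames(m)[i]
    total <- total + sum(m[i, setdiff(colnames(m), own)], na.rm = TRUE)
  }
  total / (n_d - 1)^2
}

#' Noise-weighted residuals averaged across wells
#'
#' For each well, `(y_i - z_i) / sigma_hat`; the per-timepoint mean across
#' wells is clipped to [-100, 100]. Positive values mark consistent
#' overestimation by the model.
#'
#' @param residual_list List (one element per well) of numeric residual
#'   vectors `y - z` on a shared grid.
#' @param sigma_hat Per-well noise estimates (same length as the list).
#' @return Clipped mean weighted-residual series.
#' @export
weighted_residuals <- function(residual_list, sigma_hat) {
  stopifnot(length(residual_list) == length(sigma_hat))
  if (any(sigma_hat <= 0)) {
    stop("Noise estimates must be strictly positive.", call. = FALSE)
  }
  W <- mapply(function(r, s) r / s, residual_list, sigma_hat)
  W <- matrix(unlist(W), ncol = length(residual_list))
  pmin(pmax(rowMeans(W), -100), 100)
}

#' Ensemble-consistency statistic T
#'
#' `T_i = (ybar_i - z_i) / (sigma_hat + std(y_i)/sqrt(N_predictions))`,
#' clipped to [-100, 100]. Large sustained |T| flags predictions that are
#' consistently discrepant beyond what noise and ensemble spread explain.
#' Only genuine predictions enter the ensemble: fits to the sweep under
#' evaluation are excluded by the caller.
#'
#' @param predictions Matrix of member predictions (timepoints x members,
#'   at least 2 members).
#' @param z Observed current.
#' @param sigma_hat Noise estimate for the sweep (pA).
#' @param se If `TRUE` (default) the spread term is the standard error
#'   `std/sqrt(N)`; if `FALSE`, `std/N`.
#' @return Clipped per-timepoint T series.
#' @export
consistency_T <- function(predictions, z, sigma_hat, se = TRUE) {
  predictions <- as.matrix(predictions)
  n_pred <- ncol(predictions)
  if (n_pred < 2) {
    stop("At least 2 ensemble predictions are required.", call. = FALSE)
  }
  stopifnot(nrow(predictions) == length(z), sigma_hat > 0)
  ybar <- rowMeans(predictions)
  spread <- apply(predictions, 1, stats::sd)
  denom <- sigma_hat + spread / if (se) sqrt(n_pred) else n_pred
  pmin(pmax((ybar - z) / denom, -100), 100)
}

#' Heatmap of a cross-validation table
#'
#' @param object A [cross_validation_table()].
#' @param ... Unused.
#' @return A ggplot tile plot of NRMSE by fitting and validation sweep.
#' @export
autoplot.crossval_table <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = -c("fit_protocol", "fit_sweep"),
    names_to = "validation", values_to = "nrmse")
  df$fit <- paste0(df$fit_protocol, ".", df$fit_sweep)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$validation, y = .data$fit,
                                   fill = .data$nrmse)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "validation sweep", y = "fitting sweep",
                  fill = "NRMSE") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
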