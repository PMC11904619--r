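#' End-to-end pipeline
#'
#' Orchestrates generate -> postprocess -> QC -> fit -> cross-validate ->
#' variability as one reproducible run, fully determined by the
#' configuration and the master seed.
#'
#' @name pipeline
NULL

#' Run configuration
#'
#' @param dataset A [dataset_config()] describing the synthetic experiment
#'   (or supply a pre-generated dataset to [run_pipeline()]).
#' @param fit A [fit_config()].
#' @param qc A [qc_criteria()].
#' @param seed Master seed.
#' @param out_dir Optional directory for CSV artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(dataset, fit = fit_config(), qc = qc_criteria(),
                       seed = 1, out_dir = NULL) {
  structure(list(dataset = dataset, fit = fit, qc = qc, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Generates (or takes) a dataset, postprocesses every sweep, filters wells
#' by QC, fits the model to every fitting sweep of every passing well with
#' repeated CMA-ES, builds per-well cross-validation tables with `E_fit` and
#' `E_predict`, and runs the two-way linear effects analysis on the pooled
#' parameter estimates. Individual sweep-fit failures are recorded and do
#' not abort the batch.
#'
#' @param config A [run_config()].
#' @param dataset Optional pre-generated `ikr_dataset` (skips generation).
#' @return An `ikr_run`: list with `dataset`, `postprocessed`, `qc`,
#'   `fits` (list), `fits_table`, `estimates`, `crossval` (per-well tables),
#'   `crossval_summary`, `variability`, `manifest` (if files were written),
#'   `failed_fits`.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  model <- config$dataset$model
  stage <- function(msg) message("[ikrfit] ", msg)

  stage("generating dataset")
  dataset <- dataset %||% generate_dataset(config$dataset, seed = config$seed)

  stage("postprocessing")
  pp <- postprocess_dataset(dataset, E_Nernst = config$dataset$E_Kr)

  stage("quality control")
  qc <- qc_filter(pp, config$qc)
  if (length(qc$passing) == 0) {
    warning("No wells passed QC; downstream stages are empty.", call. = FALSE)
  }

  stage("fitting")
  fit_rows <- pp$design[pp$design$drug_state == "pre" & pp$design$fitting &
                          pp$design$well %in% qc$passing, ]
  fits <- list()
  failed <- list()
  for (i in seq_len(nrow(fit_rows))) {
    row <- fit_rows[i, ]
    key <- trace_key(row$well, row$protocol, row$sweep, "pre")
    fcfg <- config$fit
    fcfg$seed <- derive_seed(config$seed, "fit", key)
    res <- tryCatch(
      fit_sweep(model, pp$traces[[key]], pp$protocols[[row$protocol]], fcfg),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[[key]] <- conditionMessage(res)
    } else {
      fits[[key]] <- res
    }
  }
  fits_table <- if (length(fits)) {
    dplyr::bind_rows(lapply(fits, glance.ikr_fit))
  } else tibble::tibble()

  stage("cross-validation")
  crossval <- list()
  cv_summary <- list()
  for (w in qc$passing) {
    wf <- fits[vapply(fits, function(f) f$well == w, logical(1))]
    if (length(wf) == 0) next
    tbl <- cross_validation_table(wf, pp, model, well = w)
    crossval[[w]] <- tbl
    cv_summary[[w]] <- tibble::tibble(
      model = model$name, well = w,
      e_fit = e_fit(tbl), e_predict = e_predict(tbl))
  }
  crossval_summary <- dplyr::bind_rows(cv_summary)

  stage("variability analysis")
  estimates <- if (length(fits)) transform_estimates(fits, model) else
    tibble::tibble()
  variability <- if (length(fits) &&
                       length(unique(estimates$protocol)) >= 2) {
    variability_analysis(estimates, model_name = model$name)
  } else tibble::tibble()

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- write_run_outputs(config, pp, qc, fits_table, estimates,
                                  crossval_summary, variability)
  }

  structure(list(dataset = dataset, postprocessed = pp, qc = qc,
                 fits = fits, fits_table = fits_table,
                 estimates = estimates, crossval = crossval,
                 crossval_summary = crossval_summary,
                 variability = variability, manifest = manifest,
                 failed_fits = failed, config = config),
            class = "ikr_run")
}

write_run_outputs <- function(config, pp, qc, fits_table, estimates,
                              crossval_summary, variability) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- config_hash(config)
  stamp <- function(df) {
    df$seed <- config$seed
    df$config_hash <- cfg_hash
    df
  }
  outputs <- list(
    annotations = stamp(pp$annotations),
    qc_flags = stamp(qc$flags),
    fits = stamp(fits_table),
    estimates = stamp(estimates),
    crossval_summary = stamp(crossval_summary),
    variability = stamp(variability))
  paths <- character(0)
  for (nm in names(outputs)) {
    if (nrow(outputs[[nm]]) == 0) next
    path <- file.path(config$out_dir, paste0(nm, ".csv"))
    utils::write.csv(outputs[[nm]], path, row.names = FALSE)
    paths <- c(paths, path)
  }
  tibble::tibble(file = basename(paths),
                 md5 = unname(tools::md5sum(paths)),
                 seed = config$seed, config_hash = cfg_hash)
}

# md5 of the serialized configuration (protocols, truth, fit and QC settings)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[c("dataset", "fit", "qc", "seed")], tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' @export
print.ikr_run <- function(x, ...) {
  cat("<ikr_run> model ", x$config$dataset$model$name, ", ",
      length(x$config$dataset$wells), " well(s): ",
      length(x$qc$passing), " passed QC, ", length(x$fits),
      " sweeps fitted, ", length(x$failed_fits), " failures\n", sep = "")
  invisible(x)
}
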