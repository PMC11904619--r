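#' Synthetic patch-clamp experiments
#'
#' Generates full synthetic datasets with the statistical structure the
#' downstream analysis assumes: per-well sweeps of a protocol battery
#' (staircase d1 four times, the others once, the whole block repeated after
#' a simulated specific blocker), each trace being
#' `I_out = IKr + gL * (Vcmd - EL) + noise` with IID Gaussian noise, a
#' systematic voltage offset `Voff` (the model sees `Vm = Vcmd + Voff`), and
#' optional well- and protocol-level heterogeneity in the kinetics (applied
#' on the `a = log(A)` and `b` scales, the same scales the two-way linear
#' effects model analyses). The post-drug sweep sets the IKr term to zero
#' (full specific block).
#'
#' @name synthetic_data
NULL

#' Per-well, per-protocol kinetic parameters with additive effects
#'
#' Draws well effects and protocol effects for each transformed kinetic
#' parameter (`a = log(A)` shifted for A-type slots, `b` shifted directly
#' for b-type slots), each IID Gaussian with the given standard deviation
#' and re-centred so effects sum to zero across levels. The maximal
#' conductance is drawn log-normally per well (no protocol dependence).
#'
#' @param model An [build_model()] object.
#' @param wells Character vector of well ids.
#' @param protocols Character vector of protocol names.
#' @param base_params Baseline parameter vector (defaults to the model's).
#' @param well_effect_sd,protocol_effect_sd SD of the effects on the
#'   `a = log(A)` scale (dimensionless).
#' @param well_effect_sd_b,protocol_effect_sd_b SD of the effects on the
#'   `b` scale (1/mV); defaults scale the a-scale SDs down by 100x since
#'   typical `b` values are ~0.01-0.07 /mV.
#' @param g_cv Coefficient of variation of the per-well log-normal maximal
#'   conductance.
#' @param seed Integer seed.
#' @return A list: `params` (tibble `well`, `protocol`, list-column
#'   `params`), `g` (named per-well conductances), `beta_w`, `beta_d`
#'   (effect matrices on the transformed scale, columns sum to zero).
#' @export
generate_well_params <- function(model, wells, protocols,
                                 base_params = model$default_params,
                                 well_effect_sd = 0, protocol_effect_sd = 0,
                                 well_effect_sd_b = well_effect_sd / 100,
                                 protocol_effect_sd_b = protocol_effect_sd / 100,
                                 g_cv = 0.3, seed = 1) {
  stopifnot(well_effect_sd >= 0, protocol_effect_sd >= 0)
  validate_params(model, base_params)
  n_kin <- model$n_kinetic_params
  kin_names <- model$param_names[seq_len(n_kin)]
  is_a <- startsWith(kin_names, "A_")
  n_w <- length(wells)
  n_d <- length(protocols)

  center <- function(M) if (nrow(M) > 1) sweep(M, 2, colMeans(M)) else M * 0
  draws <- with_seed(seed, {
    sd_vec <- ifelse(is_a, well_effect_sd, well_effect_sd_b)
    bw <- center(matrix(stats::rnorm(n_w * n_kin), n_w) %*% diag(sd_vec, n_kin))
    sd_vec_d <- ifelse(is_a, protocol_effect_sd, protocol_effect_sd_b)
    bd <- center(matrix(stats::rnorm(n_d * n_kin), n_d) %*% diag(sd_vec_d, n_kin))
    g_mu <- base_params[model$conductance_index]
    sdlog <- sqrt(log(1 + g_cv^2))
    g <- g_mu * exp(stats::rnorm(n_w, -sdlog^2 / 2, sdlog))
    list(bw = bw, bd = bd, g = g)
  })
  beta_w <- draws$bw
  beta_d <- draws$bd
  dimnames(beta_w) <- list(wells, kin_names)
  dimnames(beta_d) <- list(protocols, kin_names)
  g <- stats::setNames(draws$g, wells)
  if (well_effect_sd == 0 && well_effect_sd_b == 0) beta_w[] <- 0
  if (protocol_effect_sd == 0 && protocol_effect_sd_b == 0) beta_d[] <- 0

  base_kin <- base_params[seq_len(n_kin)]
  grid <- tidyr::crossing(well = wells, protocol = protocols)
  grid$params <- purrr::map2(grid$well, grid$protocol, function(w, d) {
    eff <- beta_w[w, ] + beta_d[d, ]
    kin <- ifelse(is_a, base_kin * exp(eff), pmax(base_kin + eff, 1e-9))
    stats::setNames(c(kin, g[w]), model$param_names)
  })
  list(params = grid, g = g, beta_w = beta_w, beta_d = beta_d)
}

#' Ground truth for one well
#'
#' @param well Well id.
#' @param kinetic_params Full parameter vector for this well (per-protocol
#'   values may override at sweep generation).
#' @param g_L Leak conductance (nS). @param E_L Leak reversal (mV).
#' @param V_off Systematic voltage offset (mV).
#' @param noise_sd Noise SD (pA).
#' @return A `well_truth` list.
#' @export
well_truth <- function(well, kinetic_params, g_L = 1, E_L = -5,
                       V_off = 0, noise_sd = 20) {
  stopifnot(noise_sd >= 0, g_L >= 0)
  structure(list(well = well, params = kinetic_params, g_L = g_L, E_L = E_L,
                 V_off = V_off, noise_sd = noise_sd),
            class = "well_truth")
}

new_sweep_trace <- function(times, current, well, protocol, sweep, drug_state) {
  out <- tibble::tibble(time_ms = times, current_pA = current)
  attr(out, "meta") <- list(well = well, protocol = protocol,
                            sweep = sweep, drug_state = drug_state)
  class(out) <- c("sweep_trace", class(out))
  out
}

trace_meta <- function(trace) attr(trace, "meta")

#' Generate one synthetic sweep
#'
#' Pre-drug: `IKr(params, Voff) + gL * (Vcmd - EL) + noise`; post-drug: the
#' IKr term is dropped (full block), leak and noise remain.
#'
#' @param truth A [well_truth()] object (its `params` may be overridden).
#' @param model An [build_model()] object.
#' @param protocol A `voltage_protocol`.
#' @param drug_state `"pre"` or `"post"`.
#' @param seed Integer seed for the noise.
#' @param sweep Sweep index recorded in the metadata.
#' @param E_Kr Reversal potential used for the true IKr (mV).
#' @param ikr_noiseless Optional precomputed noiseless IKr current on the
#'   protocol grid (to avoid re-simulating identical repeats).
#' @return A `sweep_trace` tibble (`time_ms`, `current_pA`) with metadata.
#' @export
generate_sweep <- function(truth, model, protocol, drug_state = "pre",
                           seed = 1, sweep = 1L, E_Kr = nernst_potential(4, 132),
                           ikr_noiseless = NULL) {
  times <- protocol_times(protocol)
  v_cmd <- voltage_at(protocol, times)
  leak <- truth$g_L * (v_cmd - truth$E_L)
  if (drug_state == "pre") {
    if (is.null(ikr_noiseless)) {
      sim <- simulate_current(model, truth$params, protocol,
                              E_Kr = E_Kr, V_off = truth$V_off)
      ikr_noiseless <- sim$trace$current_pA
    }
    signal <- ikr_noiseless + leak
  } else {
    signal <- leak
  }
  eps <- if (truth$noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(times), 0, truth$noise_sd))
  } else 0
  new_sweep_trace(times, signal + eps, truth$well,
                  protocol_name(protocol), sweep, drug_state)
}

#' Configuration for a synthetic dataset
#'
#' @param model An [build_model()] object.
#' @param protocols Named list of protocols (see
#'   [default_protocol_battery()]).
#' @param wells Character vector of well ids.
#' @param base_params Baseline truth parameters.
#' @param well_effect_sd,protocol_effect_sd Kinetic heterogeneity SDs on the
#'   `log(A)` scale (see [generate_well_params()]).
#' @param noise_sd Observation noise SD (pA).
#' @param g_L_range Per-well leak conductance range (nS), drawn uniformly.
#' @param E_L_sd Leak reversal SD around 0 mV.
#' @param V_off_sd Voltage-offset SD (mV).
#' @param E_Kr True reversal potential (mV).
#' @param K_out,K_in,temperature Nernst inputs used for `E_Kr`'s default.
#' @param validation_only Protocols excluded from fitting.
#' @return A `dataset_config` list.
#' @export
dataset_config <- function(model, protocols = default_protocol_battery(),
                           wells = "A01",
                           base_params = model$default_params,
                           well_effect_sd = 0, protocol_effect_sd = 0,
                           noise_sd = 20, g_L_range = c(0.1, 2), E_L_sd = 5,
                           V_off_sd = 2, K_out = 4, K_in = 132,
                           temperature = 298.15,
                           E_Kr = nernst_potential(K_out, K_in, temperature),
                           validation_only = "d6") {
  structure(list(model = model, protocols = protocols, wells = wells,
                 base_params = base_params, well_effect_sd = well_effect_sd,
                 protocol_effect_sd = protocol_effect_sd, noise_sd = noise_sd,
                 g_L_range = g_L_range, E_L_sd = E_L_sd, V_off_sd = V_off_sd,
                 E_Kr = E_Kr, validation_only = validation_only),
            class = "dataset_config")
}

trace_key <- function(well, protocol, sweep, drug_state) {
  paste(well, protocol, sweep, drug_state, sep = "|")
}

#' Generate a complete synthetic experiment
#'
#' Realises the full design for every well: two opening d1 sweeps, one sweep
#' of each other protocol, two closing d1 sweeps, then the identical block
#' "post-drug" (IKr removed). Per-sweep noise seeds are derived
#' deterministically from the master seed and the sweep's identity, so the
#' whole dataset is reproducible from `(config, seed)`.
#'
#' @param config A [dataset_config()].
#' @param seed Master integer seed.
#' @return An `ikr_dataset`: list with `design` (tibble), `traces` (named
#'   list of `sweep_trace`), `truth` (per-well [well_truth()] objects plus
#'   per-protocol parameter tables), `config`, `seed`.
#' @export
generate_dataset <- function(config, seed = 1) {
  model <- config$model
  prot_names <- names(config$protocols)
  design <- experiment_design(prot_names, config$wells,
                              config$validation_only)
  wp <- generate_well_params(model, config$wells, prot_names,
                             base_params = config$base_params,
                             well_effect_sd = config$well_effect_sd,
                             protocol_effect_sd = config$protocol_effect_sd,
                             seed = derive_seed(seed, "well-params"))
  well_env <- with_seed(derive_seed(seed, "well-artefacts"), {
    n_w <- length(config$wells)
    list(
      g_L = stats::runif(n_w, config$g_L_range[1], config$g_L_range[2]),
      E_L = stats::rnorm(n_w, 0, config$E_L_sd),
      V_off = stats::rnorm(n_w, 0, config$V_off_sd)
    )
  })

  truth <- list()
  for (i in seq_along(config$wells)) {
    w <- config$wells[i]
    truth[[w]] <- well_truth(
      well = w,
      kinetic_params = NULL,   # per-protocol, filled below
      g_L = well_env$g_L[i], E_L = well_env$E_L[i],
      V_off = well_env$V_off[i], noise_sd = config$noise_sd)
  }

  param_lookup <- wp$params
  get_params <- function(w, d) {
    param_lookup$params[[which(param_lookup$well == w &
                                 param_lookup$protocol == d)]]
  }

  traces <- list()
  for (w in config$wells) {
    ikr_cache <- list()
    for (i in which(design$well == w)) {
      d <- design$protocol[i]
      sw <- design$sweep[i]
      ds <- design$drug_state[i]
      tr_truth <- truth[[w]]
      tr_truth$params <- get_params(w, d)
      if (ds == "pre" && is.null(ikr_cache[[d]])) {
        sim <- simulate_current(model, tr_truth$params, config$protocols[[d]],
                                E_Kr = config$E_Kr, V_off = tr_truth$V_off)
        ikr_cache[[d]] <- sim$trace$current_pA
      }
      traces[[trace_key(w, d, sw, ds)]] <- generate_sweep(
        tr_truth, model, config$protocols[[d]], drug_state = ds,
        seed = derive_seed(seed, w, d, sw, ds), sweep = sw,
        E_Kr = config$E_Kr,
        ikr_noiseless = if (ds == "pre") ikr_cache[[d]] else NULL)
    }
  }

  structure(list(design = design, traces = traces, truth = truth,
                 well_params = wp, config = config, seed = seed),
            class = "ikr_dataset")
}

#' @export
print.ikr_dataset <- function(x, ...) {
  cat("<ikr_dataset> ", length(x$config$wells), " well(s) x ",
      length(x$config$protocols), " protocols, ", length(x$traces),
      " sweeps (model ", x$config$model$name, ", noise sd ",
      x$config$noise_sd, " pA, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Fetch one trace from a dataset
#' @param dataset An `ikr_dataset` (or postprocessed set).
#' @param well,protocol,sweep,drug_state Sweep identity.
#' @export
get_trace <- function(dataset, well, protocol, sweep = 1L,
                      drug_state = "pre") {
  tr <- dataset$traces[[trace_key(well, protocol, sweep, drug_state)]]
  if (is.null(tr)) {
    stop("No trace for ", trace_key(well, protocol, sweep, drug_state),
         call. = FALSE)
  }
  tr
}

#' Inject a quality-control failure into a synthetic well
#'
#' Regenerates part of one well's sweeps so that exactly one QC criterion is
#' violated: `"rundown"` regenerates the two closing pre-drug staircase
#' sweeps with a reduced maximal conductance (the current response drifts
#' over the experiment, failing the staircase-stability criterion),
#' `"noisy"` regenerates every sweep of the well with inflated noise
#' (noise-estimate failure), and `"bad_reversal"` regenerates the well with
#' a large voltage offset (observed-reversal-potential failure).
#'
#' @param dataset An `ikr_dataset`.
#' @param well Well id to corrupt.
#' @param type One of `"rundown"`, `"noisy"`, `"bad_reversal"`.
#' @param magnitude Size of the defect: remaining conductance fraction,
#'   noise multiplier, or voltage offset (mV) respectively.
#' @param staircase Name of the repeated stability protocol.
#' @return The dataset with the well's affected traces replaced.
#' @export
inject_qc_failure <- function(dataset, well,
                              type = c("rundown", "noisy", "bad_reversal"),
                              magnitude = NULL, staircase = "d1") {
  type <- match.arg(type)
  config <- dataset$config
  model <- config$model
  truth <- dataset$truth[[well]]
  if (is.null(truth)) stop("Unknown well '", well, "'.", call. = FALSE)
  g_scale <- 1
  lookup <- dataset$well_params$params
  get_params <- function(d) {
    p <- lookup$params[[which(lookup$well == well & lookup$protocol == d)]]
    p[model$conductance_index] <- p[model$conductance_index] * g_scale
    p
  }
  rows <- dataset$design[dataset$design$well == well, ]
  if (type == "rundown") {
    magnitude <- magnitude %||% 0.4
    rows <- rows[rows$protocol == staircase & rows$drug_state == "pre" &
                   rows$sweep >= 3, ]
    g_scale <- magnitude
  } else if (type == "noisy") {
    magnitude <- magnitude %||% 10
    truth$noise_sd <- truth$noise_sd * magnitude
  } else {
    magnitude <- magnitude %||% 25
    truth$V_off <- magnitude
  }
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    truth$params <- get_params(r$protocol)
    dataset$traces[[trace_key(well, r$protocol, r$sweep, r$drug_state)]] <-
      generate_sweep(truth, model, config$protocols[[r$protocol]],
                     drug_state = r$drug_state,
                     seed = derive_seed(dataset$seed, well, r$protocol,
                                        r$sweep, r$drug_state, "qcfail"),
                     sweep = r$sweep, E_Kr = config$E_Kr)
  }
  dataset
}

#' Write a dataset to disk as plain-text artifacts
#'
#' One trace CSV per sweep (`time_ms, current_pA`), a design manifest CSV
#' (well, protocol, sweep, drug_state, path), and a ground-truth JSON with
#' each well's leak, offset, noise and conductance.
#'
#' @param dataset An `ikr_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- dataset$design
  paths <- character(nrow(design))
  for (i in seq_len(nrow(design))) {
    r <- design[i, ]
    key <- trace_key(r$well, r$protocol, r$sweep, r$drug_state)
    paths[i] <- paste0(gsub("\\|", "_", key), ".csv")
    utils::write.csv(
      as.data.frame(dataset$traces[[key]][, c("time_ms", "current_pA")]),
      file.path(dir, paths[i]), row.names = FALSE)
  }
  manifest <- dplyr::mutate(design, path = paths)
  utils::write.csv(as.data.frame(manifest), file.path(dir, "design.csv"),
                   row.names = FALSE)
  truth <- lapply(dataset$truth, function(tr) {
    list(well = tr$well, g_L = tr$g_L, E_L = tr$E_L, V_off = tr$V_off,
         noise_sd = tr$noise_sd)
  })
  params <- dataset$well_params$params
  params$params <- lapply(params$params, as.list)
  jsonlite::write_json(list(wells = truth, params = params,
                            seed = dataset$seed),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
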