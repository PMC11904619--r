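#' Maximum-likelihood fitting of IKr models
#'
#' Under IID additive Gaussian noise the MLE is the nonlinear least-squares
#' minimiser of the sum of squared residuals between the simulated and
#' observed currents. Each sweep is fitted with repeated CMA-ES runs from
#' independent log-uniform initial guesses; transition rates are bounded so
#' that their maximum over the physiological voltage range stays within
#' `[1.67e-5, 1e5] / ms`, and the maximal conductance is loosely bounded
#' from the current observed during the -120 mV scaffold step.
#'
#' @name fitting
NULL

#' Fitting configuration
#'
#' @param n_repeats Number of independent CMA-ES runs per sweep (study
#'   default 30; scale down for quick runs).
#' @param rate_bound_lo,rate_bound_hi Bounds on the maximum transition rate
#'   over `v_range` (1/ms).
#' @param v_range Voltage range (mV) over which rate maxima are evaluated.
#' @param init_log10_lo,init_log10_hi Log10 bounds of the uniform initial
#'   guess distribution.
#' @param pop_size_override Named list protocol of population-size overrides
#'   by model name (the 15-parameter Wang model uses 50).
#' @param c_g_lo,c_g_hi Leniency constants for the conductance bounds.
#' @param sigma0 Initial CMA-ES step size in scaled search coordinates.
#' @param max_evals Evaluation budget per CMA-ES repeat.
#' @param tol_fun CMA-ES function-value stopping tolerance (relative).
#' @param polish Refine the best repeat with a deterministic quasi-Newton
#'   polish (L-BFGS-B on the transformed coordinates).
#' @param seed Master seed; per-repeat seeds are derived from it.
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_repeats = 30, rate_bound_lo = 1.67e-5,
                       rate_bound_hi = 1e5, v_range = c(-120, 60),
                       init_log10_lo = -7, init_log10_hi = 1,
                       pop_size_override = list(wang = 50),
                       c_g_lo = 0.01, c_g_hi = 1e4,
                       sigma0 = 0.3, max_evals = 10000, tol_fun = 1e-7,
                       polish = TRUE, seed = 1) {
  stopifnot(rate_bound_lo < rate_bound_hi, v_range[1] < v_range[2],
            init_log10_lo < init_log10_hi, c_g_lo < c_g_hi)
  structure(list(n_repeats = n_repeats, rate_bound_lo = rate_bound_lo,
                 rate_bound_hi = rate_bound_hi, v_range = v_range,
                 init_log10_lo = init_log10_lo,
                 init_log10_hi = init_log10_hi,
                 pop_size_override = pop_size_override,
                 c_g_lo = c_g_lo, c_g_hi = c_g_hi, sigma0 = sigma0,
                 max_evals = max_evals, tol_fun = tol_fun, polish = polish,
                 seed = seed),
            class = "fit_config")
}

#' Sum-of-squares objective
#'
#' `sum((y(theta) - z)^2)` between the simulated current and the observed
#' (postprocessed) current on the protocol grid. Simulation failures give
#' `Inf` (optimizer-safe) with a warning.
#'
#' @param model,params,protocol,E_Kr,V_off As in [simulate_current()].
#' @param data Observed current on the protocol grid (numeric vector or a
#'   sweep tibble with `current_pA`).
#' @return Sum of squared residuals (pA^2).
#' @export
objective <- function(model, params, protocol, data, E_Kr, V_off = 0) {
  z <- if (is.data.frame(data)) data$current_pA else data
  y <- tryCatch(
    simulate_current(model, params, protocol, E_Kr = E_Kr,
                     V_off = V_off)$trace$current_pA,
    error = function(e) {
      warning("Simulation failed in objective: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  if (is.null(y) || length(y) != length(z)) return(Inf)
  sum((y - z)^2)
}

#' Check the transition-rate bound for one rate
#'
#' The maximum of `A*exp(b*V)` over `v_range` is attained at the upper end
#' for positive exponents and (for `A*exp(-b*V)`) at the lower end; constant
#' rates have maximum `A`. Passes iff that maximum lies within
#' `[rate_bound_lo, rate_bound_hi]`.
#'
#' @param form `"pos_exp"`, `"neg_exp"`, or `"constant"`.
#' @param A,b Rate parameters.
#' @param config A [fit_config()].
#' @return `TRUE`/`FALSE`.
#' @export
check_rate_bounds <- function(form, A, b = 0, config = fit_config()) {
  k_max <- switch(form,
    pos_exp = A * exp(b * config$v_range[2]),
    neg_exp = A * exp(-b * config$v_range[1]),
    constant = A,
    stop("Unknown rate form '", form, "'.", call. = FALSE))
  k_max >= config$rate_bound_lo && k_max <= config$rate_bound_hi
}

rate_bounds_ok <- function(model, kin_params, config) {
  tr <- unique(model$transitions[, c("form", "A_index", "b_index")])
  for (i in seq_len(nrow(tr))) {
    A <- kin_params[tr$A_index[i]]
    b <- if (is.na(tr$b_index[i])) 0 else kin_params[tr$b_index[i]]
    if (b < 0) return(FALSE)
    if (!check_rate_bounds(tr$form[i], A, b, config)) return(FALSE)
  }
  TRUE
}

#' Lenient conductance bounds from the -120 mV scaffold step
#'
#' Uses the maximum absolute current observed during the -120 mV step at the
#' start of the protocol: `max|I| / |-120 - EKr|` estimates `g * xO` there,
#' and the bounds multiply it by leniency constants spanning several orders
#' of magnitude (the open probability at that step is small but unknown).
#'
#' @param trace Observed sweep (postprocessed).
#' @param protocol Its protocol.
#' @param E_Kr Reversal potential (mV).
#' @param config A [fit_config()].
#' @return `c(g_lo, g_hi)` in nS; with a degenerate (all-zero) trace the
#'   bounds are `c(0, Inf)` with a warning.
#' @export
conductance_bounds <- function(trace, protocol, E_Kr = nernst_potential(4, 132),
                               config = fit_config()) {
  step_idx <- which(protocol$section_tag == "leak_ramp" &
                      protocol$kind == "step" & protocol$v_start_mV == -120)
  if (length(step_idx) == 0) {
    warning("No -120 mV scaffold step found; conductance unbounded.",
            call. = FALSE)
    return(c(0, Inf))
  }
  ends <- cumsum(protocol$duration_ms)
  starts <- c(0, ends[-length(ends)])
  sel <- trace$time_ms >= starts[step_idx[1]] & trace$time_ms < ends[step_idx[1]]
  max_i <- max(abs(trace$current_pA[sel]))
  if (max_i == 0) {
    warning("Zero current during the -120 mV step; conductance bounds ",
            "degenerate.", call. = FALSE)
    return(c(0, Inf))
  }
  scale <- max_i / abs(-120 - E_Kr)
  c(config$c_g_lo * scale, config$c_g_hi * scale)
}

#' Population-size heuristic
#'
#' `floor(4 + 3*log(n_params))`, with an optional override (the Wang model
#' uses 50).
#'
#' @param n_params Number of model parameters.
#' @param override Optional integer override.
#' @return Integer population size.
#' @export
population_size <- function(n_params, override = NULL) {
  stopifnot(n_params >= 1)
  if (!is.null(override)) return(as.integer(override))
  as.integer(floor(4 + 3 * log(n_params)))
}

#' Sample a valid initial guess
#'
#' Each kinetic parameter and the conductance is drawn with
#' `log10(p) ~ U(-7, 1)`; draws violating the transition-rate bounds or the
#' conductance bounds are rejected and resampled.
#'
#' @param model An [build_model()] object.
#' @param config A [fit_config()].
#' @param g_bounds Conductance bounds from [conductance_bounds()].
#' @param seed Integer seed.
#' @return A full parameter vector passing all bounds.
#' @export
sample_initial_guess <- function(model, config = fit_config(),
                                 g_bounds = c(0, Inf), seed = 1) {
  n <- model$total_params
  with_seed(seed, {
    for (attempt in seq_len(1e5)) {
      p <- 10^stats::runif(n, config$init_log10_lo, config$init_log10_hi)
      kin <- p[seq_len(model$n_kinetic_params)]
      g <- p[model$total_params]
      if (rate_bounds_ok(model, kin, config) &&
          g >= g_bounds[1] && g <= g_bounds[2]) {
        return(stats::setNames(p, model$param_names))
      }
    }
    stop("Could not sample a valid initial guess after 1e5 attempts; ",
         "bounds are pathological.", call. = FALSE)
  })
}

# --- transformed search space ------------------------------------------------
# A-type parameters and g are searched in log10; b-type linearly (the rate
# exponents live on a narrow physical scale where additive moves are the
# natural ones). Coordinates are divided by fixed scales so one CMA-ES step
# size suits all of them.

param_kinds <- function(model) {
  nm <- model$param_names
  kind <- ifelse(startsWith(nm, "b_"), "b", "logA")
  kind[model$conductance_index] <- "logA"
  kind
}

to_search <- function(params, kind, scales) {
  x <- ifelse(kind == "logA", log10(params), params)
  x / scales
}

from_search <- function(x, kind, scales) {
  x <- x * scales
  ifelse(kind == "logA", 10^x, x)
}

search_scales <- function(kind) ifelse(kind == "logA", 3, 0.1)

# Repair-with-penalty: clip b >= 0, rescale A so each rate maximum respects
# the bounds, clip g into its bounds; the quadratic violation (in log10 of
# the rate maxima / conductance, and in b below zero) is added to the SSE.
repair_params <- function(model, params, g_bounds, config) {
  # guard against overflow from extreme search steps (10^x with large x)
  params[!is.finite(params)] <- 1e100
  params <- pmin(pmax(params, -1e100), 1e100)
  kin <- params[seq_len(model$n_kinetic_params)]
  g <- params[model$total_params]
  viol <- 0
  neg_b <- startsWith(model$param_names[seq_len(model$n_kinetic_params)], "b_") &
    kin < 0
  if (any(neg_b)) {
    viol <- viol + sum((kin[neg_b] / 0.1)^2)
    kin[neg_b] <- 0
  }
  tr <- unique(model$transitions[, c("form", "A_index", "b_index")])
  for (i in seq_len(nrow(tr))) {
    A <- kin[tr$A_index[i]]
    b <- if (is.na(tr$b_index[i])) 0 else kin[tr$b_index[i]]
    k_max <- switch(tr$form[i],
                    pos_exp = A * exp(b * config$v_range[2]),
                    neg_exp = A * exp(-b * config$v_range[1]),
                    constant = A)
    if (is.nan(k_max)) k_max <- Inf
    lo <- config$rate_bound_lo
    hi <- config$rate_bound_hi
    clamp <- function(x) min(max(x, 1e-300), 1e100)
    if (k_max < lo) {
      viol <- viol + (log10(lo) - log10(max(k_max, 1e-300)))^2
      kin[tr$A_index[i]] <- clamp(A * lo / max(k_max, 1e-300))
    } else if (k_max > hi) {
      viol <- viol + (log10(max(k_max, 1e-300)) - log10(hi))^2
      kin[tr$A_index[i]] <- clamp(A * hi / k_max)
    }
  }
  if (is.finite(g_bounds[1]) && g < g_bounds[1] && g_bounds[1] > 0) {
    viol <- viol + (log10(g_bounds[1]) - log10(max(g, 1e-300)))^2
    g <- g_bounds[1]
  } else if (is.finite(g_bounds[2]) && g > g_bounds[2]) {
    viol <- viol + (log10(g) - log10(g_bounds[2]))^2
    g <- g_bounds[2]
  }
  list(params = stats::setNames(c(kin, g), model$param_names), viol = viol)
}

#' Fit a model to one sweep by repeated CMA-ES
#'
#' Runs `n_repeats` independent CMA-ES optimisations of the least-squares
#' objective, each started from a fresh log-uniform initial guess; bound
#' constraints are enforced by repair-with-quadratic-penalty. Optionally the
#' best repeat is refined with a deterministic L-BFGS-B polish. The fitted
#' sweep must be postprocessed (leak-corrected, drug-subtracted) and carry
#' (or be given) its reversal potential and voltage offset.
#'
#' @param model An [build_model()] object.
#' @param trace Postprocessed sweep tibble.
#' @param protocol The sweep's protocol.
#' @param config A [fit_config()].
#' @param E_Kr,V_off Reversal potential and voltage offset; default to the
#'   trace's annotations.
#' @return An `ikr_fit` object: best parameters, SSE/RMSE, and a per-repeat
#'   diagnostics table.
#' @export
fit_sweep <- function(model, trace, protocol, config = fit_config(),
                      E_Kr = NULL, V_off = NULL) {
  meta <- attr(trace, "meta") %||% list()
  E_Kr <- E_Kr %||% meta$E_Kr
  V_off <- V_off %||% meta$V_off %||% 0
  if (is.null(E_Kr)) {
    stop("E_Kr must be supplied or present in the trace annotations.",
         call. = FALSE)
  }
  z <- trace$current_pA
  kind <- param_kinds(model)
  scales <- search_scales(kind)
  g_bounds <- conductance_bounds(trace, protocol, E_Kr, config)
  pop <- population_size(model$total_params,
                         config$pop_size_override[[model$name]])
  cache <- protocol_cache(protocol)

  sse_at <- function(params) {
    y <- tryCatch(
      suppressWarnings(sim_current_core(model, params, cache, E_Kr, V_off)),
      error = function(e) NULL)
    if (is.null(y)) return(Inf)
    sum((y - z)^2)
  }
  # capped well below double-max so finite-difference gradients stay finite
  big <- 1e15
  penalised <- function(x) {
    p_raw <- from_search(x, kind, scales)
    rep_ <- repair_params(model, p_raw, g_bounds, config)
    sse <- sse_at(rep_$params)
    if (!is.finite(sse)) return(big)
    min(sse + rep_$viol * (1e3 + sse), big)
  }

  repeats <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    guess <- sample_initial_guess(model, config, g_bounds,
                                  seed = derive_seed(config$seed, "guess", r))
    x0 <- to_search(guess, kind, scales)
    res <- cma_es(penalised, x0, sigma0 = config$sigma0, popsize = pop,
                  max_evals = config$max_evals, tol_fun = config$tol_fun,
                  seed = derive_seed(config$seed, "cma", r))
    pars <- repair_params(model, from_search(res$par, kind, scales),
                          g_bounds, config)$params
    sse <- sse_at(pars)
    repeats[[r]] <- list(params = pars, sse = sse, n_evals = res$n_evals,
                         converged = res$converged)
  }
  sses <- vapply(repeats, function(r) r$sse, numeric(1))
  best_idx <- which.min(sses)
  best <- repeats[[best_idx]]$params

  if (isTRUE(config$polish)) {
    x_best <- to_search(best, kind, scales)
    pol <- tryCatch(
      stats::optim(x_best, penalised, method = "L-BFGS-B",
                   control = list(maxit = 400, factr = 10,
                                  ndeps = rep(1e-5, length(x_best)))),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value)) {
      cand <- repair_params(model, from_search(pol$par, kind, scales),
                            g_bounds, config)$params
      cand_sse <- sse_at(cand)
      if (cand_sse < sses[best_idx]) best <- cand
    }
  }
  best_sse <- sse_at(best)

  rep_tbl <- tibble::tibble(
    repeat_id = seq_len(config$n_repeats),
    sse = sses,
    rmse = sqrt(sses / length(z)),
    n_evals = vapply(repeats, function(r) r$n_evals, numeric(1)),
    converged = vapply(repeats, function(r) r$converged, logical(1)))
  rep_tbl$params <- lapply(repeats, function(r) r$params)

  structure(
    list(theta = best, sse = best_sse, rmse = sqrt(best_sse / length(z)),
         repeats = rep_tbl, model = model$name,
         well = meta$well %||% NA_character_,
         protocol = meta$protocol %||% protocol_name(protocol),
         sweep = meta$sweep %||% 1L,
         E_Kr = E_Kr, V_off = V_off, n_obs = length(z),
         g_bounds = g_bounds, config = config),
    class = "ikr_fit")
}

#' @export
print.ikr_fit <- function(x, ...) {
  cat("<ikr_fit> model ", x$model, ", well ", x$well, ", protocol ",
      x$protocol, " sweep ", x$sweep, ": RMSE = ", signif(x$rmse, 5),
      " pA over ", x$n_obs, " points (", nrow(x$repeats),
      " CMA-ES repeats)\n", sep = "")
  invisible(x)
}

#' Tidy a fitted sweep
#'
#' One row per parameter with its estimate.
#' @param x An `ikr_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, plus the fit's identifiers.
#' @export
tidy.ikr_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta),
                 model = x$model, well = x$well, protocol = x$protocol,
                 sweep = x$sweep)
}

#' One-row summary of a fitted sweep
#'
#' @param x An `ikr_fit`.
#' @param ... Unused.
#' @return A tibble with SSE, RMSE, observation count, and the number of
#'   repeats whose SSE is within 1% of the best.
#' @export
glance.ikr_fit <- function(x, ...) {
  tibble::tibble(model = x$model, well = x$well, protocol = x$protocol,
                 sweep = x$sweep, sse = x$sse, rmse = x$rmse,
                 n_obs = x$n_obs,
                 n_repeats = nrow(x$repeats),
                 n_repeats_within_1pct =
                   sum(x$repeats$sse <= min(x$repeats$sse) * 1.01^2))
}

#' Plot per-repeat optimisation results
#'
#' RMSE of each CMA-ES repeat, ordered, highlighting the cluster within 1%
#' of the best.
#' @param object An `ikr_fit`.
#' @param ... Unused.
#' @export
autoplot.ikr_fit <- function(object, ...) {
  df <- dplyr::arrange(object$repeats, .data$rmse)
  df$rank <- seq_len(nrow(df))
  df$within_1pct <- df$rmse <= min(df$rmse) * 1.01
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$rmse,
                                   colour = .data$within_1pct)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "repeat (sorted)", y = "RMSE (pA)",
                  colour = "within 1% of best")
}
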