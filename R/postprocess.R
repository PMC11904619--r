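#' Postprocessing of raw sweeps
#'
#' Raw currents are modelled as `I_out = IKr + I_L` with linear leak
#' `I_L = gL * (Vcmd - EL)`. Postprocessing fits the leak over the dedicated
#' leak-ramp section (where IKr is negligible), subtracts it, subtracts the
#' post-drug sweep (where IKr is fully blocked) from the pre-drug sweep, and
#' infers the observed reversal potential from the zero-crossing of the
#' corrected current along the reversal ramp. The inferred
#' `Voff = ENernst - Eobs` feeds back into fitting via `Vm = Vcmd + Voff`.
#'
#' @name postprocess
NULL

ramp_window <- function(protocol, tag, kind = NULL) {
  ends <- cumsum(protocol$duration_ms)
  starts <- c(0, ends[-length(ends)])
  sel <- protocol$section_tag == tag
  if (!is.null(kind)) sel <- sel & protocol$kind == kind
  idx <- which(sel)
  if (length(idx) == 0) {
    stop("Protocol has no '", tag, "' section.", call. = FALSE)
  }
  c(starts[idx[1]], ends[idx[length(idx)]])
}

#' Fit the linear leak model over the leak ramp
#'
#' Ordinary least squares of current on command voltage over the leak-ramp
#' ramp segment (-120 to -80 mV, where IKr is small): the slope is the leak
#' conductance `gL` (nS) and the intercept is `-gL * EL`.
#'
#' @param trace A sweep tibble (`time_ms`, `current_pA`).
#' @param protocol The protocol the sweep was recorded under.
#' @return A list `leak_model`: `g_L` (nS), `E_L` (mV), `degenerate` flag.
#' @export
fit_leak <- function(trace, protocol) {
  win <- ramp_window(protocol, "leak_ramp", kind = "ramp")
  sel <- trace$time_ms >= win[1] & trace$time_ms < win[2]
  if (sum(sel) < 3) {
    stop("Fewer than 3 samples in the leak-ramp window.", call. = FALSE)
  }
  v <- voltage_at(protocol, trace$time_ms[sel])
  i <- trace$current_pA[sel]
  fit <- stats::lm.fit(cbind(1, v), i)
  g_L <- unname(fit$coefficients[2])
  icept <- unname(fit$coefficients[1])
  if (abs(g_L) < 1e-12) {
    return(structure(list(g_L = 0, E_L = 0, degenerate = TRUE),
                     class = "leak_model"))
  }
  structure(list(g_L = g_L, E_L = -icept / g_L, degenerate = FALSE),
            class = "leak_model")
}

#' Subtract a fitted leak from a sweep
#'
#' @param trace A sweep tibble.
#' @param leak A [fit_leak()] result.
#' @param protocol The sweep's protocol (for the command voltage).
#' @return The trace with `current_pA` replaced by the leak-corrected
#'   current; the leak model is recorded in the metadata.
#' @export
leak_subtract <- function(trace, leak, protocol) {
  v <- voltage_at(protocol, trace$time_ms)
  out <- trace
  out$current_pA <- trace$current_pA - leak$g_L * (v - leak$E_L)
  meta <- attr(out, "meta") %||% list()
  meta$leak <- leak
  attr(out, "meta") <- meta
  out
}

#' Drug subtraction
#'
#' Pointwise difference of the leak-corrected pre-drug and post-drug sweeps
#' of the same well/protocol, isolating IKr (the blocker removes it from the
#' post-drug sweep; endogenous currents and residual leak cancel).
#'
#' @param pre,post Leak-corrected sweeps on the same time grid.
#' @return A sweep tibble of the isolated current; metadata merged from both.
#' @export
drug_subtract <- function(pre, post) {
  if (nrow(pre) != nrow(post) ||
      max(abs(pre$time_ms - post$time_ms)) > 1e-9) {
    stop("Pre- and post-drug traces are not on the same time grid.",
         call. = FALSE)
  }
  out <- pre
  out$current_pA <- pre$current_pA - post$current_pA
  meta <- attr(pre, "meta") %||% list()
  meta$drug_subtracted <- TRUE
  meta$post_leak <- (attr(post, "meta") %||% list())$leak
  attr(out, "meta") <- meta
  out
}

#' Infer the observed reversal potential from the reversal ramp
#'
#' Fits a degree-4 polynomial to the leak-corrected, drug-subtracted current
#' against time over the reversal-ramp window, finds the root t* where the
#' fitted current crosses zero going from negative to positive driving-force
#' direction (current crossing from positive to negative as the descending
#' ramp passes the reversal potential is equivalent; the crossing within the
#' window is selected), and returns `Eobs = Vcmd(t*)`.
#'
#' @param trace Leak-corrected, drug-subtracted sweep.
#' @param protocol The sweep's protocol (must contain a reversal ramp).
#' @return `E_obs` in mV.
#' @export
infer_reversal <- function(trace, protocol) {
  win <- ramp_window(protocol, "reversal_ramp")
  sel <- trace$time_ms >= win[1] & trace$time_ms < win[2]
  if (sum(sel) < 6) {
    stop("Too few samples in the reversal-ramp window.", call. = FALSE)
  }
  t_loc <- trace$time_ms[sel] - win[1]
  i <- trace$current_pA[sel]
  t_scale <- max(t_loc)
  ts <- t_loc / t_scale
  X <- cbind(1, ts, ts^2, ts^3, ts^4)
  coefs <- stats::lm.fit(X, i)$coefficients   # increasing powers
  roots <- polyroot(coefs)
  real_roots <- sort(Re(roots[abs(Im(roots)) < 1e-6]))
  real_roots <- real_roots[real_roots >= 0 & real_roots <= 1]
  if (length(real_roots) == 0) {
    stop("No zero-crossing of the fitted current inside the reversal ramp; ",
         "sweep flagged for QC.", call. = FALSE)
  }
  # descending ramp: the physiological crossing has the current falling
  # through zero in time (positive above EKr, negative below); prefer roots
  # where the fitted polynomial's slope is negative
  slope <- vapply(real_roots,
                  function(r) sum(coefs[2:5] * (1:4) * r^(0:3)), numeric(1))
  cand <- real_roots[slope < 0]
  root <- if (length(cand) > 0) cand[1] else real_roots[1]
  t_star <- win[1] + root * t_scale
  voltage_at(protocol, t_star)
}

#' Voltage offset from the observed reversal potential
#'
#' `Voff = ENernst - Eobs`: any systematic deviation of the observed
#' reversal potential from the Nernst prediction is attributed to a
#' command-voltage offset.
#'
#' @param E_obs Observed reversal potential (mV).
#' @param E_Nernst Theoretical reversal potential (mV).
#' @return `V_off` in mV.
#' @export
compute_voltage_offset <- function(E_obs, E_Nernst) {
  stopifnot(is.finite(E_obs), is.finite(E_Nernst))
  E_Nernst - E_obs
}

#' Noise estimate from the initial holding section
#'
#' Sample standard deviation of the postprocessed current over the initial
#' -80 mV hold, where the mean signal is flat; invariant to constant
#' offsets.
#'
#' @param trace A postprocessed sweep.
#' @param protocol The sweep's protocol (must begin with a hold section).
#' @return Estimated noise SD (pA).
#' @export
estimate_noise_sd <- function(trace, protocol) {
  if (protocol$section_tag[1] != "hold") {
    stop("Protocol does not begin with a hold section.", call. = FALSE)
  }
  t_end <- protocol$duration_ms[1]
  sel <- trace$time_ms < t_end
  if (sum(sel) < 10) {
    stop("Initial hold shorter than 10 samples.", call. = FALSE)
  }
  stats::sd(trace$current_pA[sel])
}

#' Quality-control criteria
#'
#' @param max_sigma Maximum allowed noise estimate (pA).
#' @param max_staircase_drift Maximum NRMSE between the first and last
#'   pre-drug staircase (d1) sweeps.
#' @param max_Eobs_deviation Maximum |E_obs - E_Nernst| (mV).
#' @param max_postdrug_ratio Maximum RMS(post-drug leak-corrected) /
#'   RMS(pre-drug leak-corrected).
#' @return A `qc_criteria` list.
#' @export
qc_criteria <- function(max_sigma = 50, max_staircase_drift = 0.4,
                        max_Eobs_deviation = 15, max_postdrug_ratio = 0.5) {
  stopifnot(max_sigma > 0, max_staircase_drift > 0,
            max_Eobs_deviation > 0, max_postdrug_ratio > 0)
  structure(list(max_sigma = max_sigma,
                 max_staircase_drift = max_staircase_drift,
                 max_Eobs_deviation = max_Eobs_deviation,
                 max_postdrug_ratio = max_postdrug_ratio),
            class = "qc_criteria")
}

#' Postprocess a whole dataset
#'
#' Runs leak fitting and subtraction on every sweep, drug subtraction on
#' every pre/post pair, reversal-potential inference, voltage-offset and
#' noise estimation, returning corrected IKr traces plus an annotations
#' table.
#'
#' @param dataset An `ikr_dataset` (or any list with `design`, `traces`,
#'   and a `config` carrying the protocols).
#' @param E_Nernst Theoretical reversal potential (mV).
#' @return An `ikr_postprocessed` list: `traces` (named list of corrected
#'   IKr sweeps, keyed `well|protocol|sweep|pre`), `annotations` (tibble:
#'   well, protocol, sweep, g_L, E_L, E_obs, V_off, sigma_hat,
#'   postdrug_ratio, reversal_ok), `design`, `protocols`, `E_Nernst`.
#' @export
postprocess_dataset <- function(dataset, E_Nernst = nernst_potential(4, 132)) {
  protocols <- dataset$config$protocols
  design <- dataset$design
  pre_rows <- design[design$drug_state == "pre", ]
  traces <- list()
  ann <- vector("list", nrow(pre_rows))
  for (i in seq_len(nrow(pre_rows))) {
    row <- pre_rows[i, ]
    prot <- protocols[[row$protocol]]
    pre <- get_trace(dataset, row$well, row$protocol, row$sweep, "pre")
    post <- get_trace(dataset, row$well, row$protocol, row$sweep, "post")
    leak_pre <- fit_leak(pre, prot)
    leak_post <- fit_leak(post, prot)
    pre_c <- leak_subtract(pre, leak_pre, prot)
    post_c <- leak_subtract(post, leak_post, prot)
    ikr <- drug_subtract(pre_c, post_c)
    E_obs <- tryCatch(infer_reversal(ikr, prot), error = function(e) NA_real_)
    V_off <- if (is.na(E_obs)) NA_real_ else compute_voltage_offset(E_obs, E_Nernst)
    sigma_hat <- estimate_noise_sd(ikr, prot)
    meta <- attr(ikr, "meta")
    meta$E_obs <- E_obs
    meta$V_off <- V_off
    meta$sigma_hat <- sigma_hat
    meta$E_Kr <- E_Nernst
    attr(ikr, "meta") <- meta
    traces[[trace_key(row$well, row$protocol, row$sweep, "pre")]] <- ikr
    ann[[i]] <- tibble::tibble(
      well = row$well, protocol = row$protocol, sweep = row$sweep,
      g_L = leak_pre$g_L, E_L = leak_pre$E_L,
      E_obs = E_obs, V_off = V_off, sigma_hat = sigma_hat,
      postdrug_ratio = rms(post_c$current_pA) / rms(pre_c$current_pA),
      reversal_ok = !is.na(E_obs))
  }
  structure(list(traces = traces, annotations = dplyr::bind_rows(ann),
                 design = design, protocols = protocols,
                 E_Nernst = E_Nernst),
            class = "ikr_postprocessed")
}

#' @export
print.ikr_postprocessed <- function(x, ...) {
  cat("<ikr_postprocessed> ", length(x$traces),
      " corrected sweeps; E_Nernst = ", round(x$E_Nernst, 2), " mV\n",
      sep = "")
  invisible(x)
}

#' Quality-control filtering of wells
#'
#' A well passes only if every criterion passes on all of its sweeps:
#' noise below `max_sigma`, stability of the staircase response between the
#' first and last pre-drug d1 sweeps (NRMSE below `max_staircase_drift`),
#' every observed reversal potential within `max_Eobs_deviation` of the
#' Nernst value, and the post-drug leak-corrected current small relative to
#' the pre-drug one. Wells missing the four d1 repeats fail automatically.
#'
#' @param pp An [postprocess_dataset()] result.
#' @param criteria A [qc_criteria()] object.
#' @param staircase Name of the repeated stability protocol (default "d1").
#' @return A list: `passing` (character vector of wells) and `flags`
#'   (tibble well x criterion logical columns, `pass` overall).
#' @export
qc_filter <- function(pp, criteria = qc_criteria(), staircase = "d1") {
  ann <- pp$annotations
  wells <- unique(ann$well)
  flag_rows <- lapply(wells, function(w) {
    wa <- ann[ann$well == w, ]
    d1 <- wa[wa$protocol == staircase, ]
    has_repeats <- nrow(d1) >= 4
    drift <- NA_real_
    if (has_repeats) {
      first <- pp$traces[[trace_key(w, staircase, min(d1$sweep), "pre")]]
      last <- pp$traces[[trace_key(w, staircase, max(d1$sweep), "pre")]]
      drift <- nrmse(first$current_pA, last$current_pA)
    }
    ok_sigma <- all(wa$sigma_hat <= criteria$max_sigma)
    ok_drift <- has_repeats && !is.na(drift) &&
      drift <= criteria$max_staircase_drift
    ok_eobs <- all(wa$reversal_ok) &&
      all(abs(wa$E_obs - pp$E_Nernst) <= criteria$max_Eobs_deviation)
    ok_ratio <- all(wa$postdrug_ratio <= criteria$max_postdrug_ratio)
    tibble::tibble(well = w, has_d1_repeats = has_repeats,
                   sigma_ok = ok_sigma, drift_ok = ok_drift,
                   eobs_ok = ok_eobs, postdrug_ok = ok_ratio,
                   staircase_drift = drift,
                   pass = has_repeats & ok_sigma & ok_drift &
                     ok_eobs & ok_ratio)
  })
  flags <- dplyr::bind_rows(flag_rows)
  list(passing = flags$well[flags$pass], flags = flags)
}
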