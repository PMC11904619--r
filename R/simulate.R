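#' Forward simulation of IKr Markov models
#'
#' The state-occupancy ODE `dx/dt = t(Q(V)) x` is linear; while the command
#' voltage is constant the solution is a matrix exponential, and on ramps the
#' system is integrated numerically with the stiff solver LSODA at tight
#' tolerances. [simulate_current()] combines the two (matrix exponentials on
#' steps, LSODA on ramps) and maps occupancies to current through
#' `IKr = g * x_O * (Vm - EKr)` with `Vm = Vcmd + Voff`. The offset sign is
#' chosen so that the reversal-potential estimator
#' `Voff = ENernst - Eobs` recovers the same quantity the simulator consumes
#' (the observed zero-crossing then sits at `Eobs = ENernst - Voff`).
#'
#' @name simulator
NULL

# Propagate x' = Qt x from x0 to the (segment-relative) times in `times`,
# Qt constant. Eigendecomposition when well-conditioned, otherwise repeated
# uniform-step exponentials via scaling-and-squaring (Matrix::expm-free Pade
# would be overkill; eigen covers all four structures in practice).
propagate_constant <- function(Qt, x0, times) {
  n <- length(x0)
  if (length(times) == 0) {
    return(matrix(numeric(0), 0, n))
  }
  eig <- eigen(Qt, symmetric = FALSE)
  V <- eig$vectors
  co <- tryCatch(solve(V, x0), error = function(e) NULL)
  if (!is.null(co) && all(is.finite(Mod(co))) && max(Mod(co)) < 1e10) {
    M <- exp(outer(times, eig$values))      # T x N
    X <- Re((M * matrix(co, nrow = length(times), ncol = n, byrow = TRUE)) %*% t(V))
  } else {
    X <- matrix(0, length(times), n)
    ord <- order(times)
    x <- x0
    t_prev <- 0
    for (k in ord) {
      dt <- times[k] - t_prev
      if (dt > 0) x <- as.vector(expm_pade(Qt * dt) %*% x)
      X[k, ] <- x
      t_prev <- times[k]
    }
  }
  X
}

# Scaling-and-squaring matrix exponential (fallback for defective Qt).
expm_pade <- function(A) {
  n <- nrow(A)
  j <- max(0, ceiling(log2(max(1e-300, norm(A, "I")))) + 1)
  A <- A / 2^j
  # order-6 Taylor with Horner; adequate at the scaled norm
  E <- diag(n)
  term <- diag(n)
  for (k in 1:8) {
    term <- term %*% A / k
    E <- E + term
  }
  for (k in seq_len(j)) E <- E %*% E
  E
}

#' Matrix-exponential solution on a constant-voltage segment
#'
#' @param model An [build_model()] object.
#' @param params Full parameter vector.
#' @param V Constant membrane voltage (mV).
#' @param x0 Initial occupancy vector.
#' @param t_grid Times (ms, relative to the segment start) at which to
#'   return the solution.
#' @return A `length(t_grid) x n_states` occupancy matrix.
#' @export
solve_segment_constant <- function(model, params, V, x0, t_grid) {
  stopifnot(length(x0) == model$n_states,
            abs(sum(x0) - 1) < 1e-6, all(x0 >= -1e-8))
  Qt <- t(rate_matrix(model, params, V))
  X <- propagate_constant(Qt, x0, t_grid)
  colnames(X) <- model$state_names
  X
}

#' Stiff numeric integration across a whole protocol
#'
#' Integrates the occupancy ODE over every segment (steps and ramps alike)
#' with LSODA, using the protocol's command voltage and a fixed voltage
#' offset. Serves as the all-numeric reference path for the hybrid
#' simulator.
#'
#' @inheritParams solve_segment_constant
#' @param protocol A `voltage_protocol`.
#' @param x0 Initial occupancy (defaults to the steady state at the starting
#'   membrane voltage).
#' @param V_off Systematic voltage offset (mV); the model sees
#'   `Vm = Vcmd + V_off`.
#' @param rtol,atol Solver tolerances (default 1e-8, both).
#' @param times Output times (defaults to the protocol grid).
#' @return Occupancy matrix on `times`.
#' @export
solve_numeric <- function(model, params, protocol, x0 = NULL, V_off = 0,
                          rtol = 1e-8, atol = 1e-8, times = NULL) {
  validate_params(model, params)
  times <- times %||% protocol_times(protocol)
  if (is.null(x0)) {
    x0 <- steady_state(model, params, voltage_at(protocol, 0) + V_off)
  }
  deriv <- function(t, x, parms) {
    V <- voltage_at(protocol, min(t, protocol_duration(protocol))) + V_off
    list(as.vector(t(rate_matrix(model, params, V)) %*% x))
  }
  sol <- deSolve::lsoda(y = x0, times = if (times[1] == 0) times else c(0, times),
                        func = deriv, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("LSODA failed while integrating protocol '",
         protocol_name(protocol), "'.", call. = FALSE)
  }
  X <- unname(sol[, -1, drop = FALSE])
  if (times[1] != 0) X <- X[-1, , drop = FALSE]
  colnames(X) <- model$state_names
  X
}

# Map each grid time to its protocol segment (boundary -> later segment).
segment_index <- function(protocol, times) {
  ends <- cumsum(protocol$duration_ms)
  starts <- c(0, ends[-length(ends)])
  idx <- findInterval(times, starts)
  idx[times >= ends[length(ends)]] <- length(ends)
  idx
}

# Precompute everything per protocol that the per-parameter simulation loop
# reuses: the sample grid, command voltage, and per-segment sample indices.
protocol_cache <- function(protocol) {
  times <- protocol_times(protocol)
  v_cmd <- voltage_at(protocol, times)
  seg_of <- segment_index(protocol, times)
  ends <- cumsum(protocol$duration_ms)
  starts <- c(0, ends[-length(ends)])
  n_seg <- nrow(protocol)
  pts <- split(seq_along(times), factor(seg_of, levels = seq_len(n_seg)))
  tl <- lapply(seq_len(n_seg), function(s) times[pts[[s]]] - starts[s])
  list(times = times, v_cmd = v_cmd, pts = pts, tl = tl,
       durs = protocol$duration_ms, kind = protocol$kind,
       v0 = protocol$v_start_mV, v1 = protocol$v_end_mV,
       n_seg = n_seg, name = protocol_name(protocol))
}

steady_state_fast <- function(model, params, V) {
  Q <- rate_matrix_fast(model, params, V)
  n <- nrow(Q)
  x <- qr.solve(rbind(t(Q), rep(1, n)), c(rep(0, n), 1))
  x <- pmin(pmax(x, 0), 1)
  x / sum(x)
}

# Hybrid occupancy solve on a cached protocol; returns the T x N matrix.
sim_states_core <- function(model, params, cache, V_off, rtol, atol) {
  X <- matrix(0, length(cache$times), model$n_states)
  x <- steady_state_fast(model, params, -80 + V_off)
  Qt_at <- make_Qt_fun(model, params)
  for (s in seq_len(cache$n_seg)) {
    pts <- cache$pts[[s]]
    tl <- cache$tl[[s]]
    dur <- cache$durs[s]
    if (cache$kind[s] == "step") {
      Qt <- Qt_at(cache$v0[s] + V_off)
      Xl <- propagate_constant(Qt, x, c(tl, dur))
      if (length(pts)) X[pts, ] <- Xl[seq_along(pts), , drop = FALSE]
      x <- Xl[nrow(Xl), ]
    } else {
      v0 <- cache$v0[s] + V_off
      v1 <- cache$v1[s] + V_off
      slope <- (v1 - v0) / dur
      deriv <- function(t, y, parms) {
        V <- v0 + slope * if (t < dur) t else dur
        list(Qt_at(V) %*% y)
      }
      out_t <- sort(unique(c(0, tl, dur)))
      sol <- deSolve::lsoda(y = x, times = out_t, func = deriv,
                            parms = NULL, rtol = rtol, atol = atol)
      if (attr(sol, "istate")[1] < 0) {
        stop("LSODA failed on ramp segment ", s, " of protocol '",
             cache$name, "'.", call. = FALSE)
      }
      Xr <- unname(sol[, -1, drop = FALSE])
      if (length(pts)) X[pts, ] <- Xr[match(tl, out_t), , drop = FALSE]
      x <- Xr[nrow(Xr), ]
    }
    x <- pmin(pmax(x, 0), 1)
    x <- x / sum(x)
  }
  X
}

# Current on the cached grid; the fitting objective's hot path.
sim_current_core <- function(model, params, cache, E_Kr, V_off,
                             rtol = 1e-8, atol = 1e-8) {
  X <- sim_states_core(model, params, cache, V_off, rtol, atol)
  params[model$conductance_index] * X[, model$open_index] *
    (cache$v_cmd + V_off - E_Kr)
}

#' Simulate the IKr current under a protocol
#'
#' Hybrid forward simulation: matrix exponentials on constant-voltage
#' segments, LSODA (rtol = atol = 1e-8) on ramps. The initial state is the
#' steady state at the membrane voltage corresponding to the -80 mV holding
#' command. The current is `g * x_O * (Vm - EKr)` in pA with `g` in nS and
#' voltages in mV.
#'
#' @inheritParams solve_numeric
#' @param E_Kr Reversal potential (mV), e.g. from [nernst_potential()].
#' @param method `"hybrid"` (default) or `"numeric"` (LSODA on every
#'   segment).
#' @return An `ikr_simulation` object: list with `trace` (a tibble with
#'   columns `time_ms`, `v_cmd_mV`, `open_prob`, `current_pA`), `states`
#'   (occupancy matrix), and simulation metadata.
#' @export
simulate_current <- function(model, params, protocol, E_Kr,
                             V_off = 0, method = c("hybrid", "numeric"),
                             rtol = 1e-8, atol = 1e-8) {
  method <- match.arg(method)
  validate_params(model, params)
  cache <- protocol_cache(protocol)
  times <- cache$times
  v_cmd <- cache$v_cmd
  v_m <- v_cmd + V_off

  if (method == "numeric") {
    x0 <- steady_state(model, params, -80 + V_off)
    X <- solve_numeric(model, params, protocol, x0 = x0, V_off = V_off,
                       rtol = rtol, atol = atol, times = times)
  } else {
    X <- sim_states_core(model, params, cache, V_off, rtol, atol)
    colnames(X) <- model$state_names
  }

  g <- params[model$conductance_index]
  open_prob <- X[, model$open_index]
  current <- g * open_prob * (v_m - E_Kr)
  structure(
    list(
      trace = tibble::tibble(time_ms = times, v_cmd_mV = v_cmd,
                             open_prob = open_prob, current_pA = current),
      states = X,
      model = model$name,
      protocol = protocol_name(protocol),
      E_Kr = E_Kr, V_off = V_off,
      method = method, rtol = rtol, atol = atol
    ),
    class = "ikr_simulation"
  )
}

#' @export
print.ikr_simulation <- function(x, ...) {
  cat("<ikr_simulation> model ", x$model, " under protocol ", x$protocol,
      ": ", nrow(x$trace), " samples, peak |I| = ",
      signif(max(abs(x$trace$current_pA)), 4), " pA\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.ikr_simulation <- function(x, ...) x$trace

#' Plot a simulated current and command voltage
#'
#' @param object An `ikr_simulation`.
#' @param ... Unused.
#' @return A ggplot object (current and voltage panels).
#' @export
autoplot.ikr_simulation <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace,
                            c("current_pA", "v_cmd_mV"),
                            names_to = "signal", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$signal), scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = paste(object$model, "under", object$protocol))
}

#' Write / read a current trace CSV
#'
#' Columns `time_ms, current_pA`; [write_trace_csv()] accepts a sweep tibble
#' or an `ikr_simulation`.
#'
#' @param trace A tibble with `time_ms` and `current_pA`, or an
#'   `ikr_simulation`.
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "ikr_simulation")) trace <- trace$trace
  utils::write.csv(as.data.frame(trace[, c("time_ms", "current_pA")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
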