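#' Markov model structures for IKr
#'
#' `build_model()` constructs one of four literature Markov model structures
#' for the rapid delayed rectifier potassium current, IKr. Each model is a
#' small set of channel conformations (closed, open, inactivated) with
#' voltage-dependent transition rates of the form `A * exp(+/- b * V)`
#' (`A` in 1/ms, `b` in 1/mV, `V` in mV), plus a maximal conductance `g`
#' (nS) that scales open-state occupancy into current.
#'
#' Supported structures:
#' \describe{
#'   \item{`"coi"`}{Three states C-O-I in a chain; 8 kinetic parameters + g
#'     (9 total).}
#'   \item{`"beattie"`}{Four states C, O, I, IC arranged in a square with
#'     Hodgkin-Huxley-style shared rates; 8 kinetic parameters + g (9 total).
#'     Includes an I-IC-C pathway that avoids the open state.}
#'   \item{`"kemp"`}{Five states: the Beattie square (C1, O, I, IC) plus an
#'     extra closed state C2 attached to C1 with its own voltage-dependent
#'     rate pair; 12 kinetic parameters + g (13 total). The connectivity is a
#'     transcription stand-in for the published five-state structure, which
#'     is given only graphically in its source.}
#'   \item{`"wang"`}{Five states C1-C2-C3-O-I in a chain; the C2<->C3
#'     transition uses two voltage-independent rates (kf, kb); 14 kinetic
#'     parameters + g (15 total). The inactivated state connects only through
#'     the open state.}
#' }
#'
#' The parameter vector ordering follows the even/odd rate-index convention:
#' transition pairs are listed in structural order, each voltage-dependent
#' rate contributing `(A, b)` slots, each constant rate a single `A` slot;
#' the maximal conductance is always the last element.
#'
#' @param name One of `"coi"`, `"beattie"`, `"kemp"`, `"wang"`
#'   (case-insensitive; `"c-o-i"` is accepted for `"coi"`).
#' @return An object of class `ikr_model`: a list with elements
#'   `name`, `state_names`, `n_states`, `open_index`, `transitions`
#'   (a tibble with columns `from`, `to`, `form`, `A_index`, `b_index`),
#'   `n_kinetic_params`, `conductance_index`, `total_params`,
#'   `param_names`, and `default_params`.
#' @examples
#' m <- build_model("beattie")
#' m$total_params      # 9
#' rate_matrix(m, m$default_params, V = 0)
#' @export
build_model <- function(name) {
  key <- tolower(gsub("[^a-z]", "", tolower(name)))
  spec <- switch(key,
    coi = model_spec_coi(),
    beattie = model_spec_beattie(),
    kemp = model_spec_kemp(),
    wang = model_spec_wang(),
    stop("Unknown model '", name,
         "'. Supported models: coi (c-o-i), beattie, kemp, wang.",
         call. = FALSE)
  )
  spec
}

new_ikr_model <- function(name, state_names, open_state, transitions,
                          default_params) {
  n_states <- length(state_names)
  stopifnot(sum(state_names == open_state) == 1)
  n_kin <- max(c(transitions$A_index, transitions$b_index), na.rm = TRUE)
  param_names <- character(n_kin)
  for (i in seq_len(nrow(transitions))) {
    tr <- transitions[i, ]
    lab <- paste0(tr$from, "_", tr$to)
    if (param_names[tr$A_index] == "") param_names[tr$A_index] <- paste0("A_", lab)
    if (!is.na(tr$b_index) && param_names[tr$b_index] == "")
      param_names[tr$b_index] <- paste0("b_", lab)
  }
  # precomputed integer views of the transition table for fast Q assembly
  sign_of <- c(pos_exp = 1, neg_exp = -1, constant = 0)
  structure(
    list(
      name = name,
      state_names = state_names,
      n_states = n_states,
      open_index = match(open_state, state_names),
      transitions = transitions,
      n_kinetic_params = n_kin,
      conductance_index = n_kin + 1L,
      total_params = n_kin + 1L,
      param_names = c(param_names, "g"),
      default_params = default_params,
      tr_from = match(transitions$from, state_names),
      tr_to = match(transitions$to, state_names),
      tr_sign = unname(sign_of[transitions$form]),
      tr_A = transitions$A_index,
      tr_b = ifelse(is.na(transitions$b_index), 0L, transitions$b_index)
    ),
    class = "ikr_model"
  )
}

transition_row <- function(from, to, form, A_index, b_index = NA_integer_) {
  tibble::tibble(from = from, to = to, form = form,
                 A_index = as.integer(A_index), b_index = as.integer(b_index))
}

# Shared-rate square used by the Beattie and Kemp structures: forward
# activation k1 = A1 exp(b1 V), deactivation k2 = A2 exp(-b2 V),
# inactivation k3 = A3 exp(b3 V), recovery k4 = A4 exp(-b4 V).
hh_square <- function(C = "C", O = "O", I = "I", IC = "IC", offset = 0L) {
  a <- function(k) offset + c(1L, 3L, 5L, 7L)[k]
  b <- function(k) offset + c(2L, 4L, 6L, 8L)[k]
  dplyr::bind_rows(
    transition_row(C, O, "pos_exp", a(1), b(1)),
    transition_row(O, C, "neg_exp", a(2), b(2)),
    transition_row(O, I, "pos_exp", a(3), b(3)),
    transition_row(I, O, "neg_exp", a(4), b(4)),
    transition_row(IC, I, "pos_exp", a(1), b(1)),
    transition_row(I, IC, "neg_exp", a(2), b(2)),
    transition_row(C, IC, "pos_exp", a(3), b(3)),
    transition_row(IC, C, "neg_exp", a(4), b(4))
  )
}

# Room-temperature defaults in the field's usual range (the source text prints
# no parameter values); implementer-chosen, used as synthetic ground truth.
beattie_defaults <- c(2.26e-4, 0.0699, 3.45e-5, 0.05462,
                      0.0873, 8.91e-3, 5.15e-3, 0.03158, 100)

model_spec_coi <- function() {
  tr <- dplyr::bind_rows(
    transition_row("C", "O", "pos_exp", 1L, 2L),
    transition_row("O", "C", "neg_exp", 3L, 4L),
    transition_row("O", "I", "pos_exp", 5L, 6L),
    transition_row("I", "O", "neg_exp", 7L, 8L)
  )
  new_ikr_model("coi", c("C", "O", "I"), "O", tr, beattie_defaults)
}

model_spec_beattie <- function() {
  new_ikr_model("beattie", c("C", "O", "I", "IC"), "O",
                hh_square(), beattie_defaults)
}

model_spec_kemp <- function() {
  tr <- dplyr::bind_rows(
    hh_square(C = "C1"),
    transition_row("C2", "C1", "pos_exp", 9L, 10L),
    transition_row("C1", "C2", "neg_exp", 11L, 12L)
  )
  defaults <- c(beattie_defaults[1:8], 0.02, 0.02, 0.04, 0.015, 100)
  new_ikr_model("kemp", c("C1", "O", "I", "IC", "C2"), "O", tr, defaults)
}

model_spec_wang <- function() {
  tr <- dplyr::bind_rows(
    transition_row("C1", "C2", "pos_exp", 1L, 2L),
    transition_row("C2", "C1", "neg_exp", 3L, 4L),
    transition_row("C2", "C3", "constant", 5L),
    transition_row("C3", "C2", "constant", 6L),
    transition_row("C3", "O", "pos_exp", 7L, 8L),
    transition_row("O", "C3", "neg_exp", 9L, 10L),
    transition_row("O", "I", "pos_exp", 11L, 12L),
    transition_row("I", "O", "neg_exp", 13L, 14L)
  )
  # Original published rate constants (22 C) as defaults, g implementer-chosen
  defaults <- c(0.022348, 0.01176, 0.047002, 0.0631,
                0.023761, 0.036778,
                0.013733, 0.038198, 6.89e-5, 0.04178,
                0.090821, 0.023391, 0.006497, 0.03268, 100)
  new_ikr_model("wang", c("C1", "C2", "C3", "O", "I"), "O", tr, defaults)
}

#' @export
print.ikr_model <- function(x, ...) {
  cat("<ikr_model> ", x$name, ": ", x$n_states, " states (",
      paste(x$state_names, collapse = ", "), "), open state '",
      x$state_names[x$open_index], "', ", x$total_params,
      " parameters (", x$n_kinetic_params, " kinetic + g)\n", sep = "")
  invisible(x)
}

#' Evaluate a single transition rate
#'
#' Rates take one of three forms: `pos_exp` gives `A * exp(+b * V)`,
#' `neg_exp` gives `A * exp(-b * V)`, and `constant` gives `A`.
#'
#' @param form `"pos_exp"`, `"neg_exp"`, or `"constant"`.
#' @param A Pre-factor (1/ms), strictly positive.
#' @param b Exponent coefficient (1/mV), non-negative; ignored for
#'   `form = "constant"`.
#' @param V Membrane voltage (mV).
#' @return The rate in 1/ms (vectorised over `V`).
#' @export
transition_rate <- function(form, A, b = 0, V) {
  if (any(!is.finite(V))) stop("V must be finite.", call. = FALSE)
  if (any(A <= 0)) stop("Rate pre-factor A must be strictly positive.",
                        call. = FALSE)
  switch(form,
    pos_exp = A * exp(b * V),
    neg_exp = A * exp(-b * V),
    constant = rep_len(A, length(V)),
    stop("Unknown rate form '", form, "'.", call. = FALSE)
  )
}

validate_params <- function(model, params) {
  if (length(params) != model$total_params) {
    stop("Model '", model$name, "' expects ", model$total_params,
         " parameters, got ", length(params), ".", call. = FALSE)
  }
  kin <- params[seq_len(model$n_kinetic_params)]
  is_b <- startsWith(model$param_names[seq_len(model$n_kinetic_params)], "b_")
  g <- params[model$conductance_index]
  bad <- any(!is.finite(params)) || any(kin[!is_b] <= 0) ||
    any(kin[is_b] < 0) || g < 0
  if (bad) {
    stop("Rate pre-factors must be finite and strictly positive; exponent ",
         "coefficients and the conductance must be non-negative.",
         call. = FALSE)
  }
  invisible(params)
}

#' Transition-rate matrix Q at a voltage
#'
#' Builds the generator matrix of the continuous-time Markov chain at
#' membrane voltage `V`: `Q[i, j]` is the i -> j transition rate (1/ms)
#' and each diagonal entry is minus its row sum, so rows sum to zero.
#' The state-occupancy ODE is `dx/dt = t(Q) %*% x`.
#'
#' @param model An [build_model()] object.
#' @param params Full parameter vector (kinetic parameters then g).
#' @param V Voltage (mV), scalar.
#' @return An `n_states x n_states` numeric matrix.
#' @export
rate_matrix <- function(model, params, V) {
  validate_params(model, params)
  Q <- rate_matrix_fast(model, params, V)
  dimnames(Q) <- list(model$state_names, model$state_names)
  Q
}

# no-validation fast path used inside simulation loops
rate_matrix_fast <- function(model, params, V) {
  n <- model$n_states
  A <- params[model$tr_A]
  b <- params[pmax(model$tr_b, 1L)] * (model$tr_b != 0L)
  k <- A * exp(model$tr_sign * b * V)
  Q <- matrix(0, n, n)
  Q[cbind(model$tr_from, model$tr_to)] <- k
  diag(Q) <- -rowSums(Q)
  Q
}

# Factory: freeze (model, params) and return V -> t(Q) for the inner
# simulation loops (assembles the transpose directly; diagonal = -out-rates).
make_Qt_fun <- function(model, params) {
  n <- model$n_states
  A <- params[model$tr_A]
  sb <- model$tr_sign * params[pmax(model$tr_b, 1L)] * (model$tr_b != 0L)
  idx <- cbind(model$tr_to, model$tr_from)
  diag_idx <- cbind(seq_len(n), seq_len(n))
  template <- matrix(0, n, n)
  from <- model$tr_from
  function(V) {
    k <- A * exp(sb * V)
    Qt <- template
    Qt[idx] <- k
    out_rates <- numeric(n)
    for (i in seq_along(k)) out_rates[from[i]] <- out_rates[from[i]] + k[i]
    Qt[diag_idx] <- -out_rates
    Qt
  }
}

#' Nernst potential for potassium
#'
#' The theoretical reversal potential `(R*T/F) * ln(K_out / K_in)` in mV.
#' With the study solutions (4 mM external, 132 mM internal K+) at 25 C this
#' is approximately -90 mV.
#'
#' @param K_out Extracellular potassium concentration (mM).
#' @param K_in Intracellular potassium concentration (mM).
#' @param temperature Temperature in Kelvin (default 298.15 K = 25 C).
#' @return Reversal potential in mV.
#' @examples
#' nernst_potential(4, 132)  # about -90 mV
#' @export
nernst_potential <- function(K_out, K_in, temperature = 298.15) {
  if (K_out <= 0 || K_in <= 0) {
    stop("Potassium concentrations must be strictly positive.", call. = FALSE)
  }
  if (temperature <= 0) stop("Temperature must be positive.", call. = FALSE)
  R_gas <- 8.31446261815324   # J / (mol K)
  Faraday <- 96485.33212331   # C / mol
  1000 * (R_gas * temperature / Faraday) * log(K_out / K_in)
}

#' Steady-state occupancy at a fixed voltage
#'
#' Solves the linear system `t(Q) x = 0`, `sum(x) = 1` for the unique global
#' equilibrium of the governing ODE (guaranteed by the connected transition
#' graph). Used to initialise simulations at the holding potential.
#'
#' @inheritParams rate_matrix
#' @return A probability vector over states (named).
#' @export
steady_state <- function(model, params, V) {
  Q <- rate_matrix(model, params, V)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  bvec <- c(rep(0, n), 1)
  x <- tryCatch(qr.solve(A, bvec),
                error = function(e) stop("Failed to solve for steady state; ",
                                         "is the transition graph connected?",
                                         call. = FALSE))
  if (max(abs(t(Q) %*% x)) > 1e-8) {
    stop("Steady-state solve did not converge; the structure may be ",
         "disconnected or numerically singular.", call. = FALSE)
  }
  x <- pmin(pmax(x, 0), 1)
  x <- x / sum(x)
  stats::setNames(as.numeric(x), model$state_names)
}

#' Export a model structure as a plain table
#'
#' Returns one row per transition with the rate form and parameter slots,
#' suitable for serialisation (e.g. `jsonlite::toJSON()`) and documentation.
#'
#' @param model An [build_model()] object.
#' @return A tibble with columns `from`, `to`, `form`, `A_index`, `b_index`,
#'   `A_name`, `b_name`.
#' @export
model_structure_table <- function(model) {
  tr <- model$transitions
  dplyr::mutate(tr,
    A_name = model$param_names[.data$A_index],
    b_name = ifelse(is.na(.data$b_index), NA_character_,
                    model$param_names[.data$b_index]))
}
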