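# Shared fixtures: small protocols and datasets kept deliberately coarse so
# the default suite stays fast; scientific checks that need the full staircase
# use staircase_like() directly.

E_NERNST <- nernst_potential(4, 132)

# short staircase: same shape as d1 but fewer, shorter treads
short_staircase <- function(sample_interval = 10, step_ms = 100,
                            rise_mV = 40) {
  staircase_like(step_ms = step_ms, rise_mV = rise_mV, name = "d1",
                 sample_interval = sample_interval)
}

# minimal 3-protocol battery (d6 is the validation-only stand-in)
small_battery <- function(sample_interval = 10) {
  list(
    d1 = short_staircase(sample_interval),
    d2 = generate_random_protocol(seed = 21, n_main_steps = 5, name = "d2",
                                  sample_interval = sample_interval),
    d6 = generate_random_protocol(seed = 26, n_main_steps = 3, name = "d6",
                                  sample_interval = sample_interval))
}

# a two-state toy model (closed <-> open) built through the package's own
# constructor; closed-form steady state (k21, k12)/(k12 + k21)
toy_two_state <- function() {
  tr <- dplyr::bind_rows(
    ikrfit:::transition_row("C", "O", "pos_exp", 1L, 2L),
    ikrfit:::transition_row("O", "C", "neg_exp", 3L, 4L))
  ikrfit:::new_ikr_model("toy2", c("C", "O"), "O", tr,
                         c(0.02, 0.03, 0.05, 0.01, 1))
}

# synthetic pure-leak trace on a protocol grid (no ODE involved)
leak_trace <- function(protocol, g_L, E_L, sigma = 0, seed = 1) {
  times <- protocol_times(protocol)
  v <- voltage_at(protocol, times)
  cur <- g_L * (v - E_L)
  if (sigma > 0) {
    cur <- cur + withr::with_seed(seed, rnorm(length(times), 0, sigma))
  }
  out <- tibble::tibble(time_ms = times, current_pA = cur)
  attr(out, "meta") <- list(well = "W", protocol = attr(protocol, "protocol_name"),
                            sweep = 1L, drug_state = "pre")
  out
}
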