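#' Voltage-clamp protocols
#'
#' A protocol is an ordered table of command-voltage segments. Each segment
#' is a constant step or a linear ramp with a duration (ms) and start/end
#' voltages (mV), tagged with the scaffold section it belongs to. Every
#' protocol in the battery shares the same scaffolding: it starts at the
#' -80 mV holding potential, runs a leak ramp (step to -120 mV, then a slow
#' ramp back to -80 mV) and a +40 mV leak-validation step, and ends with a
#' +40 mV preconditioning step followed by a fast reversal ramp from -70 mV
#' down to -110 mV and a final hold. The leak ramp supports linear-leak
#' fitting (IKr is tiny between -120 and -80 mV); the reversal ramp lets the
#' observed reversal potential be read off from the zero-crossing of the
#' leak-corrected, drug-subtracted current.
#'
#' @name voltage_protocol
NULL

protocol_columns <- c("section_tag", "kind", "duration_ms",
                      "v_start_mV", "v_end_mV")

new_voltage_protocol <- function(segments, name, sample_interval = 1) {
  segments <- tibble::as_tibble(segments)[, protocol_columns]
  num <- c("duration_ms", "v_start_mV", "v_end_mV")
  segments[num] <- lapply(segments[num], as.numeric)
  out <- structure(segments,
                   class = c("voltage_protocol", class(tibble::tibble())))
  attr(out, "protocol_name") <- name
  attr(out, "sample_interval") <- sample_interval
  out
}

#' Validate a protocol's structural invariants
#'
#' Checks the scaffold contract: positive durations, voltages within
#' [-140, 80] mV, a -80 mV start, exactly one leak ramp at the head and one
#' reversal ramp (descending -70 to -110 mV) near the tail.
#'
#' @param protocol A protocol tibble.
#' @return The protocol, invisibly; errors describe the first violation.
#' @export
validate_protocol <- function(protocol) {
  p <- protocol
  stopifnot(all(protocol_columns %in% names(p)))
  if (any(p$duration_ms <= 0)) stop("Segment durations must be > 0.", call. = FALSE)
  volts <- c(p$v_start_mV, p$v_end_mV)
  if (any(volts < -140 | volts > 80)) {
    stop("Voltages must lie within [-140, 80] mV.", call. = FALSE)
  }
  if (p$v_start_mV[1] != -80) {
    stop("Protocols must begin at the -80 mV holding potential.", call. = FALSE)
  }
  if (any(p$kind == "step" & p$v_start_mV != p$v_end_mV)) {
    stop("Step segments must have v_start == v_end.", call. = FALSE)
  }
  lr <- which(p$section_tag == "leak_ramp")
  rr <- which(p$section_tag == "reversal_ramp")
  if (length(lr) == 0 || min(lr) > 4) {
    stop("Protocol must contain a leak_ramp section at the start.", call. = FALSE)
  }
  if (length(rr) != 1) {
    stop("Protocol must contain exactly one reversal_ramp segment.", call. = FALSE)
  }
  if (!(p$v_start_mV[rr] == -70 && p$v_end_mV[rr] == -110)) {
    stop("The reversal ramp must descend from -70 mV to -110 mV.", call. = FALSE)
  }
  invisible(protocol)
}

protocol_name <- function(protocol) {
  attr(protocol, "protocol_name") %||% "protocol"
}

sample_interval <- function(protocol) {
  attr(protocol, "sample_interval") %||% 1
}

seg_row <- function(section_tag, kind, duration_ms, v_start, v_end = v_start) {
  tibble::tibble(section_tag = section_tag, kind = kind,
                 duration_ms = duration_ms,
                 v_start_mV = v_start, v_end_mV = v_end)
}

#' Common protocol scaffolding
#'
#' Returns the leading and trailing segment blocks shared by every protocol:
#' hold at -80, step to -120, leak ramp back up to -80, a +40 mV
#' leak-validation step (leading); and a +40 mV preconditioning step, the
#' -70 to -110 mV reversal ramp, and a final -80 mV hold (trailing).
#' Durations are configurable defaults (the scaffold voltages are fixed by
#' design, the durations are not).
#'
#' @param hold_ms,step120_ms,leak_ramp_ms,validation_ms,precondition_ms,
#'   reversal_ramp_ms,final_hold_ms Section durations in ms.
#' @return A list with tibbles `leading` and `trailing`.
#' @export
make_scaffold <- function(hold_ms = 250, step120_ms = 50, leak_ramp_ms = 400,
                          validation_ms = 200, precondition_ms = 500,
                          reversal_ramp_ms = 100, final_hold_ms = 500) {
  leading <- dplyr::bind_rows(
    seg_row("hold", "step", hold_ms, -80),
    seg_row("leak_ramp", "step", step120_ms, -120),
    seg_row("leak_ramp", "ramp", leak_ramp_ms, -120, -80),
    seg_row("leak_validation", "step", validation_ms, 40)
  )
  trailing <- dplyr::bind_rows(
    seg_row("reversal_precondition", "step", precondition_ms, 40),
    seg_row("reversal_ramp", "ramp", reversal_ramp_ms, -70, -110),
    seg_row("hold", "step", final_hold_ms, -80)
  )
  list(leading = leading, trailing = trailing)
}

#' Assemble a protocol from a main section and the standard scaffold
#'
#' @param main A tibble of segments (may be empty) forming the
#'   protocol-specific main section; its `section_tag` is set to `"main"`.
#' @param name Protocol identifier (e.g. `"d2"`).
#' @param sample_interval Sampling interval in ms.
#' @param scaffold Output of [make_scaffold()].
#' @return A validated `voltage_protocol`.
#' @export
assemble_protocol <- function(main, name, sample_interval = 1,
                              scaffold = make_scaffold()) {
  if (nrow(main) > 0) main$section_tag <- "main"
  segments <- dplyr::bind_rows(scaffold$leading, main, scaffold$trailing)
  out <- new_voltage_protocol(segments, name, sample_interval)
  validate_protocol(out)
  out
}

#' Command voltage at arbitrary times
#'
#' Piecewise-constant on steps, linear on ramps. A time falling exactly on a
#' segment boundary belongs to the *later* segment (step-change semantics of
#' a command voltage).
#'
#' @param protocol A `voltage_protocol`.
#' @param t Time(s) in ms, within `[0, total duration]`.
#' @return Voltage(s) in mV.
#' @export
voltage_at <- function(protocol, t) {
  ends <- cumsum(protocol$duration_ms)
  starts <- c(0, ends[-length(ends)])
  total <- ends[length(ends)]
  if (any(t < 0 | t > total)) {
    stop("t outside the protocol duration [0, ", total, "] ms.", call. = FALSE)
  }
  # boundary belongs to the later segment; the final endpoint stays in the last
  idx <- findInterval(t, starts, left.open = FALSE)
  idx[t >= total] <- length(ends)
  frac <- (t - starts[idx]) / protocol$duration_ms[idx]
  v0 <- protocol$v_start_mV[idx]
  v1 <- protocol$v_end_mV[idx]
  ifelse(protocol$kind[idx] == "ramp", v0 + frac * (v1 - v0), v0)
}

#' Total protocol duration in ms
#' @param protocol A `voltage_protocol`.
#' @export
protocol_duration <- function(protocol) sum(protocol$duration_ms)

#' Uniform sampling grid for a protocol
#'
#' Times from 0 to the total duration at the protocol's sampling interval
#' (endpoint excluded so that all sweeps share `duration / interval` points).
#'
#' @param protocol A `voltage_protocol`.
#' @return Numeric vector of times (ms).
#' @export
protocol_times <- function(protocol) {
  dt <- sample_interval(protocol)
  seq(0, protocol_duration(protocol) - dt, by = dt)
}

#' Seeded random step protocol
#'
#' Generates a protocol with the standard scaffold around `n_main_steps`
#' random constant-voltage steps. Stands in for numerically optimised
#' experimental designs whose waveforms are deposited with data archives
#' rather than printed.
#'
#' @param seed Integer seed; identical seeds give identical protocols.
#' @param n_main_steps Number of random steps in the main section.
#' @param v_bounds Length-2 voltage bounds (mV), within [-120, 60].
#' @param dur_bounds Length-2 duration bounds (ms).
#' @param name Protocol identifier.
#' @param sample_interval Sampling interval (ms).
#' @return A `voltage_protocol`.
#' @export
generate_random_protocol <- function(seed, n_main_steps = 10,
                                     v_bounds = c(-120, 60),
                                     dur_bounds = c(50, 500),
                                     name = paste0("rand", seed),
                                     sample_interval = 1) {
  stopifnot(v_bounds[1] >= -120, v_bounds[2] <= 60,
            v_bounds[1] < v_bounds[2], dur_bounds[1] < dur_bounds[2])
  draws <- with_seed(seed, list(
    volts = round(stats::runif(n_main_steps, v_bounds[1], v_bounds[2])),
    durs = round(stats::runif(n_main_steps, dur_bounds[1], dur_bounds[2]))
  ))
  volts <- draws$volts
  durs <- draws$durs
  main <- seg_row("main", "step", durs, volts)
  assemble_protocol(main, name, sample_interval)
}

#' Deterministic staircase-style protocol
#'
#' An ascending then descending sequence of voltage steps spanning
#' [-120, 40] mV between the standard scaffolds; a stand-in for the
#' published staircase design used to make IKr kinetics identifiable from a
#' single sweep.
#'
#' @param step_ms Duration of each staircase tread (ms).
#' @param rise_mV Voltage increment between treads (mV).
#' @param name Protocol identifier (defaults to `"d1"`).
#' @param sample_interval Sampling interval (ms).
#' @return A `voltage_protocol`.
#' @export
staircase_like <- function(step_ms = 250, rise_mV = 20, name = "d1",
                           sample_interval = 1) {
  up <- seq(-120, 40, by = rise_mV)
  down <- seq(40 - rise_mV, -120, by = -rise_mV)
  volts <- c(up, down)
  main <- seg_row("main", "step", rep(step_ms, length(volts)), volts)
  assemble_protocol(main, name, sample_interval)
}

#' Read / write a protocol as CSV
#'
#' One row per segment with columns `section_tag, kind, duration_ms,
#' v_start_mV, v_end_mV`; round-trips exactly.
#'
#' @param protocol A `voltage_protocol`.
#' @param path File path.
#' @param name Protocol name on read (defaults to the file stem).
#' @param sample_interval Sampling interval attached on read.
#' @export
write_protocol_csv <- function(protocol, path) {
  utils::write.csv(as.data.frame(protocol)[, protocol_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_protocol_csv
#' @export
read_protocol_csv <- function(path, name = NULL, sample_interval = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  name <- name %||% sub("\\.csv$", "", basename(path))
  out <- new_voltage_protocol(df, name, sample_interval)
  validate_protocol(out)
  out
}

#' Default protocol battery
#'
#' Twelve protocols d1..d12: d1 is the deterministic staircase-style design;
#' d2..d12 are seeded random-step protocols standing in for the optimised
#' designs. d6 is designated validation-only (models are deliberately hard to
#' identify from it; here it is a short, sparse design).
#'
#' @param sample_interval Sampling interval (ms) shared by all protocols.
#' @param n_main_steps Steps in each random main section.
#' @param seed Base seed for the random designs.
#' @return A named list of `voltage_protocol` objects.
#' @export
default_protocol_battery <- function(sample_interval = 1, n_main_steps = 10,
                                     seed = 1234) {
  battery <- list(d1 = staircase_like(sample_interval = sample_interval))
  for (i in 2:12) {
    nm <- paste0("d", i)
    n_steps <- if (nm == "d6") 4 else n_main_steps
    battery[[nm]] <- generate_random_protocol(
      seed = seed + i, n_main_steps = n_steps, name = nm,
      sample_interval = sample_interval)
  }
  battery
}

#' Experiment design table
#'
#' The within-well ordering of sweeps: two d1 sweeps, one sweep of each other
#' protocol, two closing d1 sweeps; the whole block repeated after drug
#' addition. `fitting` marks sweeps used for model fitting (all except the
#' validation-only protocol).
#'
#' @param protocol_names Names of the battery protocols (default d1..d12).
#' @param wells Character vector of well identifiers.
#' @param validation_only Protocols excluded from fitting (default `"d6"`).
#' @return A tibble with columns `well`, `protocol`, `sweep`, `drug_state`,
#'   `order`, `fitting`.
#' @export
experiment_design <- function(protocol_names = paste0("d", 1:12),
                              wells = "A01", validation_only = "d6") {
  others <- setdiff(protocol_names, "d1")
  block <- tibble::tibble(
    protocol = c("d1", "d1", others, "d1", "d1"),
    sweep = c(1L, 2L, rep(1L, length(others)), 3L, 4L)
  )
  per_drug <- dplyr::bind_rows(
    dplyr::mutate(block, drug_state = "pre"),
    dplyr::mutate(block, drug_state = "post")
  )
  per_drug$order <- seq_len(nrow(per_drug))
  design <- tidyr::expand_grid(well = wells, per_drug)
  design$fitting <- !(design$protocol %in% validation_only)
  dplyr::select(design, "well", "protocol", "sweep", "drug_state",
                "order", "fitting")
}

#' @importFrom rlang %||% .data
NULL

#' Plot a protocol's command voltage
#'
#' @param object A `voltage_protocol`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voltage_protocol <- function(object, ...) {
  t <- protocol_times(object)
  df <- tibble::tibble(time_ms = t, v_mV = voltage_at(object, t))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$v_mV)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ms)", y = "command voltage (mV)",
                  title = protocol_name(object))
}
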