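#' Episodic voltage-step stimulation protocol
#'
#' Describes the standard IV protocol: from a holding potential, a family of
#' test steps (start..stop in fixed increments, one sweep per step) each
#' preceded by a baseline segment and followed by a fixed tail pulse.
#'
#' @param holding_mV Holding potential (baseline segment voltage), mV.
#' @param start_mV,stop_mV,increment_mV Test-step family, mV. `increment_mV`
#'   must be nonzero and divide `stop_mV - start_mV` exactly.
#' @param step_ms Test-step duration, ms.
#' @param tail_mV,tail_ms Tail-pulse voltage (mV) and duration (ms).
#' @param baseline_ms Pre-step baseline duration, ms.
#' @param rate_kHz Sampling rate, kHz.
#' @return Object of class `voltage_protocol`. Sweeps are 0-based:
#'   sweep i steps to `start_mV + i * increment_mV`.
#' @export
#' @examples
#' p <- build_step_protocol()      # -100..+180 mV, 20-mV steps
#' p$n_sweeps                      # 15
build_step_protocol <- function(holding_mV = 0, start_mV = -100,
                                stop_mV = 180, increment_mV = 20,
                                step_ms = 300, tail_mV = -80, tail_ms = 175,
                                baseline_ms = 50, rate_kHz = 5) {
  if (increment_mV == 0) stop("increment_mV must be nonzero")
  n_span <- (stop_mV - start_mV) / increment_mV
  if (abs(n_span - round(n_span)) > 1e-9)
    stop("increment_mV must divide (stop_mV - start_mV) exactly")
  if (n_span < 0) stop("increment sign must run from start to stop")
  if (any(c(step_ms, tail_ms, baseline_ms, rate_kHz) <= 0) && baseline_ms < 0)
    stop("durations and rate must be positive")
  if (step_ms <= 0 || tail_ms <= 0 || rate_kHz <= 0 || baseline_ms < 0)
    stop("durations and rate must be positive")
  structure(list(kind = "step", holding_mV = holding_mV, start_mV = start_mV,
                 stop_mV = stop_mV, increment_mV = increment_mV,
                 step_ms = step_ms, tail_mV = tail_mV, tail_ms = tail_ms,
                 baseline_ms = baseline_ms, rate_kHz = rate_kHz,
                 n_sweeps = as.integer(round(n_span)) + 1L),
            class = "voltage_protocol")
}

#' Tail-current (reversal-potential) stimulation protocol
#'
#' A fixed activating prepulse followed by a family of test ("tail") steps;
#' the tail segment is the analysis target for [estimate_vrev()].
#'
#' @param holding_mV Holding potential, mV.
#' @param prepulse_mV,prepulse_ms Activating prepulse voltage and duration.
#' @param start_mV,stop_mV,increment_mV Tail-step family, mV.
#' @param tail_ms Tail-step duration, ms.
#' @param baseline_ms Pre-prepulse baseline, ms.
#' @param rate_kHz Sampling rate, kHz.
#' @return Object of class `voltage_protocol` (kind `"tail"`); per sweep the
#'   segments are baseline, prepulse, tail step.
#' @export
#' @examples
#' build_tail_protocol()   # +140 mV prepulse, tails -50..+50 mV
build_tail_protocol <- function(holding_mV = 0, prepulse_mV = 140,
                                prepulse_ms = 200, start_mV = -50,
                                stop_mV = 50, increment_mV = 10,
                                tail_ms = 175, baseline_ms = 50,
                                rate_kHz = 5) {
  if (increment_mV == 0) stop("increment_mV must be nonzero")
  n_span <- (stop_mV - start_mV) / increment_mV
  if (abs(n_span - round(n_span)) > 1e-9)
    stop("increment_mV must divide (stop_mV - start_mV) exactly")
  if (prepulse_ms <= 0 || tail_ms <= 0 || rate_kHz <= 0 || baseline_ms < 0)
    stop("durations and rate must be positive")
  structure(list(kind = "tail", holding_mV = holding_mV,
                 prepulse_mV = prepulse_mV, prepulse_ms = prepulse_ms,
                 start_mV = start_mV, stop_mV = stop_mV,
                 increment_mV = increment_mV, tail_ms = tail_ms,
                 baseline_ms = baseline_ms, rate_kHz = rate_kHz,
                 n_sweeps = as.integer(round(n_span)) + 1L),
            class = "voltage_protocol")
}

#' Step voltages of a protocol
#'
#' @param protocol A `voltage_protocol`.
#' @return Numeric vector of per-sweep test (or tail) voltages, mV.
#' @export
protocol_voltages <- function(protocol) {
  protocol$start_mV + protocol$increment_mV * (seq_len(protocol$n_sweeps) - 1)
}

# Segment boundaries (ms from sweep start): named vector of segment end times.
.protocol_segments <- function(protocol) {
  if (protocol$kind == "step") {
    c(baseline = protocol$baseline_ms,
      step = protocol$baseline_ms + protocol$step_ms,
      tail = protocol$baseline_ms + protocol$step_ms + protocol$tail_ms)
  } else {
    c(baseline = protocol$baseline_ms,
      prepulse = protocol$baseline_ms + protocol$prepulse_ms,
      tail = protocol$baseline_ms + protocol$prepulse_ms + protocol$tail_ms)
  }
}

#' Total sweep duration (ms)
#' @param protocol A `voltage_protocol`.
#' @export
sweep_duration <- function(protocol) {
  unname(.protocol_segments(protocol)[length(.protocol_segments(protocol))])
}

#' Command voltage at a given time within a sweep
#'
#' Piecewise-constant command voltage: baseline (holding) segment, then the
#' test step (or fixed prepulse), then the tail segment.
#'
#' @param protocol A `voltage_protocol`.
#' @param sweep 0-based sweep index.
#' @param t_ms Time from sweep start, ms (vectorized).
#' @return Command voltage(s), mV.
#' @export
#' @examples
#' p <- build_step_protocol()
#' voltage_at(p, 0, c(10, 100, 400))   # holding, step (-100), tail (-80)
voltage_at <- function(protocol, sweep, t_ms) {
  if (sweep < 0 || sweep >= protocol$n_sweeps)
    stop("sweep index out of range: ", sweep)
  seg <- .protocol_segments(protocol)
  if (any(t_ms < 0 | t_ms > seg[[3]]))
    stop("t_ms outside protocol span")
  step_v <- protocol$start_mV + protocol$increment_mV * sweep
  if (protocol$kind == "step") {
    v_mid <- step_v
    v_tail <- protocol$tail_mV
  } else {
    v_mid <- protocol$prepulse_mV
    v_tail <- step_v
  }
  ifelse(t_ms < seg[[1]], protocol$holding_mV,
         ifelse(t_ms < seg[[2]], v_mid, v_tail))
}

#' Sample time base of a protocol (ms)
#'
#' Sample times start at half a sampling interval and are common to all
#' sweeps of a recording.
#' @param protocol A `voltage_protocol`.
#' @export
time_base <- function(protocol) {
  dt <- 1 / protocol$rate_kHz
  n <- round(sweep_duration(protocol) * protocol$rate_kHz)
  (seq_len(n) - 0.5) * dt
}
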