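#' Phase-coded periodic spike pattern
#'
#' A stored memory: one spiking phase per neuron relative to a collective
#' oscillation, plus the frequency at which the pattern was stored. Unit `i`
#' of pattern `mu` spikes at times `phi_i/(2 pi nu) + n/nu` (ms, with `nu` in
#' Hz converted internally), i.e. once per cycle at a fixed phase.
#'
#' @param phases numeric vector of phases in `[0, 2*pi)`, one per neuron.
#' @param frequency_hz positive storing frequency in Hz.
#' @param pattern_id positive integer identifier (`mu`).
#' @return an object of class `phase_pattern` with fields `pattern_id`,
#'   `n_units`, `phases`, `frequency_hz`.
#' @examples
#' p <- phase_pattern(c(0, pi/2, pi), 3)
#' period_ms(p)
#' @export
phase_pattern <- function(phases, frequency_hz, pattern_id = 1L) {
  if (!is.numeric(phases) || length(phases) < 1L || anyNA(phases)) {
    abort("`phases` must be a non-empty numeric vector")
  }
  if (any(phases < 0 | phases >= 2 * pi)) {
    abort("all phases must lie in [0, 2*pi)")
  }
  stopifnot_scalar_number(frequency_hz, "frequency_hz")
  pattern_id <- as.integer(pattern_id)
  if (is.na(pattern_id) || pattern_id < 1L) abort("`pattern_id` must be >= 1")
  structure(
    list(pattern_id = pattern_id, n_units = length(phases),
         phases = as.double(phases), frequency_hz = as.double(frequency_hz)),
    class = "phase_pattern")
}

#' @export
print.phase_pattern <- function(x, ...) {
  cat(sprintf("<phase_pattern %d> %d units at %g Hz (period %.6g ms)\n",
              x$pattern_id, x$n_units, x$frequency_hz, period_ms(x)))
  invisible(x)
}

#' Oscillation period of a pattern in milliseconds
#' @param pattern a [phase_pattern()].
#' @export
period_ms <- function(pattern) 1000 / pattern$frequency_hz

#' Draw a random phase pattern
#'
#' Phases are i.i.d. uniform on `[0, 2*pi)` from the seeded `"patterns"`
#' stream; the same `(seed, pattern_id)` always yields the same pattern.
#'
#' @param n_units number of neurons (N).
#' @param frequency_hz storing frequency in Hz.
#' @param seed master integer seed.
#' @param pattern_id pattern index `mu` (also the stream index).
#' @return a [phase_pattern()].
#' @export
generate_random_pattern <- function(n_units, frequency_hz, seed,
                                    pattern_id = 1L) {
  stopifnot_scalar_number(n_units, "n_units")
  if (n_units != round(n_units) || n_units < 1) {
    abort("`n_units` must be a positive integer")
  }
  stopifnot_scalar_number(frequency_hz, "frequency_hz")
  phases <- with_stream(seed, "patterns", pattern_id,
                        runif(n_units, 0, 2 * pi))
  # runif is open at both ends so phases land strictly inside [0, 2*pi)
  phase_pattern(phases, frequency_hz, pattern_id)
}

#' Draw a set of independent random patterns sharing N and frequency
#'
#' @param n_patterns number of patterns P.
#' @param n_units,frequency_hz,seed as in [generate_random_pattern()].
#' @return list of [phase_pattern()]s with ids `1..n_patterns`.
#' @export
generate_pattern_set <- function(n_patterns, n_units, frequency_hz, seed) {
  lapply(seq_len(n_patterns), function(mu) {
    generate_random_pattern(n_units, frequency_hz, seed, pattern_id = mu)
  })
}

#' Spike times of one unit of a pattern inside a time window
#'
#' All times `phi/(2 pi nu) + n/nu` falling in `[t_start, t_end)`, strictly
#' increasing — exactly one spike per period.
#'
#' @param pattern a [phase_pattern()].
#' @param unit 1-based unit index.
#' @param t_start,t_end window bounds in ms, `t_start < t_end`.
#' @return numeric vector of spike times in ms.
#' @export
pattern_spike_times <- function(pattern, unit, t_start, t_end) {
  if (unit < 1 || unit > pattern$n_units || unit != round(unit)) {
    abort(sprintf("`unit` must be an integer in 1..%d", pattern$n_units))
  }
  if (!(t_start < t_end)) abort("`t_start` must be less than `t_end`")
  T <- period_ms(pattern)
  t0 <- pattern$phases[unit] / (2 * pi) * T
  n_lo <- ceiling((t_start - t0) / T)
  n_hi <- floor((t_end - t0) / T)
  if (t0 + n_hi * T >= t_end) n_hi <- n_hi - 1L  # right-open window
  if (n_hi < n_lo) return(numeric(0))
  t0 + (n_lo:n_hi) * T
}

#' Sample the full spike train of a pattern as a tidy event table
#'
#' Convenience wrapper over [pattern_spike_times()] for all units; useful to
#' score a pattern against itself or to build synthetic replay trains.
#'
#' @inheritParams pattern_spike_times
#' @param time_scale multiply all spike times by this factor (time-compressed
#'   or dilated replay of the same phase pattern).
#' @return a `spike_train` tibble with columns `time_ms`, `unit`, `source`.
#' @export
pattern_spike_train <- function(pattern, t_start, t_end, time_scale = 1) {
  ev <- lapply(seq_len(pattern$n_units), function(u) {
    tt <- pattern_spike_times(pattern, u, t_start / time_scale,
                              t_end / time_scale) * time_scale
    if (length(tt)) tibble::tibble(time_ms = tt, unit = u) else NULL
  })
  tbl <- dplyr::bind_rows(ev)
  tbl <- dplyr::arrange(tbl, .data$time_ms, .data$unit)
  tbl$source <- "net"
  new_spike_train(tbl, n_units = pattern$n_units, duration = t_end, dt = NA_real_)
}
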