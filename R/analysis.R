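#' Estimate the period of the collective dynamics
#'
#' Default method: the median inter-spike interval pooled over all units with
#' at least two spikes in the window. During clean one-spike-per-cycle replay
#' every unit fires once per collective cycle, so the median ISI is the
#' collective period. The alternative `"max-overlap"` method scans a grid of
#' candidate periods for the one maximising the overlap with a reference
#' pattern — useful for short or non-periodic trains.
#'
#' @param train a `spike_train`.
#' @param window numeric `c(t0, t1)` analysis window in ms; default
#'   `c(600, duration)`.
#' @param method `"median-isi"` (default) or `"max-overlap"`.
#' @param pattern reference [phase_pattern()], required for `"max-overlap"`.
#' @param T_grid candidate periods (ms) for `"max-overlap"`.
#' @return the period estimate `T*` in ms.
#' @export
estimate_period <- function(train, window = NULL,
                            method = c("median-isi", "max-overlap"),
                            pattern = NULL,
                            T_grid = seq(5, 500, by = 1)) {
  method <- match.arg(method)
  window <- default_window(train, window)
  ev <- train[train$time_ms >= window[1] & train$time_ms <= window[2] &
                train$source != "cue", , drop = FALSE]
  if (nrow(ev) == 0L) abort("no spikes in the window: period undefined")
  if (method == "median-isi") {
    isis <- unlist(lapply(split(ev$time_ms, ev$unit), function(tt) {
      if (length(tt) >= 2L) diff(sort(tt)) else numeric(0)
    }), use.names = FALSE)
    if (length(isis) == 0L) {
      abort("no unit has two spikes in the window: period undefined")
    }
    return(median(isis))
  }
  if (is.null(pattern)) abort("`pattern` is required for method = \"max-overlap\"")
  scores <- vapply(T_grid, function(Ts) {
    mean(overlap_at_times(ev, pattern, Ts,
                          eval_times = seq(window[1] + Ts, window[2],
                                           length.out = 5)))
  }, numeric(1))
  T_grid[which.max(scores)]
}

default_window <- function(train, window, t_bar = 600) {
  if (!is.null(window)) return(window)
  dur <- attr(train, "duration")
  if (is.null(dur)) dur <- max(train$time_ms)
  c(min(t_bar, dur / 2), dur)
}

# core overlap evaluation at a vector of times; events must be the (already
# filtered, non-cue if desired) spike table
overlap_at_times <- function(events, pattern, T_star, eval_times) {
  N <- pattern$n_units
  if (nrow(events) == 0L) return(rep(0, length(eval_times)))
  ord <- order(events$time_ms, events$unit)
  L <- last_spike_matrix_cpp(events$time_ms[ord],
                             as.integer(events$unit[ord]) - 1L,
                             N, as.double(eval_times), T_star)
  # phase of each unit's most recent spike vs its stored phase
  Z <- exp(1i * sweep(-2 * pi * L / T_star, 2, pattern$phases, "+"))
  Z[is.na(L)] <- 0 + 0i
  Mod(rowSums(Z)) / N
}

#' Overlap order parameter at a single time
#'
#' \deqn{|m^\mu(t)| = \Big|\frac{1}{N}\sum_j e^{-i 2\pi t_j^*/T^*}
#'   e^{i\phi_j^\mu}\Big|}
#' where the sum runs over units whose most recent spike `t_j*` lies in
#' `(t - T*, t]`; units silent in that window contribute zero and the
#' prefactor stays `1/N`. Equal to 1 for a perfectly phase-aligned replay at
#' any time scale, of order `1/sqrt(N)` for phases uncorrelated with the
#' pattern.
#'
#' @param train a `spike_train` (all non-cue events are considered).
#' @param pattern a [phase_pattern()].
#' @param T_star period estimate in ms (see [estimate_period()]).
#' @param t evaluation time in ms.
#' @return `|m|` in `[0, 1]`.
#' @export
overlap <- function(train, pattern, T_star, t) {
  stopifnot_scalar_number(T_star, "T_star")
  ev <- train[train$source != "cue", , drop = FALSE]
  overlap_at_times(ev, pattern, T_star, t)
}

#' Overlap trajectories against all stored patterns
#'
#' Evaluates `|m^mu(t)|` for every stored pattern on a regular grid of times
#' (default cadence `T*/2`) inside the analysis window.
#'
#' @inheritParams overlap
#' @param patterns list of [phase_pattern()]s (or a single pattern).
#' @param window analysis window `c(t0, t1)` in ms; default `c(600, duration)`.
#' @param T_star period estimate; estimated from the train when `NULL`.
#' @param every evaluation cadence in ms (default `T_star/2`).
#' @return an `overlap_series` tibble with columns `time_ms`, `pattern_id`,
#'   `overlap`, and attribute `period_estimate` (`NA` if the window is
#'   silent, in which case the series is empty).
#' @export
overlap_series <- function(train, patterns, window = NULL, T_star = NULL,
                           every = NULL) {
  if (inherits(patterns, "phase_pattern")) patterns <- list(patterns)
  window <- default_window(train, window)
  ev <- train[train$source != "cue", , drop = FALSE]
  in_win <- ev$time_ms >= window[1] & ev$time_ms <= window[2]
  if (!any(in_win)) {
    out <- tibble::tibble(time_ms = numeric(0), pattern_id = integer(0),
                          overlap = numeric(0))
    attr(out, "period_estimate") <- NA_real_
    class(out) <- c("overlap_series", class(out))
    return(out)
  }
  if (is.null(T_star)) T_star <- estimate_period(train, window)
  if (is.null(every)) every <- T_star / 2
  eval_times <- seq(window[1] + T_star, window[2], by = every)
  if (length(eval_times) == 0L) eval_times <- window[2]
  out <- dplyr::bind_rows(lapply(patterns, function(p) {
    tibble::tibble(time_ms = eval_times,
                   pattern_id = p$pattern_id,
                   overlap = overlap_at_times(ev, p, T_star, eval_times))
  }))
  attr(out, "period_estimate") <- T_star
  class(out) <- c("overlap_series", class(out))
  out
}

#' Replay frequency of the collective dynamics
#'
#' `1000/T*` (Hz) with `T*` from [estimate_period()] on the steady-state
#' window. Replay is typically time-compressed: faster than the stored
#' frequency for low stored frequencies.
#'
#' @inheritParams estimate_period
#' @export
replay_frequency <- function(train, window = NULL, ...) {
  1000 / estimate_period(train, window, ...)
}

#' Mean number of spikes per collective cycle
#'
#' Mean over active units (>= 1 spike in the window) of the spike count
#' divided by the number of cycles the window spans. One during clean
#' one-spike-per-cycle replay; grows when the threshold is lowered at high
#' stored frequencies.
#'
#' @inheritParams overlap
#' @param window analysis window `c(t0, t1)` in ms.
#' @export
spikes_per_cycle <- function(train, T_star, window = NULL) {
  stopifnot_scalar_number(T_star, "T_star")
  window <- default_window(train, window)
  ev <- train[train$time_ms >= window[1] & train$time_ms <= window[2] &
                train$source != "cue", , drop = FALSE]
  if (nrow(ev) == 0L) abort("no spikes in the window")
  counts <- table(ev$unit)
  n_cycles <- (window[2] - window[1]) / T_star
  mean(as.numeric(counts)) / n_cycles
}

#' Per-unit oscillation periods (burst-aware)
#'
#' The collective rhythm is defined by one burst per cycle and unit: at low
#' thresholds a unit may emit several spikes within a cycle (a doublet or
#' burst) while still being locked to the single collective oscillation.
#' Spikes closer than `burst_gap` are therefore grouped into one burst and a
#' unit's oscillation period is the mean interval between successive burst
#' onsets — the quantity that is shared across units when the network keeps a
#' unique collective frequency, regardless of per-unit spike counts.
#'
#' @inheritParams spikes_per_cycle
#' @param burst_gap intervals below this (ms) are within-burst; default
#'   `T_star/2`.
#' @return tibble with one row per unit having >= 2 bursts: `unit`,
#'   `period_ms`, `n_bursts`, `spikes_per_burst`.
#' @export
unit_oscillation_periods <- function(train, T_star, window = NULL,
                                     burst_gap = T_star / 2) {
  window <- default_window(train, window)
  ev <- train[train$time_ms >= window[1] & train$time_ms <= window[2] &
                train$source != "cue", , drop = FALSE]
  rows <- lapply(split(ev$time_ms, ev$unit), function(tt) {
    tt <- sort(tt)
    starts <- tt[c(TRUE, diff(tt) >= burst_gap)]
    if (length(starts) < 2L) return(NULL)
    tibble::tibble(period_ms = mean(diff(starts)),
                   n_bursts = length(starts),
                   spikes_per_burst = length(tt) / length(starts))
  })
  keep <- !vapply(rows, is.null, logical(1))
  dplyr::bind_rows(rows[keep], .id = "unit") |>
    dplyr::mutate(unit = as.integer(.data$unit))
}

#' Size of the network response to the cue
#'
#' Number of network (non-cue) spikes after the end of the cue stimulation.
#'
#' @param train a `spike_train`.
#' @param t_cue_end end of the cue window in ms; defaults to the last cue
#'   event in the train (0 when there is none).
#' @return integer `S_tot`.
#' @export
response_size <- function(train, t_cue_end = NULL) {
  if (is.null(t_cue_end)) {
    cue_times <- train$time_ms[train$source == "cue"]
    t_cue_end <- if (length(cue_times)) max(cue_times) else 0
  }
  sum(train$source != "cue" & train$time_ms > t_cue_end)
}

#' Classify the post-cue regime of a run
#'
#' Three regimes: `"silent"` (no network spikes after `t_bar`), `"retrieval"`
#' (persistent activity whose mean overlap with some stored pattern exceeds
#' `threshold`), `"spurious"` (persistent activity with all overlaps at the
#' `1/sqrt(N)` noise floor). The classification is insensitive to the exact
#' `threshold` because steady-state overlaps concentrate near 1 or near
#' `1/sqrt(N)`.
#'
#' @param train a `spike_train`.
#' @param overlaps an [overlap_series()]; computed from `patterns` when `NULL`.
#' @param patterns list of stored [phase_pattern()]s (needed if `overlaps` is
#'   `NULL`).
#' @param t_bar steady-state onset in ms.
#' @param threshold similarity threshold on the mean steady-state overlap.
#' @return a `retrieval_result` object; see [tidy.retrieval_result()].
#' @export
classify_regime <- function(train, overlaps = NULL, patterns = NULL,
                            t_bar = 600, threshold = 0.5) {
  dur <- attr(train, "duration")
  if (is.null(dur)) dur <- max(train$time_ms)
  window <- c(t_bar, dur)
  s_tot <- response_size(train)
  persistent <- any(train$source != "cue" & train$time_ms > t_bar)
  if (!persistent) {
    return(new_retrieval_result("silent", NA_integer_, NA_real_, NA_real_,
                                s_tot, NA_real_))
  }
  if (is.null(overlaps)) {
    if (is.null(patterns)) abort("supply `overlaps` or `patterns`")
    overlaps <- overlap_series(train, patterns, window = window)
  }
  T_star <- attr(overlaps, "period_estimate")
  means <- tapply(overlaps$overlap, overlaps$pattern_id, mean)
  best <- which.max(means)
  spc <- tryCatch(spikes_per_cycle(train, T_star, window),
                  error = function(e) NA_real_)
  if (means[[best]] > threshold) {
    new_retrieval_result("retrieval", as.integer(names(means)[best]),
                         1000 / T_star, spc, s_tot, unname(means[[best]]))
  } else {
    new_retrieval_result("spurious", NA_integer_, 1000 / T_star, spc, s_tot,
                         unname(max(means)))
  }
}

new_retrieval_result <- function(regime, retrieved_pattern,
                                 replay_frequency_hz, spikes_per_cycle,
                                 s_tot, max_overlap) {
  structure(list(regime = regime, retrieved_pattern = retrieved_pattern,
                 replay_frequency_hz = replay_frequency_hz,
                 spikes_per_cycle = spikes_per_cycle,
                 s_tot = as.integer(s_tot), max_overlap = max_overlap),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("<retrieval_result> %s", x$regime))
  if (x$regime == "retrieval") {
    cat(sprintf(" of pattern %d (|m| = %.3f)", x$retrieved_pattern,
                x$max_overlap))
  }
  if (!is.na(x$replay_frequency_hz)) {
    cat(sprintf(", replay %.1f Hz, %.2f spikes/cycle", x$replay_frequency_hz,
                x$spikes_per_cycle))
  }
  cat(sprintf(", S_tot = %d\n", x$s_tot))
  invisible(x)
}
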