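#' Protocol settings for retrieval and capacity experiments
#'
#' Bundles the run-averaging and success settings of the capacity protocol:
#' `n_runs` independent realisations per condition, success judged by the mean
#' steady-state overlap with the cued pattern exceeding `success_threshold`
#' at times beyond `t_bar`. `capacity_protocol()` mirrors the full protocol
#' (50 runs); [desk_protocol()] is the reduced preset used for desk-scale
#' sweeps and in the examples.
#'
#' @param n_runs number of realisations averaged per condition.
#' @param t_bar steady-state onset (ms).
#' @param success_threshold overlap level defining success.
#' @param cue_fraction cued fraction `M/N`.
#' @param duration simulated time per run (ms), must exceed `t_bar`.
#' @param dt integration step (ms).
#' @param T_stim cue time-scale (ms).
#' @return a `capacity_protocol` object.
#' @export
capacity_protocol <- function(n_runs = 50, t_bar = 600,
                              success_threshold = 0.5, cue_fraction = 0.1,
                              duration = 1000, dt = 0.1, T_stim = 50) {
  if (n_runs < 1) abort("`n_runs` must be >= 1")
  if (success_threshold <= 0 || success_threshold >= 1) {
    abort("`success_threshold` must be in (0, 1)")
  }
  if (duration <= t_bar) abort("`duration` must exceed `t_bar`")
  structure(list(n_runs = as.integer(n_runs), t_bar = t_bar,
                 success_threshold = success_threshold,
                 cue_fraction = cue_fraction, duration = duration, dt = dt,
                 T_stim = T_stim), class = "capacity_protocol")
}

#' @rdname capacity_protocol
#' @param ... overrides passed on to [capacity_protocol()].
#' @export
desk_protocol <- function(...) {
  args <- utils::modifyList(list(n_runs = 5L), list(...))
  do.call(capacity_protocol, args)
}

run_one_retrieval <- function(patterns, theta, protocol, run_seed,
                              noise = NULL, stdp = NULL,
                              J = NULL, cue_pattern = 1L) {
  if (is.null(J)) {
    J <- build_connectivity(patterns,
                            params = if (is.null(stdp)) stdp_params() else stdp)
  }
  N <- patterns[[1L]]$n_units
  cue <- make_cue(patterns[[cue_pattern]],
                  M = round(protocol$cue_fraction * N),
                  T_stim = protocol$T_stim)
  simulate_network(J, theta, protocol$duration, dt = protocol$dt, cue = cue,
                   noise = noise, seed = run_seed)
}

mean_steady_overlap <- function(train, pattern, t_bar) {
  ov <- overlap_series(train, pattern,
                       window = c(t_bar, attr(train, "duration")))
  if (nrow(ov) == 0L) return(0)
  mean(ov$overlap)
}

#' Test retrieval success under the capacity protocol
#'
#' Runs `n_runs` seeded realisations that cue pattern 1 and averages the
#' steady-state overlap `|m^1|`. By default every run after the first redraws
#' the random patterns (same N, P and frequency) from the run's own seed
#' stream: with frozen weights and no noise a single realisation is
#' deterministic, so the run-average is an average over pattern realisations.
#'
#' @param patterns list of stored [phase_pattern()]s; pattern 1 is cued.
#' @param theta uniform spiking threshold.
#' @param protocol a [capacity_protocol()].
#' @param seed master seed; run `r` uses the `("runs", r)` stream.
#' @param noise optional [noise_params()] applied in every run.
#' @param fresh_patterns redraw patterns for runs 2..n_runs (default `TRUE`).
#' @return one-row tibble with `success`, `mean_overlap`, `n_runs`.
#' @export
retrieval_success <- function(patterns, theta, protocol = capacity_protocol(),
                              seed = 1L, noise = NULL, fresh_patterns = TRUE) {
  if (length(patterns) == 0L) abort("`patterns` must be non-empty")
  N <- patterns[[1L]]$n_units
  P <- length(patterns)
  nu <- patterns[[1L]]$frequency_hz
  overlaps <- vapply(seq_len(protocol$n_runs), function(r) {
    pats <- if (r == 1L || !fresh_patterns) {
      patterns
    } else {
      generate_pattern_set(P, N, nu, stream_seed(seed, "runs", r))
    }
    train <- run_one_retrieval(pats, theta, protocol,
                               run_seed = stream_seed(seed, "runs", r),
                               noise = noise)
    mean_steady_overlap(train, pats[[1L]], protocol$t_bar)
  }, numeric(1))
  m <- mean(overlaps)
  tibble::tibble(success = m > protocol$success_threshold, mean_overlap = m,
                 n_runs = protocol$n_runs)
}

#' Storage capacity at one (frequency, threshold) point
#'
#' Ascends the number of stored patterns P from 1, drawing fresh random
#' patterns at each P, and returns the largest P for which
#' [retrieval_success()] still holds. The success/failure transition in P is
#' sharp, so the first failure ends the search.
#'
#' @param frequency_hz stored-pattern frequency (Hz).
#' @param theta uniform spiking threshold.
#' @param n_units network size N.
#' @param protocol a [capacity_protocol()].
#' @param seed master seed.
#' @param p_max_search upper bound on the search.
#' @return a `capacity_result`: `P_max` plus the per-P detail table
#'   (see [tidy.capacity_result()]).
#' @export
storage_capacity <- function(frequency_hz, theta, n_units,
                             protocol = capacity_protocol(), seed = 1L,
                             p_max_search = 50L) {
  detail <- list()
  p_max <- 0L
  for (P in seq_len(p_max_search)) {
    pats <- generate_pattern_set(P, n_units, frequency_hz,
                                 stream_seed(seed, "patterns", P))
    res <- retrieval_success(pats, theta, protocol, seed = seed + P)
    detail[[P]] <- dplyr::mutate(res, P = P, .before = 1L)
    if (!res$success) break
    p_max <- P
  }
  structure(list(P_max = p_max, alpha = p_max / n_units,
                 frequency_hz = frequency_hz, theta = theta,
                 n_units = n_units, detail = dplyr::bind_rows(detail)),
            class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("<capacity_result> P_max = %d (alpha = %.4g) at nu = %g Hz, theta = %g, N = %d\n",
              x$P_max, x$alpha, x$frequency_hz, x$theta, x$n_units))
  invisible(x)
}

#' Storage capacity over a (threshold, frequency) grid
#'
#' @param theta_grid,nu_grid numeric grids.
#' @inheritParams storage_capacity
#' @return tibble with one row per grid cell: `theta`, `frequency_hz`,
#'   `P_max`, `alpha`.
#' @export
capacity_surface <- function(theta_grid, nu_grid, n_units,
                             protocol = capacity_protocol(), seed = 1L,
                             p_max_search = 50L) {
  grid <- tidyr::expand_grid(theta = theta_grid, frequency_hz = nu_grid)
  res <- purrr::pmap(grid, function(theta, frequency_hz) {
    cr <- storage_capacity(frequency_hz, theta, n_units, protocol, seed,
                           p_max_search)
    tibble::tibble(P_max = cr$P_max, alpha = cr$alpha)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  attr(out, "n_units") <- n_units
  attr(out, "protocol") <- protocol
  out
}

#' Persistence of activity across a threshold sweep
#'
#' For each threshold, runs `n_realisations` cued simulations (fresh random
#' patterns per realisation) and records the response size `S_tot` and whether
#' network activity persists past `t_bar`. Reports the fraction of runs with
#' `S_tot > n` for `n` in `{0, N/2, N}` and the persistent fraction. The
#' critical threshold is the largest theta whose majority of runs stay
#' persistent.
#'
#' @param theta_grid thresholds to sweep.
#' @param frequency_hz stored frequency (Hz).
#' @param n_units network size.
#' @param n_patterns number of stored patterns P.
#' @param n_realisations runs per threshold.
#' @param seed master seed; realisation r draws patterns from stream
#'   `("runs", r)` (shared across thresholds, so the same connectivity is
#'   reused along the sweep).
#' @param protocol a [capacity_protocol()] (duration, cue, t_bar).
#' @return a `persistence_sweep` object: per-theta tibble plus `theta_crit`
#'   attributes (see [tidy.persistence_sweep()]).
#' @export
persistence_sweep <- function(theta_grid, frequency_hz, n_units,
                              n_patterns = 1L, n_realisations = 5L,
                              seed = 1L, protocol = desk_protocol()) {
  # connectivity is threshold-independent: build once per realisation
  reals <- lapply(seq_len(n_realisations), function(r) {
    pats <- generate_pattern_set(n_patterns, n_units, frequency_hz,
                                 stream_seed(seed, "runs", r))
    list(patterns = pats, J = build_connectivity(pats))
  })
  rows <- lapply(sort(theta_grid), function(theta) {
    s_tot <- vapply(seq_along(reals), function(r) {
      train <- run_one_retrieval(reals[[r]]$patterns, theta, protocol,
                                 run_seed = stream_seed(seed, "runs", r),
                                 J = reals[[r]]$J)
      c(response_size(train),
        as.integer(any(train$source != "cue" &
                         train$time_ms > protocol$t_bar)))
    }, numeric(2))
    tibble::tibble(theta = theta,
                   frac_persistent = mean(s_tot[2, ]),
                   p_s_gt_0 = mean(s_tot[1, ] > 0),
                   p_s_gt_half_n = mean(s_tot[1, ] > n_units / 2),
                   p_s_gt_n = mean(s_tot[1, ] > n_units))
  })
  out <- dplyr::bind_rows(rows)
  crit_of <- function(p) {
    ok <- out$theta[p > 0.5]
    if (length(ok)) max(ok) else NA_real_
  }
  structure(list(sweep = out,
                 theta_crit = crit_of(out$p_s_gt_n),
                 theta_crit_persistent = crit_of(out$frac_persistent),
                 frequency_hz = frequency_hz, n_units = n_units,
                 n_patterns = n_patterns),
            class = "persistence_sweep")
}

#' @export
print.persistence_sweep <- function(x, ...) {
  cat(sprintf("<persistence_sweep> nu = %g Hz, N = %d, P = %d; theta_crit = %s\n",
              x$frequency_hz, x$n_units, x$n_patterns,
              format(x$theta_crit)))
  print(x$sweep)
  invisible(x)
}

#' Replay frequency and spikes per cycle across thresholds
#'
#' Runs one cued simulation per threshold (same stored patterns throughout)
#' and reports the regime, the replay frequency and the spikes per cycle.
#' Cells outside the retrieval regime are flagged by their regime label, not
#' errored.
#'
#' @inheritParams persistence_sweep
#' @param n_patterns stored patterns P (pattern 1 is cued).
#' @param n_seeds realisations averaged per threshold.
#' @return tibble with columns `theta`, `regime`, `replay_frequency_hz`,
#'   `spikes_per_cycle`, `overlap`.
#' @export
frequency_vs_threshold <- function(theta_grid, frequency_hz, n_units,
                                   n_patterns = 1L, n_seeds = 1L, seed = 1L,
                                   protocol = desk_protocol()) {
  reals <- lapply(seq_len(n_seeds), function(r) {
    pats <- generate_pattern_set(n_patterns, n_units, frequency_hz,
                                 stream_seed(seed, "runs", r))
    list(patterns = pats, J = build_connectivity(pats))
  })
  rows <- lapply(theta_grid, function(theta) {
    per_run <- lapply(seq_along(reals), function(r) {
      train <- run_one_retrieval(reals[[r]]$patterns, theta, protocol,
                                 run_seed = stream_seed(seed, "runs", r),
                                 J = reals[[r]]$J)
      res <- classify_regime(train, patterns = reals[[r]]$patterns,
                             t_bar = protocol$t_bar)
      tibble::tibble(regime = res$regime,
                     replay_frequency_hz = res$replay_frequency_hz,
                     spikes_per_cycle = res$spikes_per_cycle,
                     overlap = res$max_overlap)
    })
    per_run <- dplyr::bind_rows(per_run)
    tibble::tibble(
      theta = theta,
      regime = names(which.max(table(per_run$regime))),
      replay_frequency_hz = mean(per_run$replay_frequency_hz, na.rm = TRUE),
      spikes_per_cycle = mean(per_run$spikes_per_cycle, na.rm = TRUE),
      overlap = mean(per_run$overlap, na.rm = TRUE))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "frequency_hz") <- frequency_hz
  attr(out, "n_units") <- n_units
  out
}
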