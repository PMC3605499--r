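#' Tidy a retrieval result
#'
#' @param x a `retrieval_result` from [classify_regime()].
#' @param ... unused.
#' @return one-row tibble with `regime`, `retrieved_pattern`,
#'   `replay_frequency_hz`, `spikes_per_cycle`, `s_tot`, `max_overlap`.
#' @export
tidy.retrieval_result <- function(x, ...) {
  tibble::tibble(regime = x$regime, retrieved_pattern = x$retrieved_pattern,
                 replay_frequency_hz = x$replay_frequency_hz,
                 spikes_per_cycle = x$spikes_per_cycle, s_tot = x$s_tot,
                 max_overlap = x$max_overlap)
}

#' @rdname tidy.retrieval_result
#' @export
glance.retrieval_result <- function(x, ...) tidy.retrieval_result(x, ...)

#' Tidy a capacity result
#'
#' `tidy()` returns the per-P success table of the ascending search;
#' `glance()` the one-row summary with `P_max` and `alpha`.
#'
#' @param x a `capacity_result` from [storage_capacity()].
#' @param ... unused.
#' @export
tidy.capacity_result <- function(x, ...) x$detail

#' @rdname tidy.capacity_result
#' @export
glance.capacity_result <- function(x, ...) {
  tibble::tibble(P_max = x$P_max, alpha = x$alpha,
                 frequency_hz = x$frequency_hz, theta = x$theta,
                 n_units = x$n_units)
}

#' Tidy a persistence sweep
#'
#' `tidy()` returns the per-threshold persistence table; `glance()` the
#' critical thresholds.
#'
#' @param x a `persistence_sweep`.
#' @param ... unused.
#' @export
tidy.persistence_sweep <- function(x, ...) x$sweep

#' @rdname tidy.persistence_sweep
#' @export
glance.persistence_sweep <- function(x, ...) {
  tibble::tibble(theta_crit = x$theta_crit,
                 theta_crit_persistent = x$theta_crit_persistent,
                 frequency_hz = x$frequency_hz, n_units = x$n_units,
                 n_patterns = x$n_patterns)
}
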