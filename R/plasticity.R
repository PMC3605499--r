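#' STDP learning-window parameters
#'
#' The asymmetric spike-timing-dependent plasticity window
#' \deqn{A(\tau) = a_p e^{-\tau/T_p} - a_D e^{-\eta\tau/T_p} \quad (\tau > 0)}
#' \deqn{A(\tau) = a_p e^{\eta\tau/T_D} - a_D e^{\tau/T_D} \quad (\tau < 0)}
#' with amplitudes \eqn{a_p = \gamma\,[1/T_p + \eta/T_D]^{-1}} and
#' \eqn{a_D = \gamma\,[\eta/T_p + 1/T_D]^{-1}}. With these amplitudes the
#' window integrates to zero over the whole axis (balance between potentiation
#' and depression), which in turn balances summed excitation and inhibition in
#' the learned connectivity for uniformly distributed phases. Defaults are the
#' hippocampal-culture fit used throughout the model.
#'
#' @param T_p potentiation decay time (ms).
#' @param T_D depression decay time (ms).
#' @param eta dimensionless asymmetry factor.
#' @param gamma overall learning-rate scale; weights scale linearly in it.
#' @return object of class `stdp_params` with the derived `a_p`, `a_D`.
#' @examples
#' p <- stdp_params()
#' p$a_p; p$a_D          # ~1.7655, ~0.9833
#' stdp_window(0, p)     # a_p - a_D
#' @export
stdp_params <- function(T_p = 10.2, T_D = 28.6, eta = 4, gamma = 0.42) {
  stopifnot_scalar_number(T_p, "T_p")
  stopifnot_scalar_number(T_D, "T_D")
  stopifnot_scalar_number(eta, "eta")
  stopifnot_scalar_number(gamma, "gamma", positive = FALSE)
  if (gamma < 0) abort("`gamma` must be non-negative")
  amp <- c(a_p = gamma / (1 / T_p + eta / T_D),
           a_D = gamma / (eta / T_p + 1 / T_D))
  structure(list(T_p = T_p, T_D = T_D, eta = eta, gamma = gamma,
                 a_p = unname(amp["a_p"]), a_D = unname(amp["a_D"])),
            class = "stdp_params")
}

#' @export
print.stdp_params <- function(x, ...) {
  cat(sprintf(paste0("<stdp_params> T_p=%g ms, T_D=%g ms, eta=%g, gamma=%g ",
                     "(a_p=%.4f, a_D=%.4f)\n"),
              x$T_p, x$T_D, x$eta, x$gamma, x$a_p, x$a_D))
  invisible(x)
}

#' Closed-form window amplitudes
#' @param params an [stdp_params()] object.
#' @return named numeric vector `c(a_p=, a_D=)`.
#' @export
compute_amplitudes <- function(params = stdp_params()) {
  c(a_p = params$a_p, a_D = params$a_D)
}

#' Evaluate the STDP window A(tau)
#'
#' Vectorised over `tau` (ms, post minus pre spike time). At `tau = 0` the two
#' branches share the limit `a_p - a_D`, which is the returned value.
#'
#' @param tau numeric vector of time lags in ms.
#' @inheritParams compute_amplitudes
#' @export
stdp_window <- function(tau, params = stdp_params()) {
  if (anyNA(tau) || !is.numeric(tau)) abort("`tau` must be finite numeric")
  stdp_window_cpp(as.double(tau), params$a_p, params$a_D,
                  params$T_p, params$T_D, params$eta)
}

# span of the truncated periodic sum: everything with |arg| <= 50 T_D plus one
# period of slack; tails beyond that are < 1e-12
.weight_span <- function(params, period) 50 * params$T_D + period

#' Learned weight for one pre/post phase pair
#'
#' The periodic pairwise sum
#' \deqn{J = \sum_n A\big((\phi_{post} - \phi_{pre})/(2\pi\nu) + n/\nu\big)}
#' (post-minus-pre spike lag, the STDP convention: the connection is
#' potentiated when the postsynaptic unit fires shortly after the
#' presynaptic one), truncated to every `n` whose window argument is below
#' `50 T_D` in magnitude
#' (plus one period of slack); the neglected tail is below 1e-12. Invariant
#' under adding multiples of `2*pi` to either phase. Vectorised over phases.
#'
#' @param phase_pre,phase_post phases (radians) of the pre- and post-synaptic
#'   unit.
#' @param frequency_hz storing frequency in Hz.
#' @inheritParams compute_amplitudes
#' @export
pairwise_weight <- function(phase_pre, phase_post, frequency_hz,
                            params = stdp_params()) {
  stopifnot_scalar_number(frequency_hz, "frequency_hz")
  period <- 1000 / frequency_hz
  dt0 <- (phase_post - phase_pre) / (2 * pi) * period
  # fold into one period so truncation bounds are tight for any phase input
  dt0 <- dt0 - round(dt0 / period) * period
  periodic_weight_cpp(as.double(dt0), period, .weight_span(params, period),
                      params$a_p, params$a_D, params$T_p, params$T_D,
                      params$eta)
}

#' Synaptic matrix learned from phase patterns
#'
#' Sums the per-pattern periodic STDP contributions
#' \eqn{J_{ij} = \sum_\mu \sum_n A(t_j^\mu - t_i^\mu + nT^\mu)} over all stored
#' patterns (empty list gives the zero matrix). The diagonal is exactly zero:
#' the network has N(N-1) connections and no self-coupling.
#'
#' @param patterns list of [phase_pattern()]s sharing `n_units` (a single
#'   pattern may be passed directly).
#' @param params an [stdp_params()] object.
#' @param n_units required when `patterns` is empty.
#' @return object of class `synaptic_matrix`: fields `n_units`, `weights`
#'   (dense N x N matrix, `J[i, j]` the connection from presynaptic `j` to
#'   postsynaptic `i`), `pattern_ids`, `params`.
#' @export
build_connectivity <- function(patterns, params = stdp_params(),
                               n_units = NULL) {
  if (inherits(patterns, "phase_pattern")) patterns <- list(patterns)
  if (length(patterns) == 0L) {
    if (is.null(n_units)) abort("`n_units` is required for an empty pattern list")
    return(new_synaptic_matrix(matrix(0, n_units, n_units), integer(0), params))
  }
  ns <- vapply(patterns, function(p) p$n_units, integer(1))
  if (length(unique(ns)) != 1L) abort("all patterns must share `n_units`")
  W <- pattern_weights(patterns[[1L]], params)
  for (p in patterns[-1L]) W <- W + pattern_weights(p, params)
  new_synaptic_matrix(W, vapply(patterns, function(p) p$pattern_id, integer(1)),
                      params)
}

#' Weight contribution of a single pattern (dense matrix)
#'
#' The building block of [build_connectivity()]; exposed so capacity searches
#' can grow the matrix one pattern at a time.
#'
#' @inheritParams build_connectivity
#' @param pattern a [phase_pattern()].
#' @return plain N x N numeric matrix with zero diagonal.
#' @export
pattern_weights <- function(pattern, params = stdp_params()) {
  period <- period_ms(pattern)
  pattern_weights_cpp(pattern$phases, period, .weight_span(params, period),
                      params$a_p, params$a_D, params$T_p, params$T_D,
                      params$eta)
}

new_synaptic_matrix <- function(weights, pattern_ids, params) {
  if (any(!is.finite(weights))) abort("weights must be finite")
  structure(list(n_units = nrow(weights), weights = weights,
                 pattern_ids = pattern_ids, params = params),
            class = "synaptic_matrix")
}

#' Add one more pattern's contribution to an existing matrix
#' @param J a `synaptic_matrix`.
#' @param pattern a [phase_pattern()] with matching `n_units`.
#' @export
add_pattern <- function(J, pattern) {
  if (pattern$n_units != J$n_units) abort("`n_units` mismatch")
  new_synaptic_matrix(J$weights + pattern_weights(pattern, J$params),
                      c(J$pattern_ids, pattern$pattern_id), J$params)
}

#' @export
print.synaptic_matrix <- function(x, ...) {
  cat(sprintf("<synaptic_matrix> %d x %d, %d stored pattern(s)\n",
              x$n_units, x$n_units, length(x$pattern_ids)))
  invisible(x)
}

#' Excitation/inhibition balance of a learned matrix
#'
#' Per presynaptic neuron `j`, the summed excitation it delivers is
#' `(1/N) sum_i max(J_ij, 0)` and the summed inhibition `(1/N) sum_i
#' min(J_ij, 0)`. For patterns with uniform random phases both are O(1) in N
#' and equal in the thermodynamic limit — the excitation-inhibition balance
#' inherited from the zero-integral learning window. `imbalance` is the mean
#' over neurons of the absolute net `(1/N) sum_i J_ij`, which vanishes as
#' `1/sqrt(N)` (each column is a mean of N zero-mean terms).
#'
#' @param J a `synaptic_matrix` (or plain matrix).
#' @return one-row tibble with `mean_excitation`, `mean_inhibition` (averages
#'   over presynaptic neurons of the per-neuron summed values) and
#'   `imbalance` (mean absolute per-neuron net).
#' @export
balance_statistics <- function(J) {
  W <- if (inherits(J, "synaptic_matrix")) J$weights else J
  N <- nrow(W)
  exc <- colSums(pmax(W, 0)) / N
  inh <- colSums(pmin(W, 0)) / N
  tibble::tibble(mean_excitation = mean(exc), mean_inhibition = mean(inh),
                 imbalance = mean(abs(exc + inh)))
}
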