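#' Postsynaptic-potential kernel parameters
#'
#' Double-exponential membrane kernel
#' \deqn{\epsilon(t) = K\,(e^{-t/\tau_m} - e^{-t/\tau_s})\,\Theta(t)}
#' with the normalisation `K` chosen so the peak value is 1 (for the default
#' `tau_m = 10`, `tau_s = 5` ms the peak sits at `10 ln 2 ~ 6.93` ms and
#' `K = 4` exactly). A unit's spiking threshold is therefore measured in units
#' of the unitary PSP peak.
#'
#' @param tau_m membrane time constant (ms), must exceed `tau_s`.
#' @param tau_s synapse time constant (ms).
#' @return object of class `kernel_params` with fields `tau_m`, `tau_s`, `K`,
#'   `t_peak`.
#' @export
kernel_params <- function(tau_m = 10, tau_s = 5) {
  stopifnot_scalar_number(tau_m, "tau_m")
  stopifnot_scalar_number(tau_s, "tau_s")
  if (tau_m <= tau_s) abort("`tau_m` must be greater than `tau_s`")
  t_peak <- tau_m * tau_s / (tau_m - tau_s) * log(tau_m / tau_s)
  K <- 1 / (exp(-t_peak / tau_m) - exp(-t_peak / tau_s))
  structure(list(tau_m = tau_m, tau_s = tau_s, K = K, t_peak = t_peak),
            class = "kernel_params")
}

#' Evaluate the membrane response kernel
#'
#' @param t_since_spike time since the presynaptic arrival (ms); vectorised.
#'   Non-positive times return 0 (causality).
#' @param params a [kernel_params()] object.
#' @export
epsilon <- function(t_since_spike, params = kernel_params()) {
  t <- as.double(t_since_spike)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- params$K * (exp(-t[pos] / params$tau_m) -
                            exp(-t[pos] / params$tau_s))
  out
}

#' Build the cue stimulation for a pattern
#'
#' The cue imposes `M` spikes with the phase structure of the pattern: the `M`
#' units with the smallest phases (by default) each receive one spike at
#' `t_offset + T_stim * phi/(2 pi)`. With uniform phases and `M = N/10` the
#' whole stimulation spans about `T_stim/10` ms (5 ms at the default
#' `T_stim = 50`).
#'
#' @param pattern a [phase_pattern()].
#' @param M number of cued units; default `round(N/10)`.
#' @param T_stim cue time-scale (ms).
#' @param t_offset cue start time (ms).
#' @param selection `"lowest-phase"` (default) or `"random"`.
#' @param seed required for `selection = "random"`.
#' @return tibble with columns `time_ms`, `unit`, sorted by time.
#' @export
make_cue <- function(pattern, M = NULL, T_stim = 50, t_offset = 0,
                     selection = c("lowest-phase", "random"), seed = NULL) {
  selection <- match.arg(selection)
  N <- pattern$n_units
  if (is.null(M)) M <- round(N / 10)
  if (M < 0 || M > N) abort("`M` must be between 0 and `n_units`")
  if (M == 0) return(tibble::tibble(time_ms = numeric(0), unit = integer(0)))
  units <- if (selection == "lowest-phase") {
    order(pattern$phases)[seq_len(M)]
  } else {
    if (is.null(seed)) abort("`seed` is required for random cue selection")
    with_stream(seed, "cue", 0L, sample.int(N, M))
  }
  tbl <- tibble::tibble(
    time_ms = t_offset + T_stim * pattern$phases[units] / (2 * pi),
    unit = as.integer(units))
  dplyr::arrange(tbl, .data$time_ms, .data$unit)
}

#' Poissonian input-noise parameters
#'
#' Each neuron independently receives external arrivals with exponential
#' inter-event intervals (mean `mean_interval_ms`, default `tau_noise`, i.e. a
#' per-neuron rate of `1/tau_noise`) and i.i.d. Gaussian strengths
#' (`J_bar`, `sigma_J`). Arrivals enter the same membrane kernel as synaptic
#' spikes but are never propagated.
#'
#' @param tau_noise characteristic noise time (ms).
#' @param mean_interval_ms per-neuron mean inter-arrival interval (ms);
#'   defaults to `tau_noise`.
#' @param J_bar mean arrival strength.
#' @param sigma_J standard deviation of arrival strengths.
#' @export
noise_params <- function(tau_noise = 10, mean_interval_ms = tau_noise,
                         J_bar = 0, sigma_J = 0) {
  stopifnot_scalar_number(tau_noise, "tau_noise")
  stopifnot_scalar_number(mean_interval_ms, "mean_interval_ms")
  if (sigma_J < 0) abort("`sigma_J` must be non-negative")
  structure(list(tau_noise = tau_noise, mean_interval_ms = mean_interval_ms,
                 J_bar = J_bar, sigma_J = sigma_J), class = "noise_params")
}

#' Sample the external noise events for a simulation
#'
#' @param params a [noise_params()] object.
#' @param n_units network size.
#' @param duration simulated time (ms).
#' @param seed master seed (uses the `"noise"` stream).
#' @return tibble with columns `time_ms`, `unit`, `strength`, sorted by time.
#' @export
make_noise_events <- function(params, n_units, duration, seed) {
  ev <- with_stream(seed, "noise", 0L, {
    res <- vector("list", n_units)
    for (u in seq_len(n_units)) {
      # draw enough exponential gaps to cover the duration, then trim
      n_exp <- max(8L, ceiling(duration / params$mean_interval_ms * 1.5 + 6 *
                                 sqrt(duration / params$mean_interval_ms)))
      tt <- cumsum(rexp(n_exp, rate = 1 / params$mean_interval_ms))
      while (length(tt) && tt[length(tt)] < duration) {
        tt <- c(tt, tt[length(tt)] +
                  cumsum(rexp(n_exp, rate = 1 / params$mean_interval_ms)))
      }
      tt <- tt[tt < duration]
      res[[u]] <- tibble::tibble(
        time_ms = tt, unit = u,
        strength = rnorm(length(tt), params$J_bar, params$sigma_J))
    }
    dplyr::bind_rows(res)
  })
  dplyr::arrange(ev, .data$time_ms, .data$unit)
}

#' Heterogeneous per-unit spiking thresholds
#'
#' `theta_i = (1 + z * zeta_i) * theta` with `zeta_i` i.i.d. uniform on
#' `[-1, 1]`; `z` is the degree of heterogeneity. `z >= 1` would allow
#' non-positive thresholds and is rejected.
#'
#' @param theta mean threshold (positive).
#' @param z heterogeneity degree in `[0, 1)`.
#' @param n_units network size.
#' @param seed master seed (uses the `"heterogeneity"` stream).
#' @return numeric vector of `n_units` thresholds.
#' @export
heterogeneous_thresholds <- function(theta, z, n_units, seed) {
  stopifnot_scalar_number(theta, "theta")
  if (z < 0 || z >= 1) abort("`z` must be in [0, 1) to keep thresholds positive")
  zeta <- with_stream(seed, "heterogeneity", 0L, runif(n_units, -1, 1))
  (1 + z * zeta) * theta
}

new_spike_train <- function(tbl, n_units, duration, dt,
                            theta = NULL, seed = NULL) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "n_units") <- n_units
  attr(tbl, "duration") <- duration
  attr(tbl, "dt") <- dt
  if (!is.null(theta)) attr(tbl, "theta") <- theta
  if (!is.null(seed)) attr(tbl, "seed") <- seed
  class(tbl) <- c("spike_train", class(tbl))
  tbl
}

#' Number of units behind a spike train
#' @param train a `spike_train`.
#' @export
train_n_units <- function(train) attr(train, "n_units")

#' Simulate the spike-response network
#'
#' Advances the network on a fixed time grid of step `dt`. At each step the
#' membrane potential of unit `i` is the kernel-filtered sum of all synaptic
#' (and noise) arrivals strictly after `i`'s own last spike; units with
#' `h_i >= theta_i` fire, are reset (their entire input memory is cleared) and
#' their spikes reach the other units from the next step on. Cue events are
#' imposed output spikes of the cued units: they reset the unit and propagate
#' through `J` like endogenous spikes. Identical inputs (including seed) give
#' identical event lists.
#'
#' @param J a `synaptic_matrix` from [build_connectivity()] (or plain matrix).
#' @param theta spiking threshold: scalar (broadcast) or per-unit vector, all
#'   positive. Units at exactly `h = theta` fire.
#' @param duration simulated time (ms).
#' @param dt time step (ms).
#' @param cue optional cue event table from [make_cue()] (columns `time_ms`,
#'   `unit`); event times snap to the nearest grid step.
#' @param noise optional [noise_params()]; events are drawn internally from
#'   the `"noise"` seed stream.
#' @param seed master seed controlling the noise stream (required when `noise`
#'   has `sigma_J > 0` or nonzero `J_bar`).
#' @param kernel a [kernel_params()] object.
#' @param record_potentials keep the full potential trace (an
#'   `n_steps x N` matrix in `attr(, "potentials")`); only sensible for small
#'   networks.
#' @return a `spike_train` tibble with columns `time_ms`, `unit` (1-based),
#'   `source` (`"cue"` or `"net"`), ordered by time.
#' @export
simulate_network <- function(J, theta, duration, dt = 0.1, cue = NULL,
                             noise = NULL, seed = 0L,
                             kernel = kernel_params(),
                             record_potentials = FALSE) {
  W <- if (inherits(J, "synaptic_matrix")) J$weights else J
  N <- nrow(W)
  if (ncol(W) != N) abort("`J` must be square")
  stopifnot_scalar_number(duration, "duration")
  stopifnot_scalar_number(dt, "dt")
  if (length(theta) == 1L) theta <- rep(theta, N)
  if (length(theta) != N) abort("`theta` must have length 1 or n_units")
  if (any(theta <= 0)) abort("all thresholds must be positive")

  n_steps <- as.integer(round(duration / dt))
  snap <- function(t) pmin(pmax(as.integer(round(t / dt)), 0L), n_steps - 1L)

  if (is.null(cue) || nrow(cue) == 0L) {
    cue_step <- integer(0); cue_unit <- integer(0)
  } else {
    if (any(cue$unit < 1 | cue$unit > N)) abort("cue unit out of range")
    ord <- order(cue$time_ms, cue$unit)
    cue_step <- snap(cue$time_ms[ord]); cue_unit <- as.integer(cue$unit[ord]) - 1L
  }
  if (is.null(noise)) {
    noise_step <- integer(0); noise_unit <- integer(0); noise_w <- numeric(0)
  } else {
    ev <- make_noise_events(noise, N, duration, seed)
    noise_step <- snap(ev$time_ms)
    noise_unit <- as.integer(ev$unit) - 1L
    noise_w <- ev$strength
    ord <- order(noise_step, noise_unit)
    noise_step <- noise_step[ord]; noise_unit <- noise_unit[ord]
    noise_w <- noise_w[ord]
  }

  res <- simulate_cpp(W, as.double(theta), dt, n_steps,
                      kernel$tau_m, kernel$tau_s, kernel$K,
                      cue_step, cue_unit, noise_step, noise_unit, noise_w,
                      record_potentials)
  if (anyNA(res$step)) abort("numerical error: NaN membrane potential")
  tbl <- tibble::tibble(
    time_ms = res$step * dt,
    unit = res$unit + 1L,
    source = c("net", "cue")[res$source + 1L])
  out <- new_spike_train(tbl, n_units = N, duration = duration, dt = dt,
                         theta = theta, seed = seed)
  if (record_potentials) attr(out, "potentials") <- res$potentials
  out
}
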