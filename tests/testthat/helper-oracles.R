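# Independent reference implementations used as oracles. These deliberately
# re-derive everything in plain R, independent of the package's C++ paths.

# STDP window, branch by branch
oracle_window <- function(tau, p = stdp_params()) {
  ifelse(tau > 0,
         p$a_p * exp(-tau / p$T_p) - p$a_D * exp(-p$eta * tau / p$T_p),
         ifelse(tau < 0,
                p$a_p * exp(p$eta * tau / p$T_D) - p$a_D * exp(tau / p$T_D),
                p$a_p - p$a_D))
}

# brute-force periodic pairwise sum over n in [-n_range, n_range]
oracle_pairwise <- function(phase_pre, phase_post, nu, p = stdp_params(),
                            n_range = 1000) {
  T <- 1000 / nu
  dt0 <- (phase_post - phase_pre) / (2 * pi) * T
  sum(oracle_window(dt0 + (-n_range:n_range) * T, p))
}

# direct membrane-potential reconstruction from an event list: for unit i at
# time t, sum J[i, j] * eps(t - t_hat) over all arrivals strictly after i's
# last spike (cue spikes count as spikes of their unit and as arrivals).
oracle_potential <- function(J, train, unit, t, kernel = kernel_params()) {
  W <- if (inherits(J, "synaptic_matrix")) J$weights else J
  own <- train$time_ms[train$unit == unit & train$time_ms < t]
  last_own <- if (length(own)) max(own) else -Inf
  pre <- train[train$unit != unit & train$time_ms < t &
                 train$time_ms > last_own, , drop = FALSE]
  if (nrow(pre) == 0L) return(0)
  sum(W[unit, pre$unit] * epsilon(t - pre$time_ms, kernel))
}
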