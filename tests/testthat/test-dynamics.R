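test_that("kernel is causal, peak-normalised, and K = 4 at the defaults", {
  k <- kernel_params()
  expect_equal(k$K, 4)
  expect_equal(k$t_peak, 10 * log(2))
  expect_identical(epsilon(c(0, -5), k), c(0, 0))
  expect_equal(epsilon(k$t_peak, k), 1)
  expect_equal(epsilon(100, k), 4 * (exp(-10) - exp(-20)), tolerance = 1e-12)
  expect_error(kernel_params(tau_m = 5, tau_s = 5), "greater")
})

test_that("the cue hits the lowest-phase units on the compressed time axis", {
  pat <- generate_random_pattern(3000, 3, seed = 4)
  cue <- make_cue(pat)   # M = N/10, T_stim = 50
  expect_equal(nrow(cue), 300)
  expect_setequal(cue$unit, order(pat$phases)[1:300])
  expect_equal(cue$time_ms, 50 * pat$phases[cue$unit] / (2 * pi))
  # with uniform phases the whole stimulation lasts ~ T_stim/10 = 5 ms
  expect_lt(max(cue$time_ms) - min(cue$time_ms), 7.5)
  expect_equal(nrow(make_cue(pat, M = 0)), 0)
  expect_error(make_cue(pat, M = 3001), "between")
  off <- make_cue(pat, M = 10, t_offset = 100)
  expect_true(all(off$time_ms >= 100))
})

test_that("noise events have exponential intervals and Gaussian strengths", {
  np <- noise_params(sigma_J = 5, mean_interval_ms = 2)
  ev <- make_noise_events(np, n_units = 20, duration = 1000, seed = 6)
  expect_true(all(ev$time_ms >= 0 & ev$time_ms < 1000))
  expect_identical(ev, make_noise_events(np, 20, 1000, seed = 6))
  gaps <- unlist(lapply(split(ev$time_ms, ev$unit), function(tt) diff(sort(tt))),
                 use.names = FALSE)
  expect_gt(length(gaps), 5000)
  expect_lt(abs(mean(gaps) - 2), 3 * 2 / sqrt(length(gaps)))
  expect_lt(abs(mean(ev$strength)), 3 * 5 / sqrt(nrow(ev)))
  expect_lt(abs(sd(ev$strength) - 5), 0.3)
  # zero-variance, zero-mean strengths exist but carry no potential
  ev0 <- make_noise_events(noise_params(sigma_J = 0), 5, 200, seed = 1)
  expect_gt(nrow(ev0), 0)
  expect_identical(unique(ev0$strength), 0)
})

test_that("heterogeneous thresholds are uniform around theta", {
  expect_identical(heterogeneous_thresholds(80, 0, 100, seed = 1), rep(80, 100))
  th <- heterogeneous_thresholds(80, 0.5, 3000, seed = 1)
  expect_true(all(th >= 40 & th <= 120))
  expect_lt(abs(mean(th) - 80), 3 * 80 * 0.5 / sqrt(3) / sqrt(3000))
  expect_error(heterogeneous_thresholds(80, 1, 10, seed = 1), "\\[0, 1\\)")
})

test_that("with zero coupling the output is exactly the cue", {
  pat <- generate_random_pattern(50, 3, seed = 9)
  cue <- make_cue(pat, M = 10)
  tr <- simulate_network(matrix(0, 50, 50), theta = 1, duration = 400,
                         cue = cue)
  expect_identical(unique(tr$source), "cue")
  expect_equal(nrow(tr), 10)
  expect_setequal(tr$unit, cue$unit)
  expect_equal(sort(tr$time_ms), round(sort(cue$time_ms) / 0.1) * 0.1)
})

test_that("simulation is deterministic and no unit fires twice in one step", {
  net <- small_net()
  a <- simulate_network(net$J, 3, 400, cue = net$cue,
                        noise = noise_params(sigma_J = 1), seed = 13)
  b <- simulate_network(net$J, 3, 400, cue = net$cue,
                        noise = noise_params(sigma_J = 1), seed = 13)
  expect_identical(a, b)
  expect_false(any(duplicated(a[, c("time_ms", "unit")])))
})

test_that("scaling thresholds and weights together leaves the spike train unchanged", {
  net <- small_net()
  a <- simulate_network(net$J, 3, 500, cue = net$cue)
  J2 <- net$J
  J2$weights <- 2.5 * J2$weights
  b <- simulate_network(J2, 2.5 * 3, 500, cue = net$cue)
  expect_equal(a$time_ms, b$time_ms)
  expect_equal(a$unit, b$unit)
})

test_that("recorded potentials match a direct evaluation of the membrane sum", {
  # independent oracle: recompute h_i(t) from the event list with the kernel
  pats <- generate_pattern_set(1, 30, 8, seed = 21)
  J <- build_connectivity(pats)
  cue <- make_cue(pats[[1]], M = 6)
  dt <- 0.1
  tr <- simulate_network(J, theta = 0.8, duration = 150, dt = dt, cue = cue,
                         record_potentials = TRUE)
  pot <- attr(tr, "potentials")
  expect_gt(sum(tr$source == "net"), 10)
  withr::with_seed(2, {
    steps <- sample(50:1500, 40)
    for (s in steps) {
      u <- sample(30, 1)
      want <- oracle_potential(J, tr, u, t = s * dt)
      expect_equal(pot[s + 1L, u], want, tolerance = 1e-8)
    }
  })
})

test_that("refining the step converges: the collective phase drift is first order in dt", {
  # the discretisation error shows up as a coherent phase shift of the whole
  # replay wave that grows along the run; halving dt should roughly halve it
  pats <- generate_pattern_set(1, 300, 3, seed = 42)
  J <- build_connectivity(pats)
  cue <- make_cue(pats[[1]])
  mean_drift <- function(a, b, tmax = 100) {
    mean(vapply(unique(a$unit), function(u) {
      x <- a$time_ms[a$unit == u & a$time_ms <= tmax]
      y <- b$time_ms[b$unit == u & b$time_ms <= tmax]
      n <- min(length(x), length(y))
      if (n == 0L) return(0)
      mean(abs(x[seq_len(n)] - y[seq_len(n)]))
    }, numeric(1)))
  }
  r20 <- simulate_network(J, 3, 400, dt = 0.2, cue = cue)
  r10 <- simulate_network(J, 3, 400, dt = 0.1, cue = cue)
  r05 <- simulate_network(J, 3, 400, dt = 0.05, cue = cue)
  d_coarse <- mean_drift(r20, r10)
  d_fine <- mean_drift(r10, r05)
  expect_lt(d_coarse, 10 * 0.2)     # drift stays a small fraction of a cycle
  expect_lt(d_fine / d_coarse, 0.9) # and shrinks as the step is refined
  # the collective period at the default step is converged to under 2%
  T10 <- estimate_period(r10, window = c(150, 400))
  T05 <- estimate_period(r05, window = c(150, 400))
  expect_lt(abs(T10 - T05) / T05, 0.02)
})
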