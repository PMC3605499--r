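test_that("period estimation recovers exact periodicity and rejects silence", {
  p <- generate_random_pattern(20, 25, seed = 1)   # period 40 ms
  tr <- pattern_spike_train(p, 0, 400)
  expect_equal(estimate_period(tr, window = c(0, 400)), 40)
  empty <- event_train(numeric(0), integer(0))
  expect_error(estimate_period(empty, window = c(0, 100)), "period undefined")
  one <- event_train(50, 1)
  expect_error(estimate_period(one, window = c(0, 100)), "period undefined")
})

test_that("median-ISI and maximize-overlap period estimates agree on clean replay", {
  net <- small_net()
  tr <- small_replay()
  t1 <- estimate_period(tr, window = c(600, 1000))
  t2 <- estimate_period(tr, window = c(600, 1000), method = "max-overlap",
                        pattern = net$patterns[[1]],
                        T_grid = seq(10, 100, by = 0.25))
  expect_lt(abs(t1 - t2) / t1, 0.02)
})

test_that("overlap is 1 on phase-perfect trains at any time scale", {
  p <- generate_random_pattern(200, 3, seed = 2)
  for (scale in c(1, 2, 0.5)) {
    T <- period_ms(p) * scale
    tr <- pattern_spike_train(p, 0, 4 * T, time_scale = scale)
    expect_equal(overlap(tr, p, T, t = 4 * T), 1, tolerance = 1e-9)
  }
})

test_that("antiphase units spiking together cancel exactly", {
  p <- phase_pattern(c(0, pi), 1)
  tr <- event_train(c(10, 10), c(1, 2))
  expect_equal(overlap(tr, p, T_star = 40, t = 20), 0, tolerance = 1e-12)
})

test_that("uncorrelated phases give overlaps at the 1/sqrt(N) floor", {
  for (N in c(100, 1000)) {
    ms <- vapply(1:30, function(k) {
      stored <- generate_random_pattern(N, 3, seed = k)
      other <- generate_random_pattern(N, 3, seed = 1000 + k)
      tr <- pattern_spike_train(other, 0, period_ms(other))
      overlap(tr, stored, period_ms(other), t = period_ms(other))
    }, numeric(1))
    expect_gt(mean(ms), 0.3 / sqrt(N))
    expect_lt(mean(ms), 3 / sqrt(N))
  }
})

test_that("overlap series is bounded, on a regular grid, and empty when silent", {
  net <- small_net()
  tr <- small_replay()
  ov <- overlap_series(tr, net$patterns)
  expect_true(all(ov$overlap >= 0 & ov$overlap <= 1))
  expect_gt(nrow(ov), 5)
  expect_false(is.na(attr(ov, "period_estimate")))
  silent <- simulate_network(net$J, 50, 1000, cue = net$cue)
  ovs <- overlap_series(silent, net$patterns)
  expect_equal(nrow(ovs), 0)
  expect_true(is.na(attr(ovs, "period_estimate")))
})

test_that("spikes per cycle is 1 for one spike per period and window-stable", {
  p <- generate_random_pattern(50, 20, seed = 3)  # 50 ms period
  tr <- pattern_spike_train(p, 0, 800)
  a <- spikes_per_cycle(tr, 50, window = c(0, 400))
  b <- spikes_per_cycle(tr, 50, window = c(0, 800))
  expect_equal(a, 1, tolerance = 0.05)
  expect_lt(abs(a - b) / a, 0.05)
})

test_that("burst-aware unit periods collapse doublets onto the collective cycle", {
  # two units: one spike/cycle and a doublet/cycle, same 50 ms rhythm
  t1 <- seq(0, 500, by = 50)
  t2 <- sort(c(seq(5, 500, by = 50), seq(9, 500, by = 50)))
  tr <- event_train(sort(c(t1, t2)), c(rep(1, length(t1)), rep(2, length(t2)))[
    order(c(t1, t2))])
  up <- unit_oscillation_periods(tr, T_star = 50, window = c(0, 500))
  expect_equal(nrow(up), 2)
  expect_equal(up$period_ms, c(50, 50), tolerance = 1e-9)
  expect_equal(sort(up$spikes_per_burst), c(1, 2), tolerance = 1e-9)
})

test_that("response size counts only post-cue network spikes", {
  tr <- event_train(c(1, 2, 3, 10, 20), c(1, 2, 3, 1, 2),
                    source = c("cue", "cue", "net", "net", "net"))
  expect_equal(response_size(tr), 3)      # cue ends at 2; spikes at 3, 10, 20
  expect_equal(response_size(tr, t_cue_end = 15), 1)
  silent <- event_train(c(1, 2), c(1, 2), source = "cue")
  expect_equal(response_size(silent), 0)
})

test_that("regimes are classified as retrieval, silent, or spurious", {
  net <- small_net(P = 1)
  res <- classify_regime(small_replay(), patterns = net$patterns)
  expect_equal(res$regime, "retrieval")
  expect_equal(res$retrieved_pattern, 1L)
  expect_gt(res$max_overlap, 0.9)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(tidy(res)$regime, "retrieval")

  silent <- simulate_network(net$J, 50, 1000, cue = net$cue)
  expect_equal(classify_regime(silent, patterns = net$patterns)$regime,
               "silent")

  # overload the network far beyond capacity at low threshold
  over <- small_net(P = 12)
  tr <- simulate_network(over$J, 2, 1000, cue = over$cue)
  res_sp <- classify_regime(tr, patterns = over$patterns)
  expect_equal(res_sp$regime, "spurious")
  expect_lt(res_sp$max_overlap, 0.5)
})
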