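# Shared small-network fixtures, built once per test run. N = 300 at 3 Hz is
# the smallest size at which cued retrieval is reliable (thresholds scale with
# network size; the retrieval range here sits near theta ~ 2-5).
.fixtures <- new.env(parent = emptyenv())

small_net <- function(P = 1L, N = 300L, nu = 3, seed = 42L) {
  key <- paste("net", P, N, nu, seed, sep = "_")
  if (is.null(.fixtures[[key]])) {
    pats <- generate_pattern_set(P, N, nu, seed)
    .fixtures[[key]] <- list(
      patterns = pats,
      J = build_connectivity(pats),
      cue = make_cue(pats[[1L]]))
  }
  .fixtures[[key]]
}

# a retrieval run on the small fixture (theta = 3 sits mid retrieval range)
small_replay <- function(theta = 3, duration = 1000, ...) {
  key <- paste("replay", theta, duration, sep = "_")
  if (is.null(.fixtures[[key]])) {
    net <- small_net()
    .fixtures[[key]] <- simulate_network(net$J, theta, duration,
                                         cue = net$cue, ...)
  }
  .fixtures[[key]]
}

# plain event tibble helper for hand-built trains
event_train <- function(time_ms, unit, source = "net") {
  tibble::tibble(time_ms = time_ms, unit = as.integer(unit), source = source)
}
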