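## Fixtures shared across tests; everything is built in code.

## small rooted topologies
path3_end <- function() rooted_topology(3, rbind(c(1, 2), c(2, 3)))          # root at an end
path3_mid <- function() rooted_topology(3, rbind(c(1, 2), c(1, 3)))          # root in the middle
triangle3 <- function() rooted_topology(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
star_n <- function(n) rooted_topology(n, cbind(1L, 2:n))
cycle_n <- function(n) rooted_topology(n, rbind(cbind(1:(n - 1), 2:n), c(1, n)))

## random connected topology on n states (edge probability p over a spanning
## tree), deterministic under the caller's seed
random_topology <- function(n, p = 0.3) {
  edges <- cbind(2:n, vapply(2:n, function(k) sample.int(k - 1, 1), integer(1)))
  extra <- utils::combn(n, 2)
  for (ci in seq_len(ncol(extra))) {
    a <- extra[1, ci]; b <- extra[2, ci]
    if (stats::runif(1) < p && !any((edges[, 1] == a & edges[, 2] == b) |
                                    (edges[, 1] == b & edges[, 2] == a)))
      edges <- rbind(edges, c(a, b))
  }
  rooted_topology(n, edges)
}

## random channel model with bounded parameters
random_model <- function(topology, spread = 2) {
  k <- complexity(topology)
  params <- as.numeric(vapply(seq_len(k), function(i)
    c(stats::runif(2, -spread, spread), stats::runif(1, -50, 50),
      stats::runif(1, 5, 50)), numeric(4)))
  unpack_parameters(topology, params)
}

## analytic 2-state open-probability relaxation at fixed voltage
two_state_open_closed_form <- function(model, p_open0, v, times) {
  kf <- rate(model, 2, 1, v)   # closed -> open
  kb <- rate(model, 1, 2, v)   # open -> closed
  pinf <- kf / (kf + kb)
  pinf + (p_open0 - pinf) * exp(-(kf + kb) * times)
}

## reduced desk-scale protocol battery used by the fitting studies: the
## same protocol structure as the full training battery but with coarser
## sweep grids so a fit costs milliseconds rather than seconds per
## evaluation
desk_protocols <- function() {
  p <- protocol_set("itof")
  p$max_open <- NULL
  p$ssa$voltages <- seq(-60, 60, by = 20)
  p$ssi$cond_voltages <- seq(-120, 40, by = 20)
  p$recovery$intervals <- c(2, 10, 25, 75, 200, 600, 2000, 6000)
  p$trace_60 <- NULL
  p$trace_20$dt <- 0.5
  p
}

expect_prob_vector <- function(p, tol = 1e-9) {
  expect_true(all(p >= -tol))
  expect_true(all(p <= 1 + tol))
  expect_equal(sum(p), 1, tolerance = 1e-8)
}
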