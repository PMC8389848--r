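## Protocol simulation: conservation, closed forms, curve shapes, decay
## times, and invariances.

test_that("piecewise simulation conserves probability and matches closed form", {
  m <- ground_truth_model("two_state")
  p0 <- steady_state(m, -100)
  segs <- list(list(voltage = 0, duration = 10),
               list(voltage = -80, duration = 15))
  tr <- simulate_piecewise(m, p0, segs, dt = 0.05)
  expect_equal(rowSums(tr[, -1]), rep(1, nrow(tr)), tolerance = 1e-9)
  expect_true(all(tr[, -1] >= -1e-9 & tr[, -1] <= 1 + 1e-9))
  ## segment 1 matches the analytic 2-state relaxation to 1e-8
  seg1 <- tr[tr[, "time"] <= 10, ]
  expect_equal(seg1[, "s1"],
               two_state_open_closed_form(m, p0[1], 0, seg1[, "time"]),
               tolerance = 1e-8)
  ## zero-duration segments leave the state untouched
  tr0 <- simulate_piecewise(m, p0, list(list(voltage = 0, duration = 0)))
  expect_identical(nrow(tr0), 1L)
  expect_equal(tr0[1, -1], p0, ignore_attr = TRUE)
  expect_error(simulate_piecewise(m, p0, segs, dt = 0), "dt")
  expect_error(simulate_piecewise(m, p0, list(list(voltage = 0, duration = -1))),
               "durations")
})

test_that("steady state equals the long-time limit of simulation", {
  set.seed(20)
  for (rep in 1:5) {
    tp <- random_topology(sample(2:5, 1), p = 0.4)
    m <- random_model(tp, spread = 1.5)
    v <- stats::runif(1, -80, 20)
    pss <- steady_state(m, v)
    p0 <- rep(1 / tp$n_states, tp$n_states)
    tr <- simulate_piecewise(m, p0, list(list(voltage = v, duration = 5000)),
                             dt = 50)
    expect_equal(tr[nrow(tr), -1], pss, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("voltage-independent models produce flat normalized curves", {
  tp <- rooted_topology(2, rbind(c(1, 2)))
  m <- channel_model(tp, list(voltage_fn(0.5, 0)), list(voltage_fn(0, 0)))
  prot <- protocol_set("itof")
  expect_equal(ssa_curve(m, prot$ssa)$y, rep(1, 13), tolerance = 1e-9)
  expect_equal(ssi_curve(m, prot$ssi)$y, rep(1, 17), tolerance = 1e-9)
})

test_that("activation and availability curves have the expected monotone shape", {
  m <- ground_truth_model("two_state")
  prot <- protocol_set("itof")
  sa <- ssa_curve(m, prot$ssa)
  expect_false(is.unsorted(sa$y))          # activation increases with voltage
  expect_equal(max(sa$y), 1)               # normalized to its own maximum
  m3 <- ground_truth_model("three_state_slow")
  si <- ssi_curve(m3, prot$ssi)
  expect_false(is.unsorted(rev(si$y)))     # availability falls with prepulse
  expect_equal(max(si$y), 1)
})

test_that("recovery curves rise to one and reflect model timescales", {
  prot <- protocol_set("itof")
  m3 <- ground_truth_model("three_state_slow")
  m4 <- ground_truth_model("four_state_chain")
  r3 <- recovery_curve(m3, prot$recovery)
  r4 <- recovery_curve(m4, prot$recovery)
  expect_equal(max(r3$y), 1)
  ## the interval grid includes the 25 ms checkpoint where the chain model
  ## (fast recovery) is far ahead of the cyclic model (slow recovery)
  i25 <- which(prot$recovery$intervals == 25)
  expect_gt(r4$y[i25], 1.5 * r3$y[i25])
  ## long intervals re-attain the holding steady state
  expect_equal(r4$y[length(r4$y)], 1, tolerance = 1e-3)
  expect_equal(r3$y[length(r3$y)], 1, tolerance = 1e-3)
  ## the first interval is the least recovered
  expect_identical(which.min(r3$y), 1L)
  expect_error(recovery_curve(m3, prot$recovery, x = c(10, 2)), "unsorted|sorted")
})

test_that("use-dependent-block recovery reduces to plain recovery without slow states", {
  prot <- protocol_set("ina_hek")
  m <- ground_truth_model("two_state")   # no slow inactivated pool
  ru <- rudb_curve(m, prot$rudb)
  rc <- recovery_curve(m, prot$recovery, x = prot$rudb$intervals)
  expect_equal(ru$y, rc$y, tolerance = 1e-6)
  expect_equal(max(ru$y), 1)
  ## train accounting: 100 pulses at 25 Hz span 4000 ms
  expect_equal(prot$rudb$n_pulses * (prot$rudb$train_pulse + prot$rudb$train_gap),
               4000)
  ## with a slow pool the use-dependent curve lags plain recovery
  m5 <- ground_truth_model("five_state_cyclic")
  ru5 <- rudb_curve(m5, prot$rudb)
  rc5 <- recovery_curve(m5, prot$recovery, x = prot$rudb$intervals)
  expect_gt(max(rc5$y - ru5$y), 0.02)
})

test_that("current traces are normalized to their own peak on the 0.2 ms grid", {
  m4 <- ground_truth_model("four_state_chain")
  prot <- protocol_set("itof")
  trc <- current_trace(m4, prot$trace_20)
  expect_equal(max(trc$y), 1)
  expect_equal(diff(trc$x)[1], 0.2)
  ## matches the analytic solution for the 2-state model to 1e-8
  m2 <- ground_truth_model("two_state")
  trc2 <- current_trace(m2, prot$trace_60)
  p0 <- steady_state(m2, -70)
  exact <- two_state_open_closed_form(m2, p0[1], 60, trc2$x)
  expect_equal(trc2$y, exact / max(exact), tolerance = 1e-8)
})

test_that("half-decay times match closed forms and rescale with rates", {
  ## pure exponential decay from peak 1 crosses half at tau ln 2; build a
  ## 2-state model whose open probability decays (hyperpolarizing step)
  tp <- rooted_topology(2, rbind(c(1, 2)))
  spec <- markovchannel:::.protocol_spec("tau_test", "tau_inact",
                                         holding = 60, voltages = c(-80),
                                         duration = 25)
  m <- ground_truth_model("two_state")
  td <- suppressWarnings(time_to_half_decay(m, spec, dt = 0.01))
  kf <- rate(m, 2, 1, -80); kb <- rate(m, 1, 2, -80)
  k <- kf + kb
  p0 <- steady_state(m, 60)[1]
  pinf <- kf / k
  exact <- log((p0 - pinf) / (p0 / 2 - pinf)) / k
  expect_equal(td$y, exact, tolerance = 1e-3)
  ## halving every rate doubles the crossing time
  mh <- m
  mh$edge_barriers <- lapply(m$edge_barriers, function(f) {
    f$a <- f$a - log(2); f
  })
  tdh <- suppressWarnings(time_to_half_decay(mh, spec, dt = 0.01))
  expect_equal(tdh$y, 2 * td$y, tolerance = 1e-3)
  ## a non-decaying trace is censored with a warning
  spec_up <- markovchannel:::.protocol_spec("tau_up", "tau_inact",
                                            holding = -100, voltages = c(40),
                                            duration = 25)
  expect_warning(ce <- time_to_half_decay(m, spec_up), "censored")
  expect_true(is.na(ce$y))
})

test_that("peak-open-probability constraints follow the squared relative form", {
  prot <- protocol_set("itof")
  expect_identical(prot$max_open$targets, c(0.3, 0.45))
  expect_identical(prot$max_open$voltages, c(25, 50))
  expect_identical(protocol_set("ina_hek")$max_open$targets, c(0.27, 0.31, 0.29))
  ## a model whose simulated peaks are ~1.0 against target 0.5 contributes
  ## ((1 - 0.5)/0.5)^2 = 1 per point
  m <- ground_truth_model("two_state")
  spec <- markovchannel:::.protocol_spec("max_open", "max_open", holding = -100,
                                         voltages = 60, targets = 0.5,
                                         duration = 50)
  mo <- max_open_constraint(m, spec)
  peak <- max(markovchannel:::.open_traj(markovchannel:::.make_cache(m), 60,
                                         steady_state(m, -100),
                                         seq(0, 50, 0.05)))
  expect_equal(mo, ((peak - 0.5) / 0.5)^2, tolerance = 1e-9)
  expect_equal(max_open_constraint(m, NULL), 0)
})

test_that("protocol outputs are stable under grid refinement", {
  prot <- protocol_set("itof")
  m4 <- ground_truth_model("four_state_chain")
  for (dt in c(0.2)) {
    a1 <- ssa_curve(m4, prot$ssa, dt = dt)$y
    a2 <- ssa_curve(m4, prot$ssa, dt = dt / 2)$y
    expect_lt(max(abs(a1 - a2) / pmax(a2, 1e-6)), 0.005)
    r1 <- recovery_curve(m4, prot$recovery, dt = dt)$y
    r2 <- recovery_curve(m4, prot$recovery, dt = dt / 2)$y
    expect_lt(max(abs(r1 - r2) / pmax(r2, 1e-6)), 0.005)
  }
})

test_that("protocol sets round-trip through YAML and JSON files", {
  prot <- protocol_set("ina_hek")
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_protocols(prot, path)
    back <- read_protocols(path)
    expect_identical(names(back), names(prot))
    expect_equal(back$rudb$n_pulses, 100)
    m <- ground_truth_model("two_state")
    expect_equal(simulate_protocol(m, back$ssa)$y,
                 simulate_protocol(m, prot$ssa)$y, tolerance = 1e-12)
  }
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"ssa": {"voltages": [0]}}', bad)
  expect_error(read_protocols(bad), "holding")
})

test_that("protocol outputs are invariant to relabeling non-root states", {
  ## same physical chain written with two different state numberings
  tpA <- rooted_topology(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  tpB <- rooted_topology(4, rbind(c(1, 3), c(3, 4), c(4, 2)))
  pots <- list(voltage_fn(-3, 4, 15, 20), voltage_fn(-0.5, 0.5, 15, 20),
               voltage_fn(-4, -2, 15, 20))
  bars <- list(voltage_fn(0.5, 0), voltage_fn(1, 0), voltage_fn(0, 0))
  mA <- channel_model(tpA, pots, bars)
  ## under B's numbering the chain is 1-3-4-2: state 3 plays A's state 2,
  ## state 4 plays A's 3, state 2 plays A's 4; edges sort to (1,3),(2,4),(3,4)
  mB <- channel_model(tpB, list(pots[[3]], pots[[1]], pots[[2]]),
                      list(bars[[1]], bars[[3]], bars[[2]]))
  prot <- protocol_set("itof")
  expect_equal(ssa_curve(mB, prot$ssa)$y, ssa_curve(mA, prot$ssa)$y,
               tolerance = 1e-9)
  expect_equal(recovery_curve(mB, prot$recovery)$y,
               recovery_curve(mA, prot$recovery)$y, tolerance = 1e-9)
})
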