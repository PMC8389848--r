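## Synthetic ground truth and dataset generation.
##
## The presets are hand-parameterized channel models whose qualitative
## behavior mirrors the canonical voltage-gated currents the pipeline is
## aimed at: an analytically tractable two-state activation gate, a
## three-state cyclic model whose recovery from inactivation is slow because
## the resting probability is split between closed and inactivated states,
## and a four-state linear chain whose extra transitory state lets recovery
## be fast while the resting state holds essentially all probability.  In
## the node-potential construction the stationary distribution at voltage v
## is proportional to exp(-phi_i(v)), so occupancy targets translate
## directly into potential values and barriers set the kinetics.

#' Ground-truth channel model presets
#'
#' * `"two_state"` — closed-open activation gate; every protocol outcome has
#'   a closed form, used for oracle tests and parameter-recovery studies.
#' * `"three_state_slow"` — cyclic open/closed/inactivated model; at
#'   -70 mV the resting probability splits roughly 80/20 between closed and
#'   inactivated, which locks recovery from inactivation to a slow rate
#'   (the signature of unacceptable fast-transient-outward models).
#' * `"four_state_chain"` — linear open-closed-transitory-inactivated
#'   chain; the resting closed state holds ~99% of probability and the
#'   transitory state distances the inactivated state from the open state,
#'   so recovery at -70 mV is appropriately fast.
#' * `"four_state_reserve"` — the same linear chain rooted at an interior
#'   state (inactivated-open-closed-reserve).  Most resting probability
#'   sits in a deep reserve closed state whose release is slow at +20 mV
#'   but fast at strongly depolarized voltages, so the +20 mV trace shows a
#'   peak, a dip, and a slow rebound — two interior extrema.  A trace of
#'   any three-state model is a two-exponential relaxation with at most one
#'   interior extremum, so these data cannot be reproduced by any
#'   three-state topology; this is the fixture for structure-discrimination
#'   studies.
#' * `"five_state_cyclic"` — sodium-current-like model with two closed
#'   states, an inactivated state in a cycle with the open and closed
#'   states, and a deep slow-inactivated state reached from the
#'   inactivated state.
#'
#' @param preset Preset name.
#' @return A [channel_model()].
#' @export
ground_truth_model <- function(preset = c("two_state", "three_state_slow",
                                          "four_state_chain",
                                          "four_state_reserve",
                                          "five_state_cyclic")) {
  preset <- match.arg(preset)
  switch(preset,
    two_state = {
      tp <- rooted_topology(2L, rbind(c(1L, 2L)))
      channel_model(tp,
        state_potentials = list(voltage_fn(0, 6, 30, 15)),
        edge_barriers = list(voltage_fn(-2, 0, 0, 30)))
    },
    three_state_slow = {
      ## states: 1 open, 2 closed, 3 inactivated; triangle
      tp <- rooted_topology(3L, rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
      channel_model(tp,
        state_potentials = list(
          voltage_fn(-2.5, 2.5, 15, 20),    # closed: -5 at rest, ~0 depolarized
          voltage_fn(-4.8, -1.2, 15, 20)),  # inactivated: -3.6 -> -6
        edge_barriers = list(
          voltage_fn(1, 0, 0, 30),          # open-closed: fast gating
          voltage_fn(-2, 2, 15, 20),        # open-inactivated: shut at rest
          voltage_fn(-1.7, 0, 0, 30)))      # closed-inactivated: slow
    },
    four_state_chain = {
      ## states: 1 open, 2 closed, 3 transitory, 4 inactivated; chain.
      ## The closed state holds ~99% of resting probability; depolarization
      ## fills the transitory and inactivated pools roughly 77/23, and at
      ## -70 mV they drain back on distinct timescales (T -> C with
      ## tau ~ 17 ms, I -> T with tau ~ 400 ms), so recovery from
      ## inactivation is visibly biexponential — the structural signature
      ## a three-state model cannot reproduce together with the
      ## steady-state curves.
      tp <- rooted_topology(4L, rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)))
      channel_model(tp,
        state_potentials = list(
          voltage_fn(-3, 4, 15, 20),        # closed: -7 at rest, +1 depolarized
          voltage_fn(-2.96, -3.2, -25, 8),  # transitory: shallow at +20, deep at +40
          voltage_fn(-3.4, -1.4, 15, 20)),  # inactivated: -2 -> -4.8
        edge_barriers = list(
          voltage_fn(0.5, 0, 0, 30),        # open-closed: fast gating
          voltage_fn(-1.2, 0, 0, 30),       # closed-transitory: fast exchange
          voltage_fn(-2.07, 1.95, 15, 20))) # transitory-inactivated: slow at
                                            # rest (tau ~ 400 ms), ~6 ms at +20
    },
    four_state_reserve = {
      ## states: 1 open, 2 closed, 3 reserve (deep closed), 4 inactivated;
      ## the chain I-O-C-T rooted at the interior open state.  The reserve
      ## state holds ~90% of resting probability and releases it slowly at
      ## +20 mV (tau ~ 20 ms) but quickly at strong depolarizations, while
      ## open-state inactivation at +20 mV is fast; the +20 mV trace
      ## therefore peaks, dips, and rebounds — two interior extrema, beyond
      ## any three-state model.
      tp <- rooted_topology(4L, rbind(c(1L, 2L), c(1L, 4L), c(2L, 3L)))
      channel_model(tp,
        state_potentials = list(
          voltage_fn(-2.49, 2.33, 15, 20),    # closed: -4.8 -> -0.3
          voltage_fn(-3.6651, 3.3621, 15, 20),# reserve: -7 -> -0.5 at +20
          voltage_fn(-3.30, -1.81, 15, 20)),  # inactivated: -1.5 -> -5
        edge_barriers = list(
          voltage_fn(0.9, 0, 0, 30),          # open-closed: fast gating
          voltage_fn(1.1140, 2.5345, 15, 20), # open-inactivated: fast at +20
          voltage_fn(-1.9550, 1.084, -30, 5)))# closed-reserve: slow release
                                              # at +20, fast beyond +40
    },
    five_state_cyclic = {
      ## states: 1 open, 2 C1, 3 C2, 4 inactivated, 5 slow-inactivated;
      ## cycle open-C1-inactivated plus chain C2-C1 and I-IS
      tp <- rooted_topology(5L, rbind(c(1L, 2L), c(1L, 4L), c(2L, 3L),
                                      c(2L, 4L), c(4L, 5L)))
      channel_model(tp,
        state_potentials = list(
          voltage_fn(-2, 3, 40, 12),        # C1
          voltage_fn(-4, 5, 40, 12),        # C2: dominant at rest
          voltage_fn(-4, -3, 40, 12),       # I: dominant depolarized
          voltage_fn(-1.5, -1.5, 40, 12)),  # IS: slow pool
        edge_barriers = list(
          voltage_fn(1.5, 0, 0, 30),        # open-C1: fast activation
          voltage_fn(-1, 1, 40, 12),        # open-I: fast inactivation, open
          voltage_fn(1.5, 0, 0, 30),        # C1-C2
          voltage_fn(0, 0, 0, 30),          # C1-I
          voltage_fn(-4.5, 0, 0, 30)))      # I-IS: slow entry/exit
    })
}

#' Synthetic dataset specification
#'
#' @param preset Ground-truth preset (see [ground_truth_model()]).
#' @param protocols Protocol set to simulate; defaults to the fast
#'   transient-outward battery for the potassium-like presets and the
#'   expressed-sodium battery for `"five_state_cyclic"`.
#' @param noise_sd Relative Gaussian noise per replicate (`>= 0`).
#' @param n_replicates Replicates averaged per point (`>= 1`).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(preset = "four_state_chain", protocols = NULL,
                           noise_sd = 0.03, n_replicates = 10L, seed = 1L) {
  stopifnot(noise_sd >= 0, n_replicates >= 1)
  if (is.null(protocols))
    protocols <- protocol_set(
      if (preset == "five_state_cyclic") "ina_hek" else "itof")
  structure(list(preset = preset, protocols = protocols, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a noisy synthetic clamp dataset
#'
#' Simulates every summary-curve protocol in the spec on the ground-truth
#' model, perturbs each point with i.i.d. relative Gaussian noise averaged
#' over `n_replicates` draws, and records the replicate mean together with
#' `sem = noise_sd * |true mean| / sqrt(n_replicates)` (floored at 0.01 on
#' normalized quantities).  With `noise_sd = 0` the curves equal the exact
#' model output.
#'
#' @param spec A [synthetic_spec()].
#' @param dt Simulation sampling interval, ms.
#' @return A [clamp_dataset()] whose metadata records the generator
#'   settings.
#' @export
generate_dataset <- function(spec, dt = 0.05) {
  stopifnot(inherits(spec, "synthetic_spec"))
  model <- ground_truth_model(spec$preset)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  curves <- list()
  for (ps in spec$protocols) {
    if (ps$type == "max_open") next
    sim <- suppressWarnings(simulate_protocol(model, ps, dt = dt))
    keep <- !is.na(sim$y)
    x <- sim$x[keep]; ytrue <- sim$y[keep]
    if (spec$noise_sd > 0) {
      reps <- matrix(stats::rnorm(length(ytrue) * spec$n_replicates,
                                  mean = rep(ytrue, spec$n_replicates),
                                  sd = spec$noise_sd * abs(rep(ytrue, spec$n_replicates))),
                     nrow = length(ytrue))
      ymean <- rowMeans(reps)
    } else {
      ymean <- ytrue
    }
    sem <- pmax(spec$noise_sd * abs(ytrue) / sqrt(spec$n_replicates), 0.01)
    curves[[length(curves) + 1L]] <-
      list(protocol = ps$name, x = x, mean = ymean, sem = sem)
  }
  clamp_dataset(curves,
                metadata = list(generator = "synthetic",
                                preset = spec$preset,
                                noise_sd = spec$noise_sd,
                                n_replicates = spec$n_replicates,
                                seed = spec$seed))
}
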