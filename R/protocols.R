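## Voltage-clamp protocol simulation.
##
## Every sweep of every protocol is a piecewise-constant voltage waveform, so
## within a segment the occupancy obeys a fixed linear ODE dp/dt = A(v) p and
## the solution is the matrix exponential expm(A t) p0 — exact, no solver
## tolerance involved.  For speed each voltage's generator is
## eigendecomposed once per model evaluation and propagation reduces to
## scaling exponentials; defective or ill-conditioned decompositions fall
## back to Matrix::expm.

## ---- propagation core ---------------------------------------------------

## per-model evaluation cache of spectral data keyed by voltage, with the
## voltage-function parameters packed into matrices for vectorized
## generator assembly
.make_cache <- function(model) {
  env <- new.env(parent = emptyenv())
  env$model <- model
  tp <- model$topology
  env$n <- tp$n_states
  env$root <- tp$root
  pk <- function(fns) if (length(fns))
    matrix(unlist(lapply(fns, function(f) c(f$a, f$b, f$args1, f$args2))), 4L)
  else matrix(numeric(0), 4L, 0L)
  env$pot <- pk(model$state_potentials)
  env$bar <- pk(model$edge_barriers)
  env$nonroot <- setdiff(seq_len(tp$n_states), tp$root)
  E <- tp$edges
  env$idx_fwd <- cbind(E[, 1L], E[, 2L])   # receives rate E2 -> E1
  env$idx_bwd <- cbind(E[, 2L], E[, 1L])
  env
}

## vectorized generator assembly (same result as transition_matrix())
.tm_fast <- function(cache, v) {
  n <- cache$n
  pot <- numeric(n)
  P <- cache$pot
  if (ncol(P))
    pot[cache$nonroot] <- P[1L, ] + P[2L, ] * tanh((v + P[3L, ]) / P[4L, ])
  B <- cache$bar
  A <- matrix(0, n, n)
  if (ncol(B)) {
    barv <- B[1L, ] + B[2L, ] * tanh((v + B[3L, ]) / B[4L, ])
    A[cache$idx_fwd] <- exp(barv + pot[cache$idx_fwd[, 2L]])
    A[cache$idx_bwd] <- exp(barv + pot[cache$idx_bwd[, 2L]])
  }
  diag(A) <- -colSums(A)
  A
}

## time grids reused across sweeps
.cached_tgrid <- function(cache, duration, dt) {
  key <- sprintf("tg%.9g_%.9g", duration, dt)
  tg <- cache[[key]]
  if (is.null(tg)) {
    tg <- seq(0, duration, by = dt)
    cache[[key]] <- tg
  }
  tg
}

## Detailed balance makes every generator similar to a symmetric matrix, so
## the spectrum is real whenever the decomposition is numerically healthy;
## the complex/expm path remains as a fallback.
.spectral <- function(cache, v) {
  key <- sprintf("v%.9g", v)
  sp <- cache[[key]]
  if (!is.null(sp)) return(sp)
  A <- .tm_fast(cache, v)
  sp <- list(A = A, ok = FALSE)
  if (nrow(A) == 1L) {
    sp$ok <- TRUE
    sp$values <- 0
    sp$V <- matrix(1, 1, 1)
    sp$Vi <- matrix(1, 1, 1)
  } else {
    e <- tryCatch(eigen(A, symmetric = FALSE), error = function(err) NULL)
    if (!is.null(e) && is.complex(e$values) &&
        max(abs(Im(e$values))) <= 1e-9 * max(1, max(abs(Re(e$values))))) {
      e$values <- Re(e$values)
      e$vectors <- Re(e$vectors)
    }
    if (!is.null(e) && is.double(e$values) && is.double(e$vectors)) {
      Vi <- tryCatch(solve(e$vectors), error = function(err) NULL)
      if (!is.null(Vi) && all(is.finite(Vi))) {
        sp$ok <- TRUE
        sp$values <- e$values
        sp$V <- e$vectors
        sp$Vi <- Vi
      }
    }
  }
  cache[[key]] <- sp
  sp
}

.cached_steady <- function(cache, v) {
  key <- sprintf("ss%.9g", v)
  p <- cache[[key]]
  if (is.null(p)) {
    n <- cache$n
    if (n == 1L) {
      p <- 1
    } else {
      A <- .spectral(cache, v)$A
      A[n, ] <- 1
      p <- solve(A, c(rep(0, n - 1L), 1))
      p[p < 0 & p > -1e-12] <- 0
    }
    cache[[key]] <- p
  }
  p
}

## stiffness penalty evaluated through the shared cache
.stiffness_cached <- function(cache, cfg) {
  rc <- vapply(cfg$probe_voltages, function(v) {
    if (cache$n <= 2L) return(1)
    .rcond1(.reduced_generator(.spectral(cache, v)$A))
  }, numeric(1))
  .sp_from_rconds(rc, cfg$rcond_threshold, cfg$weight)
}

## propagate p0 by duration t (scalar): returns probability vector
.prop_state <- function(cache, v, p0, t) {
  if (t == 0) return(p0)
  sp <- .spectral(cache, v)
  if (sp$ok) {
    as.numeric(sp$V %*% (exp(sp$values * t) * (sp$Vi %*% p0)))
  } else {
    as.numeric(as.matrix(Matrix::expm(sp$A * t)) %*% p0)
  }
}

## propagate p0 by each duration in ts (vector): N x length(ts) matrix
.prop_states <- function(cache, v, p0, ts) {
  sp <- .spectral(cache, v)
  if (sp$ok) {
    c0 <- as.vector(sp$Vi %*% p0)
    sp$V %*% (exp(outer(sp$values, ts)) * c0)
  } else {
    vapply(ts, function(t) .prop_state(cache, v, p0, t),
           numeric(length(p0)))
  }
}

## open-state occupancy along a time grid (root = open state)
.open_traj <- function(cache, v, p0, tgrid) {
  sp <- .spectral(cache, v)
  open <- cache$root
  if (sp$ok) {
    c0 <- as.vector(sp$Vi %*% p0)
    w <- sp$V[open, ] * c0
    as.numeric(exp(outer(tgrid, sp$values)) %*% w)
  } else {
    tr <- .prop_states(cache, v, p0, tgrid)
    as.numeric(tr[open, ])
  }
}

## peak of a sampled trajectory with parabolic refinement at interior maxima
.peak_value <- function(y, tgrid) {
  i <- which.max(y)
  if (i > 1L && i < length(y)) {
    y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      delta <- 0.5 * (y1 - y3) / den
      if (abs(delta) <= 1) return(y2 - 0.25 * (y1 - y3) * delta)
    }
  }
  y[i]
}

## first time a trajectory decays to 0.5 * its peak, linearly interpolated;
## NA when the trace never crosses within the segment (censored)
.tau50 <- function(y, tgrid) {
  i <- which.max(y)
  half <- 0.5 * y[i]
  rest <- y[seq_along(y) >= i]
  k <- which(rest <= half)
  if (!length(k)) return(NA_real_)
  k <- k[1L]
  if (k == 1L) return(tgrid[i])
  j <- i + k - 1L
  y1 <- y[j - 1L]; y2 <- y[j]
  frac <- (y1 - half) / (y1 - y2)
  tgrid[j - 1L] + frac * (tgrid[j] - tgrid[j - 1L])
}

#' Simulate a piecewise-constant voltage-clamp waveform
#'
#' Propagates occupancies exactly (matrix-exponential solution per
#' fixed-voltage segment), sampling every `dt` ms within each segment.
#'
#' @param model A [channel_model()].
#' @param p0 Initial probability vector (sums to 1).
#' @param segments List of segments, each `list(voltage =, duration =)`
#'   (mV, ms; durations `>= 0`).
#' @param dt Sampling interval, ms (`> 0`).
#' @return A matrix with one row per sample and columns `time`, then one
#'   occupancy column per state.
#' @export
simulate_piecewise <- function(model, p0, segments, dt = 0.05) {
  if (dt <= 0) stop("dt must be positive")
  n <- model$topology$n_states
  stopifnot(length(p0) == n, abs(sum(p0) - 1) < 1e-8, all(p0 >= -1e-12))
  cache <- .make_cache(model)
  times <- 0
  states <- matrix(p0, nrow = 1L)
  t0 <- 0
  p <- p0
  for (seg in segments) {
    if (seg$duration < 0) stop("segment durations must be >= 0")
    if (seg$duration == 0) next
    tloc <- seq(dt, seg$duration, by = dt)
    if (!length(tloc) || tloc[length(tloc)] < seg$duration)
      tloc <- c(tloc, seg$duration)
    tr <- .prop_states(cache, seg$voltage, p, tloc)
    times <- c(times, t0 + tloc)
    states <- rbind(states, t(tr))
    p <- tr[, ncol(tr)]
    t0 <- t0 + seg$duration
  }
  out <- cbind(time = times, states)
  colnames(out) <- c("time", paste0("s", seq_len(n)))
  out
}

## ---- protocol specifications -------------------------------------------

.protocol_spec <- function(name, type, holding, ...) {
  structure(c(list(name = name, type = type, holding = holding), list(...)),
            class = "protocol_spec")
}

#' Voltage-clamp protocol presets
#'
#' Returns the named battery of training protocols for a current type:
#' `"itof"` (human ventricular fast transient outward K+ current),
#' `"ina_hek"` (heterologously expressed Nav1.5 Na+ current, including the
#' multi-timescale recovery-from-use-dependent-block train), or
#' `"ina_atrial"` (native atrial Na+ current with the deactivation
#' time-constant protocol).  Each element is a `protocol_spec`; elements
#' named `max_open` carry peak-open-probability targets used as direct cost
#' constraints rather than normalized curves.
#'
#' @param preset One of `"itof"`, `"ina_hek"`, `"ina_atrial"`.
#' @return Named list of `protocol_spec` objects.
#' @export
protocol_set <- function(preset = c("itof", "ina_hek", "ina_atrial")) {
  preset <- match.arg(preset)
  switch(preset,
    itof = list(
      ssa = .protocol_spec("ssa", "ssa", holding = -70,
                           voltages = seq(-60, 60, by = 10), duration = 50),
      ssi = .protocol_spec("ssi", "ssi", holding = -70,
                           cond_voltages = seq(-120, 40, by = 10),
                           cond_duration = 200,
                           test_voltage = 40, test_duration = 50),
      recovery = .protocol_spec("recovery", "recovery", holding = -70,
                                depol_voltage = 40, depol_duration = 500,
                                recovery_voltage = -70,
                                intervals = c(2, 5, 10, 25, 50, 100, 200, 400,
                                              800, 1500, 3000, 6000),
                                test_voltage = 40, test_duration = 100),
      trace_20 = .protocol_spec("trace_20", "trace", holding = -70,
                                voltage = 20, duration = 10, dt = 0.2),
      trace_60 = .protocol_spec("trace_60", "trace", holding = -70,
                                voltage = 60, duration = 10, dt = 0.2),
      max_open = .protocol_spec("max_open", "max_open", holding = -70,
                                voltages = c(25, 50), targets = c(0.3, 0.45),
                                duration = 50)),
    ina_hek = list(
      ssa = .protocol_spec("ssa", "ssa", holding = -100,
                           voltages = seq(-45, 20, by = 5), duration = 25),
      ssi = .protocol_spec("ssi", "ssi", holding = -100,
                           cond_voltages = seq(-110, 40, by = 10),
                           cond_duration = 500,
                           test_voltage = -10, test_duration = 25),
      recovery = .protocol_spec("recovery", "recovery", holding = -100,
                                depol_voltage = -10, depol_duration = 500,
                                recovery_voltage = -100,
                                intervals = c(0.5, 1, 2, 5, 10, 20, 40, 80,
                                              140, 210),
                                test_voltage = -10, test_duration = 25),
      rudb = .protocol_spec("rudb", "rudb", holding = -100,
                            train_voltage = -10, train_pulse = 25,
                            train_gap = 15, n_pulses = 100,
                            recovery_voltage = -100,
                            intervals = c(0.5, 2, 10, 50, 200, 1000, 3000,
                                          6000, 9000),
                            test_voltage = -10, test_duration = 25),
      tau_inact = .protocol_spec("tau_inact", "tau_inact", holding = -100,
                                 voltages = seq(-20, 20, by = 5),
                                 duration = 25),
      max_open = .protocol_spec("max_open", "max_open", holding = -100,
                                voltages = c(-20, -10, 0),
                                targets = c(0.27, 0.31, 0.29),
                                duration = 25)),
    ina_atrial = list(
      ssa = .protocol_spec("ssa", "ssa", holding = -100,
                           voltages = seq(-45, 20, by = 5), duration = 25),
      ssi = .protocol_spec("ssi", "ssi", holding = -100,
                           cond_voltages = seq(-110, 40, by = 10),
                           cond_duration = 500,
                           test_voltage = -10, test_duration = 25),
      recovery = .protocol_spec("recovery", "recovery", holding = -100,
                                depol_voltage = -10, depol_duration = 500,
                                recovery_voltage = -100,
                                intervals = c(0.5, 1, 2, 5, 10, 20, 40, 80,
                                              140, 210),
                                test_voltage = -10, test_duration = 25),
      tau_deact = .protocol_spec("tau_deact", "tau_deact", holding = -120,
                                 depol_voltage = -20, depol_duration = 5,
                                 voltages = seq(-110, -60, by = 10),
                                 duration = 5),
      max_open = .protocol_spec("max_open", "max_open", holding = -100,
                                voltages = c(-20, -10, 0),
                                targets = c(0.27, 0.31, 0.29),
                                duration = 25)))
}

## ---- curve extraction ---------------------------------------------------

.step_peak <- function(cache, p0, voltage, duration, dt) {
  tgrid <- .cached_tgrid(cache, duration, dt)
  y <- .open_traj(cache, voltage, p0, tgrid)
  .peak_value(y, tgrid)
}

#' Steady-state activation curve
#'
#' From steady state at the holding potential, step to each test voltage and
#' record the peak open probability, normalized to the maximum across
#' voltages.
#'
#' @param model A [channel_model()].
#' @param spec A `protocol_spec` of type `"ssa"` (see [protocol_set()]).
#' @param x Optional test voltages overriding `spec$voltages`.
#' @param dt Sampling interval for peak detection, ms.
#' @return A list with `x` (mV), `y` (normalized peak open probability).
#' @export
ssa_curve <- function(model, spec, x = NULL, dt = 0.05, cache = NULL) {
  voltages <- if (is.null(x)) spec$voltages else x
  stopifnot(length(voltages) >= 1)
  if (is.null(cache)) cache <- .make_cache(model)
  p0 <- .cached_steady(cache, spec$holding)
  peaks <- vapply(voltages, function(v)
    .step_peak(cache, p0, v, spec$duration, dt), numeric(1))
  m <- max(peaks)
  if (m <= 0) stop("all peak open probabilities are zero; cannot normalize")
  list(x = voltages, y = peaks / m)
}

#' Steady-state inactivation curve
#'
#' A conditioning prepulse at each voltage is followed by a fixed test pulse;
#' the test-pulse peak open probability is normalized to its maximum.
#'
#' @inheritParams ssa_curve
#' @param spec A `protocol_spec` of type `"ssi"`.
#' @param x Optional conditioning voltages overriding `spec$cond_voltages`.
#' @export
ssi_curve <- function(model, spec, x = NULL, dt = 0.05, cache = NULL) {
  voltages <- if (is.null(x)) spec$cond_voltages else x
  stopifnot(length(voltages) >= 1)
  if (is.null(cache)) cache <- .make_cache(model)
  p0 <- .cached_steady(cache, spec$holding)
  peaks <- vapply(voltages, function(vc) {
    p1 <- .prop_state(cache, vc, p0, spec$cond_duration)
    .step_peak(cache, p1, spec$test_voltage, spec$test_duration, dt)
  }, numeric(1))
  m <- max(peaks)
  if (m <= 0) stop("all peak open probabilities are zero; cannot normalize")
  list(x = voltages, y = peaks / m)
}

#' Recovery-from-inactivation curve
#'
#' A long depolarization inactivates the channels; after each hyperpolarized
#' recovery interval a test pulse reports the recovered fraction as the
#' normalized test-pulse peak.
#'
#' @inheritParams ssa_curve
#' @param spec A `protocol_spec` of type `"recovery"`.
#' @param x Optional recovery intervals (ms, ascending) overriding
#'   `spec$intervals`.
#' @export
recovery_curve <- function(model, spec, x = NULL, dt = 0.05, cache = NULL) {
  intervals <- if (is.null(x)) spec$intervals else x
  stopifnot(length(intervals) >= 1, !is.unsorted(intervals))
  if (is.null(cache)) cache <- .make_cache(model)
  p0 <- .cached_steady(cache, spec$holding)
  pdep <- .prop_state(cache, spec$depol_voltage, p0, spec$depol_duration)
  prec <- .prop_states(cache, spec$recovery_voltage, pdep, intervals)
  peaks <- vapply(seq_along(intervals), function(i)
    .step_peak(cache, prec[, i], spec$test_voltage, spec$test_duration, dt),
    numeric(1))
  m <- max(peaks)
  if (m <= 0) stop("all peak open probabilities are zero; cannot normalize")
  list(x = intervals, y = peaks / m)
}

#' Recovery from use-dependent block
#'
#' A 100-pulse depolarizing train (25 ms pulse at 25 Hz by default) drives
#' channels into slow inactivated states; recovery is then probed exactly as
#' in [recovery_curve()].  The per-period propagator is computed once and
#' raised to the pulse count by repeated squaring.
#'
#' @inheritParams recovery_curve
#' @param spec A `protocol_spec` of type `"rudb"`.
#' @export
rudb_curve <- function(model, spec, x = NULL, dt = 0.05, cache = NULL) {
  intervals <- if (is.null(x)) spec$intervals else x
  stopifnot(length(intervals) >= 1, !is.unsorted(intervals))
  if (is.null(cache)) cache <- .make_cache(model)
  p0 <- .cached_steady(cache, spec$holding)
  n <- model$topology$n_states
  Epulse <- .prop_matrix(cache, spec$train_voltage, spec$train_pulse)
  Egap <- .prop_matrix(cache, spec$holding, spec$train_gap)
  M <- .mat_power(Egap %*% Epulse, spec$n_pulses)
  ptrain <- as.numeric(M %*% p0)
  ptrain <- pmin(pmax(ptrain, 0), 1)
  ptrain <- ptrain / sum(ptrain)
  prec <- .prop_states(cache, spec$recovery_voltage, ptrain, intervals)
  peaks <- vapply(seq_along(intervals), function(i)
    .step_peak(cache, prec[, i], spec$test_voltage, spec$test_duration, dt),
    numeric(1))
  m <- max(peaks)
  if (m <= 0) stop("all peak open probabilities are zero; cannot normalize")
  list(x = intervals, y = peaks / m)
}

## dense propagator expm(A * t)
.prop_matrix <- function(cache, v, t) {
  sp <- .spectral(cache, v)
  if (sp$ok) {
    Re(sp$V %*% (exp(sp$values * t) * sp$Vi))
  } else {
    as.matrix(Matrix::expm(sp$A * t))
  }
}

.mat_power <- function(M, k) {
  R <- diag(nrow(M))
  while (k > 0) {
    if (k %% 2 == 1) R <- M %*% R
    M <- M %*% M
    k <- k %/% 2
  }
  R
}

#' Normalized open-probability trace at a step voltage
#'
#' @inheritParams ssa_curve
#' @param spec A `protocol_spec` of type `"trace"` (fields `voltage`,
#'   `duration`, `dt`).
#' @param x Optional sample times (ms) overriding the regular grid.
#' @return List with `x` (ms) and `y` (open probability normalized to the
#'   trace's own peak).
#' @export
current_trace <- function(model, spec, x = NULL, dt = NULL, cache = NULL) {
  dt <- if (!is.null(dt)) dt else if (!is.null(spec$dt)) spec$dt else 0.2
  tgrid <- if (is.null(x)) seq(0, spec$duration, by = dt) else x
  if (is.null(cache)) cache <- .make_cache(model)
  p0 <- .cached_steady(cache, spec$holding)
  y <- .open_traj(cache, spec$voltage, p0, tgrid)
  m <- max(y)
  if (m <= 0) stop("trace peak is zero; cannot normalize")
  list(x = tgrid, y = y / m)
}

#' Time to 50% decay of peak open probability
#'
#' For deactivation protocols the peak is recorded during a fixed
#' depolarizing pulse and the half-decay time is measured during the
#' subsequent voltage step; for inactivation protocols both happen within
#' the test step itself.  Points whose trace never decays below half peak
#' within the segment are censored (`NA` with a warning) and excluded from
#' cost.
#'
#' @inheritParams ssa_curve
#' @param spec A `protocol_spec` of type `"tau_deact"` or `"tau_inact"`.
#' @param x Optional step voltages.
#' @return List with `x` (mV) and `y` (ms; `NA` = censored).
#' @export
time_to_half_decay <- function(model, spec, x = NULL, dt = 0.05, cache = NULL) {
  voltages <- if (is.null(x)) spec$voltages else x
  if (is.null(cache)) cache <- .make_cache(model)
  p0 <- .cached_steady(cache, spec$holding)
  y <- if (spec$type == "tau_deact") {
    pdep <- .prop_state(cache, spec$depol_voltage, p0, spec$depol_duration)
    tg <- seq(0, spec$depol_duration, by = dt)
    peak <- .peak_value(.open_traj(cache, spec$depol_voltage, p0, tg), tg)
    vapply(voltages, function(v) {
      tgrid <- seq(0, spec$duration, by = dt)
      tr <- .open_traj(cache, v, pdep, tgrid)
      half <- 0.5 * peak
      k <- which(tr <= half)
      if (!length(k)) return(NA_real_)
      k <- k[1L]
      if (k == 1L) return(0)
      frac <- (tr[k - 1L] - half) / (tr[k - 1L] - tr[k])
      tgrid[k - 1L] + frac * dt
    }, numeric(1))
  } else {
    vapply(voltages, function(v) {
      tgrid <- seq(0, spec$duration, by = dt)
      tr <- .open_traj(cache, v, p0, tgrid)
      .tau50(tr, tgrid)
    }, numeric(1))
  }
  if (anyNA(y))
    warning(sprintf("%d censored point(s): no 50%% decay within the segment",
                    sum(is.na(y))))
  list(x = voltages, y = y)
}

#' Peak-open-probability constraint contribution
#'
#' Squared relative deviations of simulated peak open probabilities from the
#' given targets; added to the cost like data points but with no SEM
#' deadzone.
#'
#' @param model A [channel_model()].
#' @param spec A `protocol_spec` of type `"max_open"` (fields `voltages`,
#'   `targets`, `duration`, `holding`), or `NULL` for zero contribution.
#' @param dt Sampling interval, ms.
#' @return Non-negative cost contribution.
#' @export
max_open_constraint <- function(model, spec, dt = 0.05, cache = NULL) {
  if (is.null(spec)) return(0)
  stopifnot(length(spec$voltages) == length(spec$targets))
  if (is.null(cache)) cache <- .make_cache(model)
  p0 <- .cached_steady(cache, spec$holding)
  peaks <- vapply(spec$voltages, function(v)
    .step_peak(cache, p0, v, spec$duration, dt), numeric(1))
  sum(((peaks - spec$targets) / spec$targets)^2)
}

#' Write a protocol set to YAML or JSON
#'
#' Serializes a protocol list (preset or user-defined) so batteries can be
#' versioned and shared; [read_protocols()] restores it.  The format is
#' chosen by the file extension (`.yaml`/`.yml` needs the yaml package,
#' anything else is written as JSON).
#'
#' @param protocols Named list of `protocol_spec` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocols <- function(protocols, path) {
  plain <- lapply(protocols, unclass)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to write YAML protocol files")
    yaml::write_yaml(plain, path)
  } else {
    writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA), path)
  }
  invisible(path)
}

#' Read a protocol set from YAML or JSON
#'
#' @param path File written by [write_protocols()] (or hand-written in the
#'   same schema: a named map of specs with at least `name`, `type`, and
#'   `holding` per entry).
#' @return Named list of `protocol_spec` objects.
#' @export
read_protocols <- function(path) {
  plain <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML protocol files")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  lapply(plain, function(sp) {
    if (is.null(sp$name) || is.null(sp$type) || is.null(sp$holding))
      stop("protocol entries need name, type, and holding fields")
    structure(sp, class = "protocol_spec")
  })
}

#' Simulate one protocol to a summary curve
#'
#' Dispatches on the spec type and returns the `(x, y)` summary curve that
#' datasets are expressed in.
#'
#' @param model A [channel_model()].
#' @param spec A `protocol_spec`.
#' @param x Optional independent-variable values (test voltages, intervals,
#'   or sample times depending on the protocol).
#' @param dt Sampling interval for peak / decay detection, ms.
#' @return List with `x` and `y`.
#' @export
simulate_protocol <- function(model, spec, x = NULL, dt = 0.05, cache = NULL) {
  switch(spec$type,
         ssa = ssa_curve(model, spec, x = x, dt = dt, cache = cache),
         ssi = ssi_curve(model, spec, x = x, dt = dt, cache = cache),
         recovery = recovery_curve(model, spec, x = x, dt = dt, cache = cache),
         rudb = rudb_curve(model, spec, x = x, dt = dt, cache = cache),
         trace = current_trace(model, spec, x = x, cache = cache),
         tau_deact = ,
         tau_inact = time_to_half_decay(model, spec, x = x, dt = dt,
                                        cache = cache),
         stop("unknown protocol type: ", spec$type))
}
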