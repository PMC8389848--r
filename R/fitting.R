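## Parameter fitting: SEM-deadzone cost, train/validation split, adaptive
## simulated annealing with multistart, overfitting-guarded early stopping,
## and classification of topologies by minimum cost.

## ---- cost ---------------------------------------------------------------

## deadzone residual cost for one curve: only the part of the model-data gap
## outside the SEM counts, squared and relative to the data value
## (absolute where the data value is 0)
.deadzone_cost <- function(pred, mean, sem) {
  keep <- !is.na(pred)
  res <- pmax(0, abs(pred[keep] - mean[keep]) - sem[keep])
  denom <- ifelse(mean[keep] == 0, 1, abs(mean[keep]))
  sum((res / denom)^2)
}

#' Cost of a model against a dataset
#'
#' Sum over data points of the squared relative residual outside each
#' point's SEM (the deadzone: predictions within one SEM cost nothing),
#' plus the stiffness penalty and any peak-open-probability constraint in
#' the protocol set.  Points with `mean = 0` use the absolute residual.
#'
#' @param model A [channel_model()].
#' @param dataset A [clamp_dataset()].
#' @param protocols Protocol set (see [protocol_set()]) covering every curve.
#' @param indices Optional list (one integer vector per curve) restricting
#'   which points are charged; curves are always simulated in full so that
#'   normalization is unaffected.
#' @param stiffness A [stiffness_config()].
#' @param dt Simulation sampling interval, ms.
#' @return A list with `total`, `data_cost`, `stiffness_penalty`,
#'   `max_open`, and `per_curve`.
#' @export
model_cost <- function(model, dataset, protocols, indices = NULL,
                       stiffness = stiffness_config(), dt = 0.05) {
  per_curve <- numeric(length(dataset$curves))
  names(per_curve) <- vapply(dataset$curves, `[[`, character(1), "protocol")
  for (i in seq_along(dataset$curves)) {
    cv <- dataset$curves[[i]]
    spec <- protocols[[cv$protocol]]
    if (is.null(spec)) stop("no protocol spec named '", cv$protocol, "'")
    sim <- suppressWarnings(simulate_protocol(model, spec, x = cv$x, dt = dt))
    sel <- if (is.null(indices)) seq_along(cv$x) else indices[[i]]
    per_curve[i] <- .deadzone_cost(sim$y[sel], cv$mean[sel], cv$sem[sel])
  }
  sp <- stiffness_penalty(model, stiffness)
  mo <- max_open_constraint(model, protocols$max_open, dt = dt)
  list(total = sum(per_curve) + sp + mo,
       data_cost = sum(per_curve),
       stiffness_penalty = sp,
       max_open = mo,
       per_curve = per_curve)
}

## fast combined evaluator: one simulation pass -> training total (data +
## SP + max-open) and validation data cost
.make_cost_fn <- function(topology, dataset, protocols, split = NULL,
                          stiffness = stiffness_config(), dt = 0.05) {
  specs <- lapply(dataset$curves, function(cv) {
    spec <- protocols[[cv$protocol]]
    if (is.null(spec)) stop("no protocol spec named '", cv$protocol, "'")
    spec
  })
  nc <- length(dataset$curves)
  train_idx <- if (is.null(split)) lapply(dataset$curves, function(cv) seq_along(cv$x))
               else split$train
  val_idx <- if (is.null(split)) lapply(dataset$curves, function(cv) integer(0))
             else split$validation
  mo_spec <- protocols$max_open
  k4 <- 4L * complexity(topology)
  function(params) {
    out <- tryCatch({
      model <- .unpack_fast(topology, params, k4)
      cache <- .make_cache(model)
      train <- 0; val <- 0
      for (i in seq_len(nc)) {
        cv <- dataset$curves[[i]]
        sim <- suppressWarnings(simulate_protocol(model, specs[[i]],
                                                  x = cv$x, dt = dt,
                                                  cache = cache))
        train <- train + .deadzone_cost(sim$y[train_idx[[i]]],
                                        cv$mean[train_idx[[i]]],
                                        cv$sem[train_idx[[i]]])
        if (length(val_idx[[i]]))
          val <- val + .deadzone_cost(sim$y[val_idx[[i]]],
                                      cv$mean[val_idx[[i]]],
                                      cv$sem[val_idx[[i]]])
      }
      sp <- .stiffness_cached(cache, stiffness)
      mo <- max_open_constraint(model, mo_spec, dt = dt, cache = cache)
      c(train = train + sp + mo, val = val, sp = sp)
    }, error = function(e) c(train = Inf, val = Inf, sp = Inf))
    out
  }
}

## validation-free unpack for the optimizer's inner loop
.unpack_fast <- function(topology, params, k4) {
  if (length(params) != k4) stop("parameter length mismatch")
  npot <- topology$n_states - 1L
  fns <- lapply(seq_len(k4 %/% 4L), function(i) {
    p <- params[(4L * i - 3L):(4L * i)]
    structure(list(a = p[1], b = p[2], args1 = p[3], args2 = p[4]),
              class = "voltage_fn")
  })
  structure(list(topology = topology,
                 state_potentials = fns[seq_len(npot)],
                 edge_barriers = fns[npot + seq_len(length(fns) - npot)]),
            class = "channel_model")
}

## ---- train / validation split ------------------------------------------

#' Random per-curve train/validation split
#'
#' From each curve a fraction of points (default 20%) is set aside for
#' validation; curves with at least 5 points contribute at least one
#' validation point, shorter curves stay fully in training.
#'
#' @param dataset A [clamp_dataset()].
#' @param fraction Validation fraction in `(0, 1)`.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A list with `train` and `validation` (index vectors per curve)
#'   and `seed`.
#' @export
split_dataset <- function(dataset, fraction = 0.2, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  train <- list(); validation <- list()
  for (i in seq_along(dataset$curves)) {
    n <- length(dataset$curves[[i]]$x)
    n_val <- if (n >= 5L) max(1L, round(fraction * n)) else floor(fraction * n)
    v <- if (n_val > 0L) sort(sample.int(n, n_val)) else integer(0)
    validation[[i]] <- v
    train[[i]] <- setdiff(seq_len(n), v)
  }
  list(train = train, validation = validation, seed = seed)
}

## ---- adaptive temperature (annealing core pieces) ----------------------

#' Annealer configuration
#'
#' @param t_min Minimum (restart) temperature, `> 0`.
#' @param lambda Temperature control gain: `t = t_min + lambda * ln(1 + r)`
#'   where `r` counts consecutive worse-than-best proposals.
#' @param n_chains Independent non-interacting chains per start.
#' @param max_iterations Iteration budget per chain.
#' @param convergence_window Stop once this many iterations pass without the
#'   best cost improving by more than `convergence_fraction`.
#' @param convergence_fraction Relative improvement regarded as progress.
#' @param proposal_scale Proposal s.d. as a fraction of each parameter range.
#' @return An `annealer_config` object.
#' @export
annealer_config <- function(t_min = 0.1, lambda = 1, n_chains = 4L,
                            max_iterations = 200000L,
                            convergence_window = 20000L,
                            convergence_fraction = 0.2,
                            proposal_scale = 0.02) {
  stopifnot(t_min > 0, lambda >= 0, n_chains >= 1, max_iterations >= 0,
            convergence_window > 0, convergence_fraction > 0,
            proposal_scale > 0)
  structure(list(t_min = t_min, lambda = lambda, n_chains = as.integer(n_chains),
                 max_iterations = as.integer(max_iterations),
                 convergence_window = as.integer(convergence_window),
                 convergence_fraction = convergence_fraction,
                 proposal_scale = proposal_scale),
            class = "annealer_config")
}

#' Adaptive annealing temperature
#'
#' `t = t_min + lambda * ln(1 + r)`: the temperature starts at the lowest
#' threshold and rises with the number of consecutive worse solutions,
#' falling back to `t_min` whenever a new best is found.
#'
#' @param r Worse-solution counter (`>= 0`).
#' @param cfg An [annealer_config()].
#' @return Temperature.
#' @export
adaptive_temperature <- function(r, cfg = annealer_config()) {
  stopifnot(r >= 0)
  cfg$t_min + cfg$lambda * log1p(r)
}

#' Update the worse-solution counter
#'
#' Increment when the candidate is worse than the best cost so far, hold
#' when equal, reset to zero on improvement (which also returns the
#' temperature to `t_min`).
#'
#' @param r_prev Previous counter.
#' @param delta_c Candidate cost minus best cost.
#' @return Updated counter.
#' @export
update_counter <- function(r_prev, delta_c) {
  if (delta_c > 0) r_prev + 1L
  else if (delta_c < 0) 0L
  else r_prev
}

## ---- overfitting monitor ------------------------------------------------

#' Overfitting monitor configuration
#'
#' @param check_epoch Iterations between monitor evaluations.
#' @param strip Strip length `k`: progress is measured over the last `k`
#'   checks.
#' @param consecutive Number of consecutive increases of the overfitting
#'   ratio `Q` that trigger early stopping.
#' @param eps Floor for the progress denominator.
#' @return An `overfit_config` object.
#' @export
overfit_config <- function(check_epoch = 1000L, strip = 5L, consecutive = 3L,
                           eps = 1e-12) {
  stopifnot(check_epoch >= 1, strip >= 1, consecutive >= 1, eps > 0)
  structure(list(check_epoch = as.integer(check_epoch), strip = as.integer(strip),
                 consecutive = as.integer(consecutive), eps = eps),
            class = "overfit_config")
}

#' Create an overfitting monitor
#'
#' Tracks training progress `P` (how much the strip-average training cost
#' exceeds the strip minimum), generalization loss `GL` (how much the
#' current validation cost exceeds the best validation cost seen), and
#' their ratio `Q = GL / max(P, eps)`.  Three consecutive strict increases
#' of `Q` signal that validation performance is deteriorating while
#' training stalls — likely overfitting — and set the stop flag.
#'
#' @param cfg An [overfit_config()].
#' @return An `overfit_monitor` object.
#' @export
new_overfit_monitor <- function(cfg = overfit_config()) {
  structure(list(cfg = cfg, strip_hist = numeric(0), min_val = Inf,
                 prev_q = NA_real_, n_increase = 0L, stop = FALSE,
                 history = list()),
            class = "overfit_monitor")
}

#' Feed one check epoch to the overfitting monitor
#'
#' @param monitor An `overfit_monitor`.
#' @param train_cost Current training cost.
#' @param val_cost Current validation cost.
#' @return The updated monitor; `monitor$stop` is `TRUE` when the ratio
#'   `Q` has increased on `consecutive` successive checks.  With fewer than
#'   `strip` checks seen the monitor always continues.
#' @export
overfit_check <- function(monitor, train_cost, val_cost) {
  cfg <- monitor$cfg
  monitor$strip_hist <- utils::tail(c(monitor$strip_hist, train_cost), cfg$strip)
  monitor$min_val <- min(monitor$min_val, val_cost)
  if (length(monitor$strip_hist) < cfg$strip) {
    monitor$history[[length(monitor$history) + 1L]] <-
      c(train = train_cost, val = val_cost, P = NA, GL = NA, Q = NA)
    return(monitor)
  }
  strip_min <- min(monitor$strip_hist)
  P <- if (strip_min > 0)
    1000 * (sum(monitor$strip_hist) / (cfg$strip * strip_min) - 1)
  else 0
  GL <- if (monitor$min_val > 0) 100 * (val_cost / monitor$min_val - 1) else 0
  Q <- GL / max(P, cfg$eps)
  if (!is.na(monitor$prev_q) && Q > monitor$prev_q)
    monitor$n_increase <- monitor$n_increase + 1L
  else
    monitor$n_increase <- 0L
  monitor$prev_q <- Q
  monitor$stop <- monitor$n_increase >= cfg$consecutive
  monitor$history[[length(monitor$history) + 1L]] <-
    c(train = train_cost, val = val_cost, P = P, GL = GL, Q = Q)
  monitor
}

## ---- annealing ----------------------------------------------------------

.reflect <- function(x, lo, hi) {
  span <- hi - lo
  if (span <= 0) return(lo)
  y <- (x - lo) %% (2 * span)
  if (y < 0) y <- y + 2 * span
  lo + ifelse(y > span, 2 * span - y, y)
}

.run_chain <- function(fn, start, bounds, annealer, overfit, chain_seed,
                       stop_at = 0) {
  set.seed(chain_seed)
  lower <- bounds$lower; upper <- bounds$upper
  scale <- annealer$proposal_scale * (upper - lower)
  np <- length(start)
  cur <- start
  ecur <- fn(cur)
  best <- ecur[["train"]]
  best_params <- cur
  best_eval <- ecur
  r <- 0L
  monitor <- new_overfit_monitor(overfit)
  termination <- "max_iter"
  if (best <= stop_at) termination <- "converged"   # start already optimal
  max_iter <- if (termination == "converged") 0L else annealer$max_iterations
  win <- annealer$convergence_window
  frac <- annealer$convergence_fraction
  best_hist <- numeric(max_iter)
  trace_iter <- integer(0); trace_best <- numeric(0)
  trace_train <- numeric(0); trace_val <- numeric(0); trace_q <- numeric(0)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    j <- sample.int(np, 1L)
    cand <- cur
    ## mixture kernel: mostly local refinement, occasionally a 10x move so
    ## chains can escape local traps in the deadzone landscape
    sd_j <- if (stats::runif(1L) < 0.1) 10 * scale[j] else scale[j]
    cand[j] <- .reflect(cur[j] + stats::rnorm(1L, sd = sd_j),
                        lower[j], upper[j])
    ecand <- fn(cand)
    dbest <- ecand[["train"]] - best
    r <- update_counter(r, dbest)
    t <- adaptive_temperature(r, annealer)
    dcur <- ecand[["train"]] - ecur[["train"]]
    if (dcur <= 0 || stats::runif(1L) < exp(-dcur / t)) {
      cur <- cand
      ecur <- ecand
    }
    if (ecand[["train"]] < best) {
      best <- ecand[["train"]]
      best_params <- cand
      best_eval <- ecand
    }
    best_hist[iter] <- best
    ## the cost is bounded below by stop_at (zero for pure deadzone data):
    ## attaining it is a global optimum, nothing left to improve
    if (best <= stop_at) { termination <- "converged"; break }
    if (iter %% overfit$check_epoch == 0L) {
      monitor <- overfit_check(monitor, ecur[["train"]], ecur[["val"]])
      h <- monitor$history[[length(monitor$history)]]
      trace_iter <- c(trace_iter, iter)
      trace_best <- c(trace_best, best)
      trace_train <- c(trace_train, ecur[["train"]])
      trace_val <- c(trace_val, ecur[["val"]])
      trace_q <- c(trace_q, h[["Q"]])
      if (monitor$stop) { termination <- "early_stop"; break }
    }
    if (iter > win && is.finite(best_hist[iter - win])) {
      ref <- best_hist[iter - win]
      if (ref - best <= frac * abs(ref)) { termination <- "converged"; break }
    }
  }
  if (iter == 0L) termination <- "max_iter"
  list(params = best_params, best = best, eval = best_eval,
       iterations = iter, termination = termination,
       trace = data.frame(iteration = trace_iter, best_cost = trace_best,
                          train_cost = trace_train, val_cost = trace_val,
                          Q = trace_q))
}

#' Fit one topology from one start by adaptive simulated annealing
#'
#' Metropolis acceptance on the training cost with the adaptive temperature
#' of [adaptive_temperature()]: worse-than-best proposals heat the chain,
#' a new best resets it to `t_min`, so the optimizer escapes local minima
#' without losing its best solution (the best-cost trace is
#' non-increasing).  Runs `n_chains` independent chains and returns the
#' best.  Chains terminate on the convergence rule (no 20% cost improvement
#' across the window), the iteration budget, or overfitting early stop.
#'
#' @param topology A [rooted_topology()].
#' @param start Numeric start vector (length `4K`, inside the bounds).
#' @param dataset A [clamp_dataset()].
#' @param protocols Protocol set covering the dataset curves.
#' @param split Optional [split_dataset()] result; without it all points
#'   train and the overfitting monitor never stops.
#' @param annealer An [annealer_config()].
#' @param overfit An [overfit_config()].
#' @param stiffness A [stiffness_config()].
#' @param dt Simulation sampling interval, ms.
#' @param seed Integer seed (chains derive independent substreams).
#' @param stop_at Cost floor: a chain (and the surrounding multistart)
#'   terminates as converged once the best cost reaches this value, since
#'   the deadzone cost is bounded below (0 means a perfect within-SEM fit).
#' @return A `model_solution`: optimized parameters, cost breakdown,
#'   iteration count, termination reason, and the optimization trace.
#' @export
anneal <- function(topology, start, dataset, protocols, split = NULL,
                   annealer = annealer_config(), overfit = overfit_config(),
                   stiffness = stiffness_config(), dt = 0.05, seed = 1L,
                   stop_at = 0) {
  bounds <- parameter_bounds(topology)
  stopifnot(length(start) == length(bounds$lower))
  fn <- .make_cost_fn(topology, dataset, protocols, split, stiffness, dt)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, annealer$n_chains)
  chains <- list()
  for (cs in chain_seeds) {
    chains[[length(chains) + 1L]] <-
      .run_chain(fn, start, bounds, annealer, overfit, cs, stop_at = stop_at)
    if (chains[[length(chains)]]$best <= stop_at) break
  }
  besti <- which.min(vapply(chains, `[[`, numeric(1), "best"))
  ch <- chains[[besti]]
  structure(list(topology = topology,
                 params = ch$params,
                 train_cost = ch$best,
                 val_cost = ch$eval[["val"]],
                 stiffness_penalty = ch$eval[["sp"]],
                 iterations = ch$iterations,
                 termination = ch$termination,
                 trace = ch$trace,
                 n_chains = annealer$n_chains,
                 label = NA_character_),
            class = "model_solution")
}

#' @export
print.model_solution <- function(x, ...) {
  cat(sprintf(paste0("model_solution: %d states / %d edges (K = %d); ",
                     "train cost %.4g (SP %.3g), val cost %.4g\n"),
              x$topology$n_states, nrow(x$topology$edges),
              complexity(x$topology), x$train_cost, x$stiffness_penalty,
              x$val_cost))
  cat(sprintf("  %d iterations, termination: %s, label: %s\n",
              x$iterations, x$termination, x$label))
  invisible(x)
}

#' Multistart fit of one topology
#'
#' Runs [anneal()] from `n_starts` Sobol-distributed starting vectors and
#' returns the minimum-cost solution together with all per-start solutions
#' (the spread across starts is itself informative about the optimization
#' landscape).
#'
#' @inheritParams anneal
#' @param n_starts Number of quasi-random starts (20 or more in practice).
#' @return A list with `best` (a `model_solution`) and `solutions`.
#' @export
multistart_fit <- function(topology, dataset, protocols, n_starts = 20L,
                           split = NULL, annealer = annealer_config(),
                           overfit = overfit_config(),
                           stiffness = stiffness_config(), dt = 0.05,
                           seed = 1L, stop_at = 0) {
  bounds <- parameter_bounds(topology)
  starts <- sobol_starts(bounds, n_starts, seed = seed)
  set.seed(seed + 1L)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_starts)
  solutions <- list()
  for (i in seq_len(n_starts)) {
    solutions[[i]] <- anneal(topology, starts[i, ], dataset, protocols,
                             split = split, annealer = annealer,
                             overfit = overfit, stiffness = stiffness,
                             dt = dt, seed = run_seeds[i], stop_at = stop_at)
    ## a start at the global floor cannot be improved by further starts
    if (solutions[[i]]$train_cost <= stop_at) break
  }
  besti <- which.min(vapply(solutions, `[[`, numeric(1), "train_cost"))
  list(best = solutions[[besti]], solutions = solutions)
}

## ---- classification -----------------------------------------------------

#' Classify solutions as acceptable or unacceptable
#'
#' A solution is acceptable when its cost is no greater than `threshold`
#' times the absolute minimum cost in the batch (default 300%).
#'
#' @param solutions List of `model_solution` objects (typically the best per
#'   topology).
#' @param threshold Multiple of the batch minimum (default 3).
#' @return The solutions with `label` set to `"acceptable"` or
#'   `"unacceptable"`.
#' @export
classify_solutions <- function(solutions, threshold = 3) {
  stopifnot(length(solutions) >= 1)
  costs <- vapply(solutions, `[[`, numeric(1), "train_cost")
  cmin <- min(costs)
  for (i in seq_along(solutions))
    solutions[[i]]$label <-
      if (costs[i] <= threshold * cmin) "acceptable" else "unacceptable"
  solutions
}

#' Best cost and stiffness penalty by model complexity
#'
#' Descriptive table used to locate the point of diminishing returns: the
#' complexity beyond which adding free rate constants no longer reduces the
#' attainable cost.
#'
#' @param solutions List of `model_solution` objects.
#' @return Data frame with one row per complexity `K`: solution count,
#'   minimum cost, minimum stiffness penalty.
#' @export
diminishing_returns_table <- function(solutions) {
  if (!length(solutions))
    return(data.frame(complexity = integer(0), n_solutions = integer(0),
                      min_cost = numeric(0), min_stiffness_penalty = numeric(0)))
  k <- vapply(solutions, function(s) complexity(s$topology), integer(1))
  cost <- vapply(solutions, `[[`, numeric(1), "train_cost")
  sp <- vapply(solutions, `[[`, numeric(1), "stiffness_penalty")
  ks <- sort(unique(k))
  data.frame(complexity = ks,
             n_solutions = vapply(ks, function(x) sum(k == x), integer(1)),
             min_cost = vapply(ks, function(x) min(cost[k == x]), numeric(1)),
             min_stiffness_penalty = vapply(ks, function(x) min(sp[k == x]),
                                            numeric(1)))
}

#' Solution summary table
#'
#' One row per solution: topology features, costs, penalty, termination and
#' label — the shape of the catalog-wide result tables.
#'
#' @param solutions List of `model_solution` objects.
#' @return A data frame.
#' @export
solution_table <- function(solutions) {
  do.call(rbind, lapply(solutions, function(s) data.frame(
    key = s$topology$canonical_key,
    n_states = s$topology$n_states,
    n_edges = nrow(s$topology$edges),
    root_degree = root_degree(s$topology),
    complexity = complexity(s$topology),
    train_cost = s$train_cost,
    val_cost = s$val_cost,
    stiffness_penalty = s$stiffness_penalty,
    iterations = s$iterations,
    termination = s$termination,
    label = s$label)))
}
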