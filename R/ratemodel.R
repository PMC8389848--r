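#' Sigmoidal voltage function
#'
#' The building block of every rate: `f(v) = a + b * tanh((v + args1) / args2)`,
#' a bounded sigmoid of membrane voltage.  `a` (dimensionless offset) and `b`
#' (dimensionless amplitude) set the plateau values `a - |b|` and `a + |b|`;
#' `args1` (mV) shifts the half-point and `args2` (mV, > 0) sets the slope
#' scale.
#'
#' @param a,b Dimensionless offset and amplitude.
#' @param args1 Half-point shift, mV.
#' @param args2 Slope scale, mV (must be nonzero).
#' @return An object of class `voltage_fn`.
#' @export
voltage_fn <- function(a = 0, b = 0, args1 = 0, args2 = 30) {
  if (args2 == 0) stop("args2 must be nonzero")
  structure(list(a = a, b = b, args1 = args1, args2 = args2),
            class = "voltage_fn")
}

#' Evaluate a voltage function
#'
#' @param f A [voltage_fn()].
#' @param v Voltage(s), mV.
#' @return Numeric values in `[a - |b|, a + |b|]`.
#' @export
eval_voltage_fn <- function(f, v) {
  f$a + f$b * tanh((v + f$args1) / f$args2)
}

#' Channel model: a rooted topology with voltage-dependent rates
#'
#' Rates are built from a node-potential construction that guarantees
#' microscopic reversibility at every voltage: each non-root state `j`
#' carries a potential function `phi_j(v)` (the root's potential is pinned
#' to 0 as the gauge) and each edge `{i, j}` carries a symmetric barrier
#' function `beta_ij(v)`.  The transition rate from state `j` to state `i`
#' is `r_ji(v) = exp(beta_ij(v) + phi_j(v))` (1/ms), so the ratio of forward
#' and backward rates across an edge is `exp(phi_j - phi_i)` and rate
#' products around any cycle telescope to equality in both directions.
#' The stationary distribution at voltage `v` is proportional to
#' `exp(-phi_i(v))`.  A model has `K = N + E - 1` free voltage functions
#' (4 scalars each).
#'
#' @param topology A [rooted_topology()].
#' @param state_potentials List of [voltage_fn()], one per non-root state in
#'   increasing state order (the root is skipped).
#' @param edge_barriers List of [voltage_fn()], one per edge in the
#'   topology's edge order.
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(topology, state_potentials, edge_barriers) {
  stopifnot(inherits(topology, "rooted_topology"))
  n <- topology$n_states
  ne <- nrow(topology$edges)
  if (length(state_potentials) != n - 1L)
    stop(sprintf("need %d state potentials (one per non-root state)", n - 1L))
  if (length(edge_barriers) != ne)
    stop(sprintf("need %d edge barriers (one per edge)", ne))
  ok <- vapply(c(state_potentials, edge_barriers),
               function(f) inherits(f, "voltage_fn"), logical(1))
  if (!all(ok)) stop("all parameters must be voltage_fn objects")
  structure(list(topology = topology,
                 state_potentials = state_potentials,
                 edge_barriers = edge_barriers),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  tp <- x$topology
  cat(sprintf("channel_model on %d states, %d edges (K = %d free rate functions)\n",
              tp$n_states, nrow(tp$edges), complexity(tp)))
  invisible(x)
}

## potential of state i (root fixed at 0, the gauge)
.state_potential <- function(model, i, v) {
  root <- model$topology$root
  if (i == root) return(rep(0, length(v)))
  idx <- i - (i > root)   # position among non-root states
  eval_voltage_fn(model$state_potentials[[idx]], v)
}

.edge_index <- function(topology, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  w <- which(topology$edges[, 1L] == lo & topology$edges[, 2L] == hi)
  if (!length(w)) NA_integer_ else w[1L]
}

#' Transition rate between adjacent states
#'
#' @param model A [channel_model()].
#' @param from,to State indices; `{from, to}` must be an edge.
#' @param v Voltage(s), mV.
#' @return Rate(s) from `from` to `to`, 1/ms (strictly positive).
#' @export
rate <- function(model, from, to, v) {
  ei <- .edge_index(model$topology, from, to)
  if (is.na(ei)) stop(sprintf("states %d and %d are not adjacent", from, to))
  exp(eval_voltage_fn(model$edge_barriers[[ei]], v) +
        .state_potential(model, from, v))
}

#' Infinitesimal generator at a voltage
#'
#' Entry `(i, j)` for `i != j` is the rate from state `j` to state `i`;
#' diagonal entries are the negative column sums, so columns sum to zero.
#'
#' @param model A [channel_model()].
#' @param v Voltage, mV (scalar).
#' @return An `N x N` matrix.
#' @export
transition_matrix <- function(model, v) {
  tp <- model$topology
  n <- tp$n_states
  A <- matrix(0, n, n)
  E <- tp$edges
  for (k in seq_len(nrow(E))) {
    i <- E[k, 1L]; j <- E[k, 2L]
    bar <- eval_voltage_fn(model$edge_barriers[[k]], v)
    A[i, j] <- exp(bar + .state_potential(model, j, v))  # j -> i
    A[j, i] <- exp(bar + .state_potential(model, i, v))  # i -> j
  }
  diag(A) <- -colSums(A)
  A
}

#' Stationary distribution at a voltage
#'
#' Solves `A p = 0`, `sum(p) = 1` directly (all rates are strictly positive
#' on a connected topology, so the stationary distribution is unique).
#'
#' @param model A [channel_model()].
#' @param v Voltage, mV.
#' @return Probability vector of length `N`.
#' @export
steady_state <- function(model, v) {
  n <- model$topology$n_states
  if (n == 1L) return(1)
  A <- transition_matrix(model, v)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- tryCatch(solve(A, b), error = function(e)
    stop("stationary solve failed: ", conditionMessage(e)))
  ## clip roundoff
  p[p < 0 & p > -1e-12] <- 0
  p
}

## ---- stiffness ----------------------------------------------------------

## reciprocal 1-norm condition number of a square matrix
.rcond1 <- function(M) {
  if (nrow(M) == 1L) return(1)
  Minv <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Minv)) return(0)
  r <- 1 / (norm(M, "1") * norm(Minv, "1"))
  min(max(r, 0), 1)
}

## generator reduced by probability conservation: eliminate the last state
.reduced_generator <- function(A) {
  n <- nrow(A)
  Ar <- A[-n, -n, drop = FALSE]
  sweep(Ar, 1L, A[-n, n], "-")
}

#' Reciprocal condition number of the reduced generator
#'
#' The full generator is exactly singular (columns sum to zero), so the
#' reciprocal 1-norm condition number is evaluated on the
#' `(N-1) x (N-1)` system obtained by eliminating one state through
#' probability conservation.  Values near zero flag stiff models that force
#' tiny explicit-solver time steps.
#'
#' @param model A [channel_model()].
#' @param v Voltage, mV.
#' @return A value in `(0, 1]`; 1 by convention for `N <= 2`.
#' @export
stiffness_rcond <- function(model, v) {
  n <- model$topology$n_states
  if (n <= 2L) return(1)
  .rcond1(.reduced_generator(transition_matrix(model, v)))
}

#' Stiffness probe configuration
#'
#' @param probe_voltages Voltages at which stiffness is probed, mV.
#' @param rcond_threshold Reciprocal condition numbers below this flag a
#'   voltage as stiff (must be in `(0, 1]`).
#' @param weight Weight of the penalty in cost units.
#' @return An object of class `stiffness_config`.
#' @export
stiffness_config <- function(probe_voltages = seq(-120, 60, by = 20),
                             rcond_threshold = 1e-6, weight = 1) {
  stopifnot(rcond_threshold > 0, rcond_threshold <= 1, length(probe_voltages) >= 1)
  structure(list(probe_voltages = probe_voltages,
                 rcond_threshold = rcond_threshold, weight = weight),
            class = "stiffness_config")
}

## penalty from a vector of rconds: mean decades below threshold, flagged only
.sp_from_rconds <- function(rconds, threshold, weight) {
  flagged <- rconds < threshold
  if (!any(flagged)) return(0)
  weight * mean(log10(threshold / rconds[flagged]))
}

#' Stiffness penalty of a model
#'
#' Probes the reduced-generator reciprocal condition number across
#' `probe_voltages`; voltages with `rcond < rcond_threshold` are flagged and
#' the penalty is `weight` times the mean number of decades by which flagged
#' values fall below the threshold.  Zero when no voltage is flagged, and
#' strictly increasing as any flagged rcond shrinks.
#'
#' @param model A [channel_model()].
#' @param cfg A [stiffness_config()].
#' @return Penalty in cost units (`>= 0`).
#' @export
stiffness_penalty <- function(model, cfg = stiffness_config()) {
  rc <- vapply(cfg$probe_voltages, function(v) stiffness_rcond(model, v),
               numeric(1))
  .sp_from_rconds(rc, cfg$rcond_threshold, cfg$weight)
}

## ---- parameter packing --------------------------------------------------

#' Pack model parameters into a flat vector
#'
#' Order: the four scalars `(a, b, args1, args2)` of each non-root state
#' potential in state order, then of each edge barrier in edge order; total
#' length `4 * (N + E - 1)`.
#'
#' @param model A [channel_model()].
#' @return Numeric vector.
#' @export
pack_parameters <- function(model) {
  fns <- c(model$state_potentials, model$edge_barriers)
  as.numeric(unlist(lapply(fns, function(f) c(f$a, f$b, f$args1, f$args2))))
}

#' Build a model from a topology and a flat parameter vector
#'
#' Inverse of [pack_parameters()].
#'
#' @param topology A [rooted_topology()].
#' @param params Numeric vector of length `4 * (N + E - 1)`.
#' @return A [channel_model()].
#' @export
unpack_parameters <- function(topology, params) {
  k <- complexity(topology)
  if (length(params) != 4L * k)
    stop(sprintf("expected %d parameters (4 x K), got %d", 4L * k, length(params)))
  fns <- lapply(seq_len(k), function(i) {
    p <- params[(4L * (i - 1L) + 1L):(4L * i)]
    voltage_fn(p[1], p[2], p[3], p[4])
  })
  npot <- topology$n_states - 1L
  channel_model(topology,
                state_potentials = fns[seq_len(npot)],
                edge_barriers = fns[npot + seq_len(nrow(topology$edges))])
}

#' Optimization bounds for a topology's parameter vector
#'
#' Per voltage function: `a, b` in `[-10, 10]`; `args1` in `[-100, 100]` mV;
#' `args2` in `[1, 100]` mV.
#'
#' @param topology A [rooted_topology()].
#' @return A list with numeric vectors `lower` and `upper` of length
#'   `4 * (N + E - 1)`.
#' @export
parameter_bounds <- function(topology) {
  k <- complexity(topology)
  lower <- rep(c(-10, -10, -100, 1), k)
  upper <- rep(c(10, 10, 100, 100), k)
  list(lower = lower, upper = upper)
}

## ---- model serialization ------------------------------------------------

#' Write a channel model to JSON
#'
#' @param model A [channel_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  tp <- model$topology
  rec <- list(n_states = tp$n_states,
              edges = unname(apply(tp$edges, 1L, function(e) e - 1L,
                                   simplify = FALSE)),
              root = tp$root - 1L,
              state_potentials = lapply(model$state_potentials, unclass),
              edge_barriers = lapply(model$edge_barriers, unclass))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a channel model from JSON
#'
#' @param path File written by [write_model()].
#' @return A [channel_model()].
#' @export
read_model <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  edges <- if (length(rec$edges))
    matrix(as.integer(unlist(rec$edges)), ncol = 2L, byrow = TRUE) + 1L
  else matrix(integer(0), 0L, 2L)
  tp <- rooted_topology(rec$n_states, edges, root = rec$root + 1L)
  as_fn <- function(f) voltage_fn(f$a, f$b, f$args1, f$args2)
  channel_model(tp,
                state_potentials = lapply(rec$state_potentials, as_fn),
                edge_barriers = lapply(rec$edge_barriers, as_fn))
}
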