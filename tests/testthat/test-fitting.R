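## Cost arithmetic, splits, Sobol starts, annealer unit behavior, the
## overfitting monitor, and classification.

test_that("SEM deadzone cost matches hand-computed cases", {
  dz <- markovchannel:::.deadzone_cost
  ## single point: mean 2, sem 0, prediction 3 -> ((3-2)/2)^2 = 0.25
  expect_equal(dz(3, 2, 0), 0.25)
  ## predictions inside the SEM tube cost nothing
  expect_equal(dz(c(1.05, 0.98), c(1, 1), c(0.06, 0.05)), 0)
  ## only the excess outside the SEM counts
  expect_equal(dz(1.2, 1, 0.1), (0.1 / 1)^2)
  ## zero means use the absolute residual
  expect_equal(dz(0.3, 0, 0.1), 0.2^2)
  ## censored predictions are excluded
  expect_equal(dz(c(NA, 3), c(2, 2), c(0, 0)), 0.25)
})

test_that("model_cost decomposes into data, stiffness, and constraint parts", {
  prot <- desk_protocols()
  ds <- generate_dataset(synthetic_spec("two_state", protocols = prot,
                                        noise_sd = 0, seed = 3))
  m <- ground_truth_model("two_state")
  cb <- model_cost(m, ds, prot)
  ## the generating model reproduces its own noiseless data exactly
  expect_equal(cb$data_cost, 0)
  expect_equal(cb$total, cb$data_cost + cb$stiffness_penalty + cb$max_open)
  expect_named(cb$per_curve, vapply(ds$curves, `[[`, character(1), "protocol"))
  ## a wrong model pays on every curve
  m_bad <- unpack_parameters(m$topology, rep(c(1, 1, 0, 30), 2))
  expect_gt(model_cost(m_bad, ds, prot)$data_cost, 1e-6)
})

test_that("train/validation splits are per-curve, disjoint, and reproducible", {
  prot <- desk_protocols()
  ds <- generate_dataset(synthetic_spec("four_state_chain", protocols = prot,
                                        noise_sd = 0.03, seed = 8))
  s1 <- split_dataset(ds, fraction = 0.2, seed = 99)
  s2 <- split_dataset(ds, fraction = 0.2, seed = 99)
  expect_identical(s1, s2)
  for (i in seq_along(ds$curves)) {
    n <- length(ds$curves[[i]]$x)
    expect_identical(sort(c(s1$train[[i]], s1$validation[[i]])), seq_len(n))
    expect_length(intersect(s1$train[[i]], s1$validation[[i]]), 0L)
    if (n >= 5) expect_gte(length(s1$validation[[i]]), 1L)
  }
  ## a 10-point curve yields an 8/2 split
  ds10 <- clamp_dataset(list(list(protocol = "ssa", x = 1:10,
                                  mean = rep(0.5, 10), sem = rep(0.01, 10))))
  s10 <- split_dataset(ds10, fraction = 0.2, seed = 1)
  expect_length(s10$train[[1]], 8L)
  expect_length(s10$validation[[1]], 2L)
})

test_that("Sobol starts stratify the unit cube and map bounds exactly", {
  ## endpoint mapping of the affine rule
  expect_equal(as.numeric(scale_to_bounds(0, -3, 7)), -3)
  expect_equal(as.numeric(scale_to_bounds(1, -3, 7)), 7)
  expect_equal(as.numeric(scale_to_bounds(0.5, 0, 10)), 5)
  ## first dimension is the base-2 van der Corput sequence: the first 2^k
  ## unshifted points are exactly the k-bit fractions
  u <- sobol_sequence(8, 3)
  expect_equal(sort(u[, 1]), (0:7) / 8)
  expect_equal(sort(u[, 2]), (0:7) / 8)
  expect_equal(sort(u[, 3]), (0:7) / 8)
  ## digital shift preserves stratification and is seed-reproducible
  s1 <- sobol_sequence(16, 5, seed = 4)
  s2 <- sobol_sequence(16, 5, seed = 4)
  expect_identical(s1, s2)
  for (j in 1:5) expect_equal(sort(floor(s1[, j] * 16)), 0:15)
  expect_false(identical(sobol_sequence(16, 5, seed = 5), s1))
  ## starts respect the parameter box
  b <- parameter_bounds(triangle3())
  st <- sobol_starts(b, 7, seed = 2)
  expect_identical(dim(st), c(7L, 20L))
  expect_true(all(sweep(st, 2, b$lower, ">=")))
  expect_true(all(sweep(st, 2, b$upper, "<=")))
})

test_that("adaptive temperature and the worse-solution counter follow the update rules", {
  cfg <- annealer_config(t_min = 0.1, lambda = 2)
  expect_equal(adaptive_temperature(0, cfg), 0.1)           # ln 1 = 0
  expect_equal(adaptive_temperature(exp(1) - 1, cfg), 2.1)  # t_min + lambda
  r <- seq(0, 50, by = 5)
  expect_false(is.unsorted(adaptive_temperature(r, cfg)))   # monotone in r
  expect_identical(update_counter(5L, +0.1), 6L)            # worse: increment
  expect_identical(update_counter(5L, 0), 5L)               # equal: hold
  expect_identical(update_counter(5L, -0.1), 0L)            # better: reset
})

test_that("the overfitting monitor stops on three consecutive ratio increases only", {
  cfg <- overfit_config(check_epoch = 1, strip = 2, consecutive = 3)
  feed <- function(vals) {
    mon <- new_overfit_monitor(cfg)
    stopped_at <- NA_integer_
    for (i in seq_along(vals)) {
      mon <- overfit_check(mon, train_cost = 1, val_cost = vals[i])
      if (mon$stop && is.na(stopped_at)) stopped_at <- i
    }
    list(mon = mon, stopped_at = stopped_at)
  }
  ## with flat training cost P = 0, so Q tracks GL = val / min(val) - 1;
  ## four rising validation costs give Q increases at checks 2..5
  r <- feed(c(1, 1.1, 1.2, 1.3, 1.4))
  expect_identical(r$stopped_at, 5L)
  ## oscillating validation cost never accumulates three increases
  r2 <- feed(c(1, 2, 1, 2, 1, 2, 1, 2))
  expect_true(is.na(r2$stopped_at))
  ## non-increasing validation cost never triggers
  r3 <- feed(c(3, 2.5, 2.5, 2, 1.5, 1.5, 1))
  expect_true(is.na(r3$stopped_at))
  ## too few checks: always continue
  r4 <- feed(c(5))
  expect_false(r4$mon$stop)
})

test_that("annealing respects budgets, monotone best cost, and determinism", {
  prot <- desk_protocols()
  ds <- generate_dataset(synthetic_spec("two_state", protocols = prot,
                                        noise_sd = 0, seed = 3))
  tp <- ground_truth_model("two_state")$topology
  b <- parameter_bounds(tp)
  start <- scale_to_bounds(rep(0.5, 8), b$lower, b$upper)[1, ]
  ## zero iterations return the start point and its cost
  ann0 <- annealer_config(max_iterations = 0, n_chains = 1)
  s0 <- anneal(tp, start, ds, prot, annealer = ann0, dt = 0.25, seed = 1)
  expect_identical(s0$params, start)
  expect_identical(s0$iterations, 0L)
  cb <- model_cost(unpack_parameters(tp, start), ds, prot, dt = 0.25)
  expect_equal(s0$train_cost, cb$total)
  ## short runs: the best-cost trace never increases; reruns are identical
  ann <- annealer_config(max_iterations = 400, n_chains = 2,
                         convergence_window = 400)
  ovf <- overfit_config(check_epoch = 50)
  split <- split_dataset(ds, seed = 2)
  sA <- anneal(tp, start, ds, prot, split = split, annealer = ann,
               overfit = ovf, dt = 0.25, seed = 7)
  sB <- anneal(tp, start, ds, prot, split = split, annealer = ann,
               overfit = ovf, dt = 0.25, seed = 7)
  expect_identical(sA$params, sB$params)
  expect_identical(sA$trace, sB$trace)
  expect_false(is.unsorted(rev(sA$trace$best_cost)))
  expect_lte(sA$train_cost, s0$train_cost)
  ## a different seed explores differently
  sC <- anneal(tp, start, ds, prot, split = split, annealer = ann,
               overfit = ovf, dt = 0.25, seed = 8)
  expect_false(identical(sC$params, sA$params))
})

test_that("multistart keeps the minimum and reports the per-start spread", {
  prot <- desk_protocols()
  ds <- generate_dataset(synthetic_spec("two_state", protocols = prot,
                                        noise_sd = 0, seed = 3))
  tp <- ground_truth_model("two_state")$topology
  ann <- annealer_config(max_iterations = 300, n_chains = 1,
                         convergence_window = 300)
  f <- multistart_fit(tp, ds, prot, n_starts = 3, annealer = ann,
                      dt = 0.25, seed = 5)
  costs <- vapply(f$solutions, `[[`, numeric(1), "train_cost")
  expect_length(costs, 3L)
  expect_equal(f$best$train_cost, min(costs))
  expect_gt(stats::sd(costs), 0)   # starts genuinely differ
})

test_that("the 300% rule classifies against the batch minimum", {
  fake <- function(cost) structure(list(topology = path3_end(),
                                        train_cost = cost, val_cost = cost,
                                        stiffness_penalty = 0, iterations = 0L,
                                        termination = "max_iter",
                                        label = NA_character_),
                                   class = "model_solution")
  lab <- classify_solutions(list(fake(1), fake(2.9), fake(3.5)))
  expect_identical(vapply(lab, `[[`, character(1), "label"),
                   c("acceptable", "acceptable", "unacceptable"))
  expect_identical(classify_solutions(list(fake(42)))[[1]]$label, "acceptable")
  lab_eq <- classify_solutions(list(fake(2), fake(2), fake(2)))
  expect_true(all(vapply(lab_eq, `[[`, character(1), "label") == "acceptable"))
})

test_that("diminishing-returns and solution tables summarise batches", {
  mk <- function(tp, cost, sp) structure(list(topology = tp, train_cost = cost,
                                              val_cost = cost,
                                              stiffness_penalty = sp,
                                              iterations = 10L,
                                              termination = "converged",
                                              label = NA_character_),
                                         class = "model_solution")
  sols <- list(mk(path3_end(), 10, 1), mk(path3_mid(), 12, 2),
               mk(triangle3(), 4, 0.5),
               mk(rooted_topology(4, rbind(c(1, 2), c(2, 3), c(3, 4))), 1, 0.1))
  tab <- diminishing_returns_table(sols)
  expect_identical(tab$complexity, c(4L, 5L, 6L))
  expect_equal(tab$min_cost, c(10, 4, 1))
  expect_equal(tab$n_solutions, c(2L, 1L, 1L))
  expect_identical(nrow(diminishing_returns_table(list())), 0L)
  st <- solution_table(sols)
  expect_identical(nrow(st), 4L)
  expect_true(all(c("root_degree", "complexity", "train_cost") %in% names(st)))
})
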