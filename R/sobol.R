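## Sobol quasi-random sequences.
##
## Digital (base-2) Sobol construction: per dimension a primitive polynomial
## over GF(2) defines the direction-number recurrence
##   m_k = 2 a_1 m_{k-1} (+) 4 a_2 m_{k-2} (+) ... (+) 2^d m_{k-d} (+) m_{k-d}
## ((+) = XOR).  Primitive polynomials are generated programmatically (tested
## for irreducibility and full multiplicative order) and the free initial
## values are set to 1 (odd, < 2^k, hence valid).  Points are generated in
## Gray-code order; an optional seed applies an Owen-style random digital
## shift (per-dimension XOR mask), which preserves the base-2 net structure
## while decorrelating dimensions across seeds.

.SOBOL_BITS <- 30L

## polynomial arithmetic over GF(2); polynomials as integer bitmasks
.gf2_mulmod <- function(a, b, p, d) {
  r <- 0L
  while (b > 0L) {
    if (bitwAnd(b, 1L) == 1L) r <- bitwXor(r, a)
    b <- bitwShiftR(b, 1L)
    a <- bitwShiftL(a, 1L)
    if (bitwAnd(a, bitwShiftL(1L, d)) != 0L) a <- bitwXor(a, p)
  }
  r
}

.gf2_powmod <- function(a, e, p, d) {
  r <- 1L
  while (e > 0) {
    if (e %% 2 == 1) r <- .gf2_mulmod(r, a, p, d)
    a <- .gf2_mulmod(a, a, p, d)
    e <- e %/% 2
  }
  r
}

.is_primitive_poly <- function(p, d) {
  if (bitwAnd(p, 1L) == 0L) return(FALSE)      # x | p  => reducible
  n <- 2L^d - 1L
  if (.gf2_powmod(2L, n, p, d) != 1L) return(FALSE)
  ## order of x must be exactly 2^d - 1: no proper divisor order
  for (q in unique(.prime_factors(n)))
    if (.gf2_powmod(2L, n %/% q, p, d) == 1L) return(FALSE)
  TRUE
}

.prime_factors <- function(n) {
  f <- integer(0)
  q <- 2L
  while (q * q <= n) {
    while (n %% q == 0L) { f <- c(f, q); n <- n %/% q }
    q <- q + 1L
  }
  if (n > 1L) f <- c(f, n)
  f
}

## first `count` primitive polynomials by increasing degree (bitmask includes
## leading term); cached per session
.sobol_env <- new.env(parent = emptyenv())

.primitive_polys <- function(count) {
  cached <- .sobol_env$polys
  if (!is.null(cached) && length(cached$deg) >= count)
    return(list(poly = cached$poly[seq_len(count)],
                deg = cached$deg[seq_len(count)]))
  poly <- integer(0); deg <- integer(0)
  d <- 1L
  while (length(poly) < count) {
    for (mid in 0:(2L^(d - 1L) - 1L)) {
      p <- bitwOr(bitwOr(bitwShiftL(1L, d), bitwShiftL(mid, 1L)), 1L)
      if (.is_primitive_poly(p, d)) {
        poly <- c(poly, p); deg <- c(deg, d)
        if (length(poly) >= count) break
      }
    }
    d <- d + 1L
  }
  .sobol_env$polys <- list(poly = poly, deg = deg)
  list(poly = poly, deg = deg)
}

## direction numbers v_k (scaled to .SOBOL_BITS bits) for one dimension
.direction_numbers <- function(poly, d) {
  bits <- .SOBOL_BITS
  m <- integer(bits)
  if (d == 0L) {                      # first dimension: van der Corput
    return(bitwShiftL(1L, bits - seq_len(bits)))
  }
  m[seq_len(d)] <- 1L
  a <- bitwAnd(bitwShiftR(poly, 1L), 2L^d - 1L)  # coefficients a_1..a_{d-1}, a_d
  if (bits > d) {
    for (k in (d + 1L):bits) {
      val <- bitwXor(m[k - d], bitwShiftL(m[k - d], d))
      for (j in seq_len(d - 1L)) {
        if (d > 1L && bitwAnd(bitwShiftR(a, d - 1L - j), 1L) == 1L)
          val <- bitwXor(val, bitwShiftL(m[k - j], j))
      }
      m[k] <- val
    }
  }
  bitwShiftL(m, bits - seq_len(bits))
}

#' Sobol low-discrepancy sequence
#'
#' Generates `n` points of a `d`-dimensional base-2 digital Sobol sequence in
#' `[0, 1)`.  With the default `seed = NULL` the raw sequence is returned
#' (first point at the origin); an integer seed applies a reproducible random
#' digital shift to every dimension.
#'
#' @param n Number of points.
#' @param d Dimension.
#' @param seed Optional integer seed for the digital shift.
#' @return An `n x d` matrix of values in `[0, 1)`.
#' @export
sobol_sequence <- function(n, d, seed = NULL) {
  stopifnot(n >= 1, d >= 1)
  pp <- .primitive_polys(max(d - 1L, 1L))
  V <- matrix(0L, .SOBOL_BITS, d)
  V[, 1L] <- .direction_numbers(0L, 0L)
  if (d >= 2L) for (j in 2:d)
    V[, j] <- .direction_numbers(pp$poly[j - 1L], pp$deg[j - 1L])
  shift <- rep(0L, d)
  if (!is.null(seed)) {
    rs <- .unif_ints(d, seed)
    shift <- rs
  }
  X <- matrix(0, n, d)
  state <- rep(0L, d)
  X[1L, ] <- bitwXor(state, shift) / 2^.SOBOL_BITS
  if (n >= 2L) for (i in 2:n) {
    c <- .ctz(i - 1L) + 1L     # Gray-code bit position
    state <- bitwXor(state, V[c, ])
    X[i, ] <- bitwXor(state, shift) / 2^.SOBOL_BITS
  }
  X
}

.ctz <- function(x) {
  k <- 0L
  while (bitwAnd(x, 1L) == 0L) { x <- bitwShiftR(x, 1L); k <- k + 1L }
  k
}

## d random .SOBOL_BITS-bit integers from an isolated RNG stream
.unif_ints <- function(d, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  as.integer(floor(stats::runif(d) * 2^.SOBOL_BITS))
}

#' Map unit-cube points to parameter ranges
#'
#' Affine map `param_i = (max_i - min_i) * u_i + min_i` applied
#' coordinate-wise, so `u = 0` gives the lower bound, `u = 1` the upper.
#'
#' @param u Matrix (or vector) of unit-cube coordinates.
#' @param lower,upper Bound vectors, one entry per coordinate.
#' @return Matrix of mapped parameter vectors (rows = points).
#' @export
scale_to_bounds <- function(u, lower, upper) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1L)
  stopifnot(ncol(u) == length(lower), length(lower) == length(upper))
  sweep(sweep(u, 2L, upper - lower, "*"), 2L, lower, "+")
}

#' Quasi-random multistart parameter vectors
#'
#' Sobol points mapped into the box defined by the parameter bounds; used to
#' spread annealing starts over the search space.
#'
#' @param bounds A list with `lower` and `upper` (see [parameter_bounds()]).
#' @param n_starts Number of starting vectors (20 or more in practice).
#' @param seed Optional seed for the digital shift.
#' @return An `n_starts x length(lower)` matrix.
#' @export
sobol_starts <- function(bounds, n_starts, seed = NULL) {
  stopifnot(n_starts >= 1)
  u <- sobol_sequence(n_starts, length(bounds$lower), seed = seed)
  scale_to_bounds(u, bounds$lower, bounds$upper)
}
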