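#' Rooted channel topology
#'
#' A rooted topology is a connected, simple, undirected graph whose vertices
#' are channel conformations (states) and whose distinguished root vertex is
#' the conducting (open) state.  Two topologies are considered the same model
#' structure when a graph isomorphism exists that maps root to root; the
#' `canonical_key` field is identical exactly for such pairs.
#'
#' @param n_states Number of states (positive integer).
#' @param edges Two-column integer matrix of undirected state pairs
#'   (1-based indices), or an even-length vector taken pairwise.  No
#'   self-loops or duplicate edges; the graph must be connected.
#' @param root Index of the open state (default 1).
#' @return An object of class `rooted_topology` with fields `n_states`,
#'   `edges` (sorted two-column matrix), `root`, and `canonical_key`.
#' @examples
#' path3 <- rooted_topology(3, rbind(c(1, 2), c(2, 3)))
#' complexity(path3)   # 4 free rate functions
#' @export
rooted_topology <- function(n_states, edges, root = 1L) {
  n_states <- as.integer(n_states)
  stopifnot(n_states >= 1L)
  edges <- .as_edge_matrix(edges)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n_states))
      stop("edge endpoint outside 1..n_states")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  }
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  o <- order(lo, hi)
  edges <- cbind(lo, hi, deparse.level = 0)[o, , drop = FALSE]
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L]))) stop("duplicate edges")
  root <- as.integer(root)
  if (root < 1L || root > n_states) stop("root is not a valid state index")
  if (!.is_connected(n_states, edges)) stop("topology must be connected")
  x <- list(n_states = n_states, edges = edges, root = root,
            canonical_key = .rooted_canonical_key(n_states, edges, root))
  class(x) <- "rooted_topology"
  x
}

#' @export
print.rooted_topology <- function(x, ...) {
  cat(sprintf("rooted_topology: %d states, %d edges, root = %d (open), K = %d\n",
              x$n_states, nrow(x$edges), x$root, complexity(x)))
  if (nrow(x$edges))
    cat("  edges:", paste(x$edges[, 1], x$edges[, 2], sep = "-", collapse = " "), "\n")
  invisible(x)
}

#' Canonical key of a rooted topology
#'
#' The key is invariant under any relabeling of the non-root states and
#' distinguishes the root: it is derived from a canonical labeling of the
#' graph 2-colored as root versus non-root.  Keys of two topologies are
#' equal if and only if the topologies are root-preservingly isomorphic.
#'
#' @param topology A [rooted_topology()].
#' @return A character scalar.
#' @export
canonical_key <- function(topology) {
  stopifnot(inherits(topology, "rooted_topology"))
  topology$canonical_key
}

#' Number of free voltage-dependent rate functions
#'
#' The reversibility-preserving parameterization assigns one free function to
#' each non-root state and one to each edge, giving `K = N + E - 1`
#' independent rate functions.  This is the complexity score used to order
#' catalogs.
#'
#' @param topology A [rooted_topology()].
#' @return Integer `K`.
#' @export
complexity <- function(topology) {
  stopifnot(inherits(topology, "rooted_topology"))
  topology$n_states + nrow(topology$edges) - 1L
}

#' Degree of the open (root) state
#'
#' @param topology A [rooted_topology()].
#' @return Integer number of edges incident on the root.
#' @export
root_degree <- function(topology) {
  stopifnot(inherits(topology, "rooted_topology"))
  if (nrow(topology$edges) == 0L) return(0L)
  sum(topology$edges == topology$root)
}

## ---- internal graph machinery ------------------------------------------

.as_edge_matrix <- function(edges) {
  if (is.null(edges) || length(edges) == 0L)
    return(matrix(integer(0), 0L, 2L))
  if (!is.matrix(edges)) edges <- matrix(as.integer(edges), ncol = 2L, byrow = TRUE)
  storage.mode(edges) <- "integer"
  edges
}

.is_connected <- function(n, edges) {
  if (n == 1L) return(TRUE)
  if (nrow(edges) < n - 1L) return(FALSE)
  adj <- .adj_list(n, edges)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  all(seen)
}

.adj_list <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(v) if (is.null(v)) integer(0) else sort(v))
}

## canonical labeling (BLISS via igraph); colors: 2-coloring root vs rest
.canon <- function(n, edges, colors = NULL) {
  g <- igraph::make_graph(t(edges), n = n, directed = FALSE)
  lab <- igraph::canonical_permutation(g, colors = colors)$labeling
  if (nrow(edges)) {
    a <- lab[edges[, 1L]]; b <- lab[edges[, 2L]]
    lo <- pmin(a, b); hi <- pmax(a, b)
    o <- order(lo, hi)
    edges <- cbind(lo[o], hi[o])
  }
  list(edges = edges, lab = lab)
}

.edge_string <- function(edges) {
  if (nrow(edges) == 0L) return("")
  paste(edges[, 1L], edges[, 2L], sep = "-", collapse = ",")
}

.shape_key <- function(n, edges) {
  cn <- .canon(n, edges)
  paste0(n, "|", .edge_string(cn$edges))
}

.rooted_canonical_key <- function(n, edges, root) {
  colors <- rep(1L, n); colors[root] <- 2L
  cn <- .canon(n, edges, colors = colors)
  paste0(n, "|r", cn$lab[root], "|", .edge_string(cn$edges))
}

## canonical representative with the root relabeled to state 1
.rooted_representative <- function(n, edges, root) {
  colors <- rep(1L, n); colors[root] <- 2L
  cn <- .canon(n, edges, colors = colors)
  rpos <- cn$lab[root]
  e <- cn$edges
  if (rpos != 1L && nrow(e)) {
    swap <- function(v) ifelse(v == rpos, 1L, ifelse(v == 1L, rpos, v))
    a <- swap(e[, 1L]); b <- swap(e[, 2L])
    lo <- pmin(a, b); hi <- pmax(a, b)
    e <- cbind(lo, hi, deparse.level = 0)[order(lo, hi), , drop = FALSE]
  }
  list(edges = e, key = paste0(n, "|r", rpos, "|", .edge_string(cn$edges)))
}

## ---- shape enumeration --------------------------------------------------

## Grow connected unlabeled shapes from size k-1 to k by attaching a new
## vertex to every eligible non-empty neighbour subset; dedup canonically.
## Complete because every connected graph has a non-cut vertex whose removal
## leaves a smaller connected graph obeying the same degree cap.
.grow_shapes <- function(prev, k, max_degree = Inf) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", 0L)
  for (E in prev) {
    deg <- tabulate(E, nbins = k - 1L)
    elig <- which(deg < max_degree)
    if (!length(elig)) next
    maxpick <- min(length(elig), max_degree)
    for (sz in seq_len(maxpick)) {
      subs <- utils::combn(elig, sz)
      for (ci in seq_len(ncol(subs))) {
        E2 <- rbind(E, cbind(subs[, ci], k))
        key <- .shape_key(k, E2)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out[[length(out) + 1L]] <- .canon(k, E2)$edges
        }
      }
    }
  }
  out
}

.enum_shapes <- function(n, max_degree = Inf) {
  shapes <- vector("list", n)
  shapes[[1L]] <- list(matrix(integer(0), 0L, 2L))
  if (n >= 2L)
    for (k in 2:n) shapes[[k]] <- .grow_shapes(shapes[[k - 1L]], k, max_degree)
  shapes
}

## ---- cycle filters ------------------------------------------------------

## all simple cycles of length <= maxlen, as vertex vectors
.short_cycles <- function(n, edges, maxlen) {
  adjmat <- matrix(FALSE, n, n)
  adjmat[edges] <- TRUE
  adjmat[edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  res <- list()
  path <- integer(maxlen)
  dfs <- function(start, v, depth) {
    for (w in which(adjmat[v, ])) {
      if (w == start && depth >= 3L) {
        if (path[2L] < path[depth]) res[[length(res) + 1L]] <<- path[seq_len(depth)]
      } else if (w > start && depth < maxlen && !(w %in% path[seq_len(depth)])) {
        path[depth + 1L] <<- w
        dfs(start, w, depth + 1L)
      }
    }
  }
  for (s in seq_len(n)) {
    path[1L] <- s
    dfs(s, s, 1L)
  }
  res
}

.cycle_edge_mask <- function(cycle, eid) {
  m <- 0L
  k <- length(cycle)
  for (i in seq_len(k)) {
    a <- cycle[i]; b <- cycle[if (i == k) 1L else i + 1L]
    m <- bitwOr(m, bitwShiftL(1L, eid[a, b] - 1L))
  }
  m
}

## TRUE iff cycles of length <= maxlen span the cycle space over GF(2),
## i.e. a minimum cycle basis has all member lengths <= maxlen.
.cycle_pass_minimum <- function(n, edges, maxlen) {
  m <- nrow(edges) - n + 1L
  if (m <= 0L) return(TRUE)
  if (nrow(edges) > 30L) stop("edge bitmask overflow (more than 30 edges)")
  cycles <- .short_cycles(n, edges, maxlen)
  if (length(cycles) < m) return(FALSE)
  eid <- matrix(0L, n, n)
  for (i in seq_len(nrow(edges))) {
    eid[edges[i, 1L], edges[i, 2L]] <- i
    eid[edges[i, 2L], edges[i, 1L]] <- i
  }
  basis <- integer(0)
  lead <- integer(0)
  for (cy in cycles) {
    w <- .cycle_edge_mask(cy, eid)
    repeat {
      if (w == 0L) break
      hb <- as.integer(floor(log2(w)))
      j <- match(hb, lead)
      if (is.na(j)) { basis <- c(basis, w); lead <- c(lead, hb); break }
      w <- bitwXor(w, basis[j])
    }
    if (length(basis) >= m) return(TRUE)
  }
  FALSE
}

## Paton fundamental cycle basis (depth-first, stack discipline, neighbours
## visited in ascending order, traversal rooted at the open state).  This is
## the traversal-dependent basis construction used by common graph libraries;
## it is provided so that catalog counts under that convention can be
## reproduced deterministically, but it is NOT a graph invariant.
.paton_basis <- function(n, edges) {
  adj <- .adj_list(n, edges)
  cycles <- list()
  pred <- rep(NA_integer_, n)
  used <- vector("list", n)
  visited <- logical(n)
  root <- 1L
  pred[root] <- root
  used[[root]] <- integer(0)
  visited[root] <- TRUE
  stack <- root
  while (length(stack)) {
    z <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (nbr in adj[[z]]) {
      if (!visited[nbr]) {
        visited[nbr] <- TRUE
        pred[nbr] <- z
        used[[nbr]] <- z
        stack <- c(stack, nbr)
      } else if (!(nbr %in% used[[z]])) {
        pn <- used[[nbr]]
        cycle <- c(nbr, z)
        p <- pred[z]
        while (!(p %in% pn)) {
          cycle <- c(cycle, p)
          p <- pred[p]
        }
        cycle <- c(cycle, p)
        cycles[[length(cycles) + 1L]] <- cycle
        used[[nbr]] <- c(used[[nbr]], z)
      }
    }
  }
  cycles
}

.cycle_pass_fundamental <- function(n, edges, maxlen) {
  if (nrow(edges) - n + 1L <= 0L) return(TRUE)
  all(lengths(.paton_basis(n, edges)) <= maxlen)
}

.cycle_pass <- function(n, edges, maxlen, basis = c("minimum", "fundamental")) {
  basis <- match.arg(basis)
  if (basis == "minimum") .cycle_pass_minimum(n, edges, maxlen)
  else .cycle_pass_fundamental(n, edges, maxlen)
}

## ---- filters on topology lists -----------------------------------------

#' Filter topologies by maximum state degree
#'
#' Retains topologies in which no state has more than `max_degree` incident
#' edges; a high-degree state would imply one channel conformation with
#' direct access to many adjacent conformations.
#'
#' @param topologies List of [rooted_topology()] objects.
#' @param max_degree Maximum allowed vertex degree.
#' @return Filtered list.
#' @export
filter_degree <- function(topologies, max_degree = 4L) {
  keep <- vapply(topologies, function(tp) {
    d <- tabulate(tp$edges, nbins = tp$n_states)
    all(d <= max_degree)
  }, logical(1))
  topologies[keep]
}

#' Filter topologies by cycle length
#'
#' Retains topologies admitting a cycle basis whose member cycles all have
#' length at most `max_cycle_length`; long cycles represent implausible
#' long-range shortcuts between distant channel conformations.  Trees always
#' pass.  The default `basis = "minimum"` uses the graph-invariant criterion
#' that cycles of length `<= max_cycle_length` span the cycle space
#' (equivalently, a minimum cycle basis is all-short).  `basis =
#' "fundamental"` instead tests the particular depth-first fundamental basis
#' (Paton construction, ascending neighbours, rooted at the open state) that
#' traversal-based graph libraries return; it is deterministic here but not a
#' graph invariant, and is provided to reproduce catalog counts produced by
#' that convention.
#'
#' @param topologies List of [rooted_topology()] objects.
#' @param max_cycle_length Maximum allowed basis-cycle length (`>= 3`).
#' @param basis `"minimum"` (default) or `"fundamental"`.
#' @return Filtered list.
#' @export
filter_cycle <- function(topologies, max_cycle_length = 4L,
                         basis = c("minimum", "fundamental")) {
  basis <- match.arg(basis)
  keep <- vapply(topologies, function(tp)
    .cycle_pass(tp$n_states, tp$edges, max_cycle_length, basis), logical(1))
  topologies[keep]
}

## ---- enumeration --------------------------------------------------------

#' Enumerate all unique rooted topologies
#'
#' Generates exactly one representative per root-preserving isomorphism
#' class of connected graphs on `n_states` vertices, by iterative vertex
#' extension with canonical-form deduplication, then places the root at each
#' vertex orbit.  With `apply_filters = TRUE` the biophysical restrictions
#' are applied: the degree cap is enforced during generation and the cycle
#' filter afterwards.  Representatives are relabeled so that the root (open
#' state) is state 1, and the catalog is ordered by non-decreasing
#' complexity `K = N + E - 1`.
#'
#' @param n_states Number of states (`1..cap`; the default cap of 8 marks the
#'   workstation-scale range — 9-10 states produce catalogs in the millions
#'   and need cluster resources).
#' @param max_degree Maximum state degree (default 4).
#' @param max_cycle_length Maximum basis-cycle length (default 4).
#' @param apply_filters Apply the degree and cycle restrictions (default TRUE).
#' @param basis Cycle-filter semantics, see [filter_cycle()].
#' @param cap Refuse `n_states` above this (default 8).
#' @return A `topology_catalog`: list with `entries` (list of
#'   [rooted_topology()]) and `config`.
#' @examples
#' cat3 <- enumerate_topologies(3, apply_filters = FALSE)
#' length(cat3$entries)  # 3 unique rooted topologies on three states
#' @export
enumerate_topologies <- function(n_states, max_degree = 4L, max_cycle_length = 4L,
                                 apply_filters = TRUE,
                                 basis = c("minimum", "fundamental"),
                                 cap = 8L) {
  basis <- match.arg(basis)
  n_states <- as.integer(n_states)
  if (n_states < 1L) stop("n_states must be >= 1")
  if (n_states > cap)
    stop(sprintf(paste0("n_states = %d exceeds the workstation-scale cap of %d; ",
                        "9-10 state catalogs number in the millions and call for ",
                        "cluster resources. Raise `cap` explicitly to override."),
                 n_states, cap))
  degcap <- if (apply_filters) max_degree else Inf
  shapes <- .enum_shapes(n_states, max_degree = degcap)[[n_states]]
  if (apply_filters && basis == "minimum") {
    ## invariant filter is root-independent: prune at shape level
    keep <- vapply(shapes, function(E)
      .cycle_pass_minimum(n_states, E, max_cycle_length), logical(1))
    shapes <- shapes[keep]
  }
  entries <- list()
  for (E in shapes) {
    seen <- character(0)
    for (r in seq_len(n_states)) {
      rep <- .rooted_representative(n_states, E, r)
      if (rep$key %in% seen) next
      seen <- c(seen, rep$key)
      if (apply_filters && basis == "fundamental" &&
          !.cycle_pass_fundamental(n_states, rep$edges, max_cycle_length)) next
      tp <- list(n_states = n_states, edges = rep$edges, root = 1L,
                 canonical_key = rep$key)
      class(tp) <- "rooted_topology"
      entries[[length(entries) + 1L]] <- tp
    }
  }
  kk <- vapply(entries, complexity, integer(1))
  keys <- vapply(entries, canonical_key, character(1))
  entries <- entries[order(kk, keys)]
  structure(list(entries = entries,
                 config = list(n_states = n_states, max_degree = max_degree,
                               max_cycle_length = max_cycle_length,
                               apply_filters = apply_filters, basis = basis)),
            class = "topology_catalog")
}

#' @export
print.topology_catalog <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("topology_catalog: %d unique rooted topologies on %d states\n",
              length(x$entries), cfg$n_states))
  cat(sprintf("  filters %s (max degree %s, max cycle length %s, %s basis)\n",
              if (cfg$apply_filters) "applied" else "off",
              cfg$max_degree, cfg$max_cycle_length, cfg$basis))
  invisible(x)
}

#' Rooted-permutation accounting for a state count
#'
#' Counts the raw search space behind the unique catalog: the number of
#' unlabeled connected shapes, the rooted placements before isomorphism
#' deduplication (every vertex slot of every shape treated as distinct,
#' i.e. `n_states * shapes`), and the fully labeled permutations
#' (`rooted_pre_dedup * n_states!`).
#'
#' @param n_states Number of states.
#' @return A list with integer fields `shapes`, `rooted_pre_dedup`,
#'   `permutations`.
#' @examples
#' count_rooted_permutations(3)  # 2 shapes, 6 rooted, 36 permutations
#' @export
count_rooted_permutations <- function(n_states) {
  n_states <- as.integer(n_states)
  stopifnot(n_states >= 1L)
  shapes <- length(.enum_shapes(n_states)[[n_states]])
  rooted <- n_states * shapes
  list(shapes = shapes,
       rooted_pre_dedup = rooted,
       permutations = rooted * factorial(n_states))
}

#' Summarise a catalog by structural features
#'
#' @param catalog A `topology_catalog` or plain list of topologies.
#' @return A data frame of counts by `(n_states, n_edges, root_degree,
#'   complexity)`; counts partition the catalog.
#' @export
catalog_summary <- function(catalog) {
  entries <- if (inherits(catalog, "topology_catalog")) catalog$entries else catalog
  if (!length(entries))
    return(data.frame(n_states = integer(0), n_edges = integer(0),
                      root_degree = integer(0), complexity = integer(0),
                      count = integer(0)))
  df <- data.frame(
    n_states = vapply(entries, function(tp) tp$n_states, integer(1)),
    n_edges = vapply(entries, function(tp) nrow(tp$edges), integer(1)),
    root_degree = vapply(entries, root_degree, integer(1)),
    complexity = vapply(entries, complexity, integer(1)))
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))), by = df, FUN = sum)
  agg[order(agg$n_states, agg$n_edges, agg$root_degree), , drop = FALSE]
}

## ---- catalog I/O (JSON lines, 0-based edges, root = 0) ------------------

#' Write a topology catalog as JSON lines
#'
#' One topology per line with 0-based edges and root 0, plus the complexity
#' and root degree, so catalogs stream through standard line-oriented tools.
#'
#' @param catalog A `topology_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  entries <- if (inherits(catalog, "topology_catalog")) catalog$entries else catalog
  con <- file(path, "w")
  on.exit(close(con))
  for (tp in entries) {
    rec <- list(n_states = tp$n_states,
                edges = unname(apply(tp$edges, 1L, function(e) e - 1L,
                                     simplify = FALSE)),
                root = tp$root - 1L,
                complexity = complexity(tp),
                root_degree = root_degree(tp),
                key = tp$canonical_key)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a JSON-lines topology catalog
#'
#' @param path File written by [write_catalog()].
#' @return A `topology_catalog`.
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  entries <- lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    edges <- if (length(rec$edges)) {
      e <- rec$edges
      if (is.list(e)) e <- do.call(rbind, e)
      matrix(as.integer(e), ncol = 2L) + 1L
    } else matrix(integer(0), 0L, 2L)
    rooted_topology(rec$n_states, edges, root = rec$root + 1L)
  })
  structure(list(entries = entries, config = list(source = path)),
            class = "topology_catalog")
}
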