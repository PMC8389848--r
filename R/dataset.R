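#' Voltage-clamp summary dataset
#'
#' A set of protocol-tagged summary curves, each a list of points
#' `(x, mean, sem)` — the form in which voltage-clamp data are usually
#' published (normalized means with standard errors).
#'
#' @param curves List of curves; each curve is a list with fields
#'   `protocol` (name matching a `protocol_spec`), `x` (strictly increasing),
#'   `mean`, and `sem` (`>= 0`, same length as `x`).
#' @param metadata Optional named list (units, provenance, generator
#'   settings) carried through file round trips.
#' @return An object of class `clamp_dataset`.
#' @export
clamp_dataset <- function(curves, metadata = list()) {
  if (!length(curves)) stop("dataset must contain at least one curve")
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    if (is.null(cv$protocol) || !nzchar(cv$protocol))
      stop(sprintf("curve %d: missing protocol name", i))
    if (!length(cv$x)) stop(sprintf("curve %d (%s): empty curve", i, cv$protocol))
    if (length(cv$x) != length(cv$mean) || length(cv$x) != length(cv$sem))
      stop(sprintf("curve %d (%s): x, mean, sem lengths differ", i, cv$protocol))
    if (is.unsorted(cv$x, strictly = TRUE))
      stop(sprintf("curve %d (%s): x must be strictly increasing", i, cv$protocol))
    if (any(cv$sem < 0))
      stop(sprintf("curve %d (%s): negative sem", i, cv$protocol))
  }
  structure(list(curves = curves, metadata = metadata), class = "clamp_dataset")
}

#' @export
print.clamp_dataset <- function(x, ...) {
  cat(sprintf("clamp_dataset: %d curves, %d points\n", length(x$curves),
              sum(vapply(x$curves, function(cv) length(cv$x), integer(1)))))
  for (cv in x$curves)
    cat(sprintf("  %-12s %d points, x in [%g, %g]\n", cv$protocol,
                length(cv$x), min(cv$x), max(cv$x)))
  invisible(x)
}

#' @export
as.data.frame.clamp_dataset <- function(x, ...) {
  do.call(rbind, lapply(x$curves, function(cv)
    data.frame(protocol = cv$protocol, x = cv$x, mean = cv$mean, sem = cv$sem)))
}

#' Write a clamp dataset to CSV
#'
#' Plain CSV with columns `protocol, x, mean, sem`, preceded by one
#' `#`-prefixed JSON metadata line; the file round-trips losslessly through
#' [read_dataset()].
#'
#' @param dataset A [clamp_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "clamp_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- dataset$metadata
  if (is.null(meta)) meta <- list()
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)), con)
  writeLines("protocol,x,mean,sem", con)
  for (cv in dataset$curves)
    writeLines(sprintf("%s,%.17g,%.17g,%.17g", cv$protocol,
                       cv$x, cv$mean, cv$sem), con)
  invisible(path)
}

#' Read a clamp dataset from CSV
#'
#' @param path File written by [write_dataset()] (or any CSV with columns
#'   `protocol, x, mean, sem` and an optional `#` JSON metadata header).
#' @return A [clamp_dataset()].
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty dataset file: ", path)
  meta <- list()
  skip <- 0L
  while (skip < length(lines) && startsWith(lines[skip + 1L], "#")) {
    meta_line <- sub("^#\\s*", "", lines[skip + 1L])
    meta <- tryCatch(jsonlite::fromJSON(meta_line, simplifyVector = TRUE),
                     error = function(e)
                       stop(sprintf("line %d: malformed metadata header", skip + 1L)))
    skip <- skip + 1L
  }
  header <- strsplit(lines[skip + 1L], ",", fixed = TRUE)[[1L]]
  need <- c("protocol", "x", "mean", "sem")
  if (!identical(trimws(header), need))
    stop(sprintf("line %d: expected header 'protocol,x,mean,sem', got '%s'",
                 skip + 1L, lines[skip + 1L]))
  body <- lines[-seq_len(skip + 1L)]
  body_lineno <- (skip + 1L) + seq_along(body)
  body_keep <- nzchar(trimws(body))
  body <- body[body_keep]; body_lineno <- body_lineno[body_keep]
  if (!length(body)) stop("dataset file contains no data rows: ", path)
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop(sprintf("line %d: expected 4 comma-separated fields", body_lineno[bad[1L]]))
  proto <- vapply(parts, `[[`, character(1), 1L)
  num <- function(k, what) {
    v <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), k)))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("line %d: non-numeric %s", body_lineno[bad[1L]], what))
    v
  }
  x <- num(2L, "x"); mn <- num(3L, "mean"); sem <- num(4L, "sem")
  curves <- lapply(unique(proto), function(p) {
    sel <- proto == p
    list(protocol = p, x = x[sel], mean = mn[sel], sem = sem[sel])
  })
  clamp_dataset(curves, metadata = as.list(meta))
}
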