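#' Parameter-grid specification
#'
#' A grid is the Cartesian product of per-parameter value lists, minus
#' the rows matched by an optional exclusion predicate.  Enumeration is
#' deterministic: rows are produced in row-major (odometer) order with
#' the first parameter varying slowest and the last varying fastest;
#' case ids are assigned sequentially from 0 over the included rows.
#'
#' @param values named list of non-empty numeric vectors, one per
#'   parameter, in the documented order.
#' @param exclude optional predicate: a function taking a data frame of
#'   candidate rows and returning a logical vector (`TRUE` = drop).
#'
#' @return An object of class `gridSpec`.
#' @export
gridSpec <- function(values, exclude = NULL) {
  stopifnot(is.list(values), length(values) >= 1)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("grid parameters must be named", call. = FALSE)
  if (any(vapply(values, length, 0L) == 0L))
    stop("every parameter needs at least one admissible value", call. = FALSE)
  if (!is.null(exclude) && !is.function(exclude))
    stop("exclude must be a function or NULL", call. = FALSE)
  structure(list(values = values, exclude = exclude), class = "gridSpec")
}

# decode 0-based row indices of the full product into a data frame
gridRows <- function(grid, idx0) {
  lens <- vapply(grid$values, length, 0L)
  k <- length(lens)
  stride <- rev(cumprod(rev(c(lens[-1], 1))))
  out <- vector("list", k)
  for (j in seq_len(k))
    out[[j]] <- grid$values[[j]][(idx0 %/% stride[j]) %% lens[j] + 1]
  names(out) <- names(grid$values)
  as.data.frame(out)
}

#' Count the cases of a grid
#'
#' Exact cardinality of the Cartesian product minus exclusions, without
#' materializing the full grid: the product is streamed in chunks and
#' the exclusion predicate applied vectorized per chunk.
#'
#' @param grid a [gridSpec()].
#' @param chunk_size rows per streamed chunk.
#' @return Number of included cases (double, exact for < 2^53).
#' @export
countGrid <- function(grid, chunk_size = 2^20) {
  stopifnot(inherits(grid, "gridSpec"))
  total <- prod(vapply(grid$values, length, 0L))
  if (is.null(grid$exclude)) return(total)
  n <- 0
  at <- 0
  while (at < total) {
    take <- min(chunk_size, total - at)
    rows <- gridRows(grid, at + seq_len(take) - 1)
    drop <- grid$exclude(rows)
    if (length(drop) != take || !is.logical(drop))
      stop("exclusion predicate must return one logical per row", call. = FALSE)
    n <- n + sum(!drop)
    at <- at + take
  }
  n
}

#' Enumerate the cases of a grid
#'
#' @param grid a [gridSpec()].
#' @param max_cases safety cap on the number of returned rows.
#' @return A data frame with a 0-based `case_id` column followed by one
#'   column per parameter, in deterministic enumeration order.
#' @export
enumerateGrid <- function(grid, max_cases = 1e6) {
  stopifnot(inherits(grid, "gridSpec"))
  total <- prod(vapply(grid$values, length, 0L))
  if (total > max_cases)
    stop("grid has ", total, " raw cases; raise max_cases to enumerate",
         call. = FALSE)
  rows <- gridRows(grid, seq_len(total) - 1)
  if (!is.null(grid$exclude)) rows <- rows[!grid$exclude(rows), , drop = FALSE]
  rownames(rows) <- NULL
  cbind(case_id = seq_len(nrow(rows)) - 1L, rows)
}

#' The database screening grids
#'
#' The brute-force screening grid over eight key parameters: the leak
#' reversal potential (five values) and seven maximal conductances
#' (leak, the two synaptic currents, and four membrane currents), each
#' at eight fractions of its canonical value.  The coupled-pair grid
#' excludes cases with both synaptic conductances absent; the
#' isolated-neuron grid fixes both synaptic conductances at zero.
#'
#' @param type `"hco"` (coupled pair, 10,321,920 cases) or
#'   `"isolated"` (163,840 cases).
#' @return A [gridSpec()].
#' @export
databaseGrid <- function(type = c("hco", "isolated")) {
  type <- match.arg(type)
  scales <- c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75)
  e_leak <- c(-70, -65, -60, -55, -50)
  if (type == "hco") {
    gridSpec(values = list(E_leak = e_leak, g_leak = scales,
                           g_SynS = scales, g_SynG = scales,
                           g_P = scales, g_CaS = scales,
                           g_h = scales, g_K2 = scales),
             exclude = function(df) df$g_SynS == 0 & df$g_SynG == 0)
  } else {
    gridSpec(values = list(E_leak = e_leak, g_leak = scales,
                           g_P = scales, g_CaS = scales,
                           g_h = scales, g_K2 = scales))
  }
}

#' @export
print.gridSpec <- function(x, ...) {
  lens <- vapply(x$values, length, 0L)
  cat(sprintf("<gridSpec>  %d parameters (%s), product %.0f%s\n",
              length(lens),
              paste(sprintf("%s:%d", names(lens), lens), collapse = ", "),
              prod(lens),
              if (is.null(x$exclude)) "" else ", with exclusion predicate"))
  invisible(x)
}
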