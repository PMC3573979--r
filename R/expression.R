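#' Time-series expression dataset
#'
#' Container for a genes x time x replicate array of log2 fold-change values
#' sampled on a common time grid (hours). This is the measurement object every
#' downstream step (scaling, interpolation, regression building, simulation
#' scoring) operates on.
#'
#' @param values numeric array of dimension `genes x times x replicates`, or a
#'   matrix (`genes x times`) for a single replicate. Log2 fold-change,
#'   dimensionless.
#' @param genes character vector of unique gene identifiers (rows).
#' @param times strictly increasing numeric vector of time points in hours.
#' @param interpolated logical vector flagging grid points that were inserted
#'   by interpolation rather than measured; defaults to all-measured.
#'
#' @return An object of class `"expression_dataset"`: a list with elements
#'   `genes`, `times`, `values` (3-d array), `interpolated`.
#' @examples
#' ds <- expression_dataset(matrix(rnorm(15), 3, 5),
#'                          genes = c("g1", "g2", "g3"),
#'                          times = c(0, 3, 6, 12, 24))
#' dim(ds$values)
#' @export
expression_dataset <- function(values, genes, times, interpolated = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  genes <- as.character(genes)
  times <- as.numeric(times)
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (length(genes) != dim(values)[1L])
    stop("length(genes) does not match nrow(values)")
  if (length(times) != dim(values)[2L])
    stop("length(times) does not match the time dimension of values")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (anyNA(values)) stop("missing values are not allowed on the grid")
  if (is.null(interpolated)) interpolated <- rep(FALSE, length(times))
  stopifnot(length(interpolated) == length(times))
  dimnames(values) <- list(genes, format_time(times),
                           paste0("r", seq_len(dim(values)[3L])))
  structure(list(genes = genes, times = times, values = values,
                 interpolated = as.logical(interpolated)),
            class = "expression_dataset")
}

format_time <- function(t) {
  s <- format(t, trim = TRUE)
  # strip trailing zeros of a fractional part only (never touch "10" or "0")
  s <- ifelse(grepl("\\.", s), sub("\\.?0+$", "", s), s)
  paste0("t", s)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes, %d time points (%s h), %d replicate(s)\n",
              length(x$genes), length(x$times),
              paste(range(x$times), collapse = "-"), n_replicates(x)))
  if (any(x$interpolated))
    cat(sprintf("  %d grid points interpolated (dt = %g h)\n",
                sum(x$interpolated), unique(diff(x$times))[1]))
  invisible(x)
}

#' @rdname expression_dataset
#' @param ds an `expression_dataset`.
#' @export
n_replicates <- function(ds) dim(ds$values)[3L]

#' @rdname expression_dataset
#' @export
is_equidistant <- function(ds) {
  d <- diff(ds$times)
  length(d) == 0L || all(abs(d - d[1L]) <= 1e-9 * max(d))
}

#' Read a time-series expression table
#'
#' Parses a tab-separated table whose first column holds gene identifiers and
#' whose remaining columns are labelled `t{time}_r{replicate}` (e.g. `t0_r1`,
#' `t3_r2`). Every replicate must provide the same set of time points.
#'
#' @param path path to a TSV file.
#' @return An [expression_dataset()].
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs a gene column plus value columns")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  hdr <- names(tab)[-1L]
  m <- regmatches(hdr, regexec("^t([0-9.]+)_r([0-9]+)$", hdr))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed column header(s): ", paste(hdr[bad], collapse = ", "),
         " (expected t{time}_r{replicate})")
  t_col <- vapply(m, function(z) as.numeric(z[2L]), 0)
  r_col <- vapply(m, function(z) as.integer(z[3L]), 0L)
  times <- sort(unique(t_col))
  reps <- sort(unique(r_col))
  # every replicate must cover every time point exactly once
  for (r in reps) {
    got <- sort(t_col[r_col == r])
    if (!identical(got, times))
      stop("ragged replicate structure: replicate ", r,
           " does not cover the full time grid")
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    nn <- which(!vapply(tab[-1L], is.numeric, TRUE))
    stop("non-numeric value(s) in column(s): ", paste(hdr[nn], collapse = ", "))
  }
  arr <- array(NA_real_, dim = c(length(ids), length(times), length(reps)))
  for (j in seq_along(hdr)) {
    ti <- match(t_col[j], times); ri <- match(r_col[j], reps)
    arr[, ti, ri] <- vals[, j]
  }
  expression_dataset(arr, genes = ids, times = times)
}

#' Write a time-series expression table
#'
#' Inverse of [read_expression()]: values are written at full precision
#' (17 significant digits) so a write/read round trip reproduces the dataset
#' bit-exactly.
#'
#' @param ds an `expression_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path) {
  R <- n_replicates(ds)
  cols <- list(gene = ds$genes)
  for (r in seq_len(R))
    for (ti in seq_along(ds$times)) {
      nm <- sprintf("t%s_r%d", sub("^t", "", format_time(ds$times[ti])), r)
      cols[[nm]] <- ds$values[, ti, r]
    }
  df <- as.data.frame(cols, check.names = FALSE)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scale each gene profile to absolute maximum 1
#'
#' Divides every gene's values by a single gene-level constant, the maximum of
#' |value| over all time points and replicates, so that replicate variability
#' is preserved. All-zero profiles are left unchanged. Idempotent.
#'
#' @param ds an `expression_dataset`.
#' @return The scaled dataset; scale factors are attached as attribute
#'   `"scale_factors"` (named numeric, 1 for all-zero profiles).
#' @export
scale_profiles <- function(ds) {
  s <- apply(abs(ds$values), 1L, max)
  s[s == 0] <- 1
  out <- ds
  out$values <- sweep(ds$values, 1L, s, "/")
  dimnames(out$values) <- dimnames(ds$values)
  attr(out, "scale_factors") <- stats::setNames(s, ds$genes)
  out
}

#' Linearly interpolate a dataset onto an equidistant grid
#'
#' Inserts linearly interpolated values so that consecutive time points are
#' `dt` hours apart, per gene and per replicate independently. Measured points
#' are preserved bit-exactly and inserted points are flagged in
#' `interpolated`.
#'
#' @param ds an `expression_dataset`.
#' @param dt target grid spacing in hours; must divide every gap between
#'   measured time points.
#' @return An equidistant `expression_dataset`.
#' @export
interpolate_to_grid <- function(ds, dt = 1) {
  stopifnot(dt > 0)
  gaps <- diff(ds$times)
  ratio <- gaps / dt
  if (any(abs(ratio - round(ratio)) > 1e-8))
    stop("dt = ", dt, " does not divide all gaps between measured times")
  grid <- ds$times[1L] + dt * seq.int(0L, round((max(ds$times) - ds$times[1L]) / dt))
  keep <- vapply(grid, function(t) any(abs(ds$times - t) < 1e-8), TRUE)
  if (all(keep) && length(grid) == length(ds$times)) return(ds)
  R <- n_replicates(ds)
  arr <- array(NA_real_, dim = c(length(ds$genes), length(grid), R))
  midx <- vapply(ds$times, function(t) which.min(abs(grid - t)), 1L)
  for (r in seq_len(R))
    for (g in seq_along(ds$genes)) {
      arr[g, , r] <- stats::approx(ds$times, ds$values[g, , r], xout = grid)$y
      arr[g, midx, r] <- ds$values[g, , r]  # measured points bit-exact
    }
  expression_dataset(arr, genes = ds$genes, times = grid,
                     interpolated = !keep)
}
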