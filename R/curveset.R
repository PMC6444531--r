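# Containers and I/O for time-course matrices.
#
# A curve set is a curves x times matrix plus its sampling grid, optional
# non-negative per-curve importance weights and optional labels.  The grid
# is common to all curves (ragged grids are out of scope); missing values
# are rejected, not imputed, because the downstream registration assumes
# complete high-resolution curves.

#' Construct a curve set
#'
#' @param values numeric matrix, one row per curve, one column per time point.
#'   A single curve may be given as a vector.
#' @param times strictly increasing numeric vector of sampling times, one per
#'   column of `values`.  At least 3 points are required.
#' @param weights optional non-negative per-curve importance weights
#'   (default 1 for every curve); must not be all zero.
#' @param labels optional character vector of curve identifiers.
#' @return an object of class `curve_set` with elements `times`, `values`,
#'   `weights`, `labels`.
#' @export
#' @examples
#' cs <- curve_set(rbind(sin(0:10), cos(0:10)), times = 0:10)
#' cs
curve_set <- function(values, times, weights = NULL, labels = NULL) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  values <- as.matrix(values)
  times <- as.numeric(times)
  check_grid(times)
  if (ncol(values) != length(times))
    stop("`values` must have one column per time point (got ", ncol(values),
         " columns for ", length(times), " times)")
  if (anyNA(values) || any(!is.finite(values)))
    stop("curve values must be finite and non-missing; this method assumes ",
         "complete high-resolution curves")
  n <- nrow(values)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop("`weights` must have one entry per curve")
  if (anyNA(weights) || any(weights < 0))
    stop("`weights` must be non-negative")
  if (all(weights == 0)) stop("`weights` must not be all zero")
  if (!is.null(labels) && length(labels) != n)
    stop("`labels` must have one entry per curve")
  dimnames(values) <- NULL
  structure(
    list(times = times, values = values, weights = as.numeric(weights),
         labels = labels),
    class = "curve_set"
  )
}

check_grid <- function(times) {
  if (length(times) < 3L)
    stop("the sampling grid needs at least 3 time points")
  if (anyNA(times) || any(!is.finite(times)))
    stop("sampling times must be finite")
  if (any(diff(times) <= 0))
    stop("sampling times must be strictly increasing")
  invisible(times)
}

#' @export
print.curve_set <- function(x, ...) {
  cat("Curve set: ", nrow(x$values), " curves on ", length(x$times),
      " time points [", format(x$times[1L]), ", ",
      format(x$times[length(x$times)]), "]\n", sep = "")
  if (!all(x$weights == 1)) cat("  with per-curve weights\n")
  invisible(x)
}

#' @export
as.matrix.curve_set <- function(x, ...) x$values

#' @export
`[.curve_set` <- function(x, i, ...) {
  curve_set(x$values[i, , drop = FALSE], x$times,
            weights = x$weights[i], labels = x$labels[i])
}

#' Number of curves in a curve set
#' @param x a `curve_set`
#' @return integer count of curves
#' @export
n_curves <- function(x) nrow(x$values)

#' @export
plot.curve_set <- function(x, col = "grey30", ...) {
  graphics::matplot(x$times, t(x$values), type = "l", lty = 1, col = col,
                    xlab = "time", ylab = "value", ...)
  invisible(x)
}

#' Read a time-course matrix from CSV/TSV
#'
#' The first row is the header of numeric sampling times; each subsequent
#' row is one curve.  An optional final column named `weight` supplies
#' per-curve importance weights.  An optional first column named `label`
#' (or any non-numeric first header cell) supplies curve identifiers.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`; default guessed from the extension.
#' @return a [curve_set()].
#' @export
read_curves <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path)) "tsv" else "csv"
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", strip.white = TRUE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) < 2L) stop("need a header row of times and at least one curve")
  header <- as.character(raw[1L, ])
  body <- raw[-1L, , drop = FALSE]

  label_col <- 0L
  if (tolower(header[1L]) == "label" || is.na(suppressWarnings(as.numeric(header[1L]))))
    label_col <- 1L
  weight_col <- if (tolower(header[length(header)]) == "weight")
    length(header) else 0L

  time_cols <- setdiff(seq_along(header), c(label_col, weight_col))
  times <- suppressWarnings(as.numeric(header[time_cols]))
  if (anyNA(times))
    stop("header row must contain numeric sampling times")
  if (any(diff(times) <= 0))
    stop("header times must be strictly increasing (duplicate or ",
         "decreasing time in header)")

  parse_num <- function(col, what) {
    out <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(out))
    if (length(bad))
      stop("non-numeric ", what, " in data row ", bad[1L])
    out
  }
  values <- vapply(time_cols, function(j) parse_num(body[[j]], "value"),
                   numeric(nrow(body)))
  if (nrow(body) == 1L) values <- matrix(values, nrow = 1L)
  weights <- if (weight_col) parse_num(body[[weight_col]], "weight") else NULL
  labels <- if (label_col) as.character(body[[label_col]]) else NULL
  curve_set(values, times, weights = weights, labels = labels)
}

#' Write a curve set to CSV/TSV
#'
#' Inverse of [read_curves()]: header row of times, one row per curve, the
#' weight column appended only when any weight differs from 1.
#'
#' @param x a `curve_set`.
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_curves <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  has_w <- !all(x$weights == 1)
  has_l <- !is.null(x$labels)
  header <- c(if (has_l) "label", format(x$times, digits = 15, trim = TRUE),
              if (has_w) "weight")
  rows <- vapply(seq_len(nrow(x$values)), function(i) {
    paste(c(if (has_l) x$labels[i],
            format(x$values[i, ], digits = 15, trim = TRUE),
            if (has_w) format(x$weights[i], digits = 15, trim = TRUE)),
          collapse = sep)
  }, character(1L))
  writeLines(c(paste(header, collapse = sep), rows), path)
  invisible(path)
}

#' Map a grid affinely onto [0, 1]
#'
#' Warping functions live on the unit interval, so all registration happens
#' on the normalised grid; the returned map converts back to original units.
#'
#' @param times strictly increasing sampling times.
#' @return list with `unit_times` (first element 0, last 1), and the affine
#'   map as `shift`/`scale` plus `to_unit()`/`from_unit()` closures.
#' @export
normalize_grid <- function(times) {
  check_grid(times)
  span <- times[length(times)] - times[1L]
  if (span <= 0) stop("degenerate grid: first and last times coincide")
  shift <- times[1L]
  unit <- (times - shift) / span
  unit[1L] <- 0
  unit[length(unit)] <- 1
  list(unit_times = unit, shift = shift, scale = span,
       to_unit = function(t) (t - shift) / span,
       from_unit = function(u) shift + u * span)
}

# ---- selections -----------------------------------------------------------

#' Construct a time-point selection
#'
#' @param indices strictly increasing 1-based indices into the grid.
#' @param times full sampling grid the indices refer to.
#' @param criterion `"f1"`, `"f2"` or `"f3"`.
#' @param objective_estimate achieved Monte-Carlo objective value (>= 0).
#' @param n_samples number of Monte-Carlo samples J behind the estimate.
#' @param seed integer seed the estimate was computed under.
#' @param strategy how the selection was produced (e.g. `"dp"`, `"even"`).
#' @return an object of class `timepoint_selection`.
#' @export
selection <- function(indices, times, criterion = "f1",
                      objective_estimate = NA_real_, n_samples = NA_integer_,
                      seed = NA_integer_, strategy = "dp") {
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("a selection must contain at least one time point")
  if (any(diff(indices) <= 0)) stop("selection indices must be strictly increasing")
  if (indices[1L] < 1L || indices[length(indices)] > length(times))
    stop("selection indices out of grid range")
  criterion <- match.arg(criterion, c("f1", "f2", "f3"))
  if (!is.na(objective_estimate) && objective_estimate < -1e-12)
    stop("objective estimate must be non-negative")
  structure(
    list(indices = indices, times = times[indices], grid = as.numeric(times),
         criterion = criterion,
         objective_estimate = as.numeric(objective_estimate),
         n_samples = as.integer(n_samples), seed = as.integer(seed),
         strategy = strategy),
    class = "timepoint_selection"
  )
}

#' @export
print.timepoint_selection <- function(x, ...) {
  cat("Time-point selection (", x$strategy, ", criterion ", x$criterion,
      "): ", length(x$indices), " of ", length(x$grid), " points\n", sep = "")
  cat("  indices:", paste(x$indices, collapse = ", "), "\n")
  cat("  times:  ", paste(format(x$times, digits = 6), collapse = ", "), "\n")
  if (!is.na(x$objective_estimate))
    cat("  objective estimate:", format(x$objective_estimate, digits = 6),
        if (!is.na(x$n_samples)) paste0("(J = ", x$n_samples, ")"), "\n")
  invisible(x)
}

#' @export
as.data.frame.timepoint_selection <- function(x, ...) {
  data.frame(index = x$indices, time = x$times)
}

#' Write a selection to JSON
#'
#' Indices are 1-based; times are in the original (unnormalised) units.
#' Output is byte-stable for identical inputs.
#'
#' @param sel a `timepoint_selection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "timepoint_selection"))
  doc <- list(
    indices = sel$indices,
    times = sel$times,
    grid = sel$grid,
    criterion = sel$criterion,
    objective_estimate = sel$objective_estimate,
    n_samples = sel$n_samples,
    seed = sel$seed,
    strategy = sel$strategy,
    tool = "curvepick",
    version = as.character(utils::packageVersion("curvepick"))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a selection back from JSON
#' @param path file written by [write_selection()].
#' @return a `timepoint_selection`.
#' @export
read_selection <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  selection(doc$indices, doc$grid, criterion = doc$criterion,
            objective_estimate = doc$objective_estimate %||% NA_real_,
            n_samples = doc$n_samples %||% NA_integer_,
            seed = doc$seed %||% NA_integer_,
            strategy = doc$strategy %||% "dp")
}
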