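#' Time-indexed scalar observable
#'
#' Light container for a per-frame observable extracted from a trajectory:
#' rotation angle (deg), hydration count, RMSD (Angstrom), a 0/1 contact
#' flag, or an energy (kcal/mol).
#'
#' @param times numeric vector of times in ns, strictly increasing.
#' @param values numeric vector, same length as `times`.
#' @param label short description of the observable (used in output headers).
#' @return An object of class `ScalarSeries`: a list with elements `times`,
#'   `values` and `label`.
#' @export
scalar_series <- function(times, values, label = "") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  structure(list(times = times, values = values, label = as.character(label)),
            class = "ScalarSeries")
}

#' @export
length.ScalarSeries <- function(x) length(x$times)

#' @export
print.ScalarSeries <- function(x, ...) {
  cat(sprintf("ScalarSeries '%s': %d points, t = [%g, %g] ns\n",
              x$label, length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' @export
as.data.frame.ScalarSeries <- function(x, ...) {
  data.frame(time_ns = x$times, value = x$values)
}

#' Write a scalar series as two-column TSV
#'
#' Columns are `time_ns` and `value`.
#'
#' @param series a [scalar_series()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(series, path) {
  stopifnot(inherits(series, "ScalarSeries"))
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scalar series from two-column TSV
#'
#' @param path TSV file with columns `time_ns` and `value`.
#' @param label label for the resulting series (default: file name).
#' @return a [scalar_series()].
#' @export
read_series_tsv <- function(path, label = basename(path)) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  scalar_series(d[[1L]], d[[2L]], label)
}
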