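#' Observed or simulated time series
#'
#' A minimal container for a scalar readout sampled at discrete, strictly
#' increasing observation times, the common currency between the data
#' generator, the distance function and the samplers.
#'
#' @param time Numeric vector of strictly increasing observation times.
#' @param value Numeric vector of the same length; the observed quantity
#'   (the output species Z in the feed-forward-loop study).
#' @return A data frame of class `time_series` with columns `time` and
#'   `value`.
#' @examples
#' time_series(1:10, rep(0.5, 10))
#' @export
time_series <- function(time, value) {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value)) {
    stop("`time` and `value` must have the same length", call. = FALSE)
  }
  if (length(time) == 0L) stop("empty time series", call. = FALSE)
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(time = time, value = value),
            class = c("time_series", "data.frame"))
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d points, t in [%g, %g]\n",
              nrow(x), x$time[1L], x$time[nrow(x)]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read and write time-series CSV files
#'
#' Files use the two-column `time,value` format with an optional leading
#' `# source:` comment recording provenance.
#'
#' @param path File path.
#' @rdname time_series_io
#' @return `read_time_series()` returns a [time_series()];
#'   `write_time_series()` returns `path` invisibly.
#' @export
read_time_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- read.csv(path, comment.char = "#")
  if (!all(c("time", "value") %in% names(d))) {
    stop("expected columns `time,value` in ", path, call. = FALSE)
  }
  time_series(d$time, d$value)
}

#' @param x A `time_series`.
#' @param source Optional character scalar written as a `# source:` header
#'   comment.
#' @rdname time_series_io
#' @export
write_time_series <- function(x, path, source = NULL) {
  stopifnot(inherits(x, "time_series"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(source)) writeLines(paste("# source:", source), con)
  write.csv(as.data.frame(x)[, c("time", "value")], con, row.names = FALSE)
  invisible(path)
}
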