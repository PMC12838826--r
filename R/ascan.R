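#' A-mode pulse-echo signal container
#'
#' Holds one sampled A-scan: amplitudes on a uniform time grid starting at
#' `time_origin` (sample i sits at `time_origin + (i - 1) / sampling_rate`).
#' The simulator places the surface echo at t = 0, so `time_origin` is
#' slightly negative to cover its leading tail.
#'
#' @param samples Numeric amplitude vector; all values finite.
#' @param sampling_rate Sampling rate in Hz.
#' @param time_origin Time of the first sample in s.
#' @param load_label Text label of the load step that produced the signal.
#' @param seed Integer noise seed used, or `NULL` for noise-free.
#' @return An object of class `ascan`.
#' @export
ascan <- function(samples, sampling_rate, time_origin = 0,
                  load_label = "", seed = NULL) {
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("invalid signal: samples must be finite numbers", call. = FALSE)
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         time_origin = time_origin, load_label = as.character(load_label),
         seed = seed),
    class = "ascan"
  )
}

#' @export
print.ascan <- function(x, ...) {
  cat(sprintf("<ascan> %d samples @ %.3g MHz, t0 = %.3g us, load '%s'%s\n",
              length(x$samples), x$sampling_rate / 1e6, x$time_origin * 1e6,
              x$load_label,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Sample times of an A-scan
#' @param x An [ascan()].
#' @return Numeric vector of times in s.
#' @export
ascan_times <- function(x) {
  stopifnot(inherits(x, "ascan"))
  x$time_origin + (seq_along(x$samples) - 1) / x$sampling_rate
}

#' @export
as.data.frame.ascan <- function(x, ...) {
  data.frame(time_s = ascan_times(x), amplitude = x$samples)
}

#' Read and write A-scan CSV files
#'
#' The on-disk format is CSV with a `time_s,amplitude` header (or a
#' two-column headerless variant with `header = FALSE`). The sampling rate
#' is recovered from the median time step on read.
#'
#' @param x An [ascan()].
#' @param path File path.
#' @param header Write/expect the `time_s,amplitude` header line.
#' @param load_label Label to attach on read (defaults to the file name).
#' @return `write_ascan` returns `path` invisibly; `read_ascan` an [ascan()].
#' @rdname ascan_io
#' @export
write_ascan <- function(x, path, header = TRUE) {
  stopifnot(inherits(x, "ascan"))
  df <- as.data.frame(x)
  write.csv(format(df, digits = 12, trim = TRUE, scientific = TRUE),
            path, row.names = FALSE, quote = FALSE)
  if (!header) {
    lines <- readLines(path)
    writeLines(lines[-1], path)
  }
  invisible(path)
}

#' @rdname ascan_io
#' @export
read_ascan <- function(path, header = TRUE, load_label = NULL) {
  df <- read.csv(path, header = header,
                 col.names = c("time_s", "amplitude"))
  if (nrow(df) < 2) stop("invalid signal file: fewer than 2 samples", call. = FALSE)
  dt <- median(diff(df$time_s))
  ascan(df$amplitude, sampling_rate = 1 / dt, time_origin = df$time_s[1],
        load_label = load_label %||% sub("\\.csv$", "", basename(path)))
}
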