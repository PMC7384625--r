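#' Construct an acoustic signal
#'
#' The basic container used throughout the package: a mono amplitude sequence
#' with its sampling rate, plus optional capture metadata. Amplitudes are
#' dimensionless; recordings read from WAV are scaled to \[-1, 1\].
#'
#' @param samples numeric vector of amplitudes (length >= 2, all finite).
#' @param fs sampling rate in Hz (> 0).
#' @param timestamp optional `POSIXct` capture time of the first sample.
#' @param source_id optional string identifying the recording source.
#' @return an object of class `acoustic_signal`: a list with elements
#'   `samples`, `fs`, `timestamp`, `source_id`.
#' @examples
#' s <- acoustic_signal(sin(2 * pi * 440 * (0:999) / 8000), fs = 8000)
#' s
#' @export
acoustic_signal <- function(samples, fs, timestamp = NULL, source_id = NULL) {
  if (!is.numeric(samples) || length(samples) < 2)
    stop("`samples` must be a numeric vector of length >= 2", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("`samples` must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (!is.null(timestamp)) timestamp <- as.POSIXct(timestamp, tz = "UTC")
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         timestamp = timestamp, source_id = source_id),
    class = "acoustic_signal"
  )
}

#' @export
print.acoustic_signal <- function(x, ...) {
  cat(sprintf("<acoustic_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  if (!is.null(x$source_id)) cat("  source:   ", x$source_id, "\n", sep = "")
  if (!is.null(x$timestamp))
    cat("  timestamp: ", format(x$timestamp, "%Y-%m-%d %H:%M:%S %Z"), "\n",
        sep = "")
  invisible(x)
}

#' @export
length.acoustic_signal <- function(x) length(x$samples)

# Coerce numeric input to acoustic_signal, requiring fs when needed.
as_signal <- function(x, fs = NULL) {
  if (inherits(x, "acoustic_signal")) return(x)
  if (is.numeric(x)) {
    if (is.null(fs))
      stop("`fs` must be given when `x` is a bare numeric vector",
           call. = FALSE)
    return(acoustic_signal(x, fs))
  }
  stop("`x` must be an acoustic_signal or a numeric vector", call. = FALSE)
}

# Run expr with a fixed RNG seed, restoring global RNG state afterwards.
# All generators take explicit seeds through this; no global state leaks.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
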