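#' Read a WAV file as an acoustic signal
#'
#' Minimal RIFF/WAVE reader covering the encodings field recorders produce:
#' integer PCM at 16, 24 or 32 bits and IEEE float32. Multichannel files are
#' reduced to mono by averaging channels. Amplitudes are scaled to \[-1, 1\].
#' A timestamp is parsed from the filename when it matches
#' `<prefix>_YYYYMMDD_HHMMSS` (a common recorder convention); otherwise the
#' file modification time is used.
#'
#' @param path path to a WAV file.
#' @param timestamp_pattern regex with three capture groups (date, time) used
#'   for filename timestamps; see [parse_timestamp_filename()].
#' @return an [acoustic_signal] with `fs` from the header and `source_id` set
#'   to the file name.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, timestamp_pattern = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        fs       = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE,
                           endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("corrupt WAV (missing fmt or data chunk): ", path, call. = FALSE)
  if (length(data_raw) == 0)
    stop("empty WAV data chunk: ", path, call. = FALSE)

  bytes <- fmt$bits / 8
  n_frames <- length(data_raw) %/% (bytes * fmt$channels)
  if (fmt$format == 1 && fmt$bits == 16) {
    x <- readBin(data_raw, "integer", n_frames * fmt$channels, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 1 && fmt$bits == 24) {
    r <- as.integer(data_raw[seq_len(n_frames * fmt$channels * 3)])
    b1 <- r[seq(1, length(r), 3)]; b2 <- r[seq(2, length(r), 3)]
    b3 <- r[seq(3, length(r), 3)]
    v <- b1 + 256 * b2 + 65536 * b3
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else if (fmt$format == 1 && fmt$bits == 32) {
    x <- readBin(data_raw, "integer", n_frames * fmt$channels, 4,
                 endian = "little") / 2^31
  } else if (fmt$format == 3 && fmt$bits == 32) {
    x <- readBin(data_raw, "double", n_frames * fmt$channels, 4,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$format, ", ",
         fmt$bits, " bits): ", path, call. = FALSE)
  }
  if (fmt$channels > 1) {
    x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
  }
  ts <- parse_timestamp_filename(path, timestamp_pattern)
  if (is.null(ts)) ts <- file.mtime(path)
  acoustic_signal(x, fmt$fs, timestamp = ts, source_id = basename(path))
}

#' Write an acoustic signal to a WAV file
#'
#' @param x an [acoustic_signal] (or numeric vector with `fs`).
#' @param path output path.
#' @param bit_depth 16 (integer PCM, samples clipped to \[-1, 1\]) or 32
#'   (IEEE float).
#' @param fs sampling rate, required when `x` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bit_depth = 16, fs = NULL) {
  x <- as_signal(x, fs)
  if (!bit_depth %in% c(16, 32))
    stop("`bit_depth` must be 16 or 32", call. = FALSE)
  n <- length(x$samples)
  bytes <- bit_depth / 8
  fmt_tag <- if (bit_depth == 16) 1L else 3L
  data_size <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(x$fs), con, size = 4, endian = "little")
  writeBin(as.integer(x$fs * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")  # block align
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    v <- pmin(pmax(x$samples, -1), 32767 / 32768)
    writeBin(as.integer(round(v * 32768)), con, size = 2, endian = "little")
  } else {
    writeBin(x$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Parse a timestamp from a recorder-style file name
#'
#' Field recorders commonly encode the capture time in the file name as
#' `<prefix>_YYYYMMDD_HHMMSS.<ext>`. Returns `NULL` when the name does not
#' match.
#'
#' @param path file path or name.
#' @param pattern optional alternative regex; must contain two capture groups
#'   giving `YYYYMMDD` and `HHMMSS`.
#' @return a `POSIXct` (UTC) or `NULL`.
#' @export
parse_timestamp_filename <- function(path, pattern = NULL) {
  if (is.null(pattern)) pattern <- ".*_(\\d{8})_(\\d{6})\\.[A-Za-z0-9]+$"
  nm <- basename(path)
  m <- regmatches(nm, regexec(pattern, nm))[[1]]
  if (length(m) < 3) return(NULL)
  ts <- as.POSIXct(paste(m[2], m[3]), format = "%Y%m%d %H%M%S", tz = "UTC")
  if (is.na(ts)) NULL else ts
}

#' Split a signal into fixed-length segments
#'
#' Consecutive non-overlapping windows, the unit of analysis for all indices;
#' the field convention is 22-second segments. Each segment inherits the
#' parent's metadata with its timestamp offset by the segment start.
#'
#' @param x an [acoustic_signal].
#' @param segment_s window length in seconds (> 0), default 22.
#' @param drop_partial drop a trailing window shorter than `segment_s`
#'   (default `TRUE`).
#' @return a list of [acoustic_signal] segments (possibly empty, with a
#'   warning, when the signal is shorter than one segment).
#' @examples
#' s <- colored_noise(8000 * 66, alpha = 0, fs = 8000, seed = 1)
#' length(segment_signal(s, 22))  # 3
#' @export
segment_signal <- function(x, segment_s = 22, drop_partial = TRUE) {
  x <- as_signal(x)
  if (segment_s <= 0) stop("`segment_s` must be positive", call. = FALSE)
  seg_n <- as.integer(round(segment_s * x$fs))
  n <- length(x$samples)
  n_full <- n %/% seg_n
  if (n_full == 0 && drop_partial) {
    warning("signal shorter than one segment; returning empty list",
            call. = FALSE)
    return(list())
  }
  starts <- seq(0L, by = seg_n, length.out = n_full)
  segs <- lapply(seq_along(starts), function(i) {
    idx <- (starts[i] + 1L):(starts[i] + seg_n)
    ts <- if (is.null(x$timestamp)) NULL else x$timestamp + starts[i] / x$fs
    acoustic_signal(x$samples[idx], x$fs, timestamp = ts,
                    source_id = x$source_id)
  })
  if (!drop_partial && n %% seg_n > 0) {
    idx <- (n_full * seg_n + 1L):n
    if (length(idx) >= 2) {
      ts <- if (is.null(x$timestamp)) NULL else
        x$timestamp + (n_full * seg_n) / x$fs
      segs <- c(segs, list(acoustic_signal(x$samples[idx], x$fs,
                                           timestamp = ts,
                                           source_id = x$source_id)))
    }
  }
  segs
}

results_columns <- c("source_id", "timestamp", "segment_index", "tau_max",
                     "H", "J", "C", "aci", "ha", "hf", "ht", "adi", "aei",
                     "ndsi", "bi")

#' Write and read per-segment result tables
#'
#' `write_results()` serializes a data frame of per-segment quantifiers (and
#' optionally the comparison indices) to CSV with a fixed column set; missing
#' index values are written as empty cells, never as zeros. `read_results()`
#' inverts it, restoring timestamps as UTC `POSIXct`.
#'
#' @param results data frame with at least `H`, `J`, `C` columns; missing
#'   standard columns are filled with `NA`.
#' @param path CSV file path.
#' @return `write_results()`: `path` invisibly; `read_results()`: a data
#'   frame.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("`results` must be a non-empty data frame", call. = FALSE)
  out <- results
  for (cn in results_columns) if (is.null(out[[cn]])) out[[cn]] <- NA
  out <- out[results_columns]
  if (!is.null(out$timestamp) && inherits(out$timestamp, "POSIXct"))
    out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA, sprintf("%.15g", v))
  })
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(df$timestamp))
    df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC")
  df
}
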