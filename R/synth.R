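#' Simulate power-law colored noise
#'
#' Generates a Gaussian noise sequence whose power spectral density follows
#' a power law 1/|f|^alpha: alpha = 0 is white noise, alpha = 1 pink, and
#' alpha = 2 Brownian/red noise, the regime that rain and other geophysical
#' sounds occupy. Synthesis is by spectral shaping: white Gaussian noise is
#' transformed to the frequency domain, each Fourier coefficient is scaled by
#' |f|^(-alpha/2) (the DC term is zeroed), and the result is transformed back
#' and standardized to zero mean and unit variance.
#'
#' @param n number of samples (>= 2).
#' @param alpha power-law exponent; the soundscape reference range is
#'   \[0, 2\]. Values outside it require `extended = TRUE`.
#' @param fs sampling rate in Hz recorded on the output (default 44100, the
#'   field-recording convention).
#' @param seed integer RNG seed; fixed seed gives bit-identical output. `NULL`
#'   uses (and advances) the current RNG state.
#' @param extended allow alpha outside \[0, 2\].
#' @return an [acoustic_signal] with zero mean and unit variance.
#' @examples
#' w <- colored_noise(2^12, alpha = 0, seed = 1)   # white
#' r <- colored_noise(2^12, alpha = 2, seed = 1)   # red (rain-like)
#' @export
colored_noise <- function(n, alpha = 1, fs = 44100, seed = NULL,
                          extended = FALSE) {
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  n <- as.integer(n)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha))
    stop("`alpha` must be a single finite number", call. = FALSE)
  if (!extended && (alpha < 0 || alpha > 2))
    stop("`alpha` outside [0, 2]; pass extended = TRUE to override",
         call. = FALSE)
  x <- with_seed(seed, stats::rnorm(n))
  if (alpha != 0) {
    # frequencies of the DFT bins, in cycles/sample; shaping is scale-free so
    # the physical fs does not enter the exponent
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n
    shape <- c(0, abs(k[-1])^(-alpha / 2))
    x <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE)) / n
  }
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  acoustic_signal(x, fs)
}

#' Deterministic scene components
#'
#' Building blocks for [synth_scene()]: a steady sinusoid, a linear chirp, and
#' a train of Hann-windowed tone pulses (a crude click/call emulation). Each
#' component is active on \[`from`, `to`\] seconds and silent elsewhere.
#'
#' @param freq tone frequency in Hz (must be below the scene Nyquist).
#' @param f0,f1 chirp start/end frequencies in Hz.
#' @param rate pulse repetition rate in Hz.
#' @param width pulse width in seconds.
#' @param amplitude peak amplitude (dimensionless).
#' @param from,to activity window in seconds (`to = Inf` means whole scene).
#' @return a `scene_component` description consumed by [synth_scene()].
#' @name scene_components
NULL

#' @rdname scene_components
#' @export
scene_tone <- function(freq, amplitude = 1, from = 0, to = Inf) {
  structure(list(kind = "tone", freq = freq, amplitude = amplitude,
                 from = from, to = to), class = "scene_component")
}

#' @rdname scene_components
#' @export
scene_chirp <- function(f0, f1, amplitude = 1, from = 0, to = Inf) {
  structure(list(kind = "chirp", f0 = f0, f1 = f1, amplitude = amplitude,
                 from = from, to = to), class = "scene_component")
}

#' @rdname scene_components
#' @export
scene_pulses <- function(rate, freq, width = 0.005, amplitude = 1,
                         from = 0, to = Inf) {
  structure(list(kind = "pulse_train", rate = rate, freq = freq,
                 width = width, amplitude = amplitude, from = from, to = to),
            class = "scene_component")
}

render_component <- function(comp, t, fs, duration) {
  to <- min(comp$to, duration)
  on <- t >= comp$from & t < to
  y <- numeric(length(t))
  if (!any(on)) return(y)
  tt <- t[on] - comp$from
  y[on] <- switch(
    comp$kind,
    tone = comp$amplitude * sin(2 * pi * comp$freq * tt),
    chirp = {
      span <- to - comp$from
      k <- (comp$f1 - comp$f0) / span
      comp$amplitude * sin(2 * pi * (comp$f0 * tt + k * tt^2 / 2))
    },
    pulse_train = {
      phase <- tt %% (1 / comp$rate)
      env <- ifelse(phase < comp$width,
                    0.5 * (1 - cos(2 * pi * phase / comp$width)), 0)
      comp$amplitude * env * sin(2 * pi * comp$freq * tt)
    },
    stop("unknown component kind: ", comp$kind, call. = FALSE)
  )
  y
}

max_component_freq <- function(comp) {
  switch(comp$kind,
         tone = comp$freq,
         chirp = max(comp$f0, comp$f1),
         pulse_train = comp$freq + 2 / comp$width)
}

#' Synthesize an acoustic scene
#'
#' Renders a mixture of deterministic components (tones, chirps, pulse
#' trains) plus optional colored background noise, emulating the standard
#' decomposition of an ecoacoustic signal into a deterministic part and a
#' stochastic part. When both components and noise are present, the noise is
#' rescaled so that the ratio of total deterministic power to noise power
#' matches `snr_db`.
#'
#' @param components list of [scene_components] (may be empty).
#' @param duration_s scene length in seconds (> 0).
#' @param fs sampling rate in Hz.
#' @param noise_alpha power-law exponent of the background noise, or `NULL`
#'   for a noise-free scene.
#' @param snr_db target signal-to-noise ratio in dB (total-power definition);
#'   ignored when either part is absent.
#' @param seed integer RNG seed for the noise part.
#' @param timestamp,source_id metadata forwarded to the output signal.
#' @return an [acoustic_signal].
#' @examples
#' sc <- synth_scene(list(scene_tone(1000)), duration_s = 1, fs = 8000,
#'                   noise_alpha = 0, snr_db = 0, seed = 7)
#' @export
synth_scene <- function(components = list(), duration_s, fs = 44100,
                        noise_alpha = NULL, snr_db = NULL, seed = NULL,
                        timestamp = NULL, source_id = NULL) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be positive", call. = FALSE)
  n <- max(2L, as.integer(round(duration_s * fs)))
  t <- (seq_len(n) - 1) / fs
  for (comp in components) {
    if (!inherits(comp, "scene_component"))
      stop("every element of `components` must be a scene_component",
           call. = FALSE)
    if (max_component_freq(comp) >= fs / 2)
      stop("component frequency ", max_component_freq(comp),
           " Hz is at or above Nyquist (fs/2 = ", fs / 2, " Hz)",
           call. = FALSE)
  }
  det <- numeric(n)
  for (comp in components) det <- det + render_component(comp, t, fs, duration_s)

  if (is.null(noise_alpha)) {
    out <- det
  } else {
    noise <- colored_noise(n, alpha = noise_alpha, fs = fs, seed = seed)$samples
    if (length(components) > 0 && !is.null(snr_db)) {
      p_det <- mean(det^2)
      p_noise <- mean(noise^2)
      noise <- noise * sqrt(p_det / (p_noise * 10^(snr_db / 10)))
    }
    out <- det + noise
  }
  acoustic_signal(out, fs, timestamp = timestamp, source_id = source_id)
}

#' Simulate a timestamped monitoring stream
#'
#' Generates the segment stream a duty-cycled autonomous recorder would
#' produce over a multi-day deployment: fixed-length segments, each rendered
#' by [synth_scene()] from a scene description drawn from a diel profile.
#' The profile is a function of decimal hour-of-day (e.g. 11.5 = 11:30), so
#' transient events such as a half-hour rain shower are expressed directly in
#' the profile by returning a high-alpha noise scene on that interval.
#'
#' @param days number of days to simulate (>= 1).
#' @param segment_s segment length in seconds (default 22, the field
#'   convention).
#' @param day_profile function `(hour_decimal) -> list` with elements
#'   `components` (list of scene components, possibly empty), `noise_alpha`
#'   (or `NULL`) and `snr_db` (or `NULL`), describing the scene active at
#'   that time of day.
#' @param fs sampling rate in Hz.
#' @param seed integer RNG seed; each segment derives its own sub-seed so the
#'   stream is reproducible as a whole.
#' @param start POSIXct start of the deployment (default 2016-07-01 00:00 UTC).
#' @param segments_per_slot segments recorded at the start of each half-hour
#'   slot (duty-cycled deployment), or `NULL` for contiguous coverage.
#' @return a list of timestamped [acoustic_signal] segments, in time order.
#' @export
synth_monitoring_stream <- function(days, segment_s = 22, day_profile,
                                    fs = 44100, seed = NULL,
                                    start = as.POSIXct("2016-07-01 00:00:00",
                                                       tz = "UTC"),
                                    segments_per_slot = NULL) {
  if (!is.numeric(days) || days <= 0)
    stop("`days` must be positive", call. = FALSE)
  if (segment_s <= 0) stop("`segment_s` must be positive", call. = FALSE)
  if (!is.function(day_profile))
    stop("`day_profile` must be a function of decimal hour", call. = FALSE)

  if (is.null(segments_per_slot)) {
    n_seg <- floor(days * 86400 / segment_s)
    offsets <- (seq_len(n_seg) - 1) * segment_s
  } else {
    slot_starts <- seq(0, days * 86400 - 1, by = 1800)
    offsets <- as.vector(outer((seq_len(segments_per_slot) - 1) * segment_s,
                               slot_starts, `+`))
    offsets <- sort(offsets[offsets + segment_s <= days * 86400])
  }

  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  out <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    hour <- (offsets[i] %% 86400) / 3600
    spec <- day_profile(hour)
    seg_seed <- if (is.null(base_seed)) NULL else
      (base_seed + 7919L * i) %% .Machine$integer.max
    out[[i]] <- synth_scene(
      components = spec$components %||% list(),
      duration_s = segment_s, fs = fs,
      noise_alpha = spec$noise_alpha,
      snr_db = spec$snr_db,
      seed = seg_seed,
      timestamp = start + offsets[i],
      source_id = sprintf("synthetic_%05d", i)
    )
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
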