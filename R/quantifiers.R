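#' Singular spectrum of a matrix as a probability histogram
#'
#' Singular values of the autocorrelation Toeplitz matrix, each divided by
#' their sum. For a symmetric positive-definite matrix these coincide with
#' the eigenvalues; singular values are used so the histogram is nonnegative
#' by construction even when numerical round-off produces tiny negative
#' eigenvalues (near-singular matrices arise for pure tones).
#'
#' @param m square numeric matrix (the Toeplitz autocorrelation matrix).
#' @return numeric vector of length `ncol(m)`: nonnegative, summing to 1,
#'   sorted in decreasing order.
#' @examples
#' singular_spectrum(diag(4))  # rep(0.25, 4)
#' @export
singular_spectrum <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("`m` must be a square matrix", call. = FALSE)
  if (!all(is.finite(m)))
    stop("`m` contains non-finite entries", call. = FALSE)
  sv <- svd(m, nu = 0, nv = 0)$d
  sv / sum(sv)
}

check_pmf <- function(p, arg = "p") {
  if (!is.numeric(p) || length(p) < 2)
    stop("`", arg, "` must be a numeric vector of length >= 2", call. = FALSE)
  if (any(p < -1e-12))
    stop("`", arg, "` has negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("`", arg, "` must sum to 1", call. = FALSE)
  pmax(p, 0)
}

# Shannon entropy in nats with the 0 log 0 := 0 convention.
shannon <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Normalized Von Neumann entropy of a singular spectrum
#'
#' \deqn{H[P] = -\frac{1}{\log M} \sum_i p_i \log p_i,}
#' the Shannon entropy of the M-bin eigenvalue histogram normalized by its
#' maximum `log M`, so `0 <= H <= 1`: 1 for the uniform histogram (white
#' noise), 0 for a degenerate one (a single dominant eigenvalue). The log
#' base cancels under the normalization; natural log is used throughout.
#'
#' @param p probability vector (length M >= 2, nonnegative, sums to 1).
#' @return entropy in `[0, 1]`.
#' @examples
#' norm_entropy(rep(1 / 8, 8))      # 1
#' norm_entropy(c(1, 0, 0, 0))      # 0
#' @export
norm_entropy <- function(p) {
  p <- check_pmf(p)
  shannon(p) / log(length(p))
}

#' Jensen-Shannon divergence between two histograms
#'
#' \deqn{J[P, Q] = H[(P+Q)/2] - H[P]/2 - H[Q]/2} with the normalized entropy
#' of [norm_entropy()]; symmetric, nonnegative, and bounded by
#' `1 / q0(M)`.
#'
#' @param p,q probability vectors of the same length.
#' @return divergence (dimensionless, >= 0).
#' @export
jensen_shannon <- function(p, q) {
  p <- check_pmf(p, "p"); q <- check_pmf(q, "q")
  if (length(p) != length(q))
    stop("`p` and `q` must have the same length", call. = FALSE)
  max(0, norm_entropy((p + q) / 2) - norm_entropy(p) / 2 - norm_entropy(q) / 2)
}

#' Disequilibrium normalization constant
#'
#' `Q0` scales the Jensen-Shannon divergence from the uniform reference so
#' that the disequilibrium spans `[0, 1]`: it is the reciprocal of the
#' divergence between the most ordered (degenerate) histogram and the
#' uniform one,
#' \deqn{Q_0 = -2\log M \,/\, [\tfrac{M+1}{M}\log(M+1) - 2\log(2M) + \log M].}
#'
#' @param M histogram bin count (>= 2).
#' @return positive scalar.
#' @examples
#' q0(2) * jensen_shannon(c(1, 0), c(0.5, 0.5))  # 1
#' @export
q0 <- function(M) {
  if (!is.numeric(M) || length(M) != 1 || M < 2)
    stop("`M` must be a single integer >= 2", call. = FALSE)
  -2 * log(M) / (((M + 1) / M) * log(M + 1) - 2 * log(2 * M) + log(M))
}

#' Disequilibrium of a histogram
#'
#' Normalized Jensen-Shannon distance from maximal disorder:
#' `Q = Q0(M) * J[P, Pe]` with `Pe` uniform. 0 for the uniform histogram,
#' 1 for a degenerate one.
#'
#' @param p probability vector.
#' @return disequilibrium in `[0, 1]`.
#' @export
disequilibrium <- function(p) {
  p <- check_pmf(p)
  M <- length(p)
  q0(M) * jensen_shannon(p, rep(1 / M, M))
}

#' Generalized statistical complexity of a histogram
#'
#' The functional product `C = Q * H`: zero for both fully ordered
#' (degenerate, H = 0) and fully disordered (uniform, Q = 0) histograms, and
#' positive in between, where structure coexists with randomness.
#'
#' @param p probability vector.
#' @return complexity (>= 0).
#' @export
complexity <- function(p) {
  p <- check_pmf(p)
  disequilibrium(p) * norm_entropy(p)
}

#' Ecoacoustic Global Complexity Index of a signal
#'
#' Maps an audio segment to a single point on the entropy-complexity (HxC)
#' plane in five steps: (1) unbiased autocorrelation up to `tau_max` lags and
#' its Toeplitz matrix ([acf_unbiased()], [acf_toeplitz()]); (2) singular
#' value decomposition of the matrix; (3) normalization of the singular
#' values into a histogram `P` and its Von Neumann entropy `H`
#' ([norm_entropy()]); (4) Jensen-Shannon divergence `J` between `P` and the
#' uniform reference; (5) the complexity `C = q0(M) * J * H` — the EGCI.
#'
#' The index is invariant to affine rescaling of the waveform (the
#' autocorrelation standardizes by mean and standard deviation), so
#' recording gain does not move a segment on the plane. `tau_max` is the
#' method's single free parameter: it sets the histogram size and hence the
#' resolution of the plane; 512 is the reference choice for 22-s segments at
#' 44.1 kHz.
#'
#' @param x an [acoustic_signal] or numeric vector.
#' @param tau_max lag count (default 512); must be at most `N/2`.
#' @param fs sampling rate, required when `x` is a bare numeric vector.
#' @return object of class `egci`: list with `H`, `J`, `C`, `Q`, `spectrum`
#'   (the singular-value histogram), `tau_max`, `n`, `fs`, `timestamp`,
#'   `source_id`.
#' @examples
#' p <- egci(colored_noise(2^13, alpha = 0, fs = 8000, seed = 1),
#'           tau_max = 128)
#' p            # high H, small C: white noise is the disordered endpoint
#' @export
egci <- function(x, tau_max = 512, fs = NULL) {
  x <- as_signal(x, fs)
  a <- acf_unbiased(x, tau_max)
  p <- singular_spectrum(acf_toeplitz(a))
  M <- length(p)
  H <- norm_entropy(p)
  J <- jensen_shannon(p, rep(1 / M, M))
  Q <- q0(M) * J
  structure(
    list(H = H, J = J, C = Q * H, Q = Q, spectrum = p,
         tau_max = tau_max, n = length(x$samples), fs = x$fs,
         timestamp = x$timestamp, source_id = x$source_id),
    class = "egci"
  )
}

#' @export
print.egci <- function(x, ...) {
  cat(sprintf("<egci> tau_max = %d (N = %d @ %g Hz)\n", x$tau_max, x$n, x$fs))
  cat(sprintf("  H = %.4f   J = %.4f   C = %.4f\n", x$H, x$J, x$C))
  if (!is.null(x$source_id)) cat("  source: ", x$source_id, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.egci <- function(x, ...) {
  data.frame(
    source_id = x$source_id %||% NA_character_,
    timestamp = if (is.null(x$timestamp)) as.POSIXct(NA) else x$timestamp,
    tau_max = x$tau_max, H = x$H, J = x$J, C = x$C,
    stringsAsFactors = FALSE
  )
}

#' Plot an EGCI point on the entropy-complexity plane
#'
#' Draws the complexity boundaries for the point's `tau_max` and marks the
#' segment's position.
#'
#' @param x an `egci` object.
#' @param geometry optional precomputed [hxc_boundaries()] data frame (saves
#'   recomputing the envelope for repeated plots).
#' @param ... passed to [graphics::points()].
#' @return `x`, invisibly.
#' @export
plot.egci <- function(x, geometry = NULL, ...) {
  if (is.null(geometry)) geometry <- hxc_boundaries(x$tau_max)
  plot(geometry$H, geometry$Cmax, type = "l", lty = 2,
       xlab = "Normalized entropy H", ylab = "Statistical complexity C",
       main = sprintf("HxC plane (tau_max = %d)", x$tau_max),
       ylim = c(0, max(geometry$Cmax) * 1.05))
  graphics::lines(geometry$H, geometry$Cmin, lty = 2)
  graphics::points(x$H, x$C, pch = 19, col = "red3", ...)
  invisible(x)
}

#' Compute EGCI points for a list of segments
#'
#' Batch driver over timestamped segments (e.g. from [segment_signal()] or
#' [synth_monitoring_stream()]). Degenerate (constant) segments are skipped
#' with a warning rather than aborting the run.
#'
#' @param segments list of [acoustic_signal] objects.
#' @param tau_max lag count passed to [egci()].
#' @return data frame with one row per successful segment: `source_id`,
#'   `timestamp`, `segment_index`, `tau_max`, `H`, `J`, `C`.
#' @export
egci_batch <- function(segments, tau_max = 512) {
  rows <- vector("list", length(segments))
  skipped <- 0L
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    res <- tryCatch(egci(seg, tau_max = tau_max), error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- skipped + 1L
      next
    }
    rows[[i]] <- data.frame(
      source_id = seg$source_id %||% NA_character_,
      timestamp = if (is.null(seg$timestamp)) as.POSIXct(NA) else
        seg$timestamp,
      segment_index = i, tau_max = tau_max,
      H = res$H, J = res$J, C = res$C, stringsAsFactors = FALSE
    )
  }
  if (skipped > 0)
    warning(skipped, " degenerate segment(s) skipped", call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(source_id = character(), timestamp = as.POSIXct(character()),
                      segment_index = integer(), tau_max = integer(),
                      H = numeric(), J = numeric(), C = numeric())
  attr(out, "tz") <- "UTC"
  out
}
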