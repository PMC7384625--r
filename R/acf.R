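#' Unbiased autocorrelation function
#'
#' The unbiased autocorrelation coefficient at lag tau,
#' \deqn{r_{xx}(\tau) = \frac{1}{(N-\tau)\,s^2}
#'   \sum_{i=1}^{N-\tau} (x_i - \bar x)(x_{i+\tau} - \bar x),}
#' with the sample mean and sample standard deviation (denominator N - 1)
#' computed once over the whole segment, so that \eqn{r_{xx}(0) = 1} exactly.
#' The lag count must satisfy `tau_max <= N/2`. Computation is FFT-based
#' (circular autocovariance on a zero-padded sequence, then the per-lag
#' unbiased 1/(N - tau) correction), numerically equal to the direct sum.
#'
#' The unbiased correction can push coefficients marginally outside
#' \[-1, 1\]; values are returned unclipped, as they enter the Toeplitz
#' matrix unmodified.
#'
#' @param x an [acoustic_signal] or numeric vector.
#' @param tau_max number of lags retained (lags `0 .. tau_max - 1`); must be
#'   at least 2 and at most `N/2`.
#' @return object of class `egci_acf`: list with `values` (length
#'   `tau_max`, `values[1]` is lag 0 and equals 1), `tau_max`, `n`.
#' @examples
#' a <- acf_unbiased(sin(2 * pi * (1:1000) / 50), tau_max = 100)
#' a$values[1]  # exactly 1
#' @export
acf_unbiased <- function(x, tau_max) {
  x <- if (inherits(x, "acoustic_signal")) x$samples else as.numeric(x)
  n <- length(x)
  if (!is.numeric(tau_max) || length(tau_max) != 1 || tau_max < 2)
    stop("`tau_max` must be a single integer >= 2", call. = FALSE)
  tau_max <- as.integer(tau_max)
  if (tau_max > n / 2)
    stop("`tau_max` (", tau_max, ") exceeds N/2 = ", n / 2, call. = FALSE)
  xc <- x - mean(x)
  s2 <- sum(xc^2) / (n - 1)
  if (s2 == 0)
    stop("degenerate signal: zero variance, autocorrelation undefined",
         call. = FALSE)
  m <- stats::nextn(2L * n, 2)
  f <- stats::fft(c(xc, numeric(m - n)))
  raw <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(tau_max)] / m
  taus <- 0:(tau_max - 1L)
  vals <- raw / ((n - taus) * s2)
  vals[1] <- 1
  structure(list(values = vals, tau_max = tau_max, n = n),
            class = "egci_acf")
}

#' @export
print.egci_acf <- function(x, ...) {
  cat(sprintf("<egci_acf> %d lags from a length-%d signal\n", x$tau_max, x$n))
  cat("  r[0..min(5,tau_max)-1]:",
      paste(sprintf("%.4f", utils::head(x$values, 5)), collapse = " "), "\n")
  invisible(x)
}

#' Autocorrelation Toeplitz matrix
#'
#' Assembles the symmetric diagonal-constant matrix with entry
#' `(i, j) = r_xx(|i - j|)`, whose dimension equals the retained lag count.
#' Its eigenvalue (singular) spectrum is the probability histogram behind the
#' complexity index.
#'
#' @param acf an `egci_acf` from [acf_unbiased()], or a numeric vector of
#'   autocorrelation values starting at lag 0.
#' @return a `tau_max` x `tau_max` numeric matrix with unit diagonal.
#' @examples
#' acf_toeplitz(c(1, 0.5))  # matrix(c(1, .5, .5, 1), 2)
#' @export
acf_toeplitz <- function(acf) {
  v <- if (inherits(acf, "egci_acf")) acf$values else as.numeric(acf)
  if (length(v) < 2) stop("need at least 2 lags", call. = FALSE)
  if (abs(v[1] - 1) > 1e-9)
    stop("lag-0 autocorrelation must be 1", call. = FALSE)
  stats::toeplitz(v)
}
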