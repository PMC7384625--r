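#' Entropy-complexity plane geometry
#'
#' For a fixed histogram size M, every possible histogram lands between two
#' boundary curves on the HxC plane. The boundaries are attained by
#' one-parameter extremal families:
#' \itemize{
#' \item minimum complexity: one bin with mass `p` and the remaining `M - 1`
#'   bins sharing `1 - p` equally, `p` from `1/M` (uniform, H = 1) to 1
#'   (degenerate, H = 0);
#' \item maximum complexity: one bin with mass `p`, `K - 1` bins sharing
#'   `1 - p` equally and `M - K` empty bins, with `p` in `[0, 1/K]`. As the
#'   support size K runs over `2..M` these families tile the entropy axis:
#'   the family with support K covers exactly
#'   `H` in `[log(K-1)/log M, log K / log M]`.
#' }
#' Within a family H is strictly monotone in `p`, so `Cmin(H)` and `Cmax(H)`
#' are evaluated exactly at any H by root-finding on `p`;
#' `hxc_boundaries()` samples both on a uniform H grid for plotting and
#' export. Both curves vanish at H = 0 and H = 1: complexity is zero for the
#' totally ordered and the totally disordered state.
#'
#' @param H entropy value(s) in `[0, 1]`.
#' @param M histogram size (>= 2); use the analysis `tau_max`.
#' @param grid_size number of H grid points (>= 10, default 1000).
#' @return `hxc_min_complexity()` / `hxc_max_complexity()`: numeric vector of
#'   complexities matching `H`. `hxc_boundaries()`: data frame with columns
#'   `H`, `Cmin`, `Cmax`.
#' @examples
#' g <- hxc_boundaries(64, grid_size = 101)
#' all(g$Cmax >= g$Cmin)  # TRUE
#' @name hxc_plane
NULL

# H and C of the extremal family {p, (1-p)/(K-1) x (K-1), 0 x (M-K)},
# in closed form (natural logs; normalized by log M).
fam_hc <- function(p, K, M) {
  lM <- log(M)
  q <- if (K > 1) (1 - p) / (K - 1) else 0
  plogp <- function(v) ifelse(v > 0, v * log(v), 0)
  S <- -(plogp(p) + (K - 1) * plogp(q))
  H <- S / lM
  a <- (p + 1 / M) / 2
  b <- (q + 1 / M) / 2
  cc <- 1 / (2 * M)
  Smid <- -(plogp(a) + (K - 1) * plogp(b) + (M - K) * plogp(cc))
  J <- max(0, Smid / lM - H / 2 - 1 / 2)
  list(H = H, C = q0(M) * J * H, J = J)
}

solve_family_p <- function(H, K, M, lower, upper) {
  f <- function(p) fam_hc(p, K, M)$H - H
  stats::uniroot(f, c(lower, upper), tol = 1e-13)$root
}

#' @rdname hxc_plane
#' @export
hxc_min_complexity <- function(H, M) {
  vapply(H, function(h) {
    if (h <= 0 || h >= 1) return(0)
    # support M family; H decreasing in p on [1/M, 1]
    f <- function(p) fam_hc(p, M, M)$H - h
    p <- stats::uniroot(f, c(1 / M, 1), tol = 1e-13)$root
    fam_hc(p, M, M)$C
  }, numeric(1))
}

#' @rdname hxc_plane
#' @export
hxc_max_complexity <- function(H, M) {
  lM <- log(M)
  vapply(H, function(h) {
    if (h <= 0 || h >= 1 - 1e-15) return(0)
    K <- ceiling(exp(h * lM))
    K <- max(2L, min(as.integer(K), as.integer(M)))
    # family support K covers [log(K-1), log(K)]/log M; H increasing in p
    if (log(K) / lM < h) K <- K + 1L
    if (K > 2 && log(K - 1) / lM > h) K <- K - 1L
    fl <- fam_hc(0, K, M)
    fu <- fam_hc(1 / K, K, M)
    if (h <= fl$H) return(fl$C)
    if (h >= fu$H) return(fu$C)
    p <- solve_family_p(h, K, M, 0, 1 / K)
    fam_hc(p, K, M)$C
  }, numeric(1))
}

#' @rdname hxc_plane
#' @export
hxc_boundaries <- function(M, grid_size = 1000) {
  if (!is.numeric(M) || length(M) != 1 || M < 2)
    stop("`M` must be a single integer >= 2", call. = FALSE)
  if (grid_size < 10) stop("`grid_size` must be >= 10", call. = FALSE)
  H <- seq(0, 1, length.out = grid_size)
  data.frame(H = H,
             Cmin = hxc_min_complexity(H, M),
             Cmax = hxc_max_complexity(H, M))
}

#' Colored-noise reference curve on the HxC plane
#'
#' The positions of simulated 1/f^alpha noise series on the plane: the
#' reference line against which field recordings are compared (rain and
#' other geophysical sounds track its alpha ~ 2 end, insect choruses its
#' high-entropy end). For each exponent the EGCI is averaged over several
#' independent realizations.
#'
#' @param alphas exponents to sample (default 0 to 2 in steps of 0.1).
#' @param n samples per realization (default 2^17).
#' @param fs sampling rate in Hz.
#' @param tau_max lag count for the EGCI.
#' @param seeds integer seeds, one realization per seed (default 1:10).
#' @return data frame with columns `alpha`, `H`, `C` (seed-averaged).
#' @export
noise_reference_curve <- function(alphas = seq(0, 2, by = 0.1), n = 2^17,
                                  fs = 44100, tau_max = 512, seeds = 1:10) {
  rows <- lapply(alphas, function(a) {
    pts <- vapply(seeds, function(s) {
      e <- egci(colored_noise(n, alpha = a, fs = fs, seed = s),
                tau_max = tau_max)
      c(e$H, e$C)
    }, numeric(2))
    data.frame(alpha = a, H = mean(pts[1, ]), C = mean(pts[2, ]))
  })
  do.call(rbind, rows)
}

#' Pairwise Jensen-Shannon divergence matrix
#'
#' Peer-to-peer comparison of recordings through their singular spectra:
#' entry (i, j) is `jensen_shannon(p_i, p_j)`. Segments close on the HxC
#' plane have low divergence; the farthest pair attains the largest entry.
#'
#' @param spectra list of probability vectors (all the same length), or list
#'   of `egci` objects (their `$spectrum` is used).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
divergence_matrix <- function(spectra) {
  if (length(spectra) == 0) stop("`spectra` is empty", call. = FALSE)
  ps <- lapply(spectra, function(s) if (inherits(s, "egci")) s$spectrum else s)
  M <- length(ps[[1]])
  if (!all(vapply(ps, length, integer(1)) == M))
    stop("all spectra must have the same length", call. = FALSE)
  k <- length(ps)
  out <- matrix(0, k, k)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      out[i, j] <- out[j, i] <- jensen_shannon(ps[[i]], ps[[j]])
    }
  }
  nms <- names(spectra)
  if (!is.null(nms)) dimnames(out) <- list(nms, nms)
  out
}
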