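# Orthonormal decomposition filters. dec_lo in ascending index order;
# dec_hi is the quadrature mirror g[k] = (-1)^k h[L-1-k].
wavelet_filters <- function(wavelet) {
  h <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db4 = c(-0.010597401784997278, 0.032883011666982945,
            0.030841381835986965, -0.18703481171888114,
            -0.02798376941698385, 0.6308807679295904,
            0.7148465705525415, 0.23037781330885523),
    stop("unsupported wavelet: ", wavelet, " (use 'db4' or 'haar')"))
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  list(lo = h, hi = g)
}

# One periodized analysis step: circular convolution with filter f and
# dyadic downsampling. Orthonormal for even n, so energy is preserved
# across each lo/hi split.
wp_step <- function(x, f) {
  n <- length(x)
  if (n %% 2L == 1L) {  # extend odd lengths by repeating the last sample
    x <- c(x, x[n]); n <- n + 1L
  }
  L <- length(f)
  idx <- outer(seq(0L, n - 2L, by = 2L), seq_len(L) - 1L, `+`) %% n + 1L
  as.vector(matrix(x[idx], ncol = L) %*% f)
}

#' Wavelet packet decomposition to a fixed depth
#'
#' Full binary filter-bank decomposition with periodic boundary handling:
#' at each level both the low-pass and high-pass branches are split again,
#' yielding `2^depth` terminal frequency bands in natural (filter-bank)
#' order. The filters are orthonormal, so for even dyadic lengths the total
#' coefficient energy equals the signal energy.
#'
#' @param x numeric series.
#' @param wavelet `"db4"` or `"haar"`.
#' @param depth decomposition level (>= 1).
#' @return list of `2^depth` numeric coefficient vectors.
#' @export
wp_decompose <- function(x, wavelet = "db4", depth = 3L) {
  stopifnot(depth >= 1)
  flt <- wavelet_filters(wavelet)
  if (length(x) < 2^depth)
    stop(sprintf("series too short for depth %d decomposition", depth))
  nodes <- list(as.double(x))
  for (lev in seq_len(depth)) {
    nodes <- unlist(lapply(nodes, function(v)
      list(wp_step(v, flt$lo), wp_step(v, flt$hi))), recursive = FALSE)
  }
  nodes
}

#' Shannon entropy of a band-energy distribution
#'
#' Normalises the energies to proportions `p_j = E_j / sum(E)` and returns
#' `-sum(p_j * ln(p_j))` with the convention `0 * ln(0) = 0`. Bounded by
#' `ln(length(E))`.
#'
#' @param E non-negative band energies, not all zero.
#' @return scalar in `[0, ln(length(E))]`.
#' @export
wpen_from_energies <- function(E) {
  if (any(E < 0)) stop("band energies must be non-negative")
  tot <- sum(E)
  if (tot == 0) stop("total energy is zero: entropy undefined")
  p <- E / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Wavelet packet entropy of a time series
#'
#' Decomposes the series into `2^depth` terminal frequency bands
#' ([wp_decompose()]), computes each band's energy as the sum of squared
#' coefficients, and returns the Shannon entropy of the normalised energy
#' distribution ([wpen_from_energies()]). A flat spectrum gives the maximum
#' `ln(2^depth)`; energy concentrated in one band gives 0. Because the
#' proportions are energy ratios the statistic is invariant to amplitude
#' scaling. An all-zero signal is an error (undefined distribution).
#'
#' @inheritParams approximate_entropy
#' @return scalar in `[0, depth * ln(2)]`.
#' @export
wavelet_packet_entropy <- function(x, params = entropy_params()) {
  nodes <- wp_decompose(x, params$wavelet, params$depth)
  wpen_from_energies(vapply(nodes, function(v) sum(v^2), numeric(1)))
}
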