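#' Parameters for the nonlinear entropy features
#'
#' @param m embedding dimension for the template entropies (>= 1). The
#'   literature recommends 2--5 for short physiological windows; 2 is the
#'   common choice and the default.
#' @param r_frac match tolerance as a fraction of the segment standard
#'   deviation; recommended range 0.1--0.25, default 0.2. The tolerance `r =
#'   r_frac * sd(x)` is recomputed per segment channel, which makes the
#'   template entropies invariant to amplitude scaling.
#' @param wavelet wavelet family for the packet decomposition; `"db4"`
#'   (default) or `"haar"`.
#' @param depth wavelet packet decomposition level (>= 1); `2^depth`
#'   terminal bands, default 3.
#' @return list of class `"entropy_params"`.
#' @export
entropy_params <- function(m = 2L, r_frac = 0.2, wavelet = "db4", depth = 3L) {
  stopifnot(m >= 1, r_frac > 0, depth >= 1)
  structure(list(m = as.integer(m), r_frac = r_frac,
                 wavelet = wavelet, depth = as.integer(depth)),
            class = "entropy_params")
}

# Shared input checks; returns the resolved tolerance r, or NA for a
# zero-variance series (handled by convention in each caller).
resolve_tolerance <- function(x, params, min_n) {
  if (!is.numeric(x) || anyNA(x)) stop("series must be numeric without NA")
  if (length(x) < min_n)
    stop(sprintf("series too short: N = %d but N >= %d required",
                 length(x), min_n))
  s <- sd(x)
  if (s == 0) return(NA_real_)
  params$r_frac * s
}

#' Approximate entropy of a time series
#'
#' Regularity statistic comparing template-match frequencies at embedding
#' dimensions `m` and `m + 1` under the Chebyshev (maximum-coordinate)
#' distance, with self-matches included and matches counted as `d <= r`.
#' Returns `Phi_m(r) - Phi_{m+1}(r)` where `Phi` averages the log of the
#' per-template match fractions. Larger values indicate a more complex,
#' less predictable series.
#'
#' A zero-variance series returns 0 by convention (perfect regularity).
#'
#' @param x numeric series of length `N >= m + 2`.
#' @param params an [entropy_params()] object.
#' @return non-negative scalar.
#' @export
approximate_entropy <- function(x, params = entropy_params()) {
  r <- resolve_tolerance(x, params, params$m + 2L)
  if (is.na(r)) return(0)
  .apen_cpp(as.double(x), params$m, r)
}

#' Sample entropy of a time series
#'
#' Self-match-free variant of approximate entropy: with `B` the fraction of
#' matching template pairs at dimension `m` (over the first `N - m`
#' templates, pairs `i != j`) and `A` the same at `m + 1`, returns
#' `-ln(A / B)`. Since every `(m+1)`-match is an `m`-match, `A <= B` and the
#' value is non-negative.
#'
#' When no template pair matches at either dimension the statistic is
#' undefined; this is signalled as an error by default, or as `NA` with
#' `if_undefined = "na"`. A zero-variance series returns 0 by convention.
#'
#' @inheritParams approximate_entropy
#' @param if_undefined `"error"` (default) or `"na"`.
#' @return non-negative scalar.
#' @export
sample_entropy <- function(x, params = entropy_params(),
                           if_undefined = c("error", "na")) {
  if_undefined <- match.arg(if_undefined)
  r <- resolve_tolerance(x, params, params$m + 2L)
  if (is.na(r)) return(0)
  v <- .saen_cpp(as.double(x), params$m, r)
  if (is.na(v) && if_undefined == "error")
    stop("sample entropy undefined: no template matches at dimension m or m+1")
  v
}

# Gaussian-type fuzzy membership of a template distance: 0.5 exactly at d == r.
fuzzy_membership <- function(d, r) exp(-log(2) * (d / r)^2)

#' Fuzzy entropy of a time series
#'
#' Like sample entropy but with the hard match threshold replaced by the
#' smooth membership `A_ij = exp(-ln(2) * (D_ij / r)^2)` of the Chebyshev
#' template distance `D_ij` (membership 1/2 exactly at `D = r`). Self-pairs
#' are excluded; `Phi` is the plain average of the per-template mean
#' memberships `C_i`, and the value is `ln Phi_m - ln Phi_{m+1}`.
#'
#' Note the template mean is deliberately not subtracted before the distance
#' computation, and the membership exponent is fixed at 2.
#' A zero-variance series returns 0 by convention.
#'
#' @inheritParams approximate_entropy
#' @return non-negative scalar.
#' @export
fuzzy_entropy <- function(x, params = entropy_params()) {
  r <- resolve_tolerance(x, params, params$m + 2L)
  if (is.na(r)) return(0)
  .fuen_cpp(as.double(x), params$m, r)
}

#' Extract the four entropy features from one channel window
#'
#' Computes, in fixed order: approximate entropy, sample entropy, fuzzy
#' entropy, wavelet packet entropy. Errors from individual features are
#' re-signalled with the channel name attached.
#'
#' @param x numeric series (one channel of one segment).
#' @param channel channel name.
#' @param params an [entropy_params()] object.
#' @return object of class `"channel_features"`: list with `channel`,
#'   `apen`, `saen`, `fuen`, `wpen`.
#' @export
extract_channel_features <- function(x, channel, params = entropy_params()) {
  vals <- tryCatch(
    list(apen = approximate_entropy(x, params),
         saen = sample_entropy(x, params),
         fuen = fuzzy_entropy(x, params),
         wpen = wavelet_packet_entropy(x, params)),
    error = function(e)
      stop(sprintf("channel '%s': %s", channel, conditionMessage(e)),
           call. = FALSE))
  channel_features(channel, vals$apen, vals$saen, vals$fuen, vals$wpen)
}

#' Build a fused feature table from segments
#'
#' Runs [extract_channel_features()] on every channel of every segment and
#' fuses the per-channel features by concatenation ([fuse()]): one row per
#' segment with columns `"<channel>.<feature>"` in channel order, features
#' in the fixed order (apen, saen, fuen, wpen), plus provenance columns
#' `parent_id`, `window_index` and the class `label`.
#'
#' @param segments list of segments from [segment_recording()].
#' @param params an [entropy_params()] object.
#' @param channels channels to use, in order; defaults to the channel order
#'   of the first segment.
#' @return data.frame (a feature table).
#' @export
extract_features <- function(segments, params = entropy_params(),
                             channels = NULL) {
  stopifnot(length(segments) > 0)
  if (is.null(channels)) channels <- names(segments[[1L]]$channels)
  rows <- lapply(segments, function(seg) {
    feats <- lapply(channels, function(ch) {
      if (is.null(seg$channels[[ch]]))
        stop(sprintf("segment %s/%d lacks channel '%s'",
                     seg$parent_id, seg$window_index, ch))
      extract_channel_features(seg$channels[[ch]], ch, params)
    })
    v <- fuse(feats)
    cbind(data.frame(parent_id = seg$parent_id,
                     window_index = seg$window_index,
                     label = seg$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
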