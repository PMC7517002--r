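# Fixed feature order within each channel block.
FEATURE_ORDER <- c("apen", "saen", "fuen", "wpen")

#' Per-channel entropy feature bundle
#'
#' @param channel channel name.
#' @param apen,saen,fuen,wpen the four entropy values (finite; `wpen >= 0`).
#' @return object of class `"channel_features"`.
#' @export
channel_features <- function(channel, apen, saen, fuen, wpen) {
  vals <- c(apen = apen, saen = saen, fuen = fuen, wpen = wpen)
  if (!all(is.finite(vals))) stop("channel '", channel,
                                  "': non-finite feature value")
  if (wpen < 0) stop("wpen must be non-negative")
  structure(list(channel = as.character(channel),
                 apen = apen, saen = saen, fuen = fuen, wpen = wpen),
            class = "channel_features")
}

#' Fuse per-channel features into one vector
#'
#' Early feature-level fusion: the four entropy features of each channel are
#' concatenated in channel order, giving a `4 * n_channels` vector (16
#' dimensions for the usual four peripheral channels). Fusion adds no
#' transformation beyond concatenation, so single-channel feature sets are
#' exact sub-projections of the fused vector.
#'
#' @param per_channel list of [channel_features()] in the desired order.
#' @return named numeric vector; names are `"<channel>.<feature>"`.
#' @export
fuse <- function(per_channel) {
  stopifnot(length(per_channel) > 0)
  chans <- vapply(per_channel, function(cf) cf$channel, character(1))
  if (anyDuplicated(chans)) stop("duplicate channel name in fusion: ",
                                 chans[duplicated(chans)][1L])
  out <- unlist(lapply(per_channel, function(cf)
    unlist(cf[FEATURE_ORDER])))
  names(out) <- as.vector(t(outer(chans, FEATURE_ORDER, paste, sep = ".")))
  out
}

# Feature columns of a feature table (everything except provenance/label).
feature_columns <- function(df) {
  setdiff(names(df), c("parent_id", "window_index", "label"))
}

#' Fit a z-score scaler on a training feature table
#'
#' Learns per-column mean and standard deviation from the training rows
#' only; applying it to test rows never leaks test statistics. Columns with
#' zero variance are passed through unchanged.
#'
#' @param train feature table (data.frame) or numeric matrix.
#' @param cols columns to scale; defaults to all feature columns.
#' @return object of class `"feature_scaler"`.
#' @export
fit_scaler <- function(train, cols = NULL) {
  if (is.matrix(train)) train <- as.data.frame(train)
  if (nrow(train) == 0) stop("cannot fit a scaler on an empty table")
  if (is.null(cols)) cols <- feature_columns(train)
  m <- vapply(train[cols], mean, numeric(1))
  s <- vapply(train[cols], sd, numeric(1))
  const <- is.na(s) | s == 0  # zero-variance guard: full passthrough
  m[const] <- 0
  s[const] <- 1
  structure(list(cols = cols, center = m, scale = s),
            class = "feature_scaler")
}

#' Apply (or invert) a fitted z-score scaler
#'
#' @param df feature table or matrix with the scaler's columns.
#' @param scaler a [fit_scaler()] result.
#' @param inverse undo the transform instead of applying it.
#' @return table of the same shape.
#' @export
apply_scaler <- function(df, scaler, inverse = FALSE) {
  if (!inherits(scaler, "feature_scaler"))
    stop("`scaler` must come from fit_scaler()")
  was_matrix <- is.matrix(df)
  if (was_matrix) df <- as.data.frame(df)
  if (!all(scaler$cols %in% names(df)))
    stop("table lacks columns the scaler was fitted on")
  for (j in scaler$cols) {
    df[[j]] <- if (inverse) df[[j]] * scaler$scale[[j]] + scaler$center[[j]]
               else (df[[j]] - scaler$center[[j]]) / scaler$scale[[j]]
  }
  if (was_matrix) as.matrix(df) else df
}

# Numeric matrix of the feature columns, plus the label factor.
feature_matrix <- function(df, cols = NULL) {
  if (is.null(cols)) cols <- feature_columns(df)
  as.matrix(df[cols])
}
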