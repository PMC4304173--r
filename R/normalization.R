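#' Normalization parameters
#'
#' @param nonpositive_factor Fraction of the minimum positive value used to
#'   replace values <= 0 (default 0.95, i.e. 95\% of the minimum positive
#'   value present in a sample).
#' @param quantile_grid_size Number of equally spaced probabilities used to
#'   tabulate the reference quantile curve (default 1001).
#' @return A \code{normalization_params} list.
#' @export
normalization_params <- function(nonpositive_factor = 0.95,
                                 quantile_grid_size = 1001L) {
  stopifnot(is.numeric(nonpositive_factor), length(nonpositive_factor) == 1,
            nonpositive_factor > 0, nonpositive_factor < 1)
  quantile_grid_size <- as.integer(quantile_grid_size)
  stopifnot(quantile_grid_size >= 2L)
  structure(list(nonpositive_factor = nonpositive_factor,
                 quantile_grid_size = quantile_grid_size),
            class = "normalization_params")
}

#' Linearize values deposited on a logarithmic scale
#'
#' Datasets deposited as logarithms are converted back to the linear scale
#' before any further processing; missing values stay missing.
#'
#' @param values Numeric vector (NA = missing).
#' @param scale One of \code{"linear"}, \code{"log2"}, \code{"log10"},
#'   \code{"ln"}.
#' @return Numeric vector on the linear scale.
#' @export
linearize <- function(values, scale) {
  check_scale(scale)
  switch(scale,
         linear = values,
         log2 = 2^values,
         log10 = 10^values,
         ln = exp(values))
}

#' Replace non-positive expression values
#'
#' Values equal to or lower than zero are replaced by a fixed fraction
#' (default 95\%) of the minimum strictly positive value present in the
#' sample, so that ratios between pools stay defined while flagging
#' signal below the detection floor. Missing values are left missing.
#'
#' @param values Numeric vector; at least one strictly positive value.
#' @param factor Replacement fraction in (0, 1); default 0.95.
#' @return Numeric vector with all non-missing values strictly positive.
#' @export
replace_nonpositive <- function(values, factor = 0.95) {
  stopifnot(factor > 0, factor < 1)
  pos <- values[!is.na(values) & values > 0]
  if (length(pos) == 0) stop("sample has no positive signal")
  floor_val <- factor * min(pos)
  values[!is.na(values) & values <= 0] <- floor_val
  values
}

#' Intra-sample normalization as percentage of the mean
#'
#' Each value is expressed as a percentage of the sample mean, so every
#' sample's non-missing values average exactly 100 regardless of the
#' platform's dynamic range. Missing values are excluded from the mean
#' and stay missing.
#'
#' @param values Numeric vector, all non-missing values finite and > 0
#'   (apply \code{\link{replace_nonpositive}} first).
#' @return Numeric vector with mean 100 over non-missing entries.
#' @export
normalize_intra <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) == 0) stop("cannot normalize an empty sample")
  stopifnot(all(is.finite(obs)), all(obs > 0))
  100 * values / mean(obs)
}

#' Inter-sample scaled quantile normalization
#'
#' Maps every sample onto a common reference distribution so that samples
#' from platforms with different probe counts become comparable. The
#' reference is the pointwise mean of all samples' empirical quantile
#' functions; each value is then replaced by the reference quantile at its
#' own within-sample quantile position (midrank convention for ties).
#'
#' Each sample's empirical quantile function interpolates linearly through
#' the points \eqn{((i-1)/(n-1), x_{(i)})} (the convention of
#' \code{stats::quantile} type 7). The reference curve is tabulated on the
#' union of \code{quantile_grid_size} equally spaced probabilities and
#' every sample's own quantile positions, which makes the evaluation of
#' the piecewise-linear mean curve exact rather than grid-approximate.
#' With equal-length samples this reduces to classical quantile
#' normalization: all sorted output vectors coincide.
#'
#' @param samples List of numeric vectors (possibly different lengths;
#'   NA entries are carried through untouched and ignored in the curves).
#' @param params A \code{\link{normalization_params}} object.
#' @return List of numeric vectors, same lengths and NA patterns as the
#'   input, each mapped onto the reference distribution. Rank order within
#'   each sample is preserved.
#' @export
scaled_quantile_normalize <- function(samples, params = normalization_params()) {
  stopifnot(is.list(samples))
  if (length(samples) < 2) stop("scaled quantile normalization needs >= 2 samples")
  obs <- lapply(samples, function(v) v[!is.na(v)])
  if (any(vapply(obs, length, 0L) == 0)) stop("empty sample in quantile normalization")

  knots <- lapply(obs, function(v) {
    n <- length(v)
    if (n == 1) 0.5 else (seq_len(n) - 1) / (n - 1)
  })
  grid <- sort(unique(c(seq(0, 1, length.out = params$quantile_grid_size),
                        unlist(knots))))
  # reference = pointwise mean of the per-sample quantile curves on the grid
  curves <- vapply(obs, function(v) {
    v <- sort(v)
    if (length(v) == 1) rep(v, length(grid))
    else stats::approx(x = (seq_along(v) - 1) / (length(v) - 1), y = v,
                       xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  reference <- rowMeans(curves)

  lapply(samples, function(v) {
    out <- v
    ok <- !is.na(v)
    x <- v[ok]
    n <- length(x)
    p <- if (n == 1) 0.5 else (midrank(x) - 1) / (n - 1)
    out[ok] <- stats::approx(grid, reference, xout = p, rule = 2)$y
    out
  })
}

#' Full per-sample normalization chain
#'
#' Applies, in order: linearization of log-scale deposits, replacement of
#' non-positive values, intra-sample percent-of-mean normalization, then
#' inter-sample scaled quantile normalization jointly across all supplied
#' samples (both compared pools together, so pool ratios share one scale).
#'
#' @param datasets List of \code{sample_dataset} objects (raw values).
#' @param params A \code{\link{normalization_params}} object.
#' @return The list of datasets with \code{values} replaced by normalized
#'   values and \code{scale} set to \code{"linear"}.
#' @export
normalize_datasets <- function(datasets, params = normalization_params()) {
  stopifnot(length(datasets) >= 2)
  pre <- lapply(datasets, function(d) {
    v <- linearize(d$values, d$scale)
    v <- replace_nonpositive(v, params$nonpositive_factor)
    normalize_intra(v)
  })
  post <- scaled_quantile_normalize(pre, params)
  mapply(function(d, v) {
    names(v) <- names(d$values)
    d$values <- v
    d$scale <- "linear"
    d
  }, datasets, post, SIMPLIFY = FALSE)
}

# midrank: average rank for ties, 1..n scale
midrank <- function(x) rank(x, ties.method = "average")
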