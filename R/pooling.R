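#' Integrate normalized data points into a pooled expression table
#'
#' The expression value of each locus in a biological condition is the
#' unweighted mean of all available data points for that locus, flattened
#' across all samples and probes of the pool (so a sample measuring a
#' locus with 3 probes contributes 3 points). Alongside the mean, the
#' number of data points and the standard deviation as a percentage of
#' the mean are reported.
#'
#' @param points Long-form data frame of data points with columns
#'   \code{symbol} and \code{value} (as produced by
#'   \code{\link{decode_probes}}, rows from all samples of the pool
#'   concatenated).
#' @param pool_id Identifier of the biological condition.
#' @return A data frame of class \code{pool_expression} with columns
#'   \code{symbol}, \code{mean_value}, \code{n_points}, \code{sd_percent},
#'   one row per locus with at least one data point, ordered by symbol.
#'   The SD is the population (denominator n) standard deviation;
#'   \code{sd_percent} is 0 whenever \code{n_points} is 1. Attributes:
#'   \code{pool_id}, \code{n_data_points} (total points pooled).
#' @export
pool_values <- function(points, pool_id = "pool") {
  stopifnot(is.data.frame(points), all(c("symbol", "value") %in% names(points)))
  stopifnot(all(is.finite(points$value)))
  sym <- factor(points$symbol)
  n <- as.integer(tabulate(sym, nbins = nlevels(sym)))
  sums <- vapply(split(points$value, sym), sum, 0)
  mu <- sums / n
  sqsum <- vapply(split(points$value, sym), function(v) sum(v * v), 0)
  pop_var <- pmax(sqsum / n - mu^2, 0)
  out <- data.frame(symbol = levels(sym),
                    mean_value = unname(mu),
                    n_points = n,
                    sd_percent = unname(100 * sqrt(pop_var) / mu),
                    stringsAsFactors = FALSE)
  out$sd_percent[out$n_points == 1L] <- 0
  out <- out[order(out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pool_id") <- as.character(pool_id)
  attr(out, "n_data_points") <- nrow(points)
  class(out) <- c("pool_expression", "data.frame")
  out
}

#' Correlation between two pooled transcriptome maps
#'
#' Pearson correlation of log10 pooled mean values over the loci shared by
#' two pools, with a two-sided p-value from the standard t transform. Used
#' e.g. to check that two conditions give largely overlapping maps (the
#' male-vs-female comparison pattern: high r, a handful of sex-biased
#' outliers such as XIST).
#'
#' @param pool_x,pool_y \code{pool_expression} tables.
#' @return A list with \code{r}, \code{p} and \code{n_shared}.
#' @export
compute_pool_correlation <- function(pool_x, pool_y) {
  stopifnot(inherits(pool_x, "pool_expression"),
            inherits(pool_y, "pool_expression"))
  shared <- intersect(pool_x$symbol, pool_y$symbol)
  if (length(shared) < 3) stop("fewer than 3 shared loci between pools")
  lx <- log10(pool_x$mean_value[match(shared, pool_x$symbol)])
  ly <- log10(pool_y$mean_value[match(shared, pool_y$symbol)])
  ct <- stats::cor.test(lx, ly, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n_shared = length(shared))
}
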