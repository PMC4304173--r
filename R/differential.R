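#' Parameters for differential transcriptome mapping
#'
#' Defaults are the standard map parameters: 500,000 bp segments sliding
#' by 250,000 bp, a 12,500 bp window for single-gene maps, extreme-gene
#' flags at the highest and lowest 2.5th percentile of the ratio
#' distribution, calls at corrected q < 0.05 with at least 3 extreme
#' genes, and a minimum of 5 data points for ranked gene lists.
#'
#' @param window Segment window size in bp.
#' @param shift Segment shift in bp; \code{window >= shift > 0}.
#' @param gene_window Window size for the single-gene map in bp.
#' @param tail Fraction flagged in each ratio tail (0 < tail < 0.5).
#' @param q_threshold Significance threshold on corrected q-values.
#' @param min_extreme_genes Minimum extreme genes for a segment call.
#' @param min_data_points Minimum data points (both pools) for ranked
#'   gene lists.
#' @param correction Multiple-testing correction, \code{"bh"}
#'   (Benjamini-Hochberg, default) or \code{"bonferroni"}.
#' @return A \code{map_params} list.
#' @export
map_params <- function(window = 500000L, shift = 250000L,
                       gene_window = 12500L, tail = 0.025,
                       q_threshold = 0.05, min_extreme_genes = 3L,
                       min_data_points = 5L, correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(window >= shift, shift > 0, tail > 0, tail < 0.5,
            q_threshold > 0, min_extreme_genes >= 1, min_data_points >= 1,
            gene_window > 0)
  structure(list(window = as.integer(window), shift = as.integer(shift),
                 gene_window = as.integer(gene_window), tail = tail,
                 q_threshold = q_threshold,
                 min_extreme_genes = as.integer(min_extreme_genes),
                 min_data_points = as.integer(min_data_points),
                 correction = correction),
            class = "map_params")
}

#' Per-locus differential table between two pools
#'
#' One entry per locus having a pooled value in both conditions; loci seen
#' in only one pool are excluded. The ratio is pool A mean over pool B
#' mean.
#'
#' @param pool_a,pool_b \code{pool_expression} tables (numerator A,
#'   denominator B), on the common normalized scale.
#' @return A data frame of class \code{differential_table} with columns
#'   \code{symbol}, \code{value_A}, \code{value_B}, \code{ratio},
#'   \code{n_points_A}, \code{n_points_B}, \code{sd_percent_A},
#'   \code{sd_percent_B}, \code{flag} (initially \code{"none"};
#'   see \code{\link{flag_extremes}}).
#' @export
compute_differential <- function(pool_a, pool_b) {
  stopifnot(inherits(pool_a, "pool_expression"),
            inherits(pool_b, "pool_expression"))
  shared <- intersect(pool_a$symbol, pool_b$symbol)
  if (length(shared) == 0) stop("no loci shared between the two pools")
  ia <- match(shared, pool_a$symbol)
  ib <- match(shared, pool_b$symbol)
  out <- data.frame(symbol = shared,
                    value_A = pool_a$mean_value[ia],
                    value_B = pool_b$mean_value[ib],
                    ratio = pool_a$mean_value[ia] / pool_b$mean_value[ib],
                    n_points_A = pool_a$n_points[ia],
                    n_points_B = pool_b$n_points[ib],
                    sd_percent_A = pool_a$sd_percent[ia],
                    sd_percent_B = pool_b$sd_percent[ib],
                    flag = "none",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Flag extreme loci at the ratio-distribution tails
#'
#' Loci whose differential ratio falls within the highest or lowest
#' \code{tail} fraction of the empirical ratio distribution are flagged
#' \code{"over"} / \code{"under"}. Thresholds are the empirical
#' \code{tail} and \code{1 - tail} quantiles of all ratios; comparisons
#' are inclusive, so ties sitting exactly at a threshold are flagged.
#'
#' @param entries A \code{differential_table}.
#' @param tail Tail fraction; \code{tail = 0} flags nothing.
#' @return The table with its \code{flag} column set. Attributes
#'   \code{threshold_over} / \code{threshold_under} record the cutoffs.
#' @export
flag_extremes <- function(entries, tail = 0.025) {
  stopifnot(inherits(entries, "differential_table"), nrow(entries) > 0,
            tail >= 0, tail < 0.5)
  entries$flag <- "none"
  if (tail > 0) {
    lo <- unname(stats::quantile(entries$ratio, tail, type = 7))
    hi <- unname(stats::quantile(entries$ratio, 1 - tail, type = 7))
    over <- entries$ratio >= hi
    under <- entries$ratio <= lo
    both <- over & under   # degenerate (all-equal) distribution
    entries$flag[over & !both] <- "over"
    entries$flag[under & !both] <- "under"
    attr(entries, "threshold_over") <- hi
    attr(entries, "threshold_under") <- lo
  }
  entries
}

#' Build the sliding segment grid over an annotation
#'
#' Per chromosome, windows \code{[1 + i*shift, window + i*shift]} for
#' i = 0, 1, 2, ... are emitted while the window start does not exceed the
#' chromosome extent (the maximum annotated locus end). A locus belongs to
#' every window containing its start coordinate; with a 50\% overlap each
#' interior locus falls in exactly two windows.
#'
#' @param annotation A \code{locus_annotation}.
#' @param window,shift Window size and shift in bp.
#' @return Data frame with columns \code{chromosome}, \code{start},
#'   \code{end}, plus a list-column \code{symbols} of member loci.
#' @export
build_windows <- function(annotation, window = 500000L, shift = 250000L) {
  stopifnot(inherits(annotation, "locus_annotation"), nrow(annotation) > 0,
            window >= shift, shift > 0)
  pieces <- lapply(split(annotation, annotation$chromosome), function(ann) {
    extent <- max(ann$end)
    starts <- seq(1, extent, by = shift)
    ends <- starts + window - 1
    # window index range covering each locus start (0-based window indices)
    i_hi <- (ann$start - 1) %/% shift
    i_lo <- pmax(0, ceiling((ann$start - window) / shift))
    members <- vector("list", length(starts))
    for (j in seq_along(ann$start)) {
      idx <- seq(i_lo[j], i_hi[j]) + 1
      idx <- idx[idx <= length(starts)]
      for (i in idx) members[[i]] <- c(members[[i]], ann$symbol[j])
    }
    data.frame(chromosome = rep(ann$chromosome[1], length(starts)),
               start = starts, end = ends,
               symbols = I(members),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Hypergeometric segment p-value
#'
#' Upper-tail probability that a window of \code{n} loci contains at least
#' \code{k} flagged loci when \code{K} of the \code{N} loci with ratios
#' are flagged genome-wide: \eqn{P[X \ge k]} for
#' \eqn{X \sim Hypergeometric(N, K, n)}.
#'
#' @param N Total loci with ratios.
#' @param K Flagged loci in the tail, genome-wide.
#' @param n Window loci with ratios.
#' @param k Flagged loci in the window.
#' @return The p-value in (0, 1]; \code{k = 0} gives exactly 1.
#' @export
segment_pvalue <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (K > N || n > N || k < 0 || k > min(K, n)) {
    stop(sprintf("inconsistent hypergeometric parameters N=%d K=%d n=%d k=%d",
                 N, K, n, k))
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Multiple-testing correction of segment p-values
#'
#' Benjamini-Hochberg step-up q-values (default) or Bonferroni, over the
#' full family of window-tail tests.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param method \code{"bh"} or \code{"bonferroni"}.
#' @return Vector of q-values, same order as input.
#' @export
correct_q <- function(pvalues, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  stats::p.adjust(pvalues, method = if (method == "bh") "BH" else "bonferroni")
}

#' Call over/under-expressed genomic segments
#'
#' Every window holding at least one locus with a ratio is tested in both
#' tails with the hypergeometric p-value; q-values are corrected across
#' all window-tail tests jointly. A segment is called over- or
#' under-expressed when its q-value is below \code{q_threshold} AND it
#' contains at least \code{min_extreme_genes} flagged loci in that tail.
#' Overlapping called segments whose flagged-gene sets share more than
#' 50\% of the smaller set are deduplicated, keeping the lowest-q segment
#' (ties broken by larger absolute log ratio). The segment ratio is the
#' mean of member pool-A values over the mean of member pool-B values.
#'
#' @param entries A flagged \code{differential_table}.
#' @param windows Segment grid from \code{\link{build_windows}}.
#' @param params A \code{\link{map_params}} object.
#' @param dedup Deduplicate overlapping called segments (default TRUE).
#' @param min_extreme_genes Override of \code{params$min_extreme_genes}
#'   (used internally by the single-gene map).
#' @return Data frame of class \code{segment_results}: one row per tested
#'   window with \code{chromosome}, \code{start}, \code{end}, \code{n},
#'   \code{ratio}, \code{k_over}, \code{k_under}, \code{p_over},
#'   \code{p_under}, \code{q_over}, \code{q_under}, \code{call}, and
#'   list-columns \code{symbols} (members with ratios), \code{flagged}
#'   (members flagged in the calling tail, empty when call is none).
#'   Windows with zero member loci carrying ratios emit no test.
#' @export
call_segments <- function(entries, windows, params = map_params(),
                          dedup = TRUE,
                          min_extreme_genes = params$min_extreme_genes) {
  stopifnot(inherits(entries, "differential_table"))
  N <- nrow(entries)
  K_over <- sum(entries$flag == "over")
  K_under <- sum(entries$flag == "under")
  idx <- stats::setNames(seq_len(N), entries$symbol)

  rows <- lapply(seq_len(nrow(windows)), function(i) {
    syms <- windows$symbols[[i]]
    j <- idx[syms[syms %in% names(idx)]]
    n <- length(j)
    if (n == 0) return(NULL)
    k_over <- sum(entries$flag[j] == "over")
    k_under <- sum(entries$flag[j] == "under")
    data.frame(chromosome = windows$chromosome[i],
               start = windows$start[i], end = windows$end[i],
               n = n, ratio = mean(entries$value_A[j]) / mean(entries$value_B[j]),
               k_over = k_over, k_under = k_under,
               p_over = segment_pvalue(N, K_over, n, k_over),
               p_under = segment_pvalue(N, K_under, n, k_under),
               symbols = I(list(unname(entries$symbol[j]))),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    out <- data.frame()
    class(out) <- c("segment_results", "data.frame")
    return(out)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  q <- correct_q(c(res$p_over, res$p_under), params$correction)
  m <- nrow(res)
  res$q_over <- q[seq_len(m)]
  res$q_under <- q[m + seq_len(m)]

  call_over <- res$q_over < params$q_threshold & res$k_over >= min_extreme_genes
  call_under <- res$q_under < params$q_threshold & res$k_under >= min_extreme_genes
  res$call <- ifelse(call_over & call_under,
                     ifelse(res$q_over <= res$q_under, "over", "under"),
                     ifelse(call_over, "over",
                            ifelse(call_under, "under", "none")))
  res$flagged <- I(lapply(seq_len(m), function(i) {
    if (res$call[i] == "none") return(character(0))
    syms <- res$symbols[[i]]
    fl <- entries$flag[idx[syms]]
    syms[fl == res$call[i]]
  }))
  if (dedup) res <- dedup_segments(res)
  class(res) <- c("segment_results", "data.frame")
  res
}

# Remove overlapping called segments with similar flagged-gene content:
# among genomically overlapping calls sharing > 50% of the smaller
# flagged set, keep the lowest q (tie: larger |log ratio|).
dedup_segments <- function(res) {
  called <- which(res$call != "none")
  if (length(called) <= 1) return(res)
  qc <- ifelse(res$call[called] == "over", res$q_over[called], res$q_under[called])
  ord <- called[order(qc, -abs(log(res$ratio[called])))]
  kept <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (j in kept) {
      if (res$chromosome[i] == res$chromosome[j] &&
          res$start[i] <= res$end[j] && res$end[i] >= res$start[j]) {
        a <- res$flagged[[i]]; b <- res$flagged[[j]]
        smaller <- min(length(a), length(b))
        if (smaller > 0 && length(intersect(a, b)) > 0.5 * smaller) {
          clash <- TRUE
          break
        }
      }
    }
    if (clash) {
      res$call[i] <- "none"
      res$flagged[[i]] <- character(0)
    } else {
      kept <- c(kept, i)
    }
  }
  res
}

#' Single-gene significance map
#'
#' Re-runs the segment machinery with a small window (default 12,500 bp,
#' shifted by half its size, about a quarter of a mean gene length) and a
#' minimum of one extreme gene, so a significant window almost always
#' pinpoints a single locus. When a significant window contains more than
#' one locus, the call attaches to the flagged locus only if its pooled
#' expression value, in the pool where it is higher, strictly exceeds the
#' corresponding value of every other member locus (the "prevail" rule);
#' otherwise the call is dropped and recorded.
#'
#' @param entries A flagged \code{differential_table}.
#' @param annotation A \code{locus_annotation} covering the entries.
#' @param params A \code{\link{map_params}} object.
#' @return Data frame with one row per called locus: \code{symbol},
#'   \code{call}, \code{q}, \code{ratio}, \code{shared_window} (TRUE when
#'   the calling window held other loci and the prevail rule was
#'   exercised). Attribute \code{n_dropped} counts calls dropped by the
#'   prevail rule.
#' @export
single_gene_map <- function(entries, annotation, params = map_params()) {
  gw <- params$gene_window
  windows <- build_windows(annotation, window = gw, shift = max(1L, gw %/% 2L))
  res <- call_segments(entries, windows, params, dedup = FALSE,
                       min_extreme_genes = 1L)
  if (nrow(res) == 0) {
    return(structure(data.frame(symbol = character(0), call = character(0),
                                q = numeric(0), ratio = numeric(0),
                                shared_window = logical(0)),
                     n_dropped = 0L))
  }
  vals <- stats::setNames(pmax(entries$value_A, entries$value_B), entries$symbol)
  pool_hi <- stats::setNames(ifelse(entries$value_A >= entries$value_B, "A", "B"),
                             entries$symbol)
  value_in <- function(sym, pool) {
    i <- match(sym, entries$symbol)
    if (pool == "A") entries$value_A[i] else entries$value_B[i]
  }
  calls <- list()
  n_dropped <- 0L
  for (i in which(res$call != "none")) {
    members <- res$symbols[[i]]
    for (sym in res$flagged[[i]]) {
      others <- setdiff(members, sym)
      maintained <- TRUE
      if (length(others) > 0) {
        pool <- pool_hi[[sym]]
        maintained <- all(value_in(sym, pool) >
                            vapply(others, value_in, 0, pool = pool))
      }
      if (maintained) {
        qv <- if (res$call[i] == "over") res$q_over[i] else res$q_under[i]
        prev <- calls[[sym]]
        if (is.null(prev) || qv < prev$q) {
          calls[[sym]] <- list(call = res$call[i], q = qv,
                               shared = length(others) > 0)
        }
      } else {
        n_dropped <- n_dropped + 1L
      }
    }
  }
  if (length(calls) == 0) {
    out <- data.frame(symbol = character(0), call = character(0),
                      q = numeric(0), ratio = numeric(0),
                      shared_window = logical(0))
  } else {
    syms <- names(calls)
    out <- data.frame(symbol = syms,
                      call = vapply(calls, `[[`, "", "call"),
                      q = vapply(calls, `[[`, 0, "q"),
                      ratio = entries$ratio[match(syms, entries$symbol)],
                      shared_window = vapply(calls, `[[`, TRUE, "shared"),
                      stringsAsFactors = FALSE)
    out <- out[order(out$q, out$symbol), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Chromosome-level median expression ratios
#'
#' The median differential ratio over all loci on each chromosome; on a
#' trisomic chromosome compared against euploid cells this tracks the
#' expected ~1.5 gene-dosage ratio.
#'
#' @param entries A \code{differential_table}.
#' @param annotation A \code{locus_annotation} giving each locus its
#'   chromosome.
#' @return Data frame with columns \code{chromosome}, \code{median_ratio},
#'   \code{n_loci}; chromosomes without entries are omitted. Medians use
#'   the midpoint convention for even counts.
#' @export
chromosome_medians <- function(entries, annotation) {
  stopifnot(inherits(entries, "differential_table"), nrow(entries) > 0)
  chr <- annotation$chromosome[match(entries$symbol, annotation$symbol)]
  keep <- !is.na(chr)
  by_chr <- split(entries$ratio[keep], chr[keep])
  by_chr <- by_chr[lengths(by_chr) > 0]
  out <- data.frame(chromosome = names(by_chr),
                    median_ratio = vapply(by_chr, stats::median, 0),
                    n_loci = lengths(by_chr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chromosome), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ranked most over-/under-expressed gene lists
#'
#' Restricts to loci supported by at least \code{min_data_points} data
#' points in each pool, then ranks by ratio: descending for the
#' over-expressed list, ascending for the under-expressed list.
#'
#' @param entries A \code{differential_table}.
#' @param min_data_points Minimum of \code{n_points_A} and
#'   \code{n_points_B} required.
#' @param count Number of genes per list.
#' @return List with elements \code{over} and \code{under}, each a
#'   \code{differential_table} slice of up to \code{count} rows.
#' @export
top_genes <- function(entries, min_data_points = 5L, count = 10L) {
  stopifnot(inherits(entries, "differential_table"))
  eligible <- entries[pmin(entries$n_points_A, entries$n_points_B) >=
                        min_data_points, , drop = FALSE]
  over <- eligible[order(-eligible$ratio, eligible$symbol), , drop = FALSE]
  under <- eligible[order(eligible$ratio, eligible$symbol), , drop = FALSE]
  list(over = utils::head(over, count), under = utils::head(under, count))
}
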