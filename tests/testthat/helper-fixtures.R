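# small in-code fixtures shared across test files

make_annotation <- function(symbols, chromosome = "chr1",
                            start = seq(1e6, by = 1e6,
                                        length.out = length(symbols)),
                            end = start + 10000, cytoband = NA_character_) {
  validate_annotation(data.frame(
    symbol = symbols, chromosome = chromosome, start = start, end = end,
    cytoband = cytoband, stringsAsFactors = FALSE))
}

# a differential_table built directly from pooled means
make_entries <- function(symbols, value_A, value_B = 100,
                         n_A = 10L, n_B = 10L) {
  pa <- make_pool(symbols, value_A, n_A, "A")
  pb <- make_pool(symbols, value_B, n_B, "B")
  compute_differential(pa, pb)
}

make_pool <- function(symbols, mean_value, n_points = 10L, pool_id = "P") {
  df <- data.frame(symbol = symbols,
                   mean_value = rep_len(mean_value, length(symbols)),
                   n_points = as.integer(rep_len(n_points, length(symbols))),
                   sd_percent = 0, stringsAsFactors = FALSE)
  df <- df[order(df$symbol), ]
  rownames(df) <- NULL
  attr(df, "pool_id") <- pool_id
  attr(df, "n_data_points") <- sum(df$n_points)
  class(df) <- c("pool_expression", "data.frame")
  df
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# brute-force hypergeometric upper tail by enumerating every n-subset
enum_hyper_pvalue <- function(N, K, n, k) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked) >= k)
  mean(hits)
}

# decode -> normalize -> pool -> flag -> segment pipeline without the
# single-gene map (which the large recovery fixtures do not exercise)
run_segment_pipeline <- function(ex, compare = c("A", "B"),
                                 mp = map_params()) {
  pools <- vapply(ex$datasets, `[[`, "", "pool_id")
  ds <- ex$datasets[pools %in% compare]
  pools <- pools[pools %in% compare]
  decoded_raw <- lapply(ds, decode_probes, probe_map = ex$probe_map)
  trimmed <- mapply(function(d, dec) {
    v <- d$values[dec$probe_id]
    names(v) <- dec$probe_id
    d$values <- v
    d
  }, ds, decoded_raw, SIMPLIFY = FALSE)
  normed <- normalize_datasets(trimmed)
  decoded <- mapply(function(dec, d) {
    dec$value <- unname(d$values[dec$probe_id])
    dec
  }, decoded_raw, normed, SIMPLIFY = FALSE)
  pa <- pool_values(do.call(rbind, decoded[pools == compare[1]]), compare[1])
  pb <- pool_values(do.call(rbind, decoded[pools == compare[2]]), compare[2])
  entries <- flag_extremes(compute_differential(pa, pb), mp$tail)
  segments <- call_segments(entries, build_windows(ex$annotation,
                                                   mp$window, mp$shift), mp)
  list(entries = entries, segments = segments,
       chromosomes = chromosome_medians(entries, ex$annotation))
}
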