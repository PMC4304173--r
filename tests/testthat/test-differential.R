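test_that("compute_differential forms A/B ratios over shared loci only", {
  # the sex-comparison worked example: XIST pooled means 402.60 vs 12.20
  pa <- make_pool(c("XIST", "ACTB"), c(402.60, 100))
  pb <- make_pool(c("XIST", "ACTB", "ONLY_B"), c(12.20, 100, 7))
  entries <- compute_differential(pa, pb)
  expect_equal(nrow(entries), 2)           # ONLY_B excluded
  xist <- entries[entries$symbol == "XIST", ]
  expect_equal(round(xist$ratio), 33)
  expect_equal(signif(xist$ratio, 3), 33.0)
  expect_equal(entries$ratio[entries$symbol == "ACTB"], 1)

  only_a <- make_pool("ONLY_A", 5)
  expect_error(compute_differential(only_a, pb), "no loci shared")
})

test_that("swapping pools inverts every ratio and swaps the flags", {
  set.seed(4)
  pa <- make_pool(sprintf("L%03d", 1:300), rlnorm(300, 4, 1))
  pb <- make_pool(sprintf("L%03d", 1:300), rlnorm(300, 4, 1))
  ab <- flag_extremes(compute_differential(pa, pb))
  ba <- flag_extremes(compute_differential(pb, pa))
  i <- match(ab$symbol, ba$symbol)
  expect_equal(ba$ratio[i], 1 / ab$ratio, tolerance = 1e-12)
  swap <- c(over = "under", under = "over", none = "none")
  expect_equal(unname(swap[ab$flag]), ba$flag[i])
})

test_that("flag_extremes flags the 2.5% tails with inclusive ties", {
  set.seed(8)
  entries <- make_entries(sprintf("L%03d", 1:200), rlnorm(200, 0, 1) + 1)
  stopifnot(!anyDuplicated(entries$ratio))
  flagged <- flag_extremes(entries, 0.025)
  expect_equal(sum(flagged$flag == "over"), 5)   # 2.5% of 200
  expect_equal(sum(flagged$flag == "under"), 5)
  expect_true(all(flagged$ratio[flagged$flag == "over"] >
                    max(flagged$ratio[flagged$flag == "none"])))

  none <- flag_extremes(entries, 0)
  expect_true(all(none$flag == "none"))

  ties <- flag_extremes(make_entries(c("a", "b", "c", "d"),
                                     c(1, 1, 1, 10) * 100), 0.025)
  # brute-force type-7 quantile: upper threshold between 1 and 10
  expect_equal(ties$flag[ties$symbol == "d"], "over")
  q_hi <- unname(stats::quantile(c(1, 1, 1, 10), 0.975, type = 7))
  expect_true(10 >= q_hi && all(c(1, 1, 1) < q_hi))
})

test_that("build_windows lays the sliding grid and assigns loci by start", {
  # default grid reproduces the printed 15q21.2 segment bounds
  ann <- make_annotation("HDC", "chr15", start = 50534392, end = 50558304)
  grid <- build_windows(ann)
  hit <- grid[grid$start == 50250001, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$end, 50750000)
  expect_true("HDC" %in% hit$symbols[[1]])

  # chromosome extent 1,000,000 with defaults: 4 windows
  ann2 <- make_annotation("A", start = 990000, end = 1000000)
  grid2 <- build_windows(ann2)
  expect_equal(grid2$start, c(1, 250001, 500001, 750001))
  expect_equal(grid2$end, grid2$start + 500000 - 1)

  # interior locus start 250,100 falls in exactly the first two windows
  ann3 <- make_annotation(c("X", "FAR"), start = c(250100, 900000),
                          end = c(260000, 990000))
  grid3 <- build_windows(ann3)
  member <- vapply(grid3$symbols, function(s) "X" %in% s, TRUE)
  expect_equal(grid3$start[member], c(1, 250001))
})

test_that("segment_pvalue matches exhaustive enumeration and is monotone in k", {
  expect_equal(segment_pvalue(10, 3, 4, 2), 70 / 210, tolerance = 1e-12)
  expect_equal(segment_pvalue(10, 3, 4, 0), 1)
  expect_error(segment_pvalue(10, 3, 4, 5), "inconsistent")

  # spot-check the closed form against subset enumeration (full sweep of
  # N <= 12 lives in the acceptance suite)
  set.seed(2)
  for (i in 1:25) {
    N <- sample(2:10, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(segment_pvalue(N, K, n, k), enum_hyper_pvalue(N, K, n, k),
                 tolerance = 1e-12)
  }

  # strictly decreasing in k over the support (p is pinned at 1 below it)
  for (i in 1:10) {
    N <- sample(5:40, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    ks <- max(0, n + K - N):min(K, n)
    p <- vapply(ks, function(k) segment_pvalue(N, K, n, k), 0)
    if (length(p) > 1) expect_true(all(diff(p) < 0))
  }
})

test_that("correct_q applies Benjamini-Hochberg step-up (and Bonferroni)", {
  expect_equal(correct_q(0.01), 0.01)
  expect_equal(correct_q(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(correct_q(rep(1, 5)), rep(1, 5))
  expect_equal(correct_q(c(0.01, 0.5), "bonferroni"), c(0.02, 1))
  p <- runif(50)
  expect_true(all(correct_q(p) >= p))
})

test_that("call_segments needs k >= 3 extreme genes however small the p-value", {
  # 2 flagged loci packed in one window among many nulls: p is tiny but
  # the minimum-extreme-genes rule forbids the call
  set.seed(12)
  n_null <- 400
  ann <- make_annotation(
    c(sprintf("N%03d", 1:n_null), "HOT1", "HOT2"), "chr1",
    start = c(seq(2e6, 9e6, length.out = n_null), 1.01e6, 1.02e6))
  ratios <- c(rlnorm(n_null, 0, 0.05), 50, 60)
  entries <- flag_extremes(make_entries(ann$symbol, ratios * 100))
  expect_equal(sum(entries$flag[entries$symbol %in% c("HOT1", "HOT2")] == "over"), 2)
  res <- call_segments(entries, build_windows(ann), map_params())
  hot <- res[res$start <= 1.01e6 & res$end >= 1.02e6, ]
  expect_true(all(hot$k_over == 2))
  expect_true(all(hot$call == "none"))
  expect_lt(min(hot$p_over), 1e-3)

  # windows without member loci emit no test
  expect_true(all(res$n >= 1))
  expect_lt(nrow(res), nrow(build_windows(ann)))

  # every call carries at least min_extreme_genes flagged members
  res3 <- call_segments(entries, build_windows(ann),
                        map_params(min_extreme_genes = 1L))
  called <- res3[res3$call != "none", ]
  if (nrow(called) > 0) {
    k <- ifelse(called$call == "over", called$k_over, called$k_under)
    expect_true(all(k >= 1))
    expect_true(all(lengths(called$flagged) == k))
  }
})

test_that("call_segments recovers an injected cluster and dedups overlaps", {
  set.seed(99)
  n_null <- 600
  ann <- make_annotation(
    c(sprintf("N%03d", 1:n_null), sprintf("HOT%d", 1:4)), "chr1",
    start = c(seq(2e6, 9e6, length.out = n_null),
              1.00e6, 1.05e6, 1.10e6, 1.15e6))
  ratios <- c(rlnorm(n_null, 0, 0.05), 40, 45, 50, 55)
  entries <- flag_extremes(make_entries(ann$symbol, ratios * 100))
  res <- call_segments(entries, build_windows(ann), map_params())
  called <- res[res$call == "over", ]
  expect_equal(nrow(called), 1)  # overlapping twin removed by dedup
  expect_true(all(sprintf("HOT%d", 1:4) %in% called$symbols[[1]]))
  expect_lt(called$q_over, 0.05)
  expect_gte(called$k_over, 3)

  undeduped <- call_segments(entries, build_windows(ann), map_params(),
                             dedup = FALSE)
  expect_gt(sum(undeduped$call == "over"), 1)
})

test_that("single-gene map applies the prevail rule inside shared windows", {
  # three flagged loci share one 12.5 kb window among many spread nulls;
  # the window's hypergeometric p is tiny, so the call hinges on prevail
  build <- function(neighbor_values) {
    n_null <- 60
    syms <- c(sprintf("N%02d", 1:n_null), "TOP", "MID", "LOW")
    ann <- make_annotation(
      syms, "chr1",
      start = c(seq(1e6, 9e6, length.out = n_null), 2e4, 2.1e4, 2.2e4),
      end = c(seq(1e6, 9e6, length.out = n_null) + 5e3, 2.05e4, 2.15e4, 2.25e4))
    values_a <- c(rep(100, n_null) * exp(rnorm(n_null, 0, 0.02)),
                  neighbor_values)
    entries <- flag_extremes(make_entries(syms, values_a), 0.05)
    single_gene_map(entries, ann, map_params())
  }
  set.seed(23)
  dominated <- build(c(400, 380, 350))   # TOP prevails over MID and LOW
  expect_true("TOP" %in% dominated$symbol)
  expect_false(any(c("MID", "LOW") %in% dominated$symbol))
  # MID and LOW are each dropped in both windows covering the cluster
  expect_equal(attr(dominated, "n_dropped"), 4L)
  expect_true(all(dominated$call[dominated$symbol == "TOP"] == "over"))
  expect_true(dominated$shared_window[dominated$symbol == "TOP"])

  set.seed(23)
  tied_down <- build(c(400, 600, 350))   # MID beats TOP; TOP's call drops
  expect_false("TOP" %in% tied_down$symbol)
  expect_true("MID" %in% tied_down$symbol)
})

test_that("chromosome_medians uses the midpoint convention and matches a sort oracle", {
  ann <- make_annotation(c("A", "B", "C", "D"),
                         chromosome = c("chr21", "chr2", "chr2", "chr2"))
  entries <- make_entries(c("A", "B", "C", "D"), c(170, 100, 200, 400))
  med <- chromosome_medians(entries, ann)
  expect_equal(med$median_ratio[med$chromosome == "chr21"], 1.7)
  expect_equal(med$n_loci[med$chromosome == "chr21"], 1L)
  expect_equal(med$median_ratio[med$chromosome == "chr2"], 2)  # {1,2,4}

  set.seed(6)
  ann2 <- make_annotation(sprintf("L%03d", 1:120),
                          chromosome = sample(c("chr1", "chr2", "chr3"),
                                              120, replace = TRUE))
  entries2 <- make_entries(ann2$symbol, rlnorm(120, 0, 1) * 100)
  med2 <- chromosome_medians(entries2, ann2)
  shuffled <- chromosome_medians(entries2[sample(120), ], ann2)
  expect_equal(med2, shuffled)
  for (chr in med2$chromosome) {
    r <- sort(entries2$ratio[match(ann2$symbol[ann2$chromosome == chr],
                                   entries2$symbol)])
    n <- length(r)
    oracle <- if (n %% 2 == 1) r[(n + 1) / 2] else (r[n / 2] + r[n / 2 + 1]) / 2
    expect_equal(med2$median_ratio[med2$chromosome == chr], oracle)
  }
})

test_that("top_genes filters on data-point support before ranking", {
  pa <- make_pool(c("FEW", "BIG", "SMALL"), c(1000, 1000, 10),
                  n_points = c(4L, 8L, 9L))
  pb <- make_pool(c("FEW", "BIG", "SMALL"), c(10, 100, 100),
                  n_points = c(20L, 7L, 6L))
  entries <- compute_differential(pa, pb)
  top <- top_genes(entries, min_data_points = 5L, count = 1L)
  expect_equal(top$over$symbol, "BIG")    # FEW excluded: only 4 points in A
  expect_equal(top$under$symbol, "SMALL")

  both <- top_genes(entries, min_data_points = 5L, count = 10L)
  expect_false("FEW" %in% both$over$symbol)
  expect_equal(nrow(both$over), 2)

  none <- top_genes(entries, min_data_points = 50L, count = 3L)
  expect_equal(nrow(none$over), 0)
  expect_equal(nrow(none$under), 0)
})
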