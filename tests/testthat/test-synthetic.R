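test_that("generate_annotation is seed-deterministic and validates inputs", {
  a1 <- generate_annotation(2, 100, 1e7, seed = 7)
  a2 <- generate_annotation(2, 100, 1e7, seed = 7)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 200)
  expect_equal(sort(unique(a1$chromosome)), c("chr1", "chr2"))
  expect_true(all(a1$end > a1$start))

  a3 <- generate_annotation(2, 100, 1e7, seed = 8)
  expect_false(identical(a1$start, a3$start))

  expect_error(generate_annotation(2, 0, 1e7, seed = 1))
  expect_error(generate_annotation(1, 5, 100, seed = 1), "too small")

  # cluster regions confine their loci and per-chromosome counts can differ
  cl <- data.frame(chromosome = "chr1", start = 2e6, end = 2.4e6,
                   n_loci = 6, prefix = "CL", stringsAsFactors = FALSE)
  a4 <- generate_annotation(2, c(50, 20), 1e7, seed = 7, clusters = cl)
  expect_equal(sum(a4$chromosome == "chr2"), 20)
  in_cl <- grepl("^CL_", a4$symbol)
  expect_equal(sum(in_cl), 6)
  expect_true(all(a4$start[in_cl] >= 2e6 & a4$end[in_cl] <= 2.4e6))
})

test_that("generate_pools builds platform-heterogeneous pools from the truth", {
  ann <- generate_annotation(2, 60, 1e7, seed = 5)
  truth <- synthetic_truth(ann, n_platforms = 2L,
                           platform_coverage = c(0.6, 1.0),
                           log2_platforms = 2L, seed = 5)
  ex <- generate_pools(truth, c(A = 4L, B = 3L))
  expect_s3_class(ex, "synthetic_experiment")
  expect_length(ex$datasets, 7)
  expect_equal(sum(vapply(ex$datasets, `[[`, "", "pool_id") == "A"), 4)
  scales <- vapply(ex$datasets, `[[`, "", "scale")
  expect_setequal(unique(scales), c("linear", "log2"))

  # platform 1 covers ~60% of loci, platform 2 all of them
  pm <- ex$probe_map
  cov1 <- length(unique(pm$symbol[pm$platform_id == "PLAT1" & !is.na(pm$symbol)]))
  cov2 <- length(unique(pm$symbol[pm$platform_id == "PLAT2" & !is.na(pm$symbol)]))
  expect_equal(cov1, round(0.6 * 120))
  expect_equal(cov2, 120)
  expect_equal(attr(pm, "n_unmapped"), 2L)  # one control probe per platform

  # raw linear-scale samples contain missing and non-positive values
  lin <- ex$datasets[scales == "linear"]
  raw <- unlist(lapply(lin, `[[`, "values"))
  expect_true(anyNA(raw))
  expect_true(any(raw <= 0, na.rm = TRUE))

  expect_error(generate_pools(truth, c(A = 0L)), "at least 1 sample")
  expect_identical(generate_pools(truth, c(A = 4L, B = 3L)), ex)
})

test_that("pooled ratios converge to the injected log effect at large n", {
  # expected log-ratio of an injected locus = log(fold) under the model;
  # at n = 50 samples per pool the pooled estimate sits within 2 SE
  ann <- generate_annotation(2, c(60, 10), 1e7, seed = 101)
  segs <- data.frame(fold = 4, direction = "over", pool = "A",
                     stringsAsFactors = FALSE)
  segs$symbols <- list(c("G2_0003", "G2_0004"))
  truth <- synthetic_truth(ann, segments = segs, noise_sigma = 0.2,
                           missing_rate = 0, nonpositive_rate = 0, seed = 101)
  ex <- generate_pools(truth, c(A = 50L, B = 50L))
  # pool the generated data points directly (no inter-sample normalization),
  # so the check isolates the generative model itself
  pool_raw <- function(pool_id) {
    ds <- Filter(function(d) d$pool_id == pool_id, ex$datasets)
    pts <- do.call(rbind, lapply(ds, function(d) {
      d$values <- linearize(d$values, d$scale)
      decode_probes(d, ex$probe_map)
    }))
    pool_values(pts, pool_id)
  }
  entries <- compute_differential(pool_raw("A"), pool_raw("B"))
  hot <- entries[entries$symbol %in% segs$symbols[[1]], ]
  expect_equal(nrow(hot), 2)
  # log-scale SE of a ratio of pooled log-normal means at sigma 0.2
  se <- sqrt(2) * 0.2 / sqrt(pmin(hot$n_points_A, hot$n_points_B))
  expect_true(all(abs(log(hot$ratio) - log(4)) < 2 * se))
  # null loci carry no effect
  null_sym <- ann$symbol[!ann$symbol %in% segs$symbols[[1]]]
  null_ratio <- entries$ratio[entries$symbol %in% null_sym]
  expect_lt(abs(mean(log(null_ratio))), 0.05)
})

test_that("MCAR missingness leaves pooled means unbiased", {
  ann <- generate_annotation(1, 80, 1e7, seed = 33)
  base_truth <- function(miss) {
    synthetic_truth(ann, noise_sigma = 0.2, missing_rate = miss,
                    nonpositive_rate = 0, seed = 33)
  }
  pool_of <- function(truth) {
    ex <- generate_pools(truth, c(A = 12L, B = 12L))
    res <- compare_pools(ex$annotation, ex$probe_map, ex$datasets, c("A", "B"))
    res$entries$ratio
  }
  r_full <- pool_of(base_truth(0))
  r_miss <- pool_of(base_truth(0.15))
  # same seed, same underlying signal: ratios agree closely on average
  expect_lt(abs(mean(log(r_miss)) - mean(log(r_full))), 0.02)
  expect_gt(cor(log(r_full), log(r_miss)), 0.9)
})

test_that("the same pool drawn twice yields highly correlated maps", {
  ann <- generate_annotation(2, 60, 1e7, seed = 55)
  truth <- synthetic_truth(ann, noise_sigma = 0.2, seed = 55)
  ex <- generate_pools(truth, c(A = 8L, B = 8L))  # two null pools, no effects
  res <- compare_pools(ex$annotation, ex$probe_map, ex$datasets, c("A", "B"))
  expect_gt(res$correlation$r, 0.95)
  expect_lt(res$correlation$p, 1e-4)
})

test_that("write_fixture produces a reproducible plain-text tree", {
  ann <- generate_annotation(1, 30, 1e7, seed = 9)
  truth <- synthetic_truth(ann, seed = 9)
  ex <- generate_pools(truth, c(A = 2L, B = 2L))
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(ex, d1)
  write_fixture(ex, d2)
  expect_true(all(c("annotation.tsv", "probe_map.tsv", "truth.tsv",
                    "config.json") %in% dir(d1)))
  expect_gte(length(dir(d1)), 5)
  sums <- function(d) vapply(sort(dir(d)), function(f)
    unname(tools::md5sum(file.path(d, f))), "")
  expect_identical(sums(d1), sums(d2))
  expect_error(write_fixture(ex, d1), "not empty")
  expect_silent(write_fixture(ex, d1, force = TRUE))

  tt <- utils::read.delim(file.path(d1, "truth.tsv"))
  expect_setequal(tt$symbol, ann$symbol)
  expect_true(all(tt$effect_type == "null"))
})
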