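#' Read and validate a run configuration
#'
#' The run config is one JSON file declaring the annotation, probe maps,
#' datasets (path, platform, pool, deposited scale), the two pools to
#' compare, and any overrides of the map / normalization parameters.
#' Relative paths resolve against the config file's directory.
#'
#' @param path Path to the JSON config.
#' @return A validated \code{run_config} list with fields
#'   \code{annotation}, \code{probe_maps}, \code{datasets},
#'   \code{compare}, \code{map_params}, \code{normalization_params},
#'   \code{seed}, \code{strict}, \code{dir}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  for (field in c("annotation", "datasets", "compare")) {
    if (is.null(cfg[[field]])) stop("config is missing field '", field, "'")
  }
  compare <- unlist(cfg$compare)
  if (length(compare) != 2 || anyDuplicated(compare)) {
    stop("config 'compare' must name exactly two distinct pool ids")
  }
  datasets <- lapply(seq_along(cfg$datasets), function(i) {
    d <- cfg$datasets[[i]]
    for (f in c("path", "platform_id", "pool_id")) {
      if (is.null(d[[f]])) stop(sprintf("dataset %d is missing '%s'", i, f))
    }
    if (is.null(d$scale)) d$scale <- "linear"
    check_scale(d$scale)
    d
  })
  mp <- do.call(map_params, as_list(cfg$map_params))
  np <- do.call(normalization_params, as_list(cfg$normalization_params))
  structure(list(
    annotation = cfg$annotation,
    probe_maps = unlist(cfg$probe_maps),
    datasets = datasets,
    compare = compare,
    map_params = mp,
    normalization_params = np,
    seed = if (is.null(cfg$seed)) NA_integer_ else as.integer(cfg$seed),
    strict = isTRUE(cfg$strict),
    dir = base), class = "run_config")
}

as_list <- function(x) if (is.null(x)) list() else
  lapply(x, function(v) if (is.list(v)) unlist(v) else v)

#' Run a full two-pool differential transcriptome comparison
#'
#' Executes the whole pipeline: read annotation, probe maps and sample
#' matrices; decode probes to locus data points; normalize every sample
#' (linearize, replace non-positives, percent-of-mean, scaled quantile
#' across both pools jointly); pool per condition; compute per-locus
#' ratios and extreme flags; call segments, single genes, chromosome
#' medians and ranked gene lists. Optionally writes the report bundle
#' (TSV reports plus run.log) to \code{out_dir}.
#'
#' @param config A \code{run_config} (from \code{\link{read_run_config}})
#'   or a path to one.
#' @param out_dir Output directory for the report bundle, or NULL to
#'   skip writing.
#' @param top_n Rows in each ranked gene list (default 10).
#' @return A \code{compare_result} list: \code{pool_a}, \code{pool_b},
#'   \code{entries}, \code{segments}, \code{single_genes},
#'   \code{chromosomes}, \code{top} (over/under lists),
#'   \code{correlation}, \code{log} (named bookkeeping values: data
#'   points per pool, mapped loci per pool, shared loci, flagged counts,
#'   parameters).
#' @export
run_compare <- function(config, out_dir = NULL, top_n = 10L) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  mp <- config$map_params
  np <- config$normalization_params
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  rp <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(config$dir, p)

  annotation <- stage("annotation_io", read_annotation(rp(config$annotation)))
  probe_map <- stage("annotation_io", {
    pm <- do.call(rbind, lapply(config$probe_maps, function(p)
      as.data.frame(read_probe_map(rp(p), annotation))))
    validate_probe_map(pm, annotation)
  })
  datasets <- stage("annotation_io", {
    ds <- list()
    for (d in config$datasets) {
      ds <- c(ds, read_sample_matrix(rp(d$path), d$platform_id, d$pool_id,
                                     d$scale))
    }
    ids <- vapply(ds, `[[`, "", "sample_id")
    if (anyDuplicated(ids)) stop("duplicate sample id: ", ids[duplicated(ids)][1])
    ds
  })
  result <- compare_pools(annotation, probe_map, datasets, config$compare,
                          mp, np, strict = config$strict, top_n = top_n)
  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

#' Run the two-pool comparison pipeline in memory
#'
#' The computational core of \code{\link{run_compare}}, usable directly
#' on in-memory objects (e.g. the output of \code{\link{generate_pools}})
#' without touching the filesystem.
#'
#' @param annotation A \code{locus_annotation}.
#' @param probe_map A \code{probe_map}.
#' @param datasets List of \code{sample_dataset} objects (raw values).
#' @param compare Character vector of the two pool ids (numerator first).
#' @param mp A \code{\link{map_params}} object.
#' @param np A \code{\link{normalization_params}} object.
#' @param strict Strict probe-map coverage (see \code{\link{decode_probes}}).
#' @param top_n Rows per ranked gene list.
#' @return A \code{compare_result}; see \code{\link{run_compare}}.
#' @export
compare_pools <- function(annotation, probe_map, datasets, compare,
                          mp = map_params(), np = normalization_params(),
                          strict = FALSE, top_n = 10L) {
  stopifnot(length(compare) == 2, !anyDuplicated(compare))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  pools <- vapply(datasets, `[[`, "", "pool_id")
  if (!all(compare %in% pools)) {
    stop("[config] compared pool absent from datasets: ",
         paste(setdiff(compare, pools), collapse = ", "))
  }
  keep <- pools %in% compare
  datasets <- datasets[keep]
  pools <- pools[keep]

  # decode first so normalization sees mapped, measured probes only
  decoded_raw <- stage("annotation_io", lapply(datasets, decode_probes,
                                               probe_map = probe_map,
                                               strict = strict))
  normalized <- stage("normalization", {
    trimmed <- mapply(function(d, dec) {
      v <- d$values[dec$probe_id]
      names(v) <- dec$probe_id
      d$values <- v
      d
    }, datasets, decoded_raw, SIMPLIFY = FALSE)
    normalize_datasets(trimmed, np)
  })
  decoded <- mapply(function(dec, d) {
    dec$value <- unname(d$values[dec$probe_id])
    dec
  }, decoded_raw, normalized, SIMPLIFY = FALSE)

  a_id <- compare[1]; b_id <- compare[2]
  pool_a <- stage("pooling",
                  pool_values(do.call(rbind, decoded[pools == a_id]), a_id))
  pool_b <- stage("pooling",
                  pool_values(do.call(rbind, decoded[pools == b_id]), b_id))

  entries <- stage("differential_mapping", {
    e <- compute_differential(pool_a, pool_b)
    flag_extremes(e, mp$tail)
  })
  windows <- stage("differential_mapping",
                   build_windows(annotation, mp$window, mp$shift))
  segments <- stage("differential_mapping", call_segments(entries, windows, mp))
  single_genes <- stage("differential_mapping",
                        single_gene_map(entries, annotation, mp))
  chromosomes <- stage("differential_mapping",
                       chromosome_medians(entries, annotation))
  top <- stage("differential_mapping",
               top_genes(entries, mp$min_data_points, top_n))
  correlation <- stage("pooling", compute_pool_correlation(pool_a, pool_b))

  log <- list(
    pool_a = a_id, pool_b = b_id,
    n_samples_a = sum(pools == a_id), n_samples_b = sum(pools == b_id),
    data_points_a = attr(pool_a, "n_data_points"),
    data_points_b = attr(pool_b, "n_data_points"),
    mapped_loci_a = nrow(pool_a), mapped_loci_b = nrow(pool_b),
    shared_loci = nrow(entries),
    flagged_over = sum(entries$flag == "over"),
    flagged_under = sum(entries$flag == "under"),
    windows_tested = nrow(segments),
    segments_called = if (nrow(segments)) sum(segments$call != "none") else 0L,
    single_genes_called = nrow(single_genes),
    correlation_r = correlation$r,
    map_params = unclass(mp),
    normalization_params = unclass(np))

  result <- structure(list(
    annotation = annotation, pool_a = pool_a, pool_b = pool_b,
    entries = entries, segments = segments, single_genes = single_genes,
    chromosomes = chromosomes, top = top, correlation = correlation,
    log = log), class = "compare_result")
  result
}

#' Write the report bundle of a comparison
#'
#' Emits \code{segments.tsv} (chromosome, cytoband span, bounds, ratio,
#' q, member genes with +/- flags), \code{genes_over.tsv} /
#' \code{genes_under.tsv} (ranked lists), \code{single_genes.tsv},
#' \code{chromosomes.tsv}, \code{differential.tsv} (the full per-locus
#' table) and \code{run.log} (all parameters and bookkeeping tallies).
#'
#' @param result A \code{compare_result}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "compare_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seg <- result$segments
  if (nrow(seg) > 0) {
    ann <- result$annotation
    flags <- stats::setNames(result$entries$flag, result$entries$symbol)
    seg_out <- data.frame(
      chromosome = seg$chromosome,
      cytoband = vapply(seq_len(nrow(seg)), function(i) {
        bands <- unique(stats::na.omit(
          ann$cytoband[match(seg$symbols[[i]], ann$symbol)]))
        if (length(bands) == 0) "" else paste(bands, collapse = ";")
      }, ""),
      start = seg$start, end = seg$end,
      ratio = round(seg$ratio, 4), n = seg$n,
      k_over = seg$k_over, k_under = seg$k_under,
      q_over = signif(seg$q_over, 5), q_under = signif(seg$q_under, 5),
      call = seg$call,
      genes = vapply(seq_len(nrow(seg)), function(i) {
        syms <- seg$symbols[[i]]
        mark <- c(over = "+", under = "-", none = "")[flags[syms]]
        paste0(syms, mark, collapse = " ")
      }, ""),
      stringsAsFactors = FALSE)
  } else {
    seg_out <- data.frame(chromosome = character(0))
  }
  write_tsv(seg_out, file.path(dir, "segments.tsv"))
  gene_cols <- c("symbol", "value_A", "value_B", "ratio",
                 "n_points_A", "n_points_B", "sd_percent_A", "sd_percent_B")
  write_tsv(round_cols(result$top$over[, gene_cols]),
            file.path(dir, "genes_over.tsv"))
  write_tsv(round_cols(result$top$under[, gene_cols]),
            file.path(dir, "genes_under.tsv"))
  write_tsv(round_cols(result$single_genes), file.path(dir, "single_genes.tsv"))
  write_tsv(round_cols(result$chromosomes), file.path(dir, "chromosomes.tsv"))
  write_tsv(round_cols(as.data.frame(result$entries)),
            file.path(dir, "differential.tsv"))
  log_lines <- unlist(lapply(names(result$log), function(k) {
    v <- result$log[[k]]
    if (is.list(v)) {
      paste0(k, ".", names(v), "\t", vapply(v, format, ""))
    } else paste0(k, "\t", format(v))
  }))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

round_cols <- function(df, digits = 6) {
  for (i in seq_along(df)) {
    if (is.double(df[[i]])) df[[i]] <- round(df[[i]], digits)
  }
  df
}

#' @export
print.compare_result <- function(x, ...) {
  l <- x$log
  cat(sprintf("<compare_result> %s vs %s\n", l$pool_a, l$pool_b))
  cat(sprintf("  data points: %d / %d; mapped loci: %d / %d; shared: %d\n",
              l$data_points_a, l$data_points_b,
              l$mapped_loci_a, l$mapped_loci_b, l$shared_loci))
  cat(sprintf("  flagged: %d over, %d under; windows tested: %d; called: %d\n",
              l$flagged_over, l$flagged_under, l$windows_tested,
              l$segments_called))
  cat(sprintf("  single genes called: %d; pool correlation r = %.3f\n",
              l$single_genes_called, l$correlation_r))
  invisible(x)
}

#' Simulate a complete synthetic fixture
#'
#' Drives the synthetic-data generator end to end with a realistic
#' default world -- two pools (a "trisomic" condition vs a euploid
#' control), two platforms of unequal coverage with one depositing log2
#' values, a 1.5x dosage chromosome, one injected co-regulated 500 kb
#' cluster -- and writes it as a plain-text fixture directory ready for
#' \code{\link{run_compare}}.
#'
#' @param out Output directory.
#' @param seed Integer seed; the fixture is byte-identical per seed.
#' @param null_world If TRUE, no effects are injected (pure-null fixture).
#' @param n_loci Loci per chromosome (scalar or vector). The default
#'   gives the dosage chromosome (the last one) a third of the loci of
#'   the others, mirroring how small the trisomic chromosome is relative
#'   to the genome; normalization then absorbs little of the dosage
#'   signal.
#' @param n_chromosomes Number of chromosomes.
#' @param pool_sizes Named vector pool -> samples (default A = 12, B = 10).
#' @param force Overwrite a non-empty directory.
#' @return The config path, invisibly; prints a truth summary.
#' @export
simulate_fixture <- function(out, seed = 1L, null_world = FALSE,
                             n_loci = c(150L, 150L, 50L),
                             n_chromosomes = 3L,
                             pool_sizes = c(A = 12L, B = 10L),
                             force = FALSE) {
  clusters <- NULL
  segments <- NULL
  dosage_chr <- NA
  dosage_pool <- NA
  if (!null_world) {
    clusters <- data.frame(chromosome = "chr1", start = 2000001,
                           end = 2400000, n_loci = 6, prefix = "CL1",
                           stringsAsFactors = FALSE)
    segments <- data.frame(fold = 10, direction = "over", pool = names(pool_sizes)[1],
                           stringsAsFactors = FALSE)
    segments$symbols <- list(sprintf("CL1_%02d", 1:6))
    dosage_chr <- paste0("chr", n_chromosomes)
    dosage_pool <- names(pool_sizes)[1]
  }
  ann <- generate_annotation(n_chromosomes, n_loci, 1e7, seed = seed,
                             clusters = clusters)
  truth <- synthetic_truth(
    ann, segments = segments,
    dosage_chromosome = dosage_chr, dosage_factor = 1.5,
    dosage_pool = dosage_pool,
    n_platforms = 2L, platform_coverage = c(0.8, 1.0),
    log2_platforms = 2L, seed = seed)
  experiment <- generate_pools(truth, pool_sizes)
  cfg <- write_fixture(experiment, out, force = force)
  tt <- experiment$truth_table
  cat(sprintf("fixture '%s': %d loci, %d samples, %d segment / %d dosage / %d sex loci (seed %d)\n",
              out, nrow(ann), sum(pool_sizes),
              sum(tt$effect_type == "segment"), sum(tt$effect_type == "dosage"),
              sum(tt$effect_type == "sex"), as.integer(seed)))
  invisible(cfg)
}
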