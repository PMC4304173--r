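#' Generate a synthetic locus annotation
#'
#' Places loci uniformly at random along each chromosome with
#' log-normal-ish gene spans (median ~25 kb). Optionally packs a dense
#' cluster of loci into each requested region, mimicking co-regulated
#' gene clusters (glycophorin- or apolipoprotein-like neighbourhoods).
#' Deterministic given the seed.
#'
#' @param n_chromosomes Number of chromosomes (named chr1..chrN).
#' @param loci_per_chromosome Loci per chromosome (before clusters);
#'   scalar or vector recycled over chromosomes, so a small
#'   trisomy-21-like chromosome can carry fewer loci than the rest.
#' @param chromosome_extent Chromosome length in bp.
#' @param seed Integer seed; all placement randomness flows from it.
#' @param clusters Optional data frame with columns \code{chromosome},
#'   \code{start}, \code{end}, \code{n_loci}, \code{prefix}; each row adds
#'   \code{n_loci} extra loci confined to [start, end].
#' @return A \code{locus_annotation} data frame.
#' @export
generate_annotation <- function(n_chromosomes = 2L, loci_per_chromosome = 100L,
                                chromosome_extent = 1e7, seed = 1L,
                                clusters = NULL) {
  stopifnot(n_chromosomes >= 1, all(loci_per_chromosome >= 1),
            chromosome_extent >= 1)
  n_per_chr <- rep_len(as.integer(loci_per_chromosome), n_chromosomes)
  with_seed(seed, {
    rows <- list()
    for (c in seq_len(n_chromosomes)) {
      chrom <- paste0("chr", c)
      n_c <- n_per_chr[c]
      span <- pmax(200, round(stats::rlnorm(n_c, log(25000), 0.8)))
      max_start <- chromosome_extent - span
      if (any(max_start < 1)) {
        if (chromosome_extent < 500) stop("chromosome extent too small to place loci")
        span <- pmin(span, chromosome_extent - 1)
        max_start <- chromosome_extent - span
      }
      start <- 1 + floor(stats::runif(n_c) * max_start)
      rows[[chrom]] <- data.frame(
        symbol = sprintf("G%s_%04d", c, seq_len(n_c)),
        chromosome = chrom, start = start, end = start + span,
        cytoband = NA_character_, stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, rows)
    if (!is.null(clusters)) {
      for (i in seq_len(nrow(clusters))) {
        cl <- clusters[i, ]
        width <- cl$end - cl$start + 1
        span <- pmax(200, pmin(round(width / (2 * cl$n_loci)), 25000))
        start <- cl$start + floor(stats::runif(cl$n_loci) * (width - span - 1))
        ann <- rbind(ann, data.frame(
          symbol = sprintf("%s_%02d", cl$prefix, seq_len(cl$n_loci)),
          chromosome = cl$chromosome, start = start, end = start + span,
          cytoband = NA_character_, stringsAsFactors = FALSE))
      }
    }
    ann <- ann[order(ann$chromosome, ann$start), , drop = FALSE]
    validate_annotation(ann)
  })
}

#' Declare the ground truth of a synthetic experiment
#'
#' Fixes every generative choice: which loci carry injected segment
#' effects, which chromosome carries a trisomy-like 1.5x dosage in the
#' target pool, which loci are sex-biased, the per-platform probe layout,
#' the log-normal noise level and the missing / non-positive corruption
#' rates. Emulates the structure of multi-platform pools: 2-6 platforms
#' with different probe counts, partially overlapping gene coverage
#' (60-100\% of loci per platform), 1-3 probes per covered locus, and
#' some platforms depositing values on a log2 scale.
#'
#' @param annotation A \code{locus_annotation}.
#' @param segments Data frame of injected clusters: columns
#'   \code{symbols} (list-column of member loci), \code{fold} (> 0),
#'   \code{direction} (\code{"over"}/\code{"under"}), \code{pool}
#'   (targeted pool id). NULL for none.
#' @param dosage_chromosome Chromosome carrying the dosage effect, or NA.
#' @param dosage_factor Dosage multiplier, default 1.5 (trisomy).
#' @param dosage_pool Pool id whose samples are "trisomic".
#' @param sex_loci Data frame with columns \code{symbol}, \code{fold},
#'   \code{pool} (the pool where expression is fold-times higher), or NULL.
#' @param n_platforms Number of platforms (2-6 realistic).
#' @param platform_coverage Fraction of loci covered per platform; vector
#'   recycled across platforms, each in (0, 1].
#' @param max_probes_per_locus Probe multiplicity cap (1-3 realistic).
#' @param noise_sigma Log-normal noise SD (natural-log scale) per
#'   platform, recycled.
#' @param platform_scale_offset Multiplicative per-platform intensity
#'   offset (removed by normalization), recycled.
#' @param log2_platforms Indices of platforms deposited on log2 scale.
#' @param missing_rate Fraction of values set missing (MCAR).
#' @param nonpositive_rate Fraction of values replaced by <= 0 junk.
#' @param seed Integer seed recorded in all outputs.
#' @return A \code{synthetic_truth} list.
#' @export
synthetic_truth <- function(annotation, segments = NULL,
                            dosage_chromosome = NA, dosage_factor = 1.5,
                            dosage_pool = NA, sex_loci = NULL,
                            n_platforms = 2L, platform_coverage = c(0.8, 1.0),
                            max_probes_per_locus = 3L,
                            noise_sigma = 0.2, platform_scale_offset = 1,
                            log2_platforms = integer(0),
                            missing_rate = 0.02, nonpositive_rate = 0.01,
                            seed = 1L) {
  stopifnot(inherits(annotation, "locus_annotation"),
            n_platforms >= 1, dosage_factor > 0,
            missing_rate >= 0, missing_rate < 1,
            nonpositive_rate >= 0, nonpositive_rate < 1)
  if (!is.null(segments)) {
    stopifnot(all(unlist(segments$symbols) %in% annotation$symbol),
              all(segments$fold > 0))
  }
  if (!is.null(sex_loci)) {
    stopifnot(all(sex_loci$symbol %in% annotation$symbol),
              all(sex_loci$fold > 0))
  }
  structure(list(
    annotation = annotation, segments = segments,
    dosage_chromosome = dosage_chromosome,
    dosage_factor = dosage_factor, dosage_pool = dosage_pool,
    sex_loci = sex_loci,
    n_platforms = as.integer(n_platforms),
    platform_coverage = rep_len(platform_coverage, n_platforms),
    max_probes_per_locus = as.integer(max_probes_per_locus),
    noise_sigma = rep_len(noise_sigma, n_platforms),
    platform_scale_offset = rep_len(platform_scale_offset, n_platforms),
    log2_platforms = as.integer(log2_platforms),
    missing_rate = missing_rate, nonpositive_rate = nonpositive_rate,
    seed = as.integer(seed)), class = "synthetic_truth")
}

#' Generate probe-level sample pools from a declared truth
#'
#' Per sample, each probe measuring locus l carries
#' baseline(l) x dosage x fold x platform offset x log-normal noise,
#' where dosage applies when the sample's pool is the trisomic pool and
#' the locus sits on the dosage chromosome, and fold applies when the
#' locus belongs to an injected segment or sex-biased set targeting the
#' pool. Baselines are log-normal across loci and shared by all samples.
#' Samples are assigned to platforms round-robin; each platform covers a
#' seeded random subset of loci with 1..max multiplicity. A stated
#' fraction of values is then set missing, another replaced by
#' non-positive junk; platforms listed in \code{log2_platforms} deposit
#' log2 values (declared in the dataset scale tag).
#'
#' @param truth A \code{synthetic_truth}.
#' @param pool_sizes Named integer vector pool_id -> number of samples.
#' @return A \code{synthetic_experiment} list: \code{datasets} (list of
#'   \code{sample_dataset}), \code{probe_map}, \code{annotation},
#'   \code{truth}, \code{truth_table} (per-locus effect TSV-ready frame),
#'   \code{platforms} (layout bookkeeping).
#' @export
generate_pools <- function(truth, pool_sizes) {
  stopifnot(inherits(truth, "synthetic_truth"), length(pool_sizes) >= 1,
            !is.null(names(pool_sizes)))
  if (any(pool_sizes < 1)) stop("every pool needs at least 1 sample")
  ann <- truth$annotation
  nloc <- nrow(ann)
  with_seed(truth$seed, {
    baseline <- stats::setNames(stats::rlnorm(nloc, log(100), 1), ann$symbol)

    # per-platform probe layout: covered loci + multiplicity
    platforms <- lapply(seq_len(truth$n_platforms), function(p) {
      cov <- truth$platform_coverage[p]
      covered <- sort(sample(nloc, max(1, round(cov * nloc))))
      mult <- sample(truth$max_probes_per_locus, length(covered), replace = TRUE)
      probe_sym <- rep(ann$symbol[covered], mult)
      probe_id <- paste0("P", p, "_", seq_along(probe_sym), "_at")
      list(platform_id = paste0("PLAT", p), probe_id = probe_id,
           probe_sym = probe_sym,
           scale = if (p %in% truth$log2_platforms) "log2" else "linear")
    })
    probe_map <- do.call(rbind, lapply(platforms, function(pl) {
      data.frame(platform_id = pl$platform_id, probe_id = pl$probe_id,
                 symbol = pl$probe_sym, stringsAsFactors = FALSE)
    }))
    # one unmapped control probe per platform, like array controls
    probe_map <- rbind(probe_map, data.frame(
      platform_id = vapply(platforms, `[[`, "", "platform_id"),
      probe_id = "AFFX_ctrl", symbol = NA_character_,
      stringsAsFactors = FALSE))
    probe_map <- validate_probe_map(probe_map, ann)

    # per-pool per-locus effect multipliers
    effect <- function(pool_id) {
      e <- rep(1, nloc)
      if (!is.na(truth$dosage_chromosome) && !is.na(truth$dosage_pool) &&
          pool_id == truth$dosage_pool) {
        e[ann$chromosome == truth$dosage_chromosome] <-
          e[ann$chromosome == truth$dosage_chromosome] * truth$dosage_factor
      }
      if (!is.null(truth$segments)) {
        for (i in seq_len(nrow(truth$segments))) {
          if (truth$segments$pool[i] != pool_id) next
          f <- truth$segments$fold[i]
          if (truth$segments$direction[i] == "under") f <- 1 / f
          j <- match(truth$segments$symbols[[i]], ann$symbol)
          e[j] <- e[j] * f
        }
      }
      if (!is.null(truth$sex_loci)) {
        for (i in seq_len(nrow(truth$sex_loci))) {
          if (truth$sex_loci$pool[i] != pool_id) next
          j <- match(truth$sex_loci$symbol[i], ann$symbol)
          e[j] <- e[j] * truth$sex_loci$fold[i]
        }
      }
      e
    }

    datasets <- list()
    plat_i <- 0L
    for (pool_id in names(pool_sizes)) {
      mult <- effect(pool_id)
      for (s in seq_len(pool_sizes[[pool_id]])) {
        plat_i <- plat_i + 1L
        pl <- platforms[[(plat_i - 1L) %% truth$n_platforms + 1L]]
        p_idx <- match(pl$platform_id, vapply(platforms, `[[`, "", "platform_id"))
        loc <- match(pl$probe_sym, ann$symbol)
        v <- baseline[loc] * mult[loc] *
          truth$platform_scale_offset[p_idx] *
          stats::rlnorm(length(loc), 0, truth$noise_sigma[p_idx])
        corrupt <- stats::runif(length(v))
        miss <- corrupt < truth$missing_rate
        npos <- !miss & corrupt < truth$missing_rate + truth$nonpositive_rate
        if (pl$scale == "log2") {
          # sub-floor signal is not representable on a log deposit; the
          # MCAR corruption budget goes to missingness instead
          v[miss | npos] <- NA
          v[!is.na(v)] <- log2(v[!is.na(v)])
        } else {
          v[npos] <- -round(stats::runif(sum(npos)) * 10)  # <= 0 junk
          v[miss] <- NA
        }
        v <- c(v, NA)  # the unmapped control probe, unmeasured
        names(v) <- c(pl$probe_id, "AFFX_ctrl")
        datasets[[length(datasets) + 1L]] <- sample_dataset(
          sprintf("%s_s%02d", pool_id, s), pool_id, pl$platform_id, v,
          pl$scale)
      }
    }

    truth_table <- build_truth_table(truth)
    structure(list(datasets = datasets, probe_map = probe_map,
                   annotation = ann, truth = truth,
                   truth_table = truth_table,
                   platforms = platforms, pool_sizes = pool_sizes),
              class = "synthetic_experiment")
  })
}

build_truth_table <- function(truth) {
  ann <- truth$annotation
  type <- rep("null", nrow(ann))
  fold <- rep(1, nrow(ann))
  pool <- rep(NA_character_, nrow(ann))
  if (!is.na(truth$dosage_chromosome)) {
    j <- ann$chromosome == truth$dosage_chromosome
    type[j] <- "dosage"; fold[j] <- truth$dosage_factor
    pool[j] <- truth$dosage_pool
  }
  if (!is.null(truth$segments)) {
    for (i in seq_len(nrow(truth$segments))) {
      j <- match(truth$segments$symbols[[i]], ann$symbol)
      type[j] <- "segment"
      f <- truth$segments$fold[i]
      if (truth$segments$direction[i] == "under") f <- 1 / f
      fold[j] <- f
      pool[j] <- truth$segments$pool[i]
    }
  }
  if (!is.null(truth$sex_loci)) {
    j <- match(truth$sex_loci$symbol, ann$symbol)
    type[j] <- "sex"; fold[j] <- truth$sex_loci$fold
    pool[j] <- truth$sex_loci$pool
  }
  data.frame(symbol = ann$symbol, chromosome = ann$chromosome,
             effect_type = type, fold = fold, pool_target = pool,
             stringsAsFactors = FALSE)
}

#' Write a synthetic experiment as a plain-text fixture tree
#'
#' Writes the annotation TSV, the probe-map TSV, one sample-matrix TSV
#' per platform, the ground-truth TSV and a JSON run config referencing
#' them. Re-running with the same seed is byte-identical.
#'
#' @param experiment A \code{synthetic_experiment}.
#' @param dir Output directory (created if absent).
#' @param compare Character vector of two pool ids to declare as the
#'   A/B comparison in the config (default: first two pools).
#' @param force Overwrite a non-empty existing directory (default FALSE).
#' @return The config file path, invisibly.
#' @export
write_fixture <- function(experiment, dir, compare = NULL, force = FALSE) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force) {
    stop("output directory '", dir, "' is not empty (use force = TRUE)")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(as.data.frame(experiment$annotation), file.path(dir, "annotation.tsv"))
  pm <- as.data.frame(experiment$probe_map)
  pm$symbol[is.na(pm$symbol)] <- ""
  write_tsv(pm, file.path(dir, "probe_map.tsv"))
  write_tsv(experiment$truth_table, file.path(dir, "truth.tsv"))

  pool_ids <- names(experiment$pool_sizes)
  if (is.null(compare)) compare <- utils::head(pool_ids, 2)
  ds_decl <- list()
  for (pool_id in pool_ids) {
    ds_pool <- Filter(function(d) d$pool_id == pool_id, experiment$datasets)
    by_plat <- split(ds_pool, vapply(ds_pool, `[[`, "", "platform_id"))
    for (plat in names(by_plat)) {
      fname <- sprintf("matrix_%s_%s.tsv", pool_id, plat)
      write_sample_matrix(by_plat[[plat]], file.path(dir, fname))
      ds_decl[[length(ds_decl) + 1L]] <- list(
        path = fname, platform_id = plat, pool_id = pool_id,
        scale = by_plat[[plat]][[1]]$scale)
    }
  }
  config <- list(annotation = "annotation.tsv",
                 probe_maps = list("probe_map.tsv"),
                 datasets = ds_decl,
                 compare = as.list(compare),
                 seed = experiment$truth$seed,
                 map_params = unclass(map_params()),
                 normalization_params = unclass(normalization_params()))
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(cfg_path)
}

# evaluate expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
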