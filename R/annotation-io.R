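#' Read a locus annotation table
#'
#' Reads the genome annotation that anchors every locus (gene symbol or EST
#' cluster such as \code{"Hs.355689"}) to chromosome coordinates. Coordinates
#' are 1-based and inclusive throughout the package, matching the convention
#' of printed segment bounds such as 50,250,001--50,750,000.
#'
#' @param path Path to a tab-delimited file with header columns
#'   \code{symbol}, \code{chromosome}, \code{start}, \code{end} and an
#'   optional \code{cytoband}.
#' @return A data frame of class \code{locus_annotation} with columns
#'   \code{symbol}, \code{chromosome} (factor levels = declared chromosome
#'   list, in order of first appearance), \code{start}, \code{end},
#'   \code{cytoband} (\code{NA} when absent). Row order follows the file.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_checked(path, c("symbol", "chromosome", "start", "end"))
  if (!"cytoband" %in% names(df)) df$cytoband <- rep(NA_character_, nrow(df))
  df$cytoband[!is.na(df$cytoband) & !nzchar(df$cytoband)] <- NA_character_
  df <- df[, c("symbol", "chromosome", "start", "end", "cytoband")]
  df$start <- parse_coord(df$start, path, "start")
  df$end <- parse_coord(df$end, path, "end")
  validate_annotation(df)
}

#' Construct/validate a locus annotation object
#'
#' @param df Data frame with columns \code{symbol}, \code{chromosome},
#'   \code{start}, \code{end} and optionally \code{cytoband}.
#' @return The validated \code{locus_annotation} data frame.
#' @export
validate_annotation <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("symbol", "chromosome", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!"cytoband" %in% names(df)) df$cytoband <- rep(NA_character_, nrow(df))
  df$symbol <- as.character(df$symbol)
  df$chromosome <- as.character(df$chromosome)
  if (any(!nzchar(df$symbol)) || anyNA(df$symbol)) {
    stop("annotation contains an empty locus symbol")
  }
  dup <- df$symbol[duplicated(df$symbol)]
  if (length(dup) > 0) {
    stop("duplicate locus symbol in annotation: ", dup[1])
  }
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 1 | df$end < df$start)
  if (length(bad) > 0) {
    stop(sprintf("invalid coordinates for locus '%s' (row %d): start=%s end=%s",
                 df$symbol[bad[1]], bad[1],
                 format(df$start[bad[1]]), format(df$end[bad[1]])))
  }
  rownames(df) <- NULL
  class(df) <- c("locus_annotation", "data.frame")
  df
}

#' Read a probe-to-locus mapping table
#'
#' Probe identifiers are decoded to locus symbols through a static mapping
#' table (one locus per probe). An empty symbol marks an unmapped probe
#' (e.g. an array control); unmapped probes are retained and counted.
#'
#' @param path Tab-delimited file with header columns \code{platform_id},
#'   \code{probe_id}, \code{symbol} (symbol may be empty).
#' @param annotation A \code{locus_annotation}; every non-empty symbol must
#'   exist in it.
#' @return A data frame of class \code{probe_map} with columns
#'   \code{platform_id}, \code{probe_id}, \code{symbol} (\code{NA} =
#'   unmapped) and an attribute \code{n_unmapped}.
#' @export
read_probe_map <- function(path, annotation) {
  df <- read_tsv_checked(path, c("platform_id", "probe_id", "symbol"))
  validate_probe_map(df, annotation)
}

#' @rdname read_probe_map
#' @param df Data frame with the probe-map columns.
#' @export
validate_probe_map <- function(df, annotation) {
  stopifnot(is.data.frame(df), inherits(annotation, "locus_annotation"))
  for (col in c("platform_id", "probe_id", "symbol")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$symbol[!is.na(df$symbol) & !nzchar(df$symbol)] <- NA_character_
  key <- paste(df$platform_id, df$probe_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf("duplicate probe assignment: platform '%s' probe '%s'",
                 df$platform_id[dup[1]], df$probe_id[dup[1]]))
  }
  mapped <- !is.na(df$symbol)
  unknown <- setdiff(unique(df$symbol[mapped]), annotation$symbol)
  if (length(unknown) > 0) {
    stop("probe map references symbols absent from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  rownames(df) <- NULL
  attr(df, "n_unmapped") <- sum(!mapped)
  class(df) <- c("probe_map", "data.frame")
  df
}

#' Read a probe-level sample matrix
#'
#' Reads a GEO-series-matrix-like table: first column probe identifiers,
#' one further column per sample. Blank cells and the literal \code{NA}
#' are missing values. Values are kept raw; linearization of log-scale
#' deposits happens in the normalization step.
#'
#' @param path Tab-delimited file, header row giving sample ids.
#' @param platform_id Platform the probes belong to.
#' @param pool_id Biological condition pool the samples belong to.
#' @param scale One of \code{"linear"}, \code{"log2"}, \code{"log10"},
#'   \code{"ln"} -- the scale the values were deposited on.
#' @return A list of \code{sample_dataset} objects, one per sample column.
#'   Each is a list with fields \code{sample_id}, \code{pool_id},
#'   \code{platform_id}, \code{scale} and \code{values} (named numeric
#'   vector over probe ids, \code{NA} = missing).
#' @export
read_sample_matrix <- function(path, platform_id, pool_id, scale = "linear") {
  check_scale(scale)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty sample matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2) stop("no samples: sample matrix '", path,
                               "' has no value columns")
  ncol_exp <- length(header)
  sample_ids <- header[-1]
  nprobe <- length(fields) - 1L
  probes <- character(nprobe)
  vals <- matrix(NA_real_, nrow = nprobe, ncol = ncol_exp - 1L)
  for (i in seq_len(nprobe)) {
    row <- fields[[i + 1L]]
    # trailing empty cells are dropped by strsplit; pad them back
    if (length(row) < ncol_exp) row <- c(row, rep("", ncol_exp - length(row)))
    if (length(row) != ncol_exp) {
      stop(sprintf("ragged row at line %d of '%s': %d fields, expected %d",
                   i + 1L, path, length(row), ncol_exp))
    }
    probes[i] <- row[1]
    cell <- row[-1]
    cell[cell == "" | cell == "NA"] <- NA
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at line %d of '%s'",
                   cell[bad[1]], i + 1L, path))
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(probes)) {
    stop("duplicate probe id in sample matrix: ", probes[duplicated(probes)][1])
  }
  lapply(seq_along(sample_ids), function(j) {
    v <- vals[, j]
    names(v) <- probes
    sample_dataset(sample_ids[j], pool_id, platform_id, v, scale)
  })
}

#' Construct a sample dataset
#'
#' @param sample_id Sample identifier, unique within a run.
#' @param pool_id Condition pool identifier.
#' @param platform_id Platform identifier.
#' @param values Named numeric vector probe_id -> value (\code{NA} missing).
#' @param scale Declared value scale.
#' @return A \code{sample_dataset} object.
#' @export
sample_dataset <- function(sample_id, pool_id, platform_id, values,
                           scale = "linear") {
  check_scale(scale)
  stopifnot(is.numeric(values), !is.null(names(values)),
            all(nzchar(names(values))))
  structure(
    list(sample_id = as.character(sample_id),
         pool_id = as.character(pool_id),
         platform_id = as.character(platform_id),
         values = values, scale = scale),
    class = "sample_dataset")
}

#' @export
print.sample_dataset <- function(x, ...) {
  cat(sprintf("<sample_dataset> %s  pool=%s platform=%s scale=%s  %d probes (%d missing)\n",
              x$sample_id, x$pool_id, x$platform_id, x$scale,
              length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Decode probe-level values to locus-level data points
#'
#' Each mapped probe carrying a non-missing value yields one data point
#' under its locus; probes without an available expression value are not
#' considered, and unmapped probes contribute nothing. A locus measured by
#' several probes on one array therefore contributes several data points
#' per sample.
#'
#' @param dataset A \code{sample_dataset}.
#' @param probe_map A \code{probe_map} covering the dataset's platform.
#' @param strict If \code{TRUE}, a probe absent from the probe map is an
#'   error; if \code{FALSE} (default) such probes are skipped and counted
#'   in the \code{n_skipped} attribute.
#' @return A data frame (long form) with columns \code{symbol},
#'   \code{sample_id}, \code{probe_id}, \code{value}; one row per data
#'   point. Attribute \code{n_skipped} counts probes absent from the map.
#' @export
decode_probes <- function(dataset, probe_map, strict = FALSE) {
  stopifnot(inherits(dataset, "sample_dataset"), inherits(probe_map, "probe_map"))
  pm <- probe_map[probe_map$platform_id == dataset$platform_id, , drop = FALSE]
  probes <- names(dataset$values)
  idx <- match(probes, pm$probe_id)
  absent <- is.na(idx)
  if (any(absent) && strict) {
    stop(sprintf("probe '%s' on platform '%s' absent from probe map",
                 probes[which(absent)[1]], dataset$platform_id))
  }
  sym <- rep(NA_character_, length(probes))
  sym[!absent] <- pm$symbol[idx[!absent]]
  keep <- !absent & !is.na(sym) & !is.na(dataset$values)
  out <- data.frame(symbol = sym[keep],
                    sample_id = rep(dataset$sample_id, sum(keep)),
                    probe_id = probes[keep],
                    value = unname(dataset$values[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(absent)
  out
}

#' Write annotation / probe-map / pool tables as TSV
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a set of sample datasets as one sample-matrix TSV
#'
#' All datasets must share a platform (one matrix per platform file).
#'
#' @param datasets List of \code{sample_dataset} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sample_matrix <- function(datasets, path) {
  stopifnot(length(datasets) >= 1)
  probes <- names(datasets[[1]]$values)
  mat <- vapply(datasets, function(d) {
    stopifnot(identical(names(d$values), probes))
    d$values
  }, numeric(length(probes)))
  mat <- matrix(mat, nrow = length(probes))
  cells <- ifelse(is.na(mat), "", format_num(mat))
  header <- paste(c("probe_id", vapply(datasets, `[[`, "", "sample_id")),
                  collapse = "\t")
  body <- apply(cbind(probes, cells), 1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# ---- internal helpers -------------------------------------------------------

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "", comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("file '", path, "' is missing required columns: ",
         paste(miss, collapse = ", "))
  }
  df
}

parse_coord <- function(x, path, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad) > 0) {
    stop(sprintf("non-numeric %s coordinate '%s' at line %d of '%s'",
                 col, x[bad[1]], bad[1] + 1L, path))
  }
  v
}

check_scale <- function(scale) {
  if (!is.character(scale) || length(scale) != 1 ||
      !scale %in% c("linear", "log2", "log10", "ln")) {
    stop("unknown scale tag: ", paste(scale, collapse = ", "),
         " (expected linear, log2, log10 or ln)")
  }
  invisible(scale)
}

format_num <- function(x) {
  formatC(x, format = "fg", digits = 15, width = 1)
}
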