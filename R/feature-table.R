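#' ASV feature tables
#'
#' A `feature_table` couples an ASV-by-sample count matrix with per-sample
#' metadata (group label, month, subject). It is the common currency of the
#' preprocessing, diversity and network-construction stages.
#'
#' @param counts non-negative integer matrix, rows = ASVs, columns = samples;
#'   both dimensions must be named.
#' @param metadata data.frame with columns `sample_id`, `group`, `month`,
#'   `subject`; must cover every column of `counts`.
#' @return an object of class `feature_table` with elements `counts` and
#'   `metadata` (metadata row order defines sample order).
#' @export
feature_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_format("counts must have ASV rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_format("duplicate ASV id: ",
                rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop_format("duplicate sample id: ",
                colnames(counts)[duplicated(colnames(counts))][1])
  if (!is.numeric(counts) || any(counts < 0) || anyNA(counts))
    stop_format("counts must be non-negative numbers")
  if (any(counts != round(counts))) {
    bad <- rownames(counts)[which(rowSums(counts != round(counts)) > 0)[1]]
    stop_format("non-integer count in row ", bad)
  }
  storage.mode(counts) <- "double"
  need <- c("sample_id", "group", "month", "subject")
  if (!all(need %in% names(metadata)))
    stop_format("metadata must have columns ", paste(need, collapse = ", "))
  metadata <- as.data.frame(metadata)[, need]
  if (anyDuplicated(metadata$sample_id))
    stop_format("duplicate metadata sample_id: ",
                metadata$sample_id[duplicated(metadata$sample_id)][1])
  missing_md <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing_md))
    stop_format("metadata missing for sample ", missing_md[1])
  metadata <- metadata[metadata$sample_id %in% colnames(counts), , drop = FALSE]
  rownames(metadata) <- NULL
  counts <- counts[, metadata$sample_id, drop = FALSE]
  structure(list(counts = counts, metadata = metadata),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d ASVs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("groups: %s; months: %s\n",
              paste(sort(unique(x$metadata$group)), collapse = ", "),
              paste(sort(unique(x$metadata$month)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Subset a feature table by sample and/or ASV
#'
#' @param table a [feature_table].
#' @param samples character vector of sample ids (default: all).
#' @param asvs character vector of ASV ids (default: all).
#' @return a [feature_table] restricted to the requested rows/columns.
#' @export
subset_samples <- function(table, samples = NULL, asvs = NULL) {
  stopifnot(inherits(table, "feature_table"))
  samples <- samples %||% colnames(table$counts)
  asvs <- asvs %||% rownames(table$counts)
  md <- table$metadata[table$metadata$sample_id %in% samples, , drop = FALSE]
  feature_table(table$counts[asvs, md$sample_id, drop = FALSE], md)
}

#' Read a feature table and its sample metadata from TSV
#'
#' The table file follows the QIIME-style convention: tab-separated, first
#' column header `#OTU ID`, remaining columns one per sample. The metadata
#' file is tab-separated with columns `sample_id`, `group`, `month`,
#' `subject`. Sample order in the returned object follows the metadata file.
#'
#' @param table_path path to the count TSV.
#' @param metadata_path path to the metadata TSV.
#' @return a [feature_table].
#' @export
read_feature_table <- function(table_path, metadata_path) {
  if (!file.exists(table_path)) stop_format("no such file: ", table_path)
  if (!file.exists(metadata_path)) stop_format("no such file: ", metadata_path)
  tab <- read.delim(table_path, check.names = FALSE, comment.char = "",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_format("count table needs >= 1 sample column")
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- ids[which(rowSums(is.na(m)) > 0)[1]]
    stop_format("non-numeric count in row ", bad)
  }
  rownames(m) <- ids
  md <- read.delim(metadata_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  feature_table(m, md)
}

#' Write a feature table (and optionally metadata) to TSV
#'
#' @param table a [feature_table].
#' @param table_path output path for the count TSV (`#OTU ID` convention,
#'   counts as 0-decimal integers).
#' @param metadata_path optional output path for the metadata TSV.
#' @return invisibly, `table`.
#' @export
write_feature_table <- function(table, table_path, metadata_path = NULL) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(`#OTU ID` = rownames(table$counts),
                   format(table$counts, scientific = FALSE, trim = TRUE),
                   check.names = FALSE)
  write.table(df, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    write.table(table$metadata, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(table)
}

#' Remove rare ASVs, stratified by time point
#'
#' Within each month stratum an ASV fails if its summed count is below
#' `min_total` or it occurs (count > 0) in fewer than `min_samples` samples.
#' An ASV is dropped from the table when it fails in every stratum, i.e. it is
#' retained if at least one time point supports it. With a single time point
#' this is the plain low-abundance filter.
#'
#' @param table a [feature_table].
#' @param min_total minimum summed count per stratum (default 10).
#' @param min_samples minimum number of samples with a non-zero count
#'   (default 3).
#' @return the filtered [feature_table]; empty result raises a warning.
#' @export
filter_low_abundance <- function(table, min_total = 10, min_samples = 3) {
  stopifnot(inherits(table, "feature_table"))
  months <- unique(table$metadata$month)
  pass_any <- rep(FALSE, nrow(table$counts))
  for (m in months) {
    cols <- table$metadata$sample_id[table$metadata$month == m]
    sub <- table$counts[, cols, drop = FALSE]
    pass_any <- pass_any |
      (rowSums(sub) >= min_total & rowSums(sub > 0) >= min_samples)
  }
  if (!any(pass_any)) {
    warning("low-abundance filter removed every ASV; returning empty table")
  }
  out <- table
  out$counts <- table$counts[pass_any, , drop = FALSE]
  out
}

#' Rarefy samples to a common depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads.
#' Samples with fewer reads than `depth` are dropped (with a message).
#'
#' @param table a [feature_table].
#' @param depth target reads per sample (default 37800).
#' @param seed integer seed for reproducible subsampling.
#' @return rarefied [feature_table]; every retained sample sums to `depth`.
#' @export
rarefy <- function(table, depth = 37800, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (depth <= 0) stop_config("depth must be > 0")
  totals <- colSums(table$counts)
  keep <- names(totals)[totals >= depth]
  if (!length(keep)) stop_config("all samples are below rarefaction depth ",
                                 depth)
  dropped <- setdiff(colnames(table$counts), keep)
  if (length(dropped))
    message("rarefy: dropped ", length(dropped), " sample(s) below depth: ",
            paste(dropped, collapse = ", "))
  counts <- with_seed(seed, {
    vapply(keep, function(s) {
      x <- table$counts[, s]
      pool <- rep.int(seq_along(x), x)
      kept <- sample(pool, depth)
      tabulate(kept, nbins = length(x))
    }, numeric(nrow(table$counts)))
  })
  rownames(counts) <- rownames(table$counts)
  md <- table$metadata[table$metadata$sample_id %in% keep, , drop = FALSE]
  feature_table(counts, md)
}

#' Keep ASVs present in at least a fraction of samples
#'
#' Retains ASVs with a non-zero count in at least
#' `ceiling(min_fraction * n_samples)` samples. The half-sample default is the
#' reliability filter applied before correlation-network construction.
#'
#' @param table a [feature_table].
#' @param min_fraction required prevalence fraction in (0, 1] (default 0.5).
#' @return the filtered [feature_table].
#' @export
prevalence_filter <- function(table, min_fraction = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  if (min_fraction <= 0 || min_fraction > 1)
    stop_config("min_fraction must be in (0, 1]")
  need <- ceiling(min_fraction * ncol(table$counts))
  keep <- rowSums(table$counts > 0) >= need
  out <- table
  out$counts <- table$counts[keep, , drop = FALSE]
  out
}

#' Log-transform counts
#'
#' Elementwise `log_base(count + pseudocount)`. The base-10, pseudocount-1
#' default is the conventional transform preceding Pearson correlation of
#' ASV abundances.
#'
#' @param table a [feature_table] or a plain count matrix.
#' @param base logarithm base (default 10).
#' @param pseudocount added before taking logs; must be > 0 (default 1).
#' @return a numeric matrix (ASV x sample).
#' @export
log_transform <- function(table, base = 10, pseudocount = 1) {
  if (pseudocount <= 0) stop_config("pseudocount must be > 0")
  m <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  log(m + pseudocount, base = base)
}
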