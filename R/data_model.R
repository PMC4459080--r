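#' Construct an expression dataset
#'
#' Bundles a feature-by-sample expression matrix with per-sample metadata for
#' one molecular layer. mRNA values are expected on a log2 scale after
#' upstream normalisation; protein quantifications (e.g. AQUA immunofluorescence
#' scores) should be log2-transformed before entering the pipeline.
#'
#' @param values Numeric matrix, features as rows (rownames = feature ids),
#'   samples as columns (colnames = sample ids). Missing measurements are
#'   encoded as `NA`; non-finite values other than `NA` are rejected.
#' @param samples Data frame of sample metadata with columns `sample_id`,
#'   `condition` (token, or `"CONTROL"` for untreated samples),
#'   `tumour_model`, `time_point` (day label, numeric), `replicate`
#'   (positive integer). Order need not match the matrix columns.
#' @param layer `"mrna"` or `"protein"`.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `layer`, `values` and `samples` (metadata reordered to match the matrix
#'   columns).
#' @export
expression_dataset <- function(values, samples, layer = c("mrna", "protein")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  required <- c("sample_id", "condition", "tumour_model", "time_point", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample ids in metadata: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  only_matrix <- setdiff(colnames(values), samples$sample_id)
  only_meta <- setdiff(samples$sample_id, colnames(values))
  if (length(only_matrix) || length(only_meta))
    stop("sample ids do not match between matrix and metadata; ",
         "matrix-only: [", paste(only_matrix, collapse = ", "), "]; ",
         "metadata-only: [", paste(only_meta, collapse = ", "), "]")
  bad <- which(!is.finite(values) & !is.na(values), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite expression value at feature ", rownames(values)[bad[1, 1]],
         ", sample ", colnames(values)[bad[1, 2]])
  rownames(samples) <- samples$sample_id
  samples <- samples[colnames(values), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(layer = layer, values = values, samples = samples),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  n_ctrl <- sum(x$samples$condition == "CONTROL")
  cat(sprintf("ExpressionDataset [%s]: %d features x %d samples (%d control)\n",
              x$layer, nrow(x$values), ncol(x$values), n_ctrl))
  cat("conditions:",
      paste(sort(unique(x$samples$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression dataset from delimited text
#'
#' Reads a feature-by-sample matrix (first column feature id, header row of
#' sample ids) plus a sample metadata sheet and returns a validated
#' [expression_dataset()]. The delimiter is sniffed from the file extension
#' (`.csv` comma, otherwise tab).
#'
#' @param path Path to the expression matrix (TSV/CSV).
#' @param layer `"mrna"` or `"protein"`.
#' @param meta_path Path to the sample metadata table (TSV/CSV) with columns
#'   `sample_id`, `condition`, `tumour_model`, `time_point`, `replicate`
#'   (a `layer` column, if present, is used to subset to the requested layer).
#' @return An `ExpressionDataset`.
#' @export
read_expression_dataset <- function(path, layer = c("mrna", "protein"), meta_path) {
  layer <- match.arg(layer)
  raw <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"")
  if (ncol(raw) < 2) stop("expression matrix needs a feature id column plus samples")
  feat <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                dimnames = dimnames(cells)))
  bad <- which(is.na(num) & !(is.na(cells) | cells %in% c("", "NA", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at feature ", feat[bad[1, 1]],
         ", sample ", colnames(cells)[bad[1, 2]],
         " ('", cells[bad[1, 1], bad[1, 2]], "')")
  rownames(num) <- feat
  meta <- utils::read.table(meta_path, header = TRUE, sep = .sniff_sep(meta_path),
                            stringsAsFactors = FALSE, quote = "\"")
  if ("layer" %in% names(meta)) meta <- meta[meta$layer == layer, , drop = FALSE]
  expression_dataset(num, meta, layer = layer)
}

#' Write an expression dataset to delimited text
#'
#' Inverse of [read_expression_dataset()]: writes the matrix (first column
#' `feature_id`) and the metadata sheet as tab-delimited text.
#'
#' @param dataset An `ExpressionDataset`.
#' @param path,meta_path Output paths for matrix and metadata.
#' @return Invisibly, `dataset`.
#' @export
write_expression_dataset <- function(dataset, path, meta_path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  df <- data.frame(feature_id = rownames(dataset$values),
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- dataset$samples
  meta$layer <- dataset$layer
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

.sniff_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Collapse probes to one row per feature
#'
#' Microarray platforms carry several probes per gene; when pairing mRNA with
#' a single protein measurement, the probe with the highest average expression
#' across all its measurements is retained for each gene. Ties are broken by
#' the lexicographically smallest probe id, so the collapse is deterministic.
#'
#' @param dataset An mRNA-layer `ExpressionDataset` whose rows are probes.
#' @param probe_map Data frame with columns `probe_id`, `feature_id` mapping
#'   every probe in `dataset` to its gene.
#' @return An `ExpressionDataset` with one row per feature; rows are the
#'   retained probes' values, rownames replaced by feature ids.
#' @export
collapse_probes <- function(dataset, probe_map) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!all(c("probe_id", "feature_id") %in% names(probe_map)))
    stop("probe_map needs columns probe_id, feature_id")
  probe_map$probe_id <- as.character(probe_map$probe_id)
  probe_map$feature_id <- as.character(probe_map$feature_id)
  unmapped <- setdiff(rownames(dataset$values), probe_map$probe_id)
  if (length(unmapped))
    stop("probes absent from probe_map: ", paste(unmapped, collapse = ", "))
  probe_map <- probe_map[probe_map$probe_id %in% rownames(dataset$values), , drop = FALSE]
  feats <- sort(unique(probe_map$feature_id))
  keep <- vapply(feats, function(f) {
    probes <- sort(probe_map$probe_id[probe_map$feature_id == f])
    if (!length(probes)) stop("feature with zero probes: ", f)
    means <- rowMeans(dataset$values[probes, , drop = FALSE], na.rm = TRUE)
    # which.max returns the first maximum; probes are sorted, so ties go to
    # the smallest probe id
    probes[which.max(means)]
  }, character(1))
  vals <- dataset$values[keep, , drop = FALSE]
  rownames(vals) <- feats
  expression_dataset(vals, dataset$samples, layer = dataset$layer)
}

#' Read a two-column probe-to-feature map
#'
#' @param path TSV/CSV with columns `probe_id`, `feature_id` (header optional
#'   in that order).
#' @return Data frame with columns `probe_id`, `feature_id`.
#' @export
read_probe_map <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                          stringsAsFactors = FALSE)
  if (!all(c("probe_id", "feature_id") %in% names(pm))) {
    pm <- utils::read.table(path, header = FALSE, sep = .sniff_sep(path),
                            stringsAsFactors = FALSE)
    names(pm)[1:2] <- c("probe_id", "feature_id")
  }
  pm[, c("probe_id", "feature_id")]
}
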