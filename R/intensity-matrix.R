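#' Construct an IntensityMatrix
#'
#' The central container of the pipeline: a proteins-by-samples matrix of
#' log2 intensities (missing values as `NA`) plus per-sample metadata for a
#' paired plaque / non-plaque design.
#'
#' @param values Numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids). Values on log2 scale;
#'   `NA` encodes a protein not detected in a sample.
#' @param metadata Data frame with one row per sample and columns
#'   `sample_id`, `model`, `age_months`, `region` (`"plaque"` or
#'   `"nonplaque"`), `pair_id`, `replicate`.
#' @param validate Check pairing and identifier invariants (default `TRUE`).
#'
#' @return An object of class `IntensityMatrix`: a list with elements
#'   `values` and `metadata`.
#' @export
IntensityMatrix <- function(values, metadata, validate = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have protein ids as rownames and sample ids as colnames")
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  required <- c("sample_id", "model", "age_months", "region", "pair_id", "replicate")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  obj <- structure(list(values = values, metadata = metadata),
                   class = "IntensityMatrix")
  if (validate) validate_intensity_matrix(obj)
  obj
}

validate_intensity_matrix <- function(m) {
  v <- m$values; md <- m$metadata
  if (anyDuplicated(rownames(v))) stop("duplicate protein ids")
  if (anyDuplicated(colnames(v))) stop("duplicate sample ids")
  if (anyNA(md$sample_id) || !setequal(md$sample_id, colnames(v)))
    stop("metadata does not key every sample in the matrix")
  if (any(!is.finite(v) & !is.na(v)))
    stop("non-finite values present (only NA may encode missingness)")
  bad_region <- setdiff(unique(md$region), c("plaque", "nonplaque"))
  if (length(bad_region))
    stop("region must be 'plaque' or 'nonplaque', found: ",
         paste(bad_region, collapse = ", "))
  # every pair id: exactly one plaque + one nonplaque capture, same stratum
  strat <- interaction(md$model, md$age_months, drop = TRUE)
  for (s in levels(strat)) {
    sub <- md[strat == s, , drop = FALSE]
    tab <- table(sub$pair_id, sub$region)
    if (!all(tab == 1L))
      stop("pair ids must occur in exactly one plaque and one nonplaque sample ",
           "within stratum ", s)
  }
  invisible(m)
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("IntensityMatrix: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  cat("strata:",
      paste(unique(paste(x$metadata$model, x$metadata$age_months, sep = ":")),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.IntensityMatrix <- function(x) dim(x$values)

#' Read an intensity matrix and its sample metadata from TSV files
#'
#' The matrix file follows the DIA-NN `pg_matrix` convention: first column
#' holds protein ids, the header row holds sample ids, tab separated.
#' Empty cells and the literal tokens `NA`/`NaN` parse as missing. If the
#' metadata file carries a header comment line `# scale=raw`, values are
#' log2-transformed on read (zeros become missing); the default
#' (`# scale=log2` or no flag) is values already on log2 scale.
#'
#' @param matrix_path Path to the matrix TSV.
#' @param metadata_path Path to the sample-metadata TSV with columns
#'   `sample_id, model, age_months, region, pair_id, replicate`.
#' @return An [IntensityMatrix].
#' @export
read_intensity_matrix <- function(matrix_path, metadata_path) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  first <- readLines(metadata_path, n = 1L)
  raw_scale <- grepl("^#\\s*scale\\s*=\\s*raw\\s*$", first)
  tab <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           na.strings = c("", "NA", "NaN"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1L]])) stop("duplicate protein ids in matrix file")
  v <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- as.character(tab[[1L]])
  md <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  missing_md <- setdiff(colnames(v), md$sample_id)
  if (length(missing_md))
    stop("samples in matrix absent from metadata: ",
         paste(missing_md, collapse = ", "))
  if (raw_scale) {
    v[!is.na(v) & v <= 0] <- NA_real_
    v <- log2(v)
  }
  IntensityMatrix(v, md)
}

#' Write an intensity matrix and its metadata to TSV files
#'
#' Missing values are written as empty strings; values round-trip to at
#' least 6 significant digits.
#'
#' @param m An [IntensityMatrix].
#' @param matrix_path,metadata_path Output paths.
#' @return Invisibly, the input `m`.
#' @export
write_intensity_matrix <- function(m, matrix_path, metadata_path) {
  v <- m$values
  out <- data.frame(protein_id = rownames(v),
                    format(v, digits = 15, trim = TRUE, scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out[-1L][is.na(v)] <- ""
  colnames(out) <- c("protein_id", colnames(v))
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}

#' Read a contaminant pattern list
#'
#' One exact id or substring pattern per line; `#` starts a comment.
#' Matching downstream is case-insensitive substring matching.
#'
#' @param path Path to the pattern file.
#' @return Character vector of patterns.
#' @export
read_contaminant_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  pats <- lines[nzchar(lines)]
  if (!length(pats)) stop("contaminant list is empty")
  pats
}

#' Default contaminant patterns shipped with the package
#'
#' Keratin, trypsin and other common laboratory contaminants, matched as
#' case-insensitive substrings of the protein id.
#'
#' @return Character vector of patterns.
#' @export
default_contaminants <- function() {
  read_contaminant_list(system.file("extdata", "contaminants.txt",
                                    package = "plaqueomics", mustWork = TRUE))
}

#' Remove contaminant proteins
#'
#' Drops every protein whose id contains any of the supplied patterns
#' (case-insensitive substring match, so pattern `KRT` removes `AKRT1`
#' as well). Row order of survivors is preserved.
#'
#' @param m An [IntensityMatrix].
#' @param patterns Character vector of patterns (see
#'   [default_contaminants()]).
#' @return Filtered [IntensityMatrix] with attribute `n_removed`.
#' @export
filter_contaminants <- function(m, patterns = default_contaminants()) {
  stopifnot(length(patterns) >= 1L, all(nzchar(patterns)))
  ids <- rownames(m$values)
  hit <- rep(FALSE, length(ids))
  for (p in patterns)
    hit <- hit | grepl(p, ids, ignore.case = TRUE, fixed = FALSE)
  if (all(hit)) warning("contaminant filter removed every protein")
  out <- IntensityMatrix(m$values[!hit, , drop = FALSE], m$metadata,
                         validate = FALSE)
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Remove proteins detected in too few samples
#'
#' @param m An [IntensityMatrix].
#' @param min_samples Minimum number of non-missing values a protein must
#'   have to be retained (default 3; a protein with exactly `min_samples`
#'   detections is kept).
#' @return Filtered [IntensityMatrix] with attribute `n_removed`.
#' @export
filter_min_detection <- function(m, min_samples = 3L) {
  stopifnot(min_samples >= 1L)
  n_det <- rowSums(!is.na(m$values))
  keep <- n_det >= min_samples
  out <- IntensityMatrix(m$values[keep, , drop = FALSE], m$metadata,
                         validate = FALSE)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Median normalization on the log2 scale
#'
#' Applies a per-sample additive shift so that every sample's median of
#' observed values equals the grand median of the pre-normalization
#' sample medians. Missing cells stay missing; the overall intensity
#' scale is preserved for reporting.
#'
#' @param m An [IntensityMatrix]; every sample must have at least one
#'   observed value.
#' @return Normalized [IntensityMatrix].
#' @export
median_normalize <- function(m) {
  v <- m$values
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  if (anyNA(med))
    stop("sample(s) with zero observed values: ",
         paste(colnames(v)[is.na(med)], collapse = ", "))
  target <- stats::median(med)
  v <- sweep(v, 2L, med - target, "-")
  IntensityMatrix(v, m$metadata, validate = FALSE)
}

#' Extract the amyloid-beta tracer series
#'
#' Returns the tracer protein's observed values with sample metadata
#' attached, for QC of the plaque captures (the tracer's plaque signal is
#' expected to exceed the non-plaque signal and to grow with age).
#'
#' @param m An [IntensityMatrix].
#' @param tracer_id Protein id of the tracer.
#' @return Data frame with columns `sample_id, model, age_months, region,
#'   pair_id, value` (missing values dropped).
#' @export
extract_tracer <- function(m, tracer_id) {
  if (!tracer_id %in% rownames(m$values))
    stop("tracer protein not present: ", tracer_id)
  vals <- m$values[tracer_id, ]
  out <- cbind(m$metadata[, c("sample_id", "model", "age_months",
                              "region", "pair_id")],
               value = unname(vals))
  out[!is.na(out$value), , drop = FALSE]
}

#' Subset an IntensityMatrix to one model-by-age stratum
#'
#' @param m An [IntensityMatrix].
#' @param model Model label (e.g. `"5xFAD"`).
#' @param age_months Age label.
#' @return An [IntensityMatrix] restricted to that stratum's samples.
#' @export
subset_stratum <- function(m, model, age_months) {
  keep <- m$metadata$model == model & m$metadata$age_months == age_months
  if (!any(keep)) stop("no samples in stratum ", model, ":", age_months)
  IntensityMatrix(m$values[, m$metadata$sample_id[keep], drop = FALSE],
                  m$metadata[keep, , drop = FALSE], validate = FALSE)
}

#' Enumerate model-by-age strata present in a matrix
#'
#' @param m An [IntensityMatrix].
#' @return Data frame with columns `model`, `age_months`, `n_pairs`.
#' @export
list_strata <- function(m) {
  md <- m$metadata
  key <- unique(md[, c("model", "age_months")])
  key <- key[order(key$model, key$age_months), , drop = FALSE]
  key$n_pairs <- vapply(seq_len(nrow(key)), function(i) {
    sub <- md[md$model == key$model[i] & md$age_months == key$age_months[i], ]
    length(unique(sub$pair_id))
  }, integer(1))
  rownames(key) <- NULL
  key
}
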