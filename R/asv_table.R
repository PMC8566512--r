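# ASV count table container: samples x ASVs counts + sample metadata + taxonomy.

#' Construct an ASV count table
#'
#' The microbiome backbone of the package: a samples-by-ASVs integer count
#' matrix together with per-sample metadata (fraction, water layer, region,
#' station) and per-ASV taxonomy.
#'
#' @param counts Integer matrix, samples in rows, ASVs in columns. Row and
#'   column names are required and must be unique.
#' @param sample_data `data.frame` with one row per sample (matched to
#'   `rownames(counts)`); expected columns include `fraction` (`"FL"`, `"PA"`
#'   or `"sediment"`), `layer` (`"surface"`, `"epi"`, `"meso"`, `"bathy"` or
#'   `"sediment"`), `region` and `station`.
#' @param taxonomy Optional `data.frame` with one row per ASV (matched to
#'   `colnames(counts)`); typically has columns such as `family` and `class`.
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(counts, sample_data, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' needs sample rownames and ASV colnames", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) stop("ASV ids must be unique", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  sample_data <- as.data.frame(sample_data)
  if (!all(rownames(counts) %in% rownames(sample_data))) {
    stop("every sample needs a metadata row", call. = FALSE)
  }
  sample_data <- sample_data[rownames(counts), , drop = FALSE]
  if (!all(c("fraction", "layer") %in% names(sample_data))) {
    stop("sample metadata must contain 'fraction' and 'layer'", call. = FALSE)
  }
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!all(colnames(counts) %in% rownames(taxonomy))) {
      stop("every ASV needs a taxonomy row", call. = FALSE)
    }
    taxonomy <- taxonomy[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, sample_data = sample_data,
                 taxonomy = taxonomy),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d samples x %d ASVs (%s reads)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  cat("fractions:", paste(names(table(x$sample_data$fraction)), collapse = ", "), "\n")
  cat("layers:   ", paste(names(table(x$sample_data$layer)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

#' Subset an ASV table by samples and/or ASVs
#'
#' @param x An `asv_table`.
#' @param samples Sample names or logical/integer index over samples.
#' @param asvs ASV ids or logical/integer index over ASVs.
#' @return The subsetted `asv_table`.
#' @export
subset_asv_table <- function(x, samples = NULL, asvs = NULL) {
  stopifnot(inherits(x, "asv_table"))
  counts <- x$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(asvs)) counts <- counts[, asvs, drop = FALSE]
  asv_table(counts, x$sample_data[rownames(counts), , drop = FALSE],
            if (is.null(x$taxonomy)) NULL else
              x$taxonomy[colnames(counts), , drop = FALSE])
}

#' Read / write ASV tables as TSV
#'
#' On disk the count table is stored ASVs-by-samples (one `asv_id` column then
#' one integer column per sample), the layout common for amplicon tables; the
#' metadata file has one row per sample with a `sample_id` column.
#'
#' @param counts_path Path to the counts TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @param taxonomy_path Optional path to a taxonomy TSV (one row per ASV,
#'   `asv_id` column).
#' @return For the reader, an `asv_table`; the writer returns the paths
#'   invisibly.
#' @export
read_asv_table <- function(counts_path, meta_path, taxonomy_path = NULL) {
  ctab <- utils::read.delim(counts_path, check.names = FALSE, comment.char = "#")
  rownames(ctab) <- ctab$asv_id
  ctab$asv_id <- NULL
  counts <- t(as.matrix(ctab))
  meta <- utils::read.delim(meta_path, comment.char = "#")
  rownames(meta) <- meta$sample_id
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    tax <- utils::read.delim(taxonomy_path, comment.char = "#")
    rownames(tax) <- tax$asv_id
  }
  asv_table(counts, meta, tax)
}

#' @rdname read_asv_table
#' @param x An `asv_table` to write.
#' @export
write_asv_table <- function(x, counts_path, meta_path, taxonomy_path = NULL) {
  stopifnot(inherits(x, "asv_table"))
  ctab <- data.frame(asv_id = colnames(x$counts), t(x$counts),
                     check.names = FALSE)
  utils::write.table(ctab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = rownames(x$sample_data), x$sample_data)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(taxonomy_path) && !is.null(x$taxonomy)) {
    tax <- data.frame(asv_id = rownames(x$taxonomy), x$taxonomy)
    utils::write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(counts_path, meta_path))
}
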