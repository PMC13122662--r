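## Matrix Market + TSV readers/writers, QC arithmetic and run configuration.

#' Read a count matrix (Matrix Market + label TSVs)
#'
#' Reads `<path>` in Matrix Market coordinate format together with its
#' companion row-label and column-label files (defaults: same basename with
#' `genes.tsv` / `barcodes.tsv` alongside). Labels must match the declared
#' dimensions; mismatches raise an error naming the offending file.
#'
#' @param path Path to the `.mtx` file.
#' @param genes_path,barcodes_path Optional label file paths (one label per
#'   line, first column used).
#' @return Sparse `dgCMatrix` with gene and barcode dimnames.
#' @export
read_count_matrix <- function(path,
                              genes_path = file.path(dirname(path), "genes.tsv"),
                              barcodes_path = file.path(dirname(path),
                                                        "barcodes.tsv")) {
  m <- withCallingHandlers(
    tryCatch(Matrix::readMM(path),
             error = function(e) stop("failed to read ", path, ": ",
                                      conditionMessage(e), call. = FALSE)),
    warning = function(w) stop("failed to read ", path, ": ",
                               conditionMessage(w), call. = FALSE))
  m <- as(m, "CsparseMatrix")
  if (file.exists(genes_path)) {
    genes <- read.delim(genes_path, header = FALSE,
                        stringsAsFactors = FALSE)[, 1]
    if (length(genes) != nrow(m))
      stop(genes_path, ": ", length(genes), " labels for ", nrow(m),
           " matrix rows")
    rownames(m) <- genes
  }
  if (file.exists(barcodes_path)) {
    bc <- read.delim(barcodes_path, header = FALSE,
                     stringsAsFactors = FALSE)[, 1]
    if (length(bc) != ncol(m))
      stop(barcodes_path, ": ", length(bc), " labels for ", ncol(m),
           " matrix columns")
    colnames(m) <- bc
  }
  m
}

#' Write a count matrix (Matrix Market + label TSVs)
#'
#' @param m Matrix with dimnames.
#' @param path Output `.mtx` path; `genes.tsv` and `barcodes.tsv` are
#'   written alongside.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(Matrix(m, sparse = TRUE), "generalMatrix"), path)
  if (!is.null(rownames(m)))
    writeLines(rownames(m), file.path(dirname(path), "genes.tsv"))
  if (!is.null(colnames(m)))
    writeLines(colnames(m), file.path(dirname(path), "barcodes.tsv"))
  invisible(path)
}

#' Mapping-rate QC percentage
#'
#' `100 * mapped / total`, rounded half-up to one decimal, matching the
#' conventional read-accounting style of sequencing QC reports.
#'
#' @param mapped_reads Number of mapped reads.
#' @param total_reads Total reads, `> 0`.
#' @return Percentage with one decimal.
#' @export
qc_mapping_summary <- function(mapped_reads, total_reads) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (mapped_reads < 0) stop("mapped_reads must be non-negative")
  if (mapped_reads > total_reads)
    stop("mapped_reads exceeds total_reads")
  floor(1000 * mapped_reads / total_reads + 0.5) / 10
}

.config_known_keys <- c("simulate", "sim", "counts", "tags", "out_dir",
                        "cell_calling", "demux", "bgcorrect", "preprocess",
                        "ensemble", "trajectory", "landscape", "markers",
                        "seed", "log_level", "resume")

#' Read and validate a pipeline run configuration
#'
#' YAML with top-level blocks for each stage; unknown top-level keys are
#' rejected. See [pipeline_run()] for the recognised blocks.
#'
#' @param path YAML file path, or a list already in memory.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), .config_known_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$demux$remove_fraction)) {
    rf <- cfg$demux$remove_fraction
    if (rf < 0 || rf >= 1)
      stop("demux.remove_fraction must be in [0, 1)")
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}
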