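#' Validate a raw count matrix
#'
#' Checks the contract shared by the bulk and single-cell stages: an integer
#' gene-by-sample (or gene-by-cell) matrix with unique, non-empty gene symbols
#' as rownames and unique sample/cell identifiers as colnames.
#'
#' @param counts numeric matrix, genes in rows, samples/cells in columns.
#' @return the matrix, invisibly, after validation.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("counts must have at least 2 genes and 2 samples")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene symbols (rownames) and sample identifiers (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene symbols: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    stop("counts must be integral")
  invisible(counts)
}

#' Read a count matrix from dense TSV or a 10x-style MTX directory
#'
#' Dense layout: tab-separated, first column gene symbols, header row of
#' sample identifiers. Sparse layout: a directory containing `matrix.mtx`,
#' `features.tsv` (first column used as gene symbol) and `barcodes.tsv`.
#'
#' @param path path to a TSV file or an MTX directory.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    m <- read_counts_mtx(path)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    if (ncol(dt) < 3L) stop("malformed counts TSV: need gene column plus >= 2 samples")
    genes <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in ", path)
    rownames(m) <- genes
    storage.mode(m) <- "double"
  }
  validate_counts(m)
  m
}

read_counts_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, "features.tsv")
  barc <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feat, barc))
    if (!file.exists(f)) stop("missing MTX component: ", f)
  sm <- Matrix::readMM(mtx)
  genes <- data.table::fread(feat, header = FALSE, sep = "\t")[[1L]]
  cells <- data.table::fread(barc, header = FALSE, sep = "\t")[[1L]]
  if (length(genes) != nrow(sm))
    stop("features file has ", length(genes), " rows but matrix has ", nrow(sm))
  if (length(cells) != ncol(sm))
    stop("barcodes file has ", length(cells), " rows but matrix has ", ncol(sm))
  m <- as.matrix(sm)
  dimnames(m) <- list(as.character(genes), as.character(cells))
  m
}

#' Write a count matrix
#'
#' @param counts gene-by-sample matrix.
#' @param path output TSV path, or a directory (created) for the sparse
#'   MTX triple when `sparse = TRUE`.
#' @param sparse write the 10x-style MTX directory layout instead of dense TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, sparse = FALSE) {
  if (sparse) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), file.path(path, "matrix.mtx"))
    data.table::fwrite(data.table::data.table(rownames(counts)),
                       file.path(path, "features.tsv"), col.names = FALSE, sep = "\t")
    data.table::fwrite(data.table::data.table(colnames(counts)),
                       file.path(path, "barcodes.tsv"), col.names = FALSE, sep = "\t")
  } else {
    dt <- data.table::data.table(gene = rownames(counts))
    dt <- cbind(dt, data.table::as.data.table(counts))
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

#' Read a cohort design sheet
#'
#' CSV with header `sample_id,patient_id,arm,week,tissue` mapping each bulk
#' sample to its patient, treatment arm (etrolizumab/placebo), week (0 or 14)
#' and tissue label.
#'
#' @param path CSV path.
#' @return data.frame with those five columns.
#' @export
read_design <- function(path) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  validate_design(d)
}

validate_design <- function(design) {
  need <- c("sample_id", "patient_id", "arm", "week", "tissue")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design sheet missing columns: ", paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  design$patient_id <- as.character(design$patient_id)
  design$arm <- as.character(design$arm)
  design$week <- as.integer(design$week)
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  if (anyDuplicated(design[, c("patient_id", "week")]))
    stop("a (patient_id, week) pair occurs more than once")
  if (!all(design$week %in% c(0L, 14L))) stop("week must be 0 or 14")
  design[, need]
}

#' Write the cohort design sheet
#' @param design design data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  data.table::fwrite(design, path)
  invisible(path)
}

#' Read gene panels from a YAML or JSON file
#'
#' The file maps panel name to a character vector of gene symbols.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return named list of character vectors.
#' @export
read_panels <- function(path) {
  panels <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lapply(panels, function(p) {
    p <- as.character(p)
    if (!length(p)) stop("empty gene panel in ", path)
    if (anyDuplicated(p)) stop("duplicate symbols in a panel")
    p
  })
}

#' Default gene panels
#'
#' The five-gene T cell activation panel (CD40LG, TNFRSF4, IL2RA, CD69,
#' TNFRSF9), cytotoxic mediator genes, T cell cytokines, innate cytokines,
#' and the planted cytotoxic program used by the single-cell simulator.
#'
#' @return named list of character vectors.
#' @export
default_panels <- function() {
  list(
    activation = c("CD40LG", "TNFRSF4", "IL2RA", "CD69", "TNFRSF9"),
    cytotoxic = c("GNLY", "GZMB", "GZMH", "FASLG", "PRF1", "GZMK"),
    tcell_cytokines = c("IFNG", "IL17F", "IL22"),
    innate_cytokines = c("IL12A", "IL18", "IL15"),
    cytotoxic_program = c("GNLY", "GZMB", "GZMH", "PRF1", "FASLG", "GZMK", "KLRD1")
  )
}
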