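#' Median-of-ratios size factors
#'
#' Per-sample scaling constants equalizing sequencing depth and composition.
#' For each reference gene g (a gene with strictly positive counts in every
#' sample) the ratio of its count in sample j to its geometric mean across all
#' samples is formed; the size factor of sample j is the median of these
#' ratios. Genes with a zero in any sample carry no depth information under
#' the geometric mean and are excluded from the reference set.
#'
#' @param counts gene-by-sample count matrix (see [validate_counts()]).
#' @return named numeric vector of positive size factors, one per sample.
#' @export
compute_size_factors <- function(counts) {
  validate_counts(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) stop("no reference genes: every gene has a zero in some sample")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  # median over reference genes of K_gj / geomean(K_g.)
  sf <- apply(logc - loggeo, 2L, function(lr) exp(stats::median(lr)))
  if (any(!is.finite(sf) | sf <= 0))
    stop("undefined size factor for sample(s): ",
         paste(colnames(counts)[!is.finite(sf) | sf <= 0], collapse = ", "))
  sf
}

#' Normalize counts by size factors, optionally log-transformed
#'
#' Divides each sample's counts by its size factor; with `log = TRUE` the
#' result is natural-log transformed as ln(1 + x).
#'
#' @param counts gene-by-sample count matrix.
#' @param size_factors positive per-sample factors, as from
#'   [compute_size_factors()].
#' @param log apply the log1p transform.
#' @return numeric matrix of the same shape, with attribute
#'   `log_transformed`.
#' @export
normalize_counts <- function(counts, size_factors = compute_size_factors(counts),
                             log = FALSE) {
  if (length(size_factors) != ncol(counts))
    stop("size factor length does not match sample count")
  if (any(!is.finite(size_factors) | size_factors <= 0))
    stop("size factors must be positive and finite")
  x <- sweep(counts, 2L, size_factors, "/")
  if (log) x <- log1p(x)
  attr(x, "log_transformed") <- log
  x
}

#' Write size factors as a two-column TSV (sample, factor)
#' @param size_factors named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_size_factors <- function(size_factors, path) {
  data.table::fwrite(
    data.table::data.table(sample = names(size_factors), factor = unname(size_factors)),
    path, sep = "\t")
  invisible(path)
}
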