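# Run `expr`, prefixing any error with the pipeline stage name.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

write_metadata <- function(out_dir, meta) {
  meta$package_version <- as.character(utils::packageVersion("itgact"))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the bulk activation-score pipeline
#'
#' Chains pair filtering, size-factor normalization, activation scoring,
#' stratification and the stratified cytotoxic/cytokine contrasts, writing
#' all tables plus a machine-readable run-metadata record to `out_dir`.
#'
#' Contrasts written: per cytotoxic gene and arm, the week-14 high-vs-low
#' comparison and the paired week-0-to-14 change in the low and high strata;
#' per T cell / innate cytokine, the pooled high-vs-low contrast. Contrasts
#' whose stratum is empty within an arm are skipped and listed in the
#' metadata.
#'
#' @param counts gene x sample raw count matrix.
#' @param design cohort design sheet (data.frame or CSV path).
#' @param out_dir output directory (created).
#' @param panels named list of gene panels (default [default_panels()]).
#' @param per_timepoint_medians see [compute_activation_score()].
#' @param rout_q ROUT FDR level for the contrasts.
#' @param seed echoed into the metadata (the pipeline itself is
#'   deterministic given its inputs).
#' @return invisibly, a list with `scores`, `size_factors`, `week14`,
#'   `change`, `cytokine` tables and the `skipped` contrasts.
#' @export
run_bulk_pipeline <- function(counts, design, out_dir,
                              panels = default_panels(),
                              per_timepoint_medians = FALSE,
                              rout_q = 0.01, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(design)) design <- read_design(design)

  design <- with_stage("pair_filter", pair_filter(design))
  counts <- with_stage("pair_filter", {
    validate_counts(counts)
    counts[, design$sample_id, drop = FALSE]
  })
  sf <- with_stage("size_factors", compute_size_factors(counts))
  norm <- with_stage("normalize", normalize_counts(counts, sf, log = FALSE))
  scores <- with_stage("score", compute_activation_score(
    norm, design, panels$activation,
    per_timepoint_medians = per_timepoint_medians))
  scores <- with_stage("stratify", stratify_patients(scores))

  skipped <- character(0)
  week14 <- list(); change <- list()
  for (arm in unique(design$arm)) {
    n_hi <- sum(scores$stratum == "high" & scores$arm == arm)
    n_lo <- sum(scores$stratum == "low" & scores$arm == arm)
    for (g in panels$cytotoxic) {
      if (n_hi >= 3L && n_lo >= 3L) {
        week14[[paste(g, arm)]] <- with_stage("compare_week14",
          compare_week14(norm, design, scores, g, arm, Q = rout_q))
      } else {
        skipped <- c(skipped, paste0("week14:", g, ":", arm))
      }
      for (st in c("low", "high")) {
        n_st <- sum(scores$stratum == st & scores$arm == arm)
        if (n_st >= 3L) {
          change[[paste(g, arm, st)]] <- with_stage("compare_week_change",
            compare_week_change(norm, design, scores, g, arm, st, Q = rout_q))
        } else {
          skipped <- c(skipped, paste0("change:", g, ":", arm, ":", st))
        }
      }
    }
  }
  week14 <- if (length(week14)) do.call(rbind, week14) else NULL
  change <- if (length(change)) do.call(rbind, change) else NULL
  cytokine <- with_stage("score_group_contrast", score_group_contrast(
    norm, design, scores,
    c(panels$tcell_cytokines, panels$innate_cytokines), Q = rout_q))

  write_size_factors(sf, file.path(out_dir, "size_factors.tsv"))
  data.table::fwrite(as.data.frame(scores), file.path(out_dir, "scores.tsv"), sep = "\t")
  if (!is.null(week14))
    data.table::fwrite(week14, file.path(out_dir, "comparisons_week14.tsv"), sep = "\t")
  if (!is.null(change))
    data.table::fwrite(change, file.path(out_dir, "comparisons_change.tsv"), sep = "\t")
  data.table::fwrite(cytokine, file.path(out_dir, "cytokine_contrasts.tsv"), sep = "\t")
  write_metadata(out_dir, list(
    pipeline = "bulk", seed = seed, rout_q = rout_q,
    per_timepoint_medians = per_timepoint_medians,
    panels = panels,
    arm_counts = as.list(attr(design, "arm_counts")),
    skipped_contrasts = skipped))

  invisible(list(design = design, size_factors = sf, scores = scores,
                 week14 = week14, change = change, cytokine = cytokine,
                 skipped = skipped))
}

#' Run the single-cell integrin-subset pipeline
#'
#' Chains mitochondrial QC, size-factor normalization with log1p scaling,
#' PCA/UMAP/Leiden clustering, ITGB7/ITGB1 subset classification, cluster
#' composition with hypergeometric subset enrichment, cluster-vs-rest marker
#' ranking for the most double-positive-enriched cluster, and the
#' fraction-expressing / mean-expression signature summary of the cytotoxic
#' panel in dp vs sp cells. All tables plus run metadata are written to
#' `out_dir`.
#'
#' @param counts gene x cell raw UMI matrix.
#' @param donors donor label per cell (optional; recycled "NA" otherwise).
#' @param out_dir output directory (created).
#' @param mito_threshold,n_pcs,resolution,k_neighbors,seed pipeline
#'   parameters (defaults 0.20, 40, 0.5, 15, 1).
#' @param panels named list of gene panels.
#' @param umap compute the UMAP embedding.
#' @return invisibly, a list with `qc`, `cells` (barcode, donor,
#'   mito_fraction, subset, cluster, umap1, umap2), `composition`,
#'   `markers`, `signature`, `dp_cluster`.
#' @export
run_sc_pipeline <- function(counts, donors = NULL, out_dir,
                            mito_threshold = 0.20, n_pcs = 40L,
                            resolution = 0.5, k_neighbors = 15L, seed = 1L,
                            panels = default_panels(), umap = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(donors)) donors <- rep(NA_character_, ncol(counts))
  if (length(donors) != ncol(counts)) stop("donor labels do not match cells")
  names(donors) <- colnames(counts)

  qc <- with_stage("qc_filter", qc_filter(counts, mito_threshold = mito_threshold))
  kept <- qc$barcode[qc$retained]
  counts_f <- counts[, kept, drop = FALSE]
  sf <- with_stage("size_factors", compute_size_factors(counts_f))
  norm <- with_stage("normalize", normalize_counts(counts_f, sf, log = TRUE))
  emb <- with_stage("embed_and_cluster", embed_and_cluster(
    norm, n_pcs = n_pcs, resolution = resolution,
    k_neighbors = k_neighbors, seed = seed, umap = umap))
  subset <- with_stage("classify_subsets", classify_subsets(counts_f))

  cells <- data.frame(barcode = kept, donor = unname(donors[kept]),
                      total_counts = qc$total_counts[qc$retained],
                      mito_fraction = qc$mito_fraction[qc$retained],
                      subset = unname(subset[kept]),
                      cluster = emb$cluster,
                      umap1 = emb$umap1, umap2 = emb$umap2, row.names = NULL)

  comp <- with_stage("cluster_composition", cluster_composition(cells))
  dp <- comp[comp$subset == "ITGB1/7dp" & is.finite(comp$p_hyper), ]
  dp_cluster <- dp$cluster[which.min(dp$p_hyper)]
  markers <- with_stage("rank_markers",
    rank_markers(norm, cells$cluster, dp_cluster))
  sig_cells <- cells$subset %in% c("ITGB1/7dp", "ITGB7sp")
  signature <- with_stage("signature_summary", signature_summary(
    counts_f[, sig_cells, drop = FALSE], norm[, sig_cells, drop = FALSE],
    cells$subset[sig_cells], panels$cytotoxic))

  data.table::fwrite(cells, file.path(out_dir, "cell_table.tsv"), sep = "\t")
  data.table::fwrite(comp, file.path(out_dir, "cluster_composition.tsv"), sep = "\t")
  data.table::fwrite(markers, file.path(out_dir, "markers.tsv"), sep = "\t")
  data.table::fwrite(signature, file.path(out_dir, "signature.tsv"), sep = "\t")
  write_metadata(out_dir, list(
    pipeline = "single-cell", seed = seed, mito_threshold = mito_threshold,
    n_pcs = n_pcs, resolution = resolution, k_neighbors = k_neighbors,
    n_cells_in = ncol(counts), n_cells_retained = length(kept),
    n_clusters = max(cells$cluster), dp_enriched_cluster = dp_cluster,
    top_upregulated = attr(markers, "top_up")))

  invisible(list(qc = qc, cells = cells, composition = comp,
                 markers = markers, signature = signature,
                 dp_cluster = dp_cluster))
}
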