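#' Mitochondrial QC filtering of cells
#'
#' Computes per-cell total counts and mitochondrial fraction and removes
#' cells whose mitochondrial content is strictly higher than the threshold
#' (a cell at exactly the threshold is retained). Zero-count cells are
#' removed with a warning.
#'
#' @param counts gene-by-cell raw count matrix.
#' @param mito_genes mitochondrial gene symbols; defaults to all genes with
#'   the `MT-` prefix.
#' @param mito_threshold mitochondrial fraction above which a cell is
#'   discarded (default 0.20).
#' @return data.frame with one row per input cell: `barcode`,
#'   `total_counts`, `mito_fraction`, `retained`.
#' @export
qc_filter <- function(counts, mito_genes = NULL, mito_threshold = 0.20) {
  validate_counts(counts)
  if (mito_threshold <= 0 || mito_threshold > 1)
    stop("mito_threshold must be in (0, 1]")
  if (is.null(mito_genes)) mito_genes <- grep("^MT-", rownames(counts), value = TRUE)
  mito_genes <- intersect(mito_genes, rownames(counts))
  if (!length(mito_genes)) stop("no mitochondrial genes found (tried MT- prefix)")
  total <- colSums(counts)
  mito <- colSums(counts[mito_genes, , drop = FALSE])
  zero <- total == 0
  if (any(zero)) warning(sum(zero), " zero-count cell(s) removed")
  frac <- ifelse(zero, NA_real_, mito / total)
  data.frame(barcode = colnames(counts),
             total_counts = unname(total),
             mito_fraction = unname(frac),
             retained = !zero & frac <= mito_threshold,
             row.names = NULL)
}

#' PCA, UMAP and Leiden clustering of a normalized cell matrix
#'
#' Reduces the log-normalized matrix to `n_pcs` principal components, builds
#' a k-nearest-neighbor graph in PC space (Euclidean), detects communities
#' with the Leiden algorithm (modularity objective) at the configured
#' resolution, and embeds the cells in 2-D with UMAP. Cluster ids are
#' relabeled 1..K by decreasing cluster size.
#'
#' @param norm log-normalized gene-by-cell matrix (QC-filtered cells).
#' @param n_pcs number of principal components (default 40; reduced with a
#'   warning when fewer cells are available).
#' @param resolution Leiden resolution (default 0.5).
#' @param k_neighbors neighbors for the kNN graph and UMAP (default 15).
#' @param seed random seed driving Leiden and UMAP.
#' @param umap compute the 2-D UMAP embedding (skipped for speed if FALSE).
#' @return data.frame per cell: `barcode`, `cluster` (1-based, size-ordered),
#'   `umap1`, `umap2`; PC scores attached as attribute `pca`.
#' @export
embed_and_cluster <- function(norm, n_pcs = 40L, resolution = 0.5,
                              k_neighbors = 15L, seed = 1L, umap = TRUE) {
  n_cells <- ncol(norm)
  if (n_cells <= n_pcs) {
    warning("fewer cells than requested PCs; reducing n_pcs to ", n_cells - 1L)
    n_pcs <- n_cells - 1L
  }
  n_pcs <- min(n_pcs, nrow(norm))
  k_neighbors <- min(k_neighbors, n_cells - 1L)
  set.seed(seed)
  pcs <- stats::prcomp(t(norm), center = TRUE, scale. = FALSE, rank. = n_pcs)$x

  knn <- FNN::get.knn(pcs, k = k_neighbors)$nn.index
  edges <- cbind(rep(seq_len(n_cells), each = k_neighbors), as.vector(t(knn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10L)
  raw <- igraph::membership(comm)
  # relabel by decreasing size so "cluster 1" is the largest
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  cluster <- unname(relabel[as.character(raw)])

  if (umap) {
    emb <- uwot::umap(pcs, n_neighbors = k_neighbors, seed = seed,
                      n_threads = 1, batch = TRUE)
  } else {
    emb <- pcs[, 1:2, drop = FALSE]
  }
  out <- data.frame(barcode = colnames(norm), cluster = cluster,
                    umap1 = emb[, 1], umap2 = emb[, 2], row.names = NULL)
  attr(out, "pca") <- pcs
  out
}

#' Classify cells into ITGB7/ITGB1 integrin subsets
#'
#' Keyed on ITGB7 first: cells without ITGB7 expression are `ITGB7neg`
#' whatever their ITGB1 status; cells expressing ITGB7 but not ITGB1 are
#' single-positive `ITGB7sp`; cells expressing both are double-positive
#' `ITGB1/7dp` (the triple-integrin-expressing population among sorted
#' alpha4+ cells). "Expressing" means raw UMI count >= `min_count`.
#'
#' @param counts gene-by-cell raw count matrix containing ITGB7 and ITGB1.
#' @param min_count positivity threshold on the raw count (default 1).
#' @return character vector of subset labels, named by cell barcode.
#' @export
classify_subsets <- function(counts, min_count = 1L) {
  for (g in c("ITGB7", "ITGB1"))
    if (!g %in% rownames(counts)) stop("gene not in matrix: ", g)
  b7 <- counts["ITGB7", ] >= min_count
  b1 <- counts["ITGB1", ] >= min_count
  out <- ifelse(!b7, "ITGB7neg", ifelse(b1, "ITGB1/7dp", "ITGB7sp"))
  stats::setNames(out, colnames(counts))
}

#' Subset composition and enrichment per cluster
#'
#' For every cluster and integrin subset: cell count, within-cluster
#' proportion, hypergeometric enrichment p-value of the subset in the
#' cluster versus all other cells, and fold-enrichment (in-cluster
#' proportion over out-of-cluster proportion). With a single cluster the
#' out-group is empty and enrichment is reported as NA.
#'
#' @param cells data.frame with columns `cluster` and `subset`.
#' @return data.frame with one row per cluster x subset: `cluster`,
#'   `subset`, `n`, `cluster_size`, `proportion`, `fold_enrichment`,
#'   `p_hyper`, and BH-adjusted `p_adj`.
#' @export
cluster_composition <- function(cells) {
  stopifnot(all(c("cluster", "subset") %in% names(cells)))
  clusters <- sort(unique(cells$cluster))
  subsets <- sort(unique(cells$subset))
  n_tot <- nrow(cells)
  rows <- list()
  for (cl in clusters) {
    in_cl <- cells$cluster == cl
    k <- sum(in_cl)
    for (s in subsets) {
      m <- sum(cells$subset == s)
      x <- sum(in_cl & cells$subset == s)
      if (k == n_tot) {
        fold <- NA_real_; p <- NA_real_
      } else {
        out_prop <- (m - x) / (n_tot - k)
        fold <- if (out_prop > 0) (x / k) / out_prop else Inf
        p <- stats::phyper(x - 1, m, n_tot - m, k, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, subset = s, n = x, cluster_size = k,
        proportion = x / k, fold_enrichment = fold, p_hyper = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_hyper, method = "BH")
  out
}

#' Rank marker genes of one cluster against the pooled rest
#'
#' Per-gene Wilcoxon rank-sum test (normal approximation with tie
#' correction) of the target cluster's cells versus all other cells on
#' log-normalized expression. Genes are ranked by the signed standardized
#' statistic, ties broken by gene symbol; BH-adjusted p-values and the
#' top-k upregulated genes are reported.
#'
#' @param norm log-normalized gene-by-cell matrix.
#' @param clusters integer cluster id per cell (aligned with `colnames(norm)`).
#' @param target_cluster cluster id to contrast against the pooled rest.
#' @param top_k length of the upregulated shortlist (default 15).
#' @return data.frame ordered by decreasing statistic: `gene`, `statistic`
#'   (signed z), `log_fc` (difference of mean log expression), `p`, `p_adj`,
#'   `rank`; the shortlist is attached as attribute `top_up`.
#' @export
rank_markers <- function(norm, clusters, target_cluster, top_k = 15L) {
  if (length(clusters) != ncol(norm)) stop("cluster labels do not match cells")
  in_t <- clusters == target_cluster
  n1 <- sum(in_t); n2 <- sum(!in_t)
  if (n1 == 0L) stop("target cluster is empty")
  if (n2 == 0L) stop("need at least 2 clusters")
  n <- n1 + n2
  stat <- numeric(nrow(norm)); pval <- numeric(nrow(norm))
  for (i in seq_len(nrow(norm))) {
    x <- norm[i, ]
    r <- rank(x)
    u <- sum(r[in_t]) - n1 * (n1 + 1) / 2
    ties <- table(x)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      stat[i] <- 0; pval[i] <- 1
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(sigma2)
      stat[i] <- z
      pval[i] <- 2 * stats::pnorm(-abs(z))
    }
  }
  mean_t <- rowMeans(norm[, in_t, drop = FALSE])
  mean_r <- rowMeans(norm[, !in_t, drop = FALSE])
  out <- data.frame(gene = rownames(norm), statistic = stat,
                    log_fc = mean_t - mean_r, p = pval,
                    p_adj = stats::p.adjust(pval, method = "BH"),
                    row.names = NULL)
  out <- out[order(-out$statistic, out$gene), ]
  out$rank <- seq_len(nrow(out))
  up <- out[out$statistic > 0, ]
  attr(out, "top_up") <- utils::head(up$gene, top_k)
  out
}

#' Fraction-expressing and mean-expression signature summary
#'
#' Per gene and cell group: the fraction of cells with raw count >=
#' `min_count` and the mean log-normalized expression over all cells of the
#' group (or over expressing cells only, if requested). Empty groups give
#' NA rows.
#'
#' @param counts raw gene-by-cell counts.
#' @param norm log-normalized matrix of the same cells.
#' @param groups group label per cell.
#' @param panel gene symbols to summarize.
#' @param mean_over `"all"` (default) or `"expressing"`.
#' @param min_count positivity threshold (default 1).
#' @return data.frame: `gene`, `group`, `n_cells`, `fraction_expressing`,
#'   `mean_expression`.
#' @export
signature_summary <- function(counts, norm, groups, panel,
                              mean_over = c("all", "expressing"),
                              min_count = 1L) {
  mean_over <- match.arg(mean_over)
  miss <- setdiff(panel, rownames(counts))
  if (length(miss)) stop("gene(s) not in matrix: ", paste(miss, collapse = ", "))
  glev <- sort(unique(groups))
  rows <- list()
  for (g in panel) {
    for (grp in glev) {
      sel <- groups == grp
      if (!sum(sel)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, group = grp, n_cells = 0L,
          fraction_expressing = NA_real_, mean_expression = NA_real_)
        next
      }
      pos <- counts[g, sel] >= min_count
      mexp <- if (mean_over == "all") {
        mean(norm[g, sel])
      } else if (any(pos)) mean(norm[g, sel][pos]) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, group = grp, n_cells = sum(sel),
        fraction_expressing = mean(pos), mean_expression = mexp)
    }
  }
  do.call(rbind, rows)
}
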