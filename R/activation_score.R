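#' Keep only patients with matched week-0 and week-14 samples
#'
#' @param design cohort design data.frame (see [read_design()]).
#' @return the design restricted to paired patients, with attribute
#'   `arm_counts` (retained patients per arm). Warns when nothing is left.
#' @export
pair_filter <- function(design) {
  design <- validate_design(design)
  tab <- table(design$patient_id, factor(design$week, levels = c(0L, 14L)))
  paired <- rownames(tab)[tab[, "0"] == 1L & tab[, "14"] == 1L]
  out <- design[design$patient_id %in% paired, , drop = FALSE]
  if (!nrow(out)) warning("no patient has both week 0 and week 14 samples")
  arms <- out[out$week == 0L, ]
  attr(out, "arm_counts") <- table(arms$arm)
  out
}

#' Per-gene median expression over all samples of the cohort
#'
#' @param norm normalized expression matrix (genes x samples).
#' @param panel character vector of gene symbols.
#' @return named numeric vector of medians.
#' @export
gene_medians <- function(norm, panel) {
  miss <- setdiff(panel, rownames(norm))
  if (length(miss)) stop("gene(s) not in matrix: ", paste(miss, collapse = ", "))
  apply(norm[panel, , drop = FALSE], 1L, stats::median)
}

#' Compute the per-patient T cell activation score
#'
#' For every panel gene and both timepoints, a patient scores 1 when their
#' expression is strictly greater than the gene's median over all samples of
#' the cohort (both arms and both timepoints pooled by default). The week-0
#' and week-14 subscores (0..panel size) sum to the cumulative score.
#'
#' @param norm normalized expression matrix (genes x samples); the score is
#'   invariant to any strictly monotone per-gene transform, so size-factor
#'   normalized counts and their log1p give identical scores.
#' @param design pair-filtered cohort design.
#' @param panel activation gene symbols; default the five-gene panel
#'   CD40LG, TNFRSF4, IL2RA, CD69, TNFRSF9.
#' @param per_timepoint_medians compare against medians computed within each
#'   timepoint instead of pooled over both.
#' @return data.frame of class `activation_scores` with one row per patient:
#'   `patient_id`, `arm`, `subscore_w0`, `subscore_w14`, `cumulative`,
#'   `stratum` (NA until [stratify_patients()]); the per-gene per-timepoint
#'   indicator table is attached as attribute `indicators`.
#' @export
compute_activation_score <- function(norm, design,
                                     panel = default_panels()$activation,
                                     per_timepoint_medians = FALSE) {
  design <- validate_design(design)
  miss <- setdiff(design$sample_id, colnames(norm))
  if (length(miss)) stop("design samples absent from matrix: ", paste(miss, collapse = ", "))
  tab <- table(design$patient_id, design$week)
  if (any(tab != 1L))
    stop("patient missing a timepoint; run pair_filter() first")
  expr <- norm[panel, design$sample_id, drop = FALSE]

  med_for <- function(week) {
    if (per_timepoint_medians) {
      apply(expr[, design$week == week, drop = FALSE], 1L, stats::median)
    } else {
      apply(expr, 1L, stats::median)
    }
  }
  medians <- list(`0` = med_for(0L), `14` = med_for(14L))

  patients <- unique(design$patient_id)
  ind <- do.call(rbind, lapply(patients, function(p) {
    do.call(rbind, lapply(c(0L, 14L), function(w) {
      s <- design$sample_id[design$patient_id == p & design$week == w]
      data.frame(patient_id = p, week = w, gene = panel,
                 indicator = as.integer(expr[, s] > medians[[as.character(w)]]),
                 row.names = NULL)
    }))
  }))

  sub <- function(p, w) sum(ind$indicator[ind$patient_id == p & ind$week == w])
  arms <- design$arm[match(patients, design$patient_id)]
  scores <- data.frame(
    patient_id = patients,
    arm = arms,
    subscore_w0 = vapply(patients, sub, integer(1), w = 0L),
    subscore_w14 = vapply(patients, sub, integer(1), w = 14L),
    row.names = NULL)
  scores$cumulative <- scores$subscore_w0 + scores$subscore_w14
  scores$stratum <- NA_character_
  attr(scores, "indicators") <- ind
  attr(scores, "panel") <- panel
  class(scores) <- c("activation_scores", "data.frame")
  scores
}

#' Stratify patients into high / low / intermediate T cell activation
#'
#' High: cumulative score >= 6 and no timepoint subscore below 2.
#' Low: cumulative score <= 4 and no timepoint subscore above 3.
#' Everyone else is intermediate and excluded from high-vs-low contrasts.
#'
#' @param scores result of [compute_activation_score()].
#' @return the same data.frame with `stratum` filled.
#' @export
stratify_patients <- function(scores) {
  s0 <- scores$subscore_w0
  s14 <- scores$subscore_w14
  cum <- scores$cumulative
  stopifnot(all(cum == s0 + s14))
  high <- cum >= 6L & pmin(s0, s14) >= 2L
  low <- cum <= 4L & pmax(s0, s14) <= 3L
  scores$stratum <- ifelse(high, "high", ifelse(low, "low", "intermediate"))
  scores
}

# Expression values of one gene for a set of patients at one week.
patient_values <- function(norm, design, gene, patients, week) {
  if (!gene %in% rownames(norm)) stop("gene not in matrix: ", gene)
  sel <- design$patient_id %in% patients & design$week == week
  v <- norm[gene, design$sample_id[sel]]
  names(v) <- design$patient_id[sel]
  v[patients[patients %in% names(v)]]
}

comparison_row <- function(gene, arm, comparison, groups, res, n_pre, n_post) {
  data.frame(
    gene = gene, arm = arm, comparison = comparison,
    group_a = groups[1], group_b = groups[2],
    n_a_pre = n_pre[1], n_b_pre = n_pre[2],
    n_a = n_post[1], n_b = n_post[2],
    test = res$test, statistic = res$statistic, p = res$p.value,
    mean_a = res$estimates$mean_a, mean_b = res$estimates$mean_b,
    median_a = res$estimates$median_a, median_b = res$estimates$median_b,
    row.names = NULL)
}

#' Week-14 high-vs-low contrast of one gene within one arm
#'
#' Compares week-14 expression of `gene` between high- and low-activation
#' patients of the given arm: 1% ROUT outlier removal per group, then the
#' normality-dispatched two-group test ([two_group_test()]).
#'
#' @param norm normalized expression matrix.
#' @param design pair-filtered cohort design.
#' @param scores stratified activation scores ([stratify_patients()]).
#' @param gene gene symbol.
#' @param arm `"etrolizumab"` or `"placebo"`.
#' @param Q ROUT FDR level.
#' @return one-row data.frame (gene, arm, groups, pre/post-outlier n, test,
#'   statistic, p, group means/medians); group a = high, group b = low.
#' @export
compare_week14 <- function(norm, design, scores, gene, arm, Q = 0.01) {
  hi <- scores$patient_id[scores$stratum == "high" & scores$arm == arm]
  lo <- scores$patient_id[scores$stratum == "low" & scores$arm == arm]
  if (!length(hi) || !length(lo)) stop("stratum empty in arm ", arm)
  a <- patient_values(norm, design, gene, hi, 14L)
  b <- patient_values(norm, design, gene, lo, 14L)
  a_kept <- remove_outliers(a, Q)
  b_kept <- remove_outliers(b, Q)
  res <- two_group_test(a_kept, b_kept)
  comparison_row(gene, arm, "week14 high vs low", c("high", "low"), res,
                 c(length(a), length(b)), c(length(a_kept), length(b_kept)))
}

#' Paired week-0 to week-14 contrast of one gene within one patient group
#'
#' Tests the within-patient change from week 0 to week 14 for the patients of
#' one arm and stratum: ROUT outlier removal on the paired differences (a
#' flagged difference drops the pair), then the paired normality-dispatched
#' test.
#'
#' @inheritParams compare_week14
#' @param stratum `"high"`, `"low"` or `"intermediate"`.
#' @return one-row data.frame; group a = week 0, group b = week 14, with
#'   `mean_change` appended.
#' @export
compare_week_change <- function(norm, design, scores, gene, arm, stratum,
                                Q = 0.01) {
  pats <- scores$patient_id[scores$stratum == stratum & scores$arm == arm]
  if (length(pats) < 3L) stop("insufficient pairs (need >= 3)")
  w0 <- patient_values(norm, design, gene, pats, 0L)
  w14 <- patient_values(norm, design, gene, pats, 14L)
  d <- w14 - w0
  rr <- rout_outliers(d, Q)
  keep <- setdiff(seq_along(d), rr$outlier_idx)
  if (length(keep) < 3L) stop("insufficient pairs after outlier removal")
  res <- two_group_test(w0[keep], w14[keep], paired = TRUE)
  out <- comparison_row(gene, arm, paste0("week0 vs week14 (", stratum, ")"),
                        c("week0", "week14"), res,
                        c(length(d), length(d)), c(length(keep), length(keep)))
  out$mean_change <- mean(d[keep])
  out
}

#' High-vs-low contrast of a gene panel across both timepoints
#'
#' Face-validity check of the score: per panel gene, compares expression in
#' high- versus low-activation patients with week-0 and week-14 samples
#' pooled, within an arm or across the whole cohort.
#'
#' @inheritParams compare_week14
#' @param panel character vector of gene symbols (empty gives an empty table).
#' @param arm optional arm restriction; default uses all patients.
#' @return data.frame with one row per gene (columns as [compare_week14()]).
#' @export
score_group_contrast <- function(norm, design, scores, panel, arm = NULL,
                                 Q = 0.01) {
  if (!length(panel)) {
    return(data.frame(
      gene = character(0), arm = character(0), comparison = character(0),
      group_a = character(0), group_b = character(0),
      n_a_pre = integer(0), n_b_pre = integer(0),
      n_a = integer(0), n_b = integer(0),
      test = character(0), statistic = numeric(0), p = numeric(0),
      mean_a = numeric(0), mean_b = numeric(0),
      median_a = numeric(0), median_b = numeric(0)))
  }
  sel <- if (is.null(arm)) rep(TRUE, nrow(scores)) else scores$arm == arm
  hi <- scores$patient_id[sel & scores$stratum == "high"]
  lo <- scores$patient_id[sel & scores$stratum == "low"]
  if (!length(hi) || !length(lo)) stop("stratum empty")
  do.call(rbind, lapply(panel, function(g) {
    a <- c(patient_values(norm, design, g, hi, 0L),
           patient_values(norm, design, g, hi, 14L))
    b <- c(patient_values(norm, design, g, lo, 0L),
           patient_values(norm, design, g, lo, 14L))
    a_kept <- remove_outliers(a, Q)
    b_kept <- remove_outliers(b, Q)
    res <- two_group_test(a_kept, b_kept)
    comparison_row(g, if (is.null(arm)) "all" else arm,
                   "high vs low (both weeks)", c("high", "low"), res,
                   c(length(a), length(b)), c(length(a_kept), length(b_kept)))
  }))
}
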