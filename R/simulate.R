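#' Parameters for the bulk cohort simulator
#'
#' Defaults mirror the paired two-timepoint ileal cohort the score analysis
#' targets: 34 etrolizumab and 8 placebo patients, each with week-0 and
#' week-14 samples; a binary patient-level latent activation level (P(high)
#' = 0.5) scales the activation panel, the T cell cytokines and the
#' cytotoxic genes by `coupling_fold` at both weeks; cytotoxic genes of
#' etrolizumab-treated low-activation patients are additionally multiplied
#' by `reduction_fold` at week 14; innate cytokines are independent of the
#' latent level. Counts are negative binomial with per-gene dispersion and
#' log-normal library-size variation.
#'
#' @param n_etrolizumab,n_placebo paired patients per arm.
#' @param n_background background genes.
#' @param baseline_meanlog,baseline_sdlog log-normal hyperprior of per-gene
#'   baseline means (counts).
#' @param dispersion_meanlog,dispersion_sdlog log-normal hyperprior of
#'   per-gene NB dispersion (variance = mu + dispersion * mu^2).
#' @param p_high probability a patient's latent activation is high.
#' @param coupling_fold fold change of activation-coupled genes in
#'   high-activation patients.
#' @param reduction_fold week-14 multiplier of cytotoxic genes in
#'   etrolizumab x low-activation patients (1 = no effect).
#' @param lib_cv coefficient of variation of library sizes.
#' @param latent `"binary"` or `"continuous"` (continuous exercises the
#'   intermediate stratum; labels are high when the latent level > 0.5).
#' @param seed random seed.
#' @return parameter list for [simulate_bulk_cohort()].
#' @export
bulk_sim_params <- function(n_etrolizumab = 34L, n_placebo = 8L,
                            n_background = 500L,
                            baseline_meanlog = log(30), baseline_sdlog = 1,
                            dispersion_meanlog = log(0.1), dispersion_sdlog = 0.3,
                            p_high = 0.5, coupling_fold = 3,
                            reduction_fold = 0.5, lib_cv = 0.2,
                            latent = c("binary", "continuous"), seed = 1L) {
  p <- list(n_etrolizumab = as.integer(n_etrolizumab),
            n_placebo = as.integer(n_placebo),
            n_background = as.integer(n_background),
            baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
            dispersion_meanlog = dispersion_meanlog,
            dispersion_sdlog = dispersion_sdlog,
            p_high = p_high, coupling_fold = coupling_fold,
            reduction_fold = reduction_fold, lib_cv = lib_cv,
            latent = match.arg(latent), seed = as.integer(seed))
  if (p$n_etrolizumab < 2L || p$n_placebo < 2L) stop("need >= 2 patients per arm")
  if (p$coupling_fold <= 0 || p$reduction_fold <= 0) stop("folds must be > 0")
  if (p$p_high < 0 || p$p_high > 1) stop("p_high must be in [0, 1]")
  if (p$lib_cv < 0) stop("lib_cv must be >= 0")
  p
}

#' Simulate a paired two-timepoint bulk RNA-seq cohort
#'
#' @param params list from [bulk_sim_params()].
#' @return list with `counts` (gene x sample), `design` (sample sheet),
#'   `truth` (per patient: latent activation label and level) and `params`.
#' @export
simulate_bulk_cohort <- function(params = bulk_sim_params()) {
  set.seed(params$seed)
  panels <- default_panels()
  genes <- c(panels$activation, panels$cytotoxic, panels$tcell_cytokines,
             panels$innate_cytokines,
             sprintf("BG%04d", seq_len(params$n_background)))
  coupled <- c(panels$activation, panels$tcell_cytokines, panels$cytotoxic)

  n_pat <- params$n_etrolizumab + params$n_placebo
  patients <- sprintf("P%03d", seq_len(n_pat))
  arms <- rep(c("etrolizumab", "placebo"),
              c(params$n_etrolizumab, params$n_placebo))

  level <- if (params$latent == "binary") {
    ifelse(stats::rbinom(n_pat, 1L, params$p_high) == 1L, 1, 0)
  } else {
    stats::runif(n_pat)
  }
  label <- ifelse(level > 0.5, "high", "low")

  baseline <- stats::rlnorm(length(genes), params$baseline_meanlog,
                            params$baseline_sdlog)
  names(baseline) <- genes
  dispersion <- stats::rlnorm(length(genes), params$dispersion_meanlog,
                              params$dispersion_sdlog)
  names(dispersion) <- genes

  design <- data.frame(
    sample_id = paste0(rep(patients, each = 2L), "_w", rep(c(0L, 14L), n_pat)),
    patient_id = rep(patients, each = 2L),
    arm = rep(arms, each = 2L),
    week = rep(c(0L, 14L), n_pat),
    tissue = "terminal ileum")
  lib <- stats::rlnorm(nrow(design),
                       meanlog = -log(1 + params$lib_cv^2) / 2,
                       sdlog = sqrt(log(1 + params$lib_cv^2)))

  counts <- matrix(0, nrow = length(genes), ncol = nrow(design),
                   dimnames = list(genes, design$sample_id))
  for (j in seq_len(nrow(design))) {
    p_idx <- match(design$patient_id[j], patients)
    # latent coupling: fold^(2 level - 1) is fold for high, 1/fold-free
    # baseline for low under the binary model (level in {0, 1})
    act_mult <- params$coupling_fold^level[p_idx]
    mu <- baseline * lib[j]
    mu[coupled] <- mu[coupled] * act_mult
    if (design$arm[j] == "etrolizumab" && label[p_idx] == "low" &&
        design$week[j] == 14L) {
      mu[panels$cytotoxic] <- mu[panels$cytotoxic] * params$reduction_fold
    }
    counts[, j] <- stats::rnbinom(length(genes), mu = mu, size = 1 / dispersion)
  }

  truth <- data.frame(patient_id = patients, arm = arms,
                      activation = label, latent_level = level)
  list(counts = counts, design = design, truth = truth, params = params)
}

#' Parameters for the single-cell UMI simulator
#'
#' Emulates a sorted alpha4+ memory T cell dataset from two donors: cells
#' carry an ITGB7/ITGB1 integrin subset label (neg / single-positive /
#' double-positive); double-positive cells express a cytotoxic program
#' (GNLY, GZMB, GZMH, PRF1, FASLG, GZMK, KLRD1 plus dedicated background
#' program genes) elevated `program_fold`-fold; the remaining cells are
#' spread over `k_programs - 1` latent expression programs with their own
#' marker genes, which drive cluster structure; a small tail of cells
#' carries a high mitochondrial fraction. UMI counts are Poisson around
#' cell-depth-scaled means; integrin counts are zero-inflated Poisson so
#' that structural zeros (subset identity) and sampling zeros coexist.
#'
#' @param n_cells number of cells.
#' @param donor_freq named frequencies for donors CD and CON.
#' @param subset_freq named frequencies for ITGB7neg / ITGB7sp / ITGB1/7dp
#'   (must sum to 1).
#' @param integrin_mean Poisson mean of an expressed integrin transcript.
#' @param neg_itgb1_rate probability an ITGB7neg cell expresses ITGB1.
#' @param program_fold elevation of the cytotoxic program in dp cells
#'   (default 2.5) and of each latent program's markers in its cells.
#' @param k_programs latent programs including the dp cytotoxic program.
#' @param markers_per_program marker genes per non-dp program.
#' @param n_extra_program background genes joining the 7 cytotoxic genes in
#'   the dp program (default 8, making a 15-gene program).
#' @param dp_program_purity probability a dp cell follows the cytotoxic
#'   program rather than a random other program (affects nothing but the
#'   echoed truth; cytotoxic elevation follows the subset label).
#' @param mito_base mean baseline mitochondrial fraction.
#' @param high_mito_fraction fraction of cells planted with a high
#'   mitochondrial tail (default 0.025).
#' @param high_mito_range uniform range of planted high mito fractions.
#' @param n_background background genes without program membership.
#' @param depth_sdlog log-normal sd of per-cell depth factors.
#' @param seed random seed.
#' @return parameter list for [simulate_scrna()].
#' @export
sc_sim_params <- function(n_cells = 3000L,
                          donor_freq = c(CD = 0.5, CON = 0.5),
                          subset_freq = c("ITGB7neg" = 0.4, "ITGB7sp" = 0.3,
                                          "ITGB1/7dp" = 0.3),
                          integrin_mean = 4, neg_itgb1_rate = 0.5,
                          program_fold = 2.5, k_programs = 6L,
                          markers_per_program = 25L, n_extra_program = 8L,
                          dp_program_purity = 0.85,
                          mito_base = 0.06, high_mito_fraction = 0.025,
                          high_mito_range = c(0.3, 0.5),
                          n_background = 400L, depth_sdlog = 0.3, seed = 1L) {
  p <- as.list(environment())
  p$n_cells <- as.integer(n_cells)
  p$k_programs <- as.integer(k_programs)
  if (abs(sum(subset_freq) - 1) > 1e-8) stop("subset frequencies must sum to 1")
  if (p$n_cells < 10L) stop("need >= 10 cells")
  if (program_fold <= 0) stop("folds must be > 0")
  if (high_mito_fraction < 0 || high_mito_fraction >= 1)
    stop("high_mito_fraction must be in [0, 1)")
  p
}

#' Simulate a single-cell UMI count matrix with planted structure
#'
#' @param params list from [sc_sim_params()].
#' @return list with `counts` (gene x cell UMI matrix), `cells` (skeleton
#'   cell table: barcode, donor), `truth` (per cell: subset, program,
#'   high-mito flag; plus the program gene sets) and `params`.
#' @export
simulate_scrna <- function(params = sc_sim_params()) {
  set.seed(params$seed)
  n <- params$n_cells
  panels <- default_panels()
  cyto <- panels$cytotoxic_program

  housekeeping <- c(ACTB = 60, B2M = 80, GAPDH = 40, TMSB4X = 50, PTPRC = 30)
  mito_genes <- paste0("MT-", c("CO1", "CO2", "CO3", "ND1", "ND2", "ND3",
                                "ND4", "ND5", "ATP6", "CYB"))
  extra_prog <- sprintf("CTXPRG%02d", seq_len(params$n_extra_program))
  dp_program <- c(cyto, extra_prog)
  other_programs <- lapply(seq_len(params$k_programs - 1L), function(j)
    sprintf("PRG%d_%02d", j, seq_len(params$markers_per_program)))
  background <- sprintf("BGC%04d", seq_len(params$n_background))
  genes <- c("ITGB7", "ITGB1", names(housekeeping), mito_genes, dp_program,
             unlist(other_programs), background)

  base <- stats::setNames(numeric(length(genes)), genes)
  base[names(housekeeping)] <- housekeeping
  base[cyto] <- 1.5
  base[extra_prog] <- 1.5
  base[unlist(other_programs)] <- 2
  base[background] <- stats::rlnorm(length(background), log(1), 0.8)
  base[c("ITGB7", "ITGB1")] <- 0  # drawn separately, subset-conditional

  subset <- sample(names(params$subset_freq), n, replace = TRUE,
                   prob = params$subset_freq)
  donor <- sample(names(params$donor_freq), n, replace = TRUE,
                  prob = params$donor_freq)
  k_other <- params$k_programs - 1L
  program <- ifelse(
    subset == "ITGB1/7dp",
    ifelse(stats::runif(n) < params$dp_program_purity, "cytotoxic",
           paste0("program", sample.int(k_other, n, replace = TRUE))),
    ifelse(subset == "ITGB7sp" & stats::runif(n) < 0.7,
           paste0("program", k_other),
           paste0("program", sample.int(max(k_other - 1L, 1L), n, replace = TRUE))))

  high_mito <- stats::runif(n) < params$high_mito_fraction
  mito_frac <- ifelse(high_mito,
                      stats::runif(n, params$high_mito_range[1],
                                   params$high_mito_range[2]),
                      pmin(0.15, stats::rbeta(n, 15, 235)))
  depth <- stats::rlnorm(n, 0, params$depth_sdlog)

  counts <- matrix(0L, nrow = length(genes), ncol = n,
                   dimnames = list(genes, sprintf("CELL%04d", seq_len(n))))
  for (j in seq_len(n)) {
    mu <- base * depth[j]
    if (subset[j] == "ITGB1/7dp") mu[dp_program] <- mu[dp_program] * params$program_fold
    if (program[j] != "cytotoxic") {
      idx <- as.integer(sub("program", "", program[j]))
      mu[other_programs[[idx]]] <- mu[other_programs[[idx]]] * 3
    }
    # subset-conditional zero-inflated integrin means
    mu["ITGB7"] <- if (subset[j] == "ITGB7neg") 0 else params$integrin_mean * depth[j]
    mu["ITGB1"] <- switch(subset[j],
      "ITGB1/7dp" = params$integrin_mean * depth[j],
      "ITGB7sp" = 0,
      "ITGB7neg" = if (stats::runif(1) < params$neg_itgb1_rate)
        params$integrin_mean / 2 * depth[j] else 0)
    # mitochondrial means chosen so the realized fraction targets mito_frac[j]
    mu[mito_genes] <- sum(mu) * mito_frac[j] / (1 - mito_frac[j]) / length(mito_genes)
    counts[, j] <- stats::rpois(length(genes), mu)
  }

  truth <- data.frame(barcode = colnames(counts), donor = donor,
                      subset = subset, program = program,
                      high_mito = high_mito, target_mito_fraction = mito_frac,
                      row.names = NULL)
  list(counts = counts,
       cells = data.frame(barcode = colnames(counts), donor = donor,
                          row.names = NULL),
       truth = truth,
       program_genes = c(list(cytotoxic = dp_program),
                         stats::setNames(other_programs,
                                         paste0("program", seq_len(k_other)))),
       params = params)
}
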