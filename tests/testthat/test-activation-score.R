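test_that("stratification matches the brute-force rule on all 36 subscore pairs", {
  grid <- expand.grid(s0 = 0:5, s14 = 0:5)
  scores <- data.frame(patient_id = sprintf("P%02d", seq_len(nrow(grid))),
                       arm = "etrolizumab",
                       subscore_w0 = grid$s0, subscore_w14 = grid$s14,
                       cumulative = grid$s0 + grid$s14,
                       stratum = NA_character_)
  got <- stratify_patients(scores)$stratum
  want <- mapply(brute_force_stratum, grid$s0, grid$s14)
  expect_equal(got, unname(want))

  # the rule's corner cases, spelled out
  pick <- function(s0, s14) got[grid$s0 == s0 & grid$s14 == s14]
  expect_equal(pick(3, 3), "high")          # cumulative 6, both >= 2
  expect_equal(pick(5, 1), "intermediate")  # cumulative 6, one timepoint < 2
  expect_equal(pick(4, 0), "intermediate")  # cumulative 4, one timepoint > 3
  expect_equal(pick(2, 2), "low")
})

test_that("pair filtering keeps exactly the patients with both weeks", {
  design <- data.frame(
    sample_id = c("a0", "a14", "b0"),
    patient_id = c("A", "A", "B"),
    arm = "etrolizumab", week = c(0L, 14L, 0L), tissue = "ileum")
  out <- pair_filter(design)
  expect_setequal(out$patient_id, "A")

  full <- pair_filter(design[design$patient_id == "A", ])
  expect_equal(nrow(full), 2L)

  expect_warning(pair_filter(design[design$patient_id == "B", ]), "no patient")
})

test_that("indicators use a strict above-median comparison", {
  # 4 paired patients, one gene; values chosen so the pooled median (2.5)
  # separates patients cleanly and a tie at the median scores 0
  tc <- toy_cohort(list(ACT = c(1, 1, 2, 2, 3, 3, 4, 4)),
                   arms = rep("etrolizumab", 4))
  expect_equal(unname(gene_medians(tc$norm, "ACT")), 2.5)
  sc <- compute_activation_score(tc$norm, tc$design, panel = "ACT")
  expect_equal(sc$cumulative, c(0L, 0L, 2L, 2L))

  # all values exactly at the median score 0
  tc2 <- toy_cohort(list(ACT = rep(5, 8)), arms = rep("etrolizumab", 4))
  sc2 <- compute_activation_score(tc2$norm, tc2$design, panel = "ACT")
  expect_true(all(sc2$cumulative == 0L))

  expect_error(gene_medians(tc$norm, "MISSING"), "MISSING")
  expect_error(
    compute_activation_score(tc$norm, tc$design[-1, ], panel = "ACT"),
    "timepoint")
})

test_that("subscores are bounded by the panel and cumulative is their sum", {
  sim <- simulate_bulk_cohort(bulk_sim_params(n_etrolizumab = 6, n_placebo = 4,
                                              n_background = 30, seed = 7))
  norm <- normalize_counts(sim$counts)
  sc <- compute_activation_score(norm, sim$design)
  expect_true(all(sc$subscore_w0 %in% 0:5 & sc$subscore_w14 %in% 0:5))
  expect_equal(sc$cumulative, sc$subscore_w0 + sc$subscore_w14)
})

test_that("score is invariant to strictly monotone per-gene transforms", {
  sim <- simulate_bulk_cohort(bulk_sim_params(n_etrolizumab = 8, n_placebo = 4,
                                              n_background = 50, seed = 3))
  norm <- normalize_counts(sim$counts)
  sc <- compute_activation_score(norm, sim$design)

  transformed <- norm
  panel <- default_panels()$activation
  transforms <- list(function(x) log1p(x), function(x) 3 * x + 2,
                     function(x) x^3, function(x) exp(x / max(x)),
                     function(x) rank(x, ties.method = "min"))
  for (i in seq_along(panel))
    transformed[panel[i], ] <- transforms[[i]](transformed[panel[i], ])
  sc2 <- compute_activation_score(transformed, sim$design)
  expect_equal(sc2$subscore_w0, sc$subscore_w0)
  expect_equal(sc2$subscore_w14, sc$subscore_w14)
  expect_equal(attr(sc2, "indicators")$indicator, attr(sc, "indicators")$indicator)
})

test_that("stratum recovery on strongly coupled synthetic cohorts is near-perfect", {
  sens <- spec <- numeric(3)
  for (i in 1:3) {
    sim <- simulate_bulk_cohort(bulk_sim_params(seed = 100 + i))
    norm <- normalize_counts(sim$counts)
    sc <- stratify_patients(compute_activation_score(norm, sim$design))
    truth <- sim$truth$activation[match(sc$patient_id, sim$truth$patient_id)]
    sens[i] <- sum(sc$stratum == "high" & truth == "high") / sum(truth == "high")
    spec[i] <- sum(sc$stratum == "low" & truth == "low") / sum(truth == "low")
  }
  expect_true(all(sens >= 0.9))
  expect_true(all(spec >= 0.9))
})

test_that("week-14 contrast flags a planted reduction and is flat on identical groups", {
  sim <- simulate_bulk_cohort(bulk_sim_params(seed = 1))
  norm <- normalize_counts(sim$counts)
  sc <- stratify_patients(compute_activation_score(norm, sim$design))
  res <- compare_week14(norm, sim$design, sc, "GZMB", "etrolizumab")
  expect_lt(res$p, 0.05)
  expect_gt(res$mean_a, res$mean_b)  # high group above the reduced low group
  expect_true(res$n_a >= 10 && res$n_b >= 10)

  # identical strata values give a flat contrast
  tc <- toy_cohort(list(G = rep(c(1, 2, 3, 5, 8, 13), 2)),
                   arms = rep("etrolizumab", 6))
  sc2 <- data.frame(patient_id = tc$patients, arm = "etrolizumab",
                    subscore_w0 = 0L, subscore_w14 = 0L, cumulative = 0L,
                    stratum = rep(c("high", "low"), 3))
  res2 <- compare_week14(tc$norm, tc$design, sc2, "G", "etrolizumab")
  expect_gt(res2$p, 0.99)

  expect_error(compare_week14(tc$norm, tc$design,
                              transform(sc2, stratum = "high"),
                              "G", "etrolizumab"),
               "stratum empty")
})

test_that("week-14 contrast is calibrated when no effect is planted", {
  # null configuration: no activation coupling, no treatment reduction, so
  # the high/low strata are exchangeable and rejections are chance events
  rejected <- 0L; tested <- 0L
  for (i in 1:20) {
    sim <- simulate_bulk_cohort(bulk_sim_params(coupling_fold = 1,
                                                reduction_fold = 1,
                                                seed = 500 + i))
    norm <- normalize_counts(sim$counts)
    sc <- stratify_patients(compute_activation_score(norm, sim$design))
    if (sum(sc$stratum == "high" & sc$arm == "etrolizumab") < 3L ||
        sum(sc$stratum == "low" & sc$arm == "etrolizumab") < 3L) next
    res <- compare_week14(norm, sim$design, sc, "GNLY", "etrolizumab")
    tested <- tested + 1L
    rejected <- rejected + (res$p < 0.05)
  }
  expect_gte(tested, 15L)
  expect_lte(rejected / tested, 0.2)
})

test_that("paired week-change contrast handles planted, degenerate and mirrored data", {
  sim <- simulate_bulk_cohort(bulk_sim_params(seed = 2))
  norm <- normalize_counts(sim$counts)
  sc <- stratify_patients(compute_activation_score(norm, sim$design))
  res <- compare_week_change(norm, sim$design, sc, "FASLG", "etrolizumab", "low")
  expect_lt(res$p, 0.05)
  expect_lt(res$mean_change, 0)

  # no change at all: p = 1 by convention
  w0 <- c(2, 4, 6, 9, 11, 13)
  tc <- toy_cohort(list(G = rep(w0, each = 2)), arms = rep("etrolizumab", 6))
  scf <- data.frame(patient_id = tc$patients, arm = "etrolizumab",
                    subscore_w0 = 0L, subscore_w14 = 0L, cumulative = 0L,
                    stratum = "low")
  flat <- compare_week_change(tc$norm, tc$design, scf, "G", "etrolizumab", "low")
  expect_equal(flat$p, 1)
  expect_equal(flat$mean_change, 0)

  # reflecting the change flips the sign of the statistic
  d <- c(1.2, 0.8, 1.9, 0.4, 1.1, 1.6)
  up <- toy_cohort(list(G = as.vector(rbind(w0, w0 + d))),
                   arms = rep("etrolizumab", 6))
  dn <- toy_cohort(list(G = as.vector(rbind(w0, w0 - d))),
                   arms = rep("etrolizumab", 6))
  r_up <- compare_week_change(up$norm, up$design, scf, "G", "etrolizumab", "low")
  r_dn <- compare_week_change(dn$norm, dn$design, scf, "G", "etrolizumab", "low")
  expect_equal(r_up$statistic, -r_dn$statistic)
  expect_equal(r_up$p, r_dn$p)

  expect_error(compare_week_change(tc$norm, tc$design, scf[1:2, ],
                                   "G", "etrolizumab", "low"),
               "insufficient pairs")
})

test_that("cytokine face-validity contrast separates coupled from independent panels", {
  sim <- simulate_bulk_cohort(bulk_sim_params(seed = 4))
  norm <- normalize_counts(sim$counts)
  sc <- stratify_patients(compute_activation_score(norm, sim$design))
  panels <- default_panels()
  tc <- score_group_contrast(norm, sim$design, sc, panels$tcell_cytokines)
  expect_true(all(tc$mean_a > tc$mean_b))  # T cell cytokines up in "high"
  expect_true(all(tc$p < 0.05))

  # innate cytokines are simulated independent of the latent level:
  # across several seeds there is no systematic direction
  dirs <- sapply(1:5, function(i) {
    s <- simulate_bulk_cohort(bulk_sim_params(seed = 300 + i))
    nm <- normalize_counts(s$counts)
    st <- stratify_patients(compute_activation_score(nm, s$design))
    ic <- score_group_contrast(nm, s$design, st, panels$innate_cytokines)
    sign(ic$mean_a - ic$mean_b)
  })
  expect_gt(mean(dirs > 0), 0.1)
  expect_lt(mean(dirs > 0), 0.9)

  empty <- score_group_contrast(norm, sim$design, sc, character(0))
  expect_equal(nrow(empty), 0L)
})
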