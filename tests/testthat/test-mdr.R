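test_that("modal imputation is deterministic with documented tie-breaks", {
  g <- cbind(rs1 = c(0L, 0L, 1L, NA), rs2 = c(1L, 2L, NA, NA),
             rs3 = c(0L, 1L, 2L, 0L))
  st <- genotype_study(g, c("case", "case", "control", "control"))
  imp <- impute_missing(st)
  expect_equal(unname(imp$genotypes[4, "rs1"]), 0L)
  # tie between 1 and 2 resolves to the lower code
  expect_equal(unname(imp$genotypes[3:4, "rs2"]), c(1L, 1L))
  expect_equal(unname(attr(imp, "imputed")), c(1L, 2L, 0L))
  expect_identical(impute_missing(imp)$genotypes, imp$genotypes)
})

test_that("cell labelling reproduces a hand-built 3x3 contingency table", {
  # 2 SNPs; hand-chosen cells, T = 20/20 = 1
  cells <- list(c(0, 0), c(0, 1), c(1, 1), c(2, 2))
  cnt <- rbind(c(6, 2),    # cell 00: ratio 3    -> high
               c(4, 8),    # cell 01: ratio 0.5  -> low
               c(5, 5),    # cell 11: ratio 1 = T -> high (>= convention)
               c(5, 5))    # cell 22: ratio 1     -> high
  g <- NULL; ph <- NULL
  for (i in seq_along(cells)) {
    g <- rbind(g, matrix(rep(cells[[i]], sum(cnt[i, ])), ncol = 2,
                         byrow = TRUE))
    ph <- c(ph, rep(c("case", "control"), cnt[i, ]))
  }
  colnames(g) <- c("rs1", "rs2")
  st <- genotype_study(g, ph)
  lab <- label_cells(st, c("rs1", "rs2"))
  expect_equal(lab$threshold_T, 1)
  idx <- function(g1, g2) g1 * 3 + g2 + 1
  expect_equal(lab$cell_labels[idx(0, 0)], "high_risk")
  expect_equal(lab$cell_labels[idx(0, 1)], "low_risk")
  expect_equal(lab$cell_labels[idx(1, 1)], "high_risk")  # ratio = T
  expect_equal(lab$cell_labels[idx(2, 2)], "high_risk")
  expect_equal(lab$cell_labels[idx(2, 0)], "empty")
  expect_equal(sum(lab$case_counts) + sum(lab$control_counts), nrow(g))
  # subject order is irrelevant
  perm <- sample(nrow(g))
  st2 <- genotype_study(g[perm, ], ph[perm])
  expect_identical(label_cells(st2, c("rs1", "rs2"))$cell_labels,
                   lab$cell_labels)
})

test_that("balanced accuracy has the documented degenerate values", {
  cells <- c(1L, 1L, 2L, 2L, 3L, 3L)
  is_case <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  # all cells high_risk: sensitivity 1, specificity 0
  expect_equal(balanced_accuracy(rep("high_risk", 9), cells, is_case), 0.5)
  # perfect separation
  labs <- c("high_risk", rep("low_risk", 8))
  expect_equal(balanced_accuracy(labs, c(1L, 1L, 2L, 2L, 3L, 3L),
                                 c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)),
               1.0)
  expect_error(balanced_accuracy(rep("empty", 9), cells, is_case),
               "no evaluable")
})

test_that("ratio labelling attains maximal training balanced accuracy", {
  # brute force over all 2^9 labelings of a toy 2-SNP table
  set.seed(19)
  g <- matrix(sample(0:2, 120 * 2, replace = TRUE), 120, 2)
  colnames(g) <- c("rs1", "rs2")
  ph <- sample(c("case", "control"), 120, replace = TRUE, prob = c(.45, .55))
  st <- genotype_study(g, ph)
  lab <- label_cells(st, c("rs1", "rs2"))
  cells <- episyn:::cell_index(st$genotypes, c("rs1", "rs2"))
  is_case <- ph == "case"
  ba_ratio <- balanced_accuracy(lab$cell_labels, cells, is_case)
  non_empty <- which(lab$cell_labels != "empty")
  best <- 0
  for (mask in 0:(2^length(non_empty) - 1)) {
    labs <- lab$cell_labels
    bits <- as.integer(intToBits(mask))[seq_along(non_empty)]
    labs[non_empty] <- ifelse(bits == 1, "high_risk", "low_risk")
    best <- max(best, balanced_accuracy(labs, cells, is_case))
  }
  expect_equal(ba_ratio, best, tolerance = 1e-12)
})

test_that("a planted interaction is recovered with high CV consistency", {
  sim <- simulate_study(sim_config(
    n_cases = 1000, n_controls = 1000,
    panel = c(IIS = 5, pro_antioxidant = 5, DNA_repair = 5),
    effects = list(list(type = "penetrance", loci = c(4, 11),
                        table = xor_penetrance())),
    survival_law = NULL, seed = 23))
  fit <- run_mdr(sim$study, k = 2, n_perm = 100, seed = 2)
  expect_setequal(fit$best$loci, sim$truth$effects[[1]]$snp_ids)
  expect_gte(fit$models$cvc[1], 8)
  expect_lte(fit$p_perm, 0.05)
  expect_gt(fit$models$mean_train_ba[1], 0.5)
  expect_true(fit$models$reported[1])
})

test_that("degenerate candidate list of exactly k SNPs is evaluated", {
  sim <- null_study(100, 100, 3, seed = 37)
  st <- impute_missing(sim$study)
  fit <- run_mdr(st, k = 2, n_perm = 100, seed = 5,
                 candidate_loci = st$snp_ids[1:2])
  expect_equal(nrow(fit$models), 1L)
  expect_equal(fit$models$cvc[1], 10)
  expect_setequal(fit$best$loci, st$snp_ids[1:2])
  expect_true(!is.na(fit$p_perm))
  expect_error(run_mdr(st, k = 4), "k must be 2 or 3")
})

test_that("run_mdr is reproducible under a fixed seed", {
  sim <- null_study(150, 120, 4, seed = 47)
  f1 <- run_mdr(sim$study, k = 2, n_perm = 100, seed = 11)
  f2 <- run_mdr(sim$study, k = 2, n_perm = 100, seed = 11)
  expect_identical(f1$models, f2$models)
  expect_identical(f1$p_perm, f2$p_perm)
  expect_identical(f1$best$cell_labels, f2$best$cell_labels)
})

test_that("three-locus search works on a small candidate panel", {
  sim <- null_study(200, 150, 3, seed = 53)
  st <- sim$study
  fit <- run_mdr(st, k = 3, n_perm = 0, seed = 7,
                 candidate_loci = st$snp_ids[1:6])
  expect_equal(length(fit$best$loci), 3L)
  expect_equal(length(fit$best$cell_labels), 27L)
  big <- null_study(60, 60, 60, seed = 53)
  expect_error(run_mdr(big$study, k = 3, n_perm = 0, seed = 1),
               "candidate_loci")
})

test_that("entropy graph reports redundancy and main effects correctly", {
  set.seed(67)
  n <- 400
  g1 <- sample(0:2, n, replace = TRUE, prob = c(.36, .48, .16))
  ph <- ifelse(g1 == 2, "case",
               sample(c("case", "control"), n, replace = TRUE))
  g <- cbind(rs1 = g1, rs2 = g1, rs3 = sample(0:2, n, replace = TRUE))
  st <- genotype_study(g, ph)
  eg <- entropy_graph(st, c("rs1", "rs2", "rs3"))
  pct <- eg$pairwise_pct
  dup <- pct[pct$snp1 == "rs1" & pct$snp2 == "rs2", "pct"]
  expect_lt(dup, 0)                      # duplicates are redundant
  expect_gt(eg$main_effect_pct[["rs1"]], eg$main_effect_pct[["rs3"]])
  # dendrogram distance is max(syn) - syn: the most synergistic pair
  # sits at distance zero
  expect_equal(min(eg$dendrogram$height), 0, tolerance = 1e-12)
  # a deterministic single-SNP effect explains 100% of the entropy
  ph2 <- ifelse(g1 >= 1, "case", "control")
  st2 <- genotype_study(cbind(rs1 = g1, rs2 = g[, 3]), ph2)
  eg2 <- entropy_graph(st2, c("rs1", "rs2"))
  expect_equal(eg2$main_effect_pct[["rs1"]], 100, tolerance = 1e-9)
})

test_that("combination odds ratios match the cross-product closed form", {
  # carrier x phenotype table (30, 10 / 10, 30) -> OR 9
  g <- cbind(rs1 = c(rep(2L, 40), rep(0L, 40)))
  ph <- c(rep(c("case", "control"), c(30, 10)),
          rep(c("case", "control"), c(10, 30)))
  st <- genotype_study(g, ph)
  comb <- genotype_combination("rs1", conditions = list(2L))
  res <- combination_odds_ratio(st, comb)
  expect_equal(res$or, 9.0)
  se <- sqrt(1 / 30 + 1 / 10 + 1 / 10 + 1 / 30)
  expect_equal(res$ci, exp(log(9) + c(-1, 1) * qnorm(0.975) * se))
  # exact independence construction gives OR 1
  g2 <- cbind(rs1 = rep(c(2L, 2L, 0L, 0L), 10))
  ph2 <- rep(c("case", "control", "case", "control"), 10)
  res2 <- combination_odds_ratio(genotype_study(g2, ph2), comb)
  expect_equal(res2$or, 1.0)
})

test_that("planted protective combinations are covered by the OR interval", {
  cover <- vapply(1:30, function(s) {
    sim <- simulate_study(sim_config(
      n_cases = 1000, n_controls = 1000,
      panel = c(IIS = 2, pro_antioxidant = 1, DNA_repair = 1),
      effects = list(list(type = "logistic", loci = 1L, beta0 = 0,
                          beta = log(0.6), beta_int = 0)),
      survival_law = NULL, seed = 1700 + s))
    comb <- genotype_combination(sim$study$snp_ids[1],
                                 conditions = list(c(1L, 2L)))
    res <- combination_odds_ratio(sim$study, comb)
    # per-allele OR 0.6 under a dominant-ish carrier summary: accept CI
    # covering the carrier-aggregated truth computed from the generator
    maf <- sim$truth$maf[1]
    pr <- episyn:::hwe_probs(maf)
    p_case_g <- plogis(0 + log(0.6) * (0:2))
    p_carrier_case <- sum(pr[2:3] * p_case_g[2:3]) /
      sum(pr * p_case_g)
    p_carrier_ctrl <- sum(pr[2:3] * (1 - p_case_g[2:3])) /
      sum(pr * (1 - p_case_g))
    truth_or <- (p_carrier_case / (1 - p_carrier_case)) /
      (p_carrier_ctrl / (1 - p_carrier_ctrl))
    res$ci[1] <= truth_or && truth_or <= res$ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.83)
})
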