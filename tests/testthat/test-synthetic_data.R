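test_that("the same seed reproduces a study byte for byte", {
  cfg <- sim_config(n_cases = 80, n_controls = 60,
                    panel = c(IIS = 4, pro_antioxidant = 4, DNA_repair = 4),
                    missing_rate = 0.05, seed = 7)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$study$genotypes, s2$study$genotypes)
  expect_identical(s1$study$months, s2$study$months)
  expect_identical(s1$annotation, s2$annotation)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_genotype_table(s1$study, f1)
  write_genotype_table(s2$study, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("null genotypes are calibrated: MAF, HWE, quotas, sex ratios", {
  hwe_fail <- 0; n_snps <- 0
  for (s in 1:20) {
    sim <- null_study(500, 400, 4, seed = 1200 + s)
    st <- sim$study
    expect_equal(sum(st$phenotype == "case"), 500)
    expect_equal(sum(st$phenotype == "control"), 400)
    maf_emp <- apply(st$genotypes, 2, minor_allele_frequency)
    expect_true(all(abs(maf_emp - pmin(sim$truth$maf,
                                       1 - sim$truth$maf)) < 0.04))
    for (j in seq_len(ncol(st$genotypes))) {
      gc <- st$genotypes[st$phenotype == "control", j]
      p <- hwe_exact_test(sum(gc == 0), sum(gc == 1), sum(gc == 2))
      n_snps <- n_snps + 1
      if (p < 0.001) hwe_fail <- hwe_fail + 1
    }
  }
  # HWE violations at the 0.001 cutoff should be about 0.1% of SNPs
  expect_lte(hwe_fail / n_snps, 0.01)
  sim <- null_study(1000, 1000, 2, seed = 1300)
  fem_cases <- mean(sim$study$sex[sim$study$phenotype == "case"] ==
                      "female")
  fem_ctrl <- mean(sim$study$sex[sim$study$phenotype == "control"] ==
                     "female")
  expect_equal(fem_cases, 0.71, tolerance = 0.05)
  expect_equal(fem_ctrl, 0.50, tolerance = 0.05)
})

test_that("missingness matches the configured rate", {
  sim <- simulate_study(sim_config(
    n_cases = 500, n_controls = 500,
    panel = c(IIS = 10, pro_antioxidant = 10, DNA_repair = 10),
    missing_rate = 0.03, seed = 17))
  expect_lt(abs(mean(is.na(sim$study$genotypes)) - 0.03), 0.005)
})

test_that("LD blocks reach their target correlation and are pruned", {
  sim <- simulate_study(sim_config(
    n_cases = 400, n_controls = 400,
    panel = c(IIS = 4, pro_antioxidant = 4, DNA_repair = 4),
    ld_blocks = list(list(snps = 1:2, r = 0.95)),
    seed = 19))
  g <- sim$study$genotypes
  r2 <- episyn:::genotypic_r2(g[, 1], g[, 2])
  expect_gte(r2, 0.8)
  qc <- apply_marker_qc(sim$study, sim$annotation)
  expect_equal(sum(qc$report$drop_reason == "ld_redundant"), 1L)
  dropped <- qc$report$snp_id[qc$report$drop_reason == "ld_redundant"]
  expect_true(dropped %in% sim$study$snp_ids[1:2])
})

test_that("analytic decomposition has the documented degenerate values", {
  # constant penetrance: independence, all informations zero
  d0 <- analytic_decomposition(matrix(0.3, 3, 3), c(0.3, 0.4))
  expect_equal(d0$I_joint, 0, tolerance = 1e-14)
  expect_equal(d0$syn, 0, tolerance = 1e-14)
  # deterministic cell-wise phenotype: joint information = H(phenotype)
  tab <- matrix(0, 3, 3); tab[1, ] <- 1
  d1 <- analytic_decomposition(tab, c(0.3, 0.4))
  p_case <- episyn:::hwe_probs(0.3)[1]
  expect_equal(d1$I_joint, entropy(c(p_case, 1 - p_case) * 1e6),
               tolerance = 1e-9)
  # additive-logit table with no interaction term: the interaction
  # information is an order of magnitude below the joint information
  # (it need not be exactly non-positive: information additivity and
  # log-odds additivity are different nulls)
  gg <- expand.grid(g1 = 0:2, g2 = 0:2)
  add_tab <- matrix(plogis(-0.5 + 0.4 * gg$g1 + 0.3 * gg$g2), 3, 3)
  d2 <- analytic_decomposition(add_tab, c(0.35, 0.25))
  expect_lt(abs(d2$syn), 0.1 * d2$I_joint)
})

test_that("empirical decompositions converge to the analytic values", {
  tab <- xor_penetrance(0.30, 0.60)
  errs <- vapply(c(500, 4000, 32000), function(n) {
    med <- vapply(1:20, function(s) {
      sim <- simulate_study(sim_config(
        n_cases = n / 2, n_controls = n / 2,
        panel = c(IIS = 2, pro_antioxidant = 1, DNA_repair = 1),
        maf_range = c(0.5, 0.5),
        effects = list(list(type = "penetrance", loci = 1:2, table = tab)),
        survival_law = NULL, seed = 2000 + s * 7 + n))
      d <- synergy(sim$study$genotypes[, 1], sim$study$genotypes[, 2],
                   sim$study$phenotype)
      truth <- analytic_decomposition(tab, c(0.5, 0.5),
                                      case_fraction = 0.5)
      abs(d$syn - truth$syn)
    }, numeric(1))
    median(med)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))     # error shrinks with n
  expect_lt(errs[3], 0.01)
})

test_that("survival generation respects the planted hazard ratio", {
  comb <- genotype_combination("rs00001", conditions = list(c(1L, 2L)))
  sim <- simulate_study(sim_config(
    n_cases = 2000, n_controls = 100,
    panel = c(IIS = 2, pro_antioxidant = 1, DNA_repair = 1),
    survival_law = list(dist = "exponential", median_months = 40,
                        hr_combination = comb, hr = 0.7,
                        censor_range = c(60, 144)),
    seed = 23))
  carrier <- classify_carriers(sim$study, comb)
  cases <- episyn:::subset_subjects(sim$study,
                                    sim$study$phenotype == "case")
  idx <- match(names(carrier), cases$subject_ids)
  fit <- cox_hr(cases$months[idx], cases$event[idx], carrier)
  expect_equal(fit$log_hr, log(0.7), tolerance = 0.15)
})
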