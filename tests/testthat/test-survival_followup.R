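make_survival_study <- function(n = 200, hr = 1, seed = 1,
                                carrier_maf = 0.35) {
  set.seed(seed)
  g <- cbind(rs1 = sample(0:2, n, replace = TRUE,
                          prob = episyn:::hwe_probs(carrier_maf)))
  carrier <- g[, 1] >= 1
  t_death <- rexp(n, rate = log(2) / 40 * ifelse(carrier, hr, 1))
  t_cens <- runif(n, 60, 144)
  genotype_study(rbind(g, cbind(rs1 = rep(1L, 10))),
                 c(rep("case", n), rep("control", 10)),
                 sex = c(sample(c("female", "male"), n, replace = TRUE,
                                prob = c(0.71, 0.29)),
                         rep("male", 10)),
                 months = c(round(pmin(t_death, t_cens), 1), rep(NA, 10)),
                 event = c(as.integer(t_death <= t_cens), rep(NA, 10)))
}

test_that("carrier classification matches hand labels and logs exclusions", {
  g <- cbind(rs1 = c(2L, 2L, 1L, NA, 0L, 2L),
             rs2 = c(1L, 0L, 2L, 1L, 1L, 2L))
  st <- genotype_study(g, c(rep("case", 5), "control"),
                       months = c(10, 20, 30, 40, 50, NA),
                       event = c(1L, 1L, 0L, 1L, 1L, NA))
  comb <- genotype_combination(c("rs1", "rs2"),
                               conditions = list(2L, c(1L, 2L)))
  cl <- classify_carriers(st, comb)
  expect_identical(as.vector(cl), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(attr(cl, "n_excluded"), 1L)
  expect_identical(names(cl), c("S1", "S2", "S3", "S5"))
  # no contrast when every subject matches
  all_comb <- genotype_combination("rs2", conditions = list(0:2))
  expect_error(classify_carriers(st, all_comb), "contrast")
})

test_that("Kaplan-Meier matches hand-computed product-limit tables", {
  # all censored: survival stays at 1
  km0 <- kaplan_meier(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # all events: S = 2/3, 1/3, 0
  km1 <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$survival, c(1, 2 / 3, 1 / 3, 0))
  # mixed censoring, 6 subjects, hand-computed:
  #  t=1 (d): S=5/6; t=2 (1 death, 1 censored): 5/6*4/5=2/3;
  #  t=3 (d): 2/3*2/3=4/9; t=4 censored; t=5 (d): 4/9*0=0
  km <- kaplan_meier(c(1, 2, 2, 3, 4, 5), c(1, 0, 1, 1, 0, 1))
  surv_at <- function(t) km$survival[max(which(km$time <= t))]
  expect_equal(surv_at(1), 5 / 6)
  expect_equal(surv_at(2), 2 / 3)
  expect_equal(surv_at(3), 4 / 9)
  expect_equal(surv_at(5), 0)
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM equals one minus the empirical CDF without censoring", {
  set.seed(5)
  tt <- round(rexp(60, 1 / 30), 1)
  km <- kaplan_meier(tt, rep(1, 60))
  for (q in stats::quantile(tt, c(.2, .5, .8)))
    expect_equal(km$survival[max(which(km$time <= q))],
                 mean(tt > q), tolerance = 1e-12)
})

test_that("log-rank agrees with the observed-minus-expected oracle", {
  # identical groups: no signal
  lr0 <- logrank_test(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # 8-subject toy with ties and censoring
  t1 <- c(2, 4, 4, 7); e1 <- c(1, 1, 0, 1)
  t2 <- c(3, 5, 8, 9); e2 <- c(1, 0, 1, 0)
  lr <- logrank_test(t1, e1, t2, e2)
  expect_equal(lr$chi2, logrank_oracle(t1, e1, t2, e2), tolerance = 1e-8)
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3), c(0)), "events")
  # power at hazard ratio 2 (moderate scale)
  rej <- vapply(1:25, function(s) {
    set.seed(3000 + s)
    ta <- rexp(200, 1 / 40); tb <- rexp(200, 2 / 40)
    ca <- runif(200, 30, 90); cb <- runif(200, 30, 90)
    lr <- logrank_test(pmin(ta, ca), as.integer(ta <= ca),
                       pmin(tb, cb), as.integer(tb <= cb))
    lr$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("Cox HR for a binary covariate matches the grid-search oracle", {
  set.seed(13)
  x <- rep(c(TRUE, FALSE), each = 40)
  tt <- rexp(80, rate = ifelse(x, 1.8, 1) / 50)
  cc <- runif(80, 20, 120)
  times <- round(pmin(tt, cc), 1); events <- as.integer(tt <= cc)
  fit <- cox_hr(times, events, x)
  beta_oracle <- cox_grid_oracle(times, events, x)
  expect_equal(fit$log_hr, beta_oracle, tolerance = 1e-4)
  expect_true(fit$ci[1] < fit$hr && fit$hr < fit$ci[2])
  expect_error(cox_hr(times, events, rep(TRUE, 80)), "constant")
})

test_that("null Cox coverage and HR recovery behave as designed", {
  res <- vapply(1:40, function(s) {
    st <- make_survival_study(n = 700, hr = 0.7, seed = 4000 + s)
    comb <- genotype_combination("rs1", conditions = list(c(1L, 2L)))
    carrier <- classify_carriers(st, comb)
    cases <- episyn:::subset_subjects(st, st$phenotype == "case")
    idx <- match(names(carrier), cases$subject_ids)
    fit <- cox_hr(cases$months[idx], cases$event[idx], carrier)
    c(fit$hr, fit$ci)
  }, numeric(3))
  expect_equal(mean(res[1, ]), 0.7, tolerance = 0.05)
  cover <- mean(res[2, ] <= 0.7 & 0.7 <= res[3, ])
  expect_gte(cover, 0.85)
})

test_that("sex-stratified survival screen finds a female-only effect", {
  set.seed(29)
  n <- 1200
  g <- cbind(rs1 = sample(0:2, n, replace = TRUE,
                          prob = episyn:::hwe_probs(0.4)))
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(.6, .4))
  carrier <- g[, 1] >= 1
  hr <- ifelse(carrier & sex == "female", 0.55, 1)
  t_death <- rexp(n, rate = log(2) / 40 * hr)
  t_cens <- runif(n, 80, 160)
  st <- genotype_study(rbind(g, cbind(rs1 = rep(1L, 20))),
                       c(rep("case", n), rep("control", 20)),
                       sex = c(sex, rep("male", 20)),
                       months = c(round(pmin(t_death, t_cens), 1),
                                  rep(NA, 20)),
                       event = c(as.integer(t_death <= t_cens),
                                 rep(NA, 20)))
  comb <- genotype_combination("rs1", conditions = list(c(1L, 2L)),
                               label = "rs1 minor carriers")
  sv <- survival_screen(st, list(comb))
  expect_equal(nrow(sv), 2L)
  fem <- sv[sv$stratum == "female", ]
  mal <- sv[sv$stratum == "male", ]
  expect_lt(fem$logrank_p, 0.05)
  expect_lt(fem$hr, 1)
  expect_gt(mal$logrank_p, 0.05)
  expect_true(all(c("carrier", "noncarrier") %in%
                    names(attr(sv, "km")[[1]])))
  # empty combination list returns an empty frame
  expect_equal(nrow(survival_screen(st, list())), 0L)
})

test_that("log-rank p agrees with a permutation log-rank on toy data", {
  set.seed(31)
  ta <- rexp(30, 1 / 30); tb <- rexp(30, 1.6 / 30)
  ea <- rep(1L, 30); eb <- rep(1L, 30)
  lr <- logrank_test(ta, ea, tb, eb)
  tt <- c(ta, tb); ee <- c(ea, eb)
  grp <- rep(c(TRUE, FALSE), each = 30)
  stat <- vapply(1:2000, function(i) {
    pg <- sample(grp)
    logrank_oracle(tt[pg], ee[pg], tt[!pg], ee[!pg])
  }, numeric(1))
  p_perm <- mean(stat >= lr$chi2)
  expect_lt(abs(p_perm - lr$p), 3 * sqrt(lr$p * (1 - lr$p) / 2000) + 0.01)
})
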