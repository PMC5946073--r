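# Independent oracles and fixture builders shared by the suite. Each
# oracle deliberately uses a different algorithm from the package path
# it checks.

# Hardy-Weinberg exact test by the normalized recurrence over
# heterozygote counts (not the direct log-multinomial formula used by
# the package).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    hom_a <- (na - h) / 2
    hom_A <- n - h - hom_a
    probs[i] <- probs[i - 1] * 4 * hom_A * hom_a / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# Mutual information by the direct double sum over the joint table.
mi_oracle <- function(tab, base = 2) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  out <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0)
      out <- out + p[i, j] * log(p[i, j] / (px[i] * py[j]), base = base)
  as.numeric(out)
}

# Benjamini-Yekutieli by explicit step-up with the harmonic factor.
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  raw <- m * cm * p[ord] / seq_len(m)
  adj <- rev(cummin(rev(pmin(raw, 1))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Benjamini-Hochberg step-up (for the BY >= BH dominance property).
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  raw <- m * p[ord] / seq_len(m)
  adj <- rev(cummin(rev(pmin(raw, 1))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Two-group log-rank by the observed-minus-expected form.
logrank_oracle <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O1 <- E1 <- V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d2 <- sum(t2 == tt & e2 == 1)
    d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + n1 * d / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Breslow partial log-likelihood for a binary covariate; maximized on a
# fine grid by optimize() as an independent route to the Cox HR.
cox_grid_oracle <- function(times, events, x) {
  x <- as.numeric(x)
  loglik <- function(beta) {
    ll <- 0
    for (tt in unique(times[events == 1])) {
      risk <- times >= tt
      dead <- times == tt & events == 1
      ll <- ll + beta * sum(x[dead]) -
        sum(dead) * log(sum(exp(beta * x[risk])))
    }
    ll
  }
  stats::optimize(loglik, c(-5, 5), maximum = TRUE, tol = 1e-7)$maximum
}

# Small deterministic study: genotypes chosen by hand.
toy_study <- function() {
  g <- rbind(c(0L, 1L, 2L), c(1L, 1L, 0L), c(2L, 0L, 1L),
             c(0L, 2L, 2L), c(1L, 0L, 0L), c(2L, 1L, 1L))
  colnames(g) <- c("rsA", "rsB", "rsC")
  genotype_study(g, rep(c("case", "control"), each = 3),
                 sex = c("female", "male", "female",
                         "male", "female", "male"))
}

# Null study (no planted effects) at a given scale.
null_study <- function(n_cases, n_controls, m_per_pathway, seed,
                       missing_rate = 0) {
  sim <- simulate_study(sim_config(
    n_cases = n_cases, n_controls = n_controls,
    panel = c(IIS = m_per_pathway, pro_antioxidant = m_per_pathway,
              DNA_repair = m_per_pathway),
    missing_rate = missing_rate, seed = seed))
  sim
}

# Pure-epistasis XOR-flavoured penetrance table: risk depends on the
# parity of the summed minor-allele counts, which has exactly zero
# marginal effect when both MAFs are 0.5.
xor_penetrance <- function(lo = 0.35, hi = 0.65) {
  tab <- matrix(lo, 3, 3)
  odd <- outer(0:2, 0:2, "+") %% 2 == 1
  tab[odd] <- hi
  tab
}
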