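#' Configuration for a synthetic case-control genotype study
#'
#' Describes the full recipe the simulator executes: sample sizes, a
#' pathway-structured SNP panel, the MAF law, optional LD blocks,
#' planted phenotype effects, the survival/censoring law for the case
#' cohort, sex ratios, missingness and the seed. Defaults emulate the
#' nonagenarian-vs-middle-aged design the pipeline targets (cases ~71%
#' female, controls balanced) at a test-friendly scale of 60 SNPs in
#' three pathways and 400 cases / 300 controls.
#'
#' @param n_cases,n_controls Group sizes.
#' @param panel Named integer vector: SNPs per pathway.
#' @param maf_range MAF drawn uniformly from this interval (low >= 0.05).
#' @param ld_blocks Optional list of `list(snps = <ids or count>, r =
#'   <target genotypic correlation>)`; blocks are built by conditional
#'   copying of the block's first SNP.
#' @param effects List of planted effect specs. Each is a list with
#'   `type = "penetrance"` (fields `loci` — indices into the panel or
#'   SNP ids — and `table`, a 3x3 (or 3x3x3) matrix of P(case | cell))
#'   or `type = "logistic"` (fields `loci`, `beta0`, `beta` per-locus
#'   additive log-odds, `beta_int` product-interaction log-odds).
#' @param survival_law List: `dist` ("exponential" or "weibull"),
#'   `median_months` baseline median survival, `shape` (Weibull),
#'   `hr_combination` an optional [genotype_combination()] with
#'   `hr` the carrier hazard ratio, and `censor_range` (months) for
#'   uniform administrative censoring.
#' @param sex_ratio_cases,sex_ratio_controls Fraction female.
#' @param missing_rate Per-cell missingness probability.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 400, n_controls = 300,
                       panel = c(IIS = 20, pro_antioxidant = 20,
                                 DNA_repair = 20),
                       maf_range = c(0.10, 0.45),
                       ld_blocks = NULL,
                       effects = list(),
                       survival_law = list(dist = "exponential",
                                           median_months = 40,
                                           censor_range = c(60, 144)),
                       sex_ratio_cases = 0.71,
                       sex_ratio_controls = 0.50,
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1,
            maf_range[1] >= 0.05, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1,
            sex_ratio_cases >= 0, sex_ratio_cases <= 1,
            sex_ratio_controls >= 0, sex_ratio_controls <= 1)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 panel = panel, maf_range = maf_range,
                 ld_blocks = ld_blocks, effects = effects,
                 survival_law = survival_law,
                 sex_ratio_cases = sex_ratio_cases,
                 sex_ratio_controls = sex_ratio_controls,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

hwe_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

draw_hwe <- function(n, maf) {
  sample.int(3L, n, replace = TRUE, prob = hwe_probs(maf)) - 1L
}

# P(case | genotype row) for one planted effect
effect_prob <- function(effect, g) {
  loci <- effect$loci
  if (identical(effect$type, "penetrance")) {
    tab <- effect$table
    if (length(loci) == 2L) tab[cbind(g[, loci[1L]] + 1L,
                                      g[, loci[2L]] + 1L)]
    else tab[cbind(g[, loci[1L]] + 1L, g[, loci[2L]] + 1L,
                   g[, loci[3L]] + 1L)]
  } else {
    lin <- effect$beta0
    for (i in seq_along(loci)) lin <- lin + effect$beta[i] * g[, loci[i]]
    if (!is.null(effect$beta_int) && effect$beta_int != 0) {
      prod_g <- g[, loci[1L]]
      for (i in seq_along(loci)[-1L]) prod_g <- prod_g * g[, loci[i]]
      lin <- lin + effect$beta_int * prod_g
    }
    stats::plogis(lin)
  }
}

case_probability <- function(config, g, base_rate = 0.5) {
  if (!length(config$effects)) return(rep(base_rate, nrow(g)))
  # combine effects on the log-odds scale relative to the neutral rate
  lin <- stats::qlogis(base_rate)
  for (eff in config$effects) {
    p <- effect_prob(eff, g)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    lin <- lin + stats::qlogis(p) - stats::qlogis(base_rate)
  }
  stats::plogis(lin)
}

#' Simulate a pathway-structured case-control genotype study
#'
#' Draws per-SNP genotypes from Hardy-Weinberg proportions at MAFs
#' sampled from the configured law, builds optional LD blocks by
#' conditional copying (a block member equals the block head with
#' probability `r`, else a fresh HWE draw, giving genotypic correlation
#' ~ `r`), assigns phenotype by rejection sampling against the planted
#' effect model until the case and control quotas fill, draws
#' genotype-dependent censored survival for cases, and applies uniform
#' missingness. All randomness flows from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `study` (a [genotype_study()]), `annotation` (a
#'   [snp_annotation()]: SNPs grouped into synthetic genes of ~3 SNPs,
#'   one chromosome per pathway, positions 10 kb apart) and `truth` (the
#'   planted effect specs plus their analytic information decomposition
#'   and the survival law).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- sum(config$panel)
  snp_ids <- sprintf("rs%05d", seq_len(m))
  pathway <- rep(names(config$panel), config$panel)
  # synthetic genes of ~3 SNPs; one chromosome per pathway, 10 kb spacing
  gene <- paste0("G", cumsum(rep_len(c(1L, 0L, 0L), m)))
  chromosome <- as.character(match(pathway, names(config$panel)))
  position <- integer(m)
  for (pw in unique(pathway)) {
    idx <- which(pathway == pw)
    position[idx] <- 1L + (seq_along(idx) - 1L) * 10000L
  }
  ann <- snp_annotation(snp_ids, gene, pathway, chromosome, position,
                        pathways = names(config$panel))

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  # resolve effect loci given as panel indices or SNP ids
  effects <- lapply(config$effects, function(eff) {
    if (is.character(eff$loci)) eff$loci <- match(eff$loci, snp_ids)
    if (anyNA(eff$loci) || any(eff$loci > m))
      stop("planted effect refers to loci outside the panel",
           call. = FALSE)
    eff
  })
  cfg <- config; cfg$effects <- effects

  ld_members <- integer(0)
  blocks <- lapply(config$ld_blocks, function(bl) {
    ids <- if (is.character(bl$snps)) match(bl$snps, snp_ids)
           else bl$snps
    list(ids = as.integer(ids), r = bl$r)
  })

  draw_genotypes <- function(n_draw) {
    g <- matrix(0L, n_draw, m)
    for (j in seq_len(m)) g[, j] <- draw_hwe(n_draw, maf[j])
    for (bl in blocks) {
      head_col <- bl$ids[1L]
      for (j in bl$ids[-1L]) {
        copy <- stats::runif(n_draw) < bl$r
        g[copy, j] <- g[copy, head_col]
      }
    }
    g
  }

  n_cases <- config$n_cases; n_controls <- config$n_controls
  got_case <- 0L; got_ctrl <- 0L
  case_rows <- vector("list", 0); ctrl_rows <- vector("list", 0)
  batch <- max(1000L, n_cases + n_controls)
  tries <- 0L
  while (got_case < n_cases || got_ctrl < n_controls) {
    tries <- tries + 1L
    if (tries > 200L)
      stop("case/control quotas unreachable: degenerate penetrance?",
           call. = FALSE)
    g <- draw_genotypes(batch)
    p_case <- case_probability(cfg, g)
    is_case <- stats::runif(batch) < p_case
    need_case <- n_cases - got_case
    need_ctrl <- n_controls - got_ctrl
    take_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
    take_ctrl <- which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))]
    if (length(take_case)) {
      case_rows[[length(case_rows) + 1L]] <- g[take_case, , drop = FALSE]
      got_case <- got_case + length(take_case)
    }
    if (length(take_ctrl)) {
      ctrl_rows[[length(ctrl_rows) + 1L]] <- g[take_ctrl, , drop = FALSE]
      got_ctrl <- got_ctrl + length(take_ctrl)
    }
  }
  g <- rbind(do.call(rbind, case_rows), do.call(rbind, ctrl_rows))
  colnames(g) <- snp_ids
  phenotype <- rep(c("case", "control"), c(n_cases, n_controls))
  sex <- c(ifelse(stats::runif(n_cases) < config$sex_ratio_cases,
                  "female", "male"),
           ifelse(stats::runif(n_controls) < config$sex_ratio_controls,
                  "female", "male"))

  # genotype-dependent censored survival for the case cohort
  sl <- config$survival_law
  months <- rep(NA_real_, n_cases + n_controls)
  event <- rep(NA_integer_, n_cases + n_controls)
  if (!is.null(sl)) {
    idx <- seq_len(n_cases)
    hr <- rep(1, n_cases)
    if (!is.null(sl$hr_combination)) {
      tmp_study <- genotype_study(g[idx, , drop = FALSE],
                                  rep("case", n_cases))
      carrier <- matches_combination(tmp_study, sl$hr_combination)
      hr[which(carrier)] <- sl$hr
    }
    if (identical(sl$dist, "weibull")) {
      shape <- if (is.null(sl$shape)) 1.5 else sl$shape
      scale0 <- sl$median_months / log(2)^(1 / shape)
      t_death <- scale0 * (-log(stats::runif(n_cases)) / hr)^(1 / shape)
    } else {
      rate0 <- log(2) / sl$median_months
      t_death <- stats::rexp(n_cases, rate = rate0 * hr)
    }
    t_cens <- stats::runif(n_cases, sl$censor_range[1], sl$censor_range[2])
    months[idx] <- round(pmin(t_death, t_cens), 1)
    event[idx] <- as.integer(t_death <= t_cens)
  }

  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(g)) < config$missing_rate,
                   nrow(g), ncol(g))
    g[drop] <- NA_integer_
  }

  study <- genotype_study(g, phenotype, sex = sex,
                          months = if (is.null(sl)) NULL else months,
                          event = if (is.null(sl)) NULL else event)
  truth <- list(
    effects = lapply(effects, function(eff) {
      eff$snp_ids <- snp_ids[eff$loci]
      if (identical(eff$type, "penetrance") && length(eff$loci) == 2L)
        eff$analytic <- analytic_decomposition(
          eff$table, maf[eff$loci],
          case_fraction = n_cases / (n_cases + n_controls))
      eff
    }),
    maf = stats::setNames(maf, snp_ids),
    survival_law = sl)
  list(study = study, annotation = ann, truth = truth)
}

#' Population information decomposition of a two-locus penetrance table
#'
#' Closed-form synergy decomposition implied by HWE genotype frequencies
#' and a 3x3 penetrance table, used as the analytic oracle for the
#' plug-in estimators. With `case_fraction` given, the joint law is
#' re-weighted to case-control (retrospective) sampling at that case
#' share, matching how a simulated study is ascertained; otherwise the
#' prospective (population prevalence) law is used.
#'
#' @param table 3x3 matrix of P(case | g1, g2).
#' @param mafs Length-2 minor allele frequencies in `(0, 0.5]`.
#' @param case_fraction Optional case share under case-control sampling.
#' @param base Logarithm base (default 2).
#' @return An `info_decomposition` (with `n_used = NA`).
#' @export
analytic_decomposition <- function(table, mafs, case_fraction = NULL,
                                   base = 2) {
  stopifnot(all(dim(table) == c(3, 3)), length(mafs) == 2,
            all(mafs > 0), all(mafs <= 0.5),
            all(table >= 0), all(table <= 1))
  pg <- outer(hwe_probs(mafs[1]), hwe_probs(mafs[2]))   # 3x3 cell law
  joint_case <- pg * table
  joint_ctrl <- pg * (1 - table)
  if (!is.null(case_fraction)) {
    joint_case <- joint_case / sum(joint_case) * case_fraction
    joint_ctrl <- joint_ctrl / sum(joint_ctrl) * (1 - case_fraction)
  }
  mi_law <- function(pc, pq) {
    # pc, pq: matching arrays of joint P(x, case), P(x, control)
    px <- pc + pq
    py <- c(sum(pc), sum(pq))
    terms <- function(pxy, pyv)
      sum(ifelse(pxy > 0, pxy * log(pxy / (px * pyv), base = base), 0))
    terms(pc, py[1]) + terms(pq, py[2])
  }
  I_joint <- mi_law(joint_case, joint_ctrl)
  I1 <- mi_law(rowSums(joint_case), rowSums(joint_ctrl))
  I2 <- mi_law(colSums(joint_case), colSums(joint_ctrl))
  d <- new_info_decomposition(I_joint, I1, I2, NA_integer_)
  d
}
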