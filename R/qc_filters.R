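#' Minor allele frequency of a genotype column
#'
#' Computed over non-missing alleles only and folded so the returned
#' frequency is that of the less common allele (always <= 0.5).
#'
#' @param g Integer vector of minor-allele counts (0/1/2, NA missing).
#' @return Frequency in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) stop("all genotypes missing", call. = FALSE)
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts, conditioning on the observed
#' allele counts: the p-value is the total conditional probability of all
#' heterozygote counts whose probability does not exceed that of the
#' observed table. Typically applied to the control group only, since
#' departures in cases can carry association signal.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major hom, het, minor hom).
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop("negative genotype count", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("need at least one genotyped subject", call. = FALSE)
  n_a <- 2 * n_aa + n_Aa            # minor allele count
  # heterozygote counts achievable given the allele counts share parity
  het <- seq.int(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  # log conditional probability of each table:
  #   P(nAa | n, na) = n! 2^nAa na! nA! / (nAA! nAa! naa! (2n)!)
  hom_a <- (n_a - het) / 2
  hom_A <- n - het - hom_a
  logp <- lgamma(n + 1) - lgamma(hom_A + 1) - lgamma(het + 1) -
    lgamma(hom_a + 1) + het * log(2) +
    lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  p_obs <- logp[match(n_Aa, het)]
  min(1, sum(exp(logp[logp <= p_obs + 1e-10])))
}

# genotypic r^2: squared Pearson correlation of allele counts over
# pairwise-complete subjects (composite LD surrogate for unphased data)
genotypic_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) return(NA_real_)
  if (stats::sd(g1[ok]) == 0 || stats::sd(g2[ok]) == 0) return(NA_real_)
  stats::cor(g1[ok], g2[ok])^2
}

#' Marker-level quality control
#'
#' Applies, in order: a call-rate guard (per-SNP missingness), a
#' whole-sample MAF threshold, a Hardy-Weinberg exact-test filter in the
#' control group, and within-chromosome tag pruning of pairs with
#' genotypic r-squared at or above `r2_max` or physical separation below
#' `min_distance_bp`, keeping the higher-MAF member of each redundant
#' pair (identifier order breaks MAF ties).
#'
#' @param study A [genotype_study()] with both phenotype groups.
#' @param ann Optional [snp_annotation()]; required for the
#'   chromosome/distance part of pruning. SNPs without annotation are
#'   exempt from pruning (recorded in the report).
#' @param maf_min Minimum whole-sample MAF (default 0.05).
#' @param hwe_alpha HWE exact-test cutoff in controls (default 0.001).
#' @param r2_max Genotypic r-squared at or above which one of a pair is
#'   pruned (default 0.8).
#' @param min_distance_bp Minimum within-chromosome separation in base
#'   pairs (default 60).
#' @param max_missing Maximum per-SNP missing fraction (default 0.10).
#' @return A list with the filtered `study` and a `report` data.frame of
#'   class `qc_report` (snp_id, call_rate, maf, hwe_p, kept, drop_reason,
#'   tag_of, r2).
#' @export
apply_marker_qc <- function(study, ann = NULL, maf_min = 0.05,
                            hwe_alpha = 0.001, r2_max = 0.8,
                            min_distance_bp = 60, max_missing = 0.10) {
  check_two_groups(study)
  g <- study$genotypes
  snps <- study$snp_ids
  ctrl <- study$phenotype == "control"
  m <- length(snps)

  call_rate <- colMeans(!is.na(g))
  maf <- vapply(seq_len(m), function(j) minor_allele_frequency(g[, j]),
                numeric(1))
  hwe_p <- vapply(seq_len(m), function(j) {
    gc <- g[ctrl, j]
    gc <- gc[!is.na(gc)]
    if (!length(gc)) return(NA_real_)
    hwe_exact_test(sum(gc == 0L), sum(gc == 1L), sum(gc == 2L))
  }, numeric(1))

  drop_reason <- rep("none", m)
  drop_reason[call_rate < 1 - max_missing] <- "call_rate"
  drop_reason[drop_reason == "none" & maf < maf_min] <- "maf"
  drop_reason[drop_reason == "none" & !is.na(hwe_p) &
                hwe_p < hwe_alpha] <- "hwe"

  tag_of <- rep(NA_character_, m)
  r2_rec <- rep(NA_real_, m)
  surv <- which(drop_reason == "none")
  if (!is.null(ann) && length(surv) > 1L) {
    pos <- ann$position[match(snps, ann$snp_id)]
    chr <- ann$chromosome[match(snps, ann$snp_id)]
    # priority: higher MAF first, identifier order on ties -> the kept
    # set is invariant to input column order
    ord <- surv[order(-maf[surv], snps[surv])]
    kept_idx <- integer(0)
    for (j in ord) {
      if (is.na(chr[j])) { kept_idx <- c(kept_idx, j); next }
      conflict <- NA_integer_
      for (kk in kept_idx) {
        if (is.na(chr[kk]) || chr[kk] != chr[j]) next
        close_bp <- !is.na(pos[j]) && !is.na(pos[kk]) &&
          abs(pos[j] - pos[kk]) < min_distance_bp
        r2 <- genotypic_r2(g[, j], g[, kk])
        if (close_bp || (!is.na(r2) && r2 >= r2_max)) {
          conflict <- kk
          r2_rec[j] <- r2
          break
        }
      }
      if (is.na(conflict)) kept_idx <- c(kept_idx, j)
      else {
        drop_reason[j] <- "ld_redundant"
        tag_of[j] <- snps[conflict]
      }
    }
  }

  report <- data.frame(snp_id = snps, call_rate = call_rate, maf = maf,
                       hwe_p = hwe_p, kept = drop_reason == "none",
                       drop_reason = drop_reason, tag_of = tag_of,
                       r2 = r2_rec, stringsAsFactors = FALSE)
  class(report) <- c("qc_report", "data.frame")
  keep <- snps[report$kept]
  if (!length(keep)) stop("QC removed every SNP", call. = FALSE)
  list(study = subset_snps(study, keep), report = report)
}

#' Write a QC report as TSV
#'
#' @param report A `qc_report` from [apply_marker_qc()].
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
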