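#' Shannon entropy of label counts
#'
#' Plug-in estimate from counts, with `0 * log 0 = 0`. Base-2 logarithms
#' by default, so entropies and informations are in bits.
#'
#' @param counts Non-negative counts, total >= 1.
#' @param base Logarithm base (default 2).
#' @return Entropy in bits (or `base`-ary units).
#' @export
entropy <- function(counts, base = 2) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("entropy of an empty distribution", call. = FALSE)
  p <- counts[counts > 0] / n
  -sum(p * log(p, base = base))
}

# MI from a joint count table (rows = feature levels, cols = classes)
mi_from_table <- function(tab, base = 2) {
  n <- sum(tab)
  h_y <- entropy(colSums(tab), base = base)
  h_cond <- sum(vapply(seq_len(nrow(tab)), function(i) {
    ni <- sum(tab[i, ])
    if (ni == 0) return(0)
    (ni / n) * entropy(tab[i, ], base = base)
  }, numeric(1)))
  max(0, h_y - h_cond)
}

#' Information gain of a feature about the phenotype
#'
#' Mutual information `I(feature; phenotype) = H(phenotype) -
#' H(phenotype | feature)`, plug-in estimate over pairwise-complete
#' subjects. For one SNP the feature has up to 3 levels; for a SNP pair,
#' pass the 9-level joint genotype.
#'
#' @param feature Discrete feature vector (<= 9 levels; NA dropped).
#' @param phenotype Class labels, two classes required after
#'   complete-case removal.
#' @param base Logarithm base (default 2).
#' @return Information in bits.
#' @export
information_gain <- function(feature, phenotype, base = 2) {
  ok <- !is.na(feature) & !is.na(phenotype)
  feature <- feature[ok]; phenotype <- phenotype[ok]
  if (length(feature) < 2L)
    stop("need at least two complete cases", call. = FALSE)
  if (length(unique(phenotype)) < 2L)
    stop("a single phenotype class remains after missing-data removal",
         call. = FALSE)
  if (length(unique(feature)) > 9L)
    stop("feature has more than 9 levels", call. = FALSE)
  mi_from_table(table(feature, phenotype), base = base)
}

new_info_decomposition <- function(I_joint, I1, I2, n_used) {
  structure(list(I_joint = I_joint, I1 = I1, I2 = I2,
                 syn = I_joint - I1 - I2, n_used = n_used),
            class = "info_decomposition")
}

#' @export
print.info_decomposition <- function(x, digits = 4, ...) {
  cat(sprintf("synergy decomposition (n = %d):\n", x$n_used))
  cat(sprintf("  I(pair)  = %.*f bits\n  I1       = %.*f\n  I2       = %.*f\n  Syn      = %+.*f\n",
              digits, x$I_joint, digits, x$I1, digits, x$I2, digits, x$syn))
  invisible(x)
}

#' Information-theoretic synergy of a SNP pair on the phenotype
#'
#' Computes the interaction information `Syn = I(joint; phenotype) -
#' I(SNP1; phenotype) - I(SNP2; phenotype)` on the subjects with both
#' genotypes observed (listwise within the pair). Positive synergy means
#' the pair carries information about the phenotype beyond the additive
#' single-SNP expectation; negative synergy marks redundancy, as seen
#' between SNPs in linkage disequilibrium.
#'
#' @param g1,g2 Genotype vectors (0/1/2, NA missing).
#' @param phenotype Case/control labels.
#' @param base Logarithm base (default 2).
#' @param min_n Minimum complete cases required (default 30).
#' @param pair Optional identifier pair used in error messages.
#' @return An `info_decomposition` with fields `I_joint`, `I1`, `I2`,
#'   `syn` and `n_used`.
#' @export
synergy <- function(g1, g2, phenotype, base = 2, min_n = 30, pair = NULL) {
  ok <- !is.na(g1) & !is.na(g2) & !is.na(phenotype)
  if (sum(ok) < min_n)
    stop("fewer than ", min_n, " complete cases",
         if (!is.null(pair)) paste0(" for pair ", paste(pair, collapse = "/")),
         call. = FALSE)
  g1 <- g1[ok]; g2 <- g2[ok]; ph <- phenotype[ok]
  if (length(unique(ph)) < 2L)
    stop("a single phenotype class remains after missing-data removal",
         call. = FALSE)
  y <- as.integer(factor(ph))
  counts <- pair_counts(g1, g2, y == 1L)
  decomposition_from_counts(counts$case, counts$ctrl, base = base)
}

# 2 x 9 counts of the joint genotype by class
pair_counts <- function(g1, g2, is_case) {
  cell <- g1 * 3L + g2 + 1L            # 1..9
  list(case = tabulate(cell[is_case], 9L),
       ctrl = tabulate(cell[!is_case], 9L))
}

# InfoDecomposition from per-class 9-cell counts (cell = g1*3+g2+1); the
# single-SNP informations come from the row/column marginals of the same
# table, so all three terms share one complete-case subject set.
decomposition_from_counts <- function(case9, ctrl9, base = 2) {
  tab <- cbind(case9, ctrl9)
  I_joint <- mi_from_table(tab, base = base)
  m1_case <- rowsum_3(case9, by = "g1"); m1_ctrl <- rowsum_3(ctrl9, "g1")
  m2_case <- rowsum_3(case9, by = "g2"); m2_ctrl <- rowsum_3(ctrl9, "g2")
  I1 <- mi_from_table(cbind(m1_case, m1_ctrl), base = base)
  I2 <- mi_from_table(cbind(m2_case, m2_ctrl), base = base)
  new_info_decomposition(I_joint, I1, I2, sum(tab))
}

rowsum_3 <- function(cells9, by = c("g1", "g2")) {
  by <- match.arg(by)
  m <- matrix(cells9, 3, 3, byrow = TRUE)  # rows g1, cols g2
  if (by == "g1") rowSums(m) else colSums(m)
}
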