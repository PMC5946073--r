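#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary
#' dependence, using the harmonic-sum factor `c(m) = sum(1/i)`. Returned
#' values are monotone in rank and capped at 1.
#'
#' @param p p-values in `(0, 1]`.
#' @return Adjusted values, same order as `p`.
#' @export
benjamini_yekutieli <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BY")
}

# x * log2(x) with 0 -> 0, vectorized over matrices
xlog2 <- function(x) {
  out <- x * log2(x)
  out[x == 0] <- 0
  out
}

# Vectorized synergy decomposition for P pairs at once.
# C, D: P x 9 matrices of case/control counts of the joint genotype,
# cell = g1*3 + g2 + 1. Returns list of per-pair vectors.
syn_from_count_mats <- function(C, D) {
  n_case <- rowSums(C); n_ctrl <- rowSums(D); n <- n_case + n_ctrl
  Sy <- xlog2(n_case) + xlog2(n_ctrl)
  mi <- function(Cm, Dm)
    (rowSums(xlog2(Cm)) + rowSums(xlog2(Dm)) - rowSums(xlog2(Cm + Dm)) -
       Sy + xlog2(n)) / n
  I_joint <- mi(C, D)
  g1_groups <- list(1:3, 4:6, 7:9)
  g2_groups <- list(c(1L, 4L, 7L), c(2L, 5L, 8L), c(3L, 6L, 9L))
  margin <- function(M, groups) {
    out <- vapply(groups, function(cols) rowSums(M[, cols, drop = FALSE]),
                  numeric(nrow(M)))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
    out
  }
  I1 <- mi(margin(C, g1_groups), margin(D, g1_groups))
  I2 <- mi(margin(C, g2_groups), margin(D, g2_groups))
  list(I_joint = pmax(0, I_joint), I1 = pmax(0, I1), I2 = pmax(0, I2),
       syn = I_joint - I1 - I2, n_used = n)
}

# Long-format cell index for a set of pairs: for pair p (columns a, b)
# and subject i with both genotypes observed, one entry
# gcell = (p-1)*9 + g_a*3 + g_b + 1 together with the subject row. One
# tabulate() over gcell restricted to one class yields all pairs' 9-cell
# class counts in a single pass.
build_pair_cells <- function(g, pairs_a, pairs_b) {
  P <- length(pairs_a)
  n <- nrow(g)
  cells <- vector("list", P)
  rows <- vector("list", P)
  for (p in seq_len(P)) {
    c1 <- g[, pairs_a[p]]; c2 <- g[, pairs_b[p]]
    ok <- which(!is.na(c1) & !is.na(c2))
    cells[[p]] <- (p - 1L) * 9L + c1[ok] * 3L + c2[ok] + 1L
    rows[[p]] <- ok
  }
  list(gcell = unlist(cells, use.names = FALSE),
       rowid = unlist(rows, use.names = FALSE), P = P)
}

count_mats <- function(cellidx, is_case_row, rowid, P) {
  case <- tabulate(cellidx[is_case_row[rowid]], 9L * P)
  ctrl <- tabulate(cellidx[!is_case_row[rowid]], 9L * P)
  list(C = matrix(case, P, 9, byrow = TRUE),
       D = matrix(ctrl, P, 9, byrow = TRUE))
}

#' Exhaustive pairwise synergy screen with permutation significance
#'
#' For every in-scope unordered SNP pair, computes the information
#' decomposition (joint, single-SNP, synergy) on the pair's
#' complete-case subjects, a one-sided permutation p-value in the
#' synergistic direction, and a Benjamini-Yekutieli FDR across all
#' in-scope pairs. Each permutation replicate shuffles the phenotype
#' once and applies the same shuffled labels to every pair, preserving
#' the dependence between pair statistics that the FDR must survive.
#'
#' Pairs that are clearly non-significant are released early from the
#' permutation loop (once 200 replicates put their running p-value above
#' `p_stop`); any pair still in contention receives the full `n_perm`
#' replicates.
#'
#' @param study A QC-filtered [genotype_study()].
#' @param ann Optional [snp_annotation()] supplying gene/pathway labels
#'   (required for pathway-restricted scopes and edge classification).
#' @param n_perm Number of phenotype permutations (>= 100, or 0 to skip
#'   the significance stage and rank by synergy only).
#' @param scope `"all"`, `"within_pathway"` or `"between_pathways"`.
#' @param seed Integer seed for the shared permutation stream.
#' @param min_n Minimum complete cases per pair; pairs below it are
#'   skipped with a warning.
#' @param base Logarithm base for informations (default 2).
#' @param early_stop Release clearly non-significant pairs early
#'   (default TRUE).
#' @param p_stop Running p-value above which a pair is released
#'   (default 0.2).
#' @return An object of class `synergy_screen`: `records` is a
#'   data.frame with one row per pair (snp1 < snp2 by identifier), with
#'   `I`, `I1`, `I2`, `syn`, `n_used`, `p_perm`, `fdr_q`, gene/pathway
#'   labels and `category`, sorted by ascending FDR then descending
#'   synergy.
#' @export
screen_pairs <- function(study, ann = NULL, n_perm = 1000,
                         scope = c("all", "within_pathway",
                                   "between_pathways"),
                         seed = 1L, min_n = 30, base = 2,
                         early_stop = TRUE, p_stop = 0.2) {
  scope <- match.arg(scope)
  check_two_groups(study)
  if (n_perm != 0 && n_perm < 100)
    stop("n_perm must be at least 100 (or 0 to skip)", call. = FALSE)
  snps <- study$snp_ids
  m <- length(snps)
  if (m < 2L) stop("need at least two SNPs", call. = FALSE)

  gene <- pathway <- rep(NA_character_, m)
  if (!is.null(ann)) {
    idx <- match(snps, ann$snp_id)
    gene <- ann$gene[idx]
    pathway <- ann$pathway[idx]
  }
  pairs <- t(utils::combn(m, 2L))
  # canonical orientation: snp1 < snp2 by identifier order
  flip <- snps[pairs[, 1L]] > snps[pairs[, 2L]]
  pairs[flip, ] <- pairs[flip, c(2L, 1L)]
  if (scope != "all") {
    if (is.null(ann))
      stop("pathway-restricted scope requires an annotation", call. = FALSE)
    same <- pathway[pairs[, 1L]] == pathway[pairs[, 2L]]
    same[is.na(same)] <- FALSE
    pairs <- pairs[if (scope == "within_pathway") same else !same, ,
                   drop = FALSE]
  }
  if (!nrow(pairs)) stop("scope yields zero pairs", call. = FALSE)

  g <- study$genotypes
  is_case <- study$phenotype == "case"
  pc <- build_pair_cells(g, pairs[, 1L], pairs[, 2L])
  P <- pc$P
  obs_counts <- count_mats(pc$gcell, is_case, pc$rowid, P)
  obs <- syn_from_count_mats(obs_counts$C, obs_counts$D)

  too_few <- obs$n_used < min_n
  if (any(too_few))
    warning(sum(too_few), " pair(s) with fewer than ", min_n,
            " complete cases skipped")

  # permutation loop: shared shuffled phenotype per replicate, early
  # release of hopeless pairs between blocks
  set.seed(as.integer(seed))
  n <- nrow(g)
  exceed <- integer(P)          # replicates with perm syn >= observed
  used <- integer(P)            # replicates seen per pair
  active <- which(!too_few)
  gcell <- pc$gcell; rowid <- pc$rowid
  pair_of <- rep(seq_len(P), times = tabulate(
    (pc$gcell - 1L) %/% 9L + 1L, P))
  done <- 0L
  block <- 100L
  syn_obs_eps <- obs$syn - 1e-12
  while (done < n_perm && length(active)) {
    B <- min(block, n_perm - done)
    # map active pairs to compact offsets for this block
    keep <- pair_of %in% active
    sub_gcell <- gcell[keep]; sub_rowid <- rowid[keep]
    new_id <- match((sub_gcell - 1L) %/% 9L + 1L, active)
    sub_gcell <- (new_id - 1L) * 9L + (sub_gcell - 1L) %% 9L + 1L
    Pa <- length(active)
    for (r in seq_len(B)) {
      perm_case <- is_case[sample.int(n)]
      cm <- count_mats(sub_gcell, perm_case, sub_rowid, Pa)
      s <- syn_from_count_mats(cm$C, cm$D)
      exceed[active] <- exceed[active] + (s$syn >= syn_obs_eps[active])
    }
    used[active] <- used[active] + B
    done <- done + B
    if (early_stop && done >= 200L && done < n_perm) {
      phat <- (exceed[active] + 1) / (used[active] + 1)
      active <- active[phat <= p_stop]
    }
  }
  p_perm <- rep(NA_real_, P)
  got <- used > 0L
  p_perm[got] <- (exceed[got] + 1) / (used[got] + 1)

  keep_rec <- !too_few
  a <- pairs[keep_rec, 1L]; b <- pairs[keep_rec, 2L]
  category <- ifelse(!is.na(gene[a]) & gene[a] == gene[b], "intra_gene",
              ifelse(!is.na(pathway[a]) & pathway[a] == pathway[b],
                     "intra_pathway", "inter_pathway"))
  records <- data.frame(
    snp1 = snps[a], snp2 = snps[b],
    gene1 = gene[a], gene2 = gene[b],
    pathway1 = pathway[a], pathway2 = pathway[b],
    I = obs$I_joint[keep_rec], I1 = obs$I1[keep_rec],
    I2 = obs$I2[keep_rec], syn = obs$syn[keep_rec],
    n_used = obs$n_used[keep_rec], p_perm = p_perm[keep_rec],
    stringsAsFactors = FALSE)
  records$fdr_q <- if (all(is.na(records$p_perm))) NA_real_
                   else benjamini_yekutieli(records$p_perm)
  records$category <- category
  records <- records[if (all(is.na(records$fdr_q)))
    order(-records$syn) else order(records$fdr_q, -records$syn), ]
  rownames(records) <- NULL
  structure(list(records = records, n_perm = n_perm, scope = scope,
                 seed = seed, n_subjects = n,
                 h_phenotype = entropy(c(sum(is_case), sum(!is_case)),
                                       base = base)),
            class = "synergy_screen")
}

#' @export
print.synergy_screen <- function(x, ...) {
  cat("synergy_screen: ", nrow(x$records), " SNP pairs (scope ", x$scope,
      "), ", x$n_perm, " permutations\n", sep = "")
  cat("  pairs with Syn > 0:", sum(x$records$syn > 0), "\n")
  cat("  top pairs:\n")
  top <- utils::head(x$records[, c("snp1", "snp2", "syn", "I", "p_perm",
                                   "fdr_q")], 5L)
  print(top, digits = 4)
  invisible(x)
}

#' @export
summary.synergy_screen <- function(object, fdr_max = 0.005,
                                   p_max = 1e-4, ...) {
  r <- object$records
  sig <- r$fdr_q < fdr_max & r$p_perm < p_max
  out <- list(n_pairs = nrow(r), n_synergistic = sum(r$syn > 0),
              n_significant = sum(sig),
              category_counts = table(r$category[sig]),
              fdr_max = fdr_max, p_max = p_max)
  class(out) <- "summary.synergy_screen"
  out
}

#' @export
print.summary.synergy_screen <- function(x, ...) {
  cat("pairs screened:      ", x$n_pairs, "\n")
  cat("synergistic (Syn>0): ", x$n_synergistic, "\n")
  cat(sprintf("significant (FDR < %g, p < %g): %d\n", x$fdr_max, x$p_max,
              x$n_significant))
  if (x$n_significant) print(x$category_counts)
  invisible(x)
}

#' Build the interaction network from screen records
#'
#' Retains pairs passing both the FDR and permutation-p thresholds,
#' classifies each edge as intra-gene, intra-pathway or inter-pathway,
#' and tallies the partition. Intra-gene edges are flagged for residual
#' LD review: synergy between markers of one gene can reflect modest
#' correlation below the QC pruning threshold rather than epistasis.
#'
#' @param screen A `synergy_screen` (or its `records` data.frame).
#' @param fdr_max FDR threshold (default 0.005).
#' @param p_max Permutation-p threshold (default 1e-4).
#' @return An object of class `interaction_network` with `edges`,
#'   `nodes` and `partition` (edge counts by category and pathway pair).
#' @export
build_network <- function(screen, fdr_max = 0.005, p_max = 1e-4) {
  records <- if (inherits(screen, "synergy_screen")) screen$records
             else screen
  sig <- records[records$fdr_q < fdr_max & records$p_perm < p_max, ,
                 drop = FALSE]
  sig$ld_flag <- sig$category == "intra_gene"
  node_label <- function(snp, gene) ifelse(is.na(gene), snp, gene)
  nodes <- unique(data.frame(
    snp_id = c(sig$snp1, sig$snp2),
    label = c(node_label(sig$snp1, sig$gene1),
              node_label(sig$snp2, sig$gene2)),
    stringsAsFactors = FALSE))
  pw_pair <- ifelse(sig$category == "inter_pathway",
                    paste(pmin(sig$pathway1, sig$pathway2),
                          pmax(sig$pathway1, sig$pathway2), sep = "-"),
                    sig$pathway1)
  partition <- as.data.frame(table(category = sig$category,
                                   pathways = pw_pair),
                             stringsAsFactors = FALSE)
  partition <- partition[partition$Freq > 0, , drop = FALSE]
  rownames(partition) <- NULL
  structure(list(edges = sig, nodes = nodes, partition = partition,
                 fdr_max = fdr_max, p_max = p_max),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network: ", nrow(x$edges), " edges among ",
      nrow(x$nodes), " SNPs (FDR < ", x$fdr_max, ", p < ", x$p_max,
      ")\n", sep = "")
  if (nrow(x$partition)) print(x$partition)
  if (any(x$edges$ld_flag))
    cat(sum(x$edges$ld_flag),
        "intra-gene edge(s) flagged for residual-LD review\n")
  invisible(x)
}

#' Write screen results and network exports
#'
#' `write_screen` emits the ranked pair table as TSV; `write_network`
#' emits the edge list as TSV and a Graphviz DOT file with gene-symbol
#' node labels (rsID fallback).
#'
#' @param screen A `synergy_screen`.
#' @param network An `interaction_network`.
#' @param path,edge_path,dot_path Output paths.
#' @export
write_screen <- function(screen, path) {
  utils::write.table(screen$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_screen
#' @export
write_network <- function(network, edge_path, dot_path = NULL) {
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(dot_path)) {
    lines <- c("graph interactions {",
               sprintf('  "%s" [label="%s"];', network$nodes$snp_id,
                       network$nodes$label),
               sprintf('  "%s" -- "%s" [label="%.4f"];',
                       network$edges$snp1, network$edges$snp2,
                       network$edges$syn),
               "}")
    writeLines(lines, dot_path)
  }
  invisible(edge_path)
}
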