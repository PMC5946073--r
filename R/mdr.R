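#' Impute missing genotypes by the per-SNP mode
#'
#' Global (whole-sample) modal replacement, matching the classical MDR
#' preprocessing convention. Ties between modal genotypes resolve to the
#' lower code. The number of imputed cells per SNP is attached as the
#' `"imputed"` attribute of the returned study.
#'
#' @param study A [genotype_study()].
#' @return The study with no missing genotypes.
#' @export
impute_missing <- function(study) {
  g <- study$genotypes
  n_imp <- integer(ncol(g))
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (!any(miss)) next
    cnt <- tabulate(g[!miss, j] + 1L, 3L)
    if (sum(cnt) == 0L)
      stop("SNP '", colnames(g)[j], "' has no observed genotypes",
           call. = FALSE)
    mode_code <- which.max(cnt) - 1L   # which.max takes the lower tie
    g[miss, j] <- mode_code
    n_imp[j] <- sum(miss)
  }
  study$genotypes <- g
  attr(study, "imputed") <- stats::setNames(n_imp, colnames(g))
  study
}

# cell index 1..3^k for the loci columns (first locus varies slowest)
cell_index <- function(g, loci) {
  k <- length(loci)
  cell <- rep(0L, nrow(g))
  for (i in seq_len(k)) cell <- cell * 3L + g[, loci[i]]
  cell + 1L
}

#' Label multilocus genotype cells by case:control ratio
#'
#' The MDR reduction step: with `T` the overall case:control ratio, a
#' non-empty cell is `high_risk` when its own case:control ratio is at
#' least `T` (a cell with cases but no controls is high-risk); cells
#' with no subjects are `empty`.
#'
#' @param study An imputed [genotype_study()].
#' @param loci Character vector of 2 or 3 SNP identifiers.
#' @return A list with `cell_labels` (length `3^k`, values
#'   `high_risk`/`low_risk`/`empty`), `threshold_T`, and the per-cell
#'   `case_counts` and `control_counts`.
#' @export
label_cells <- function(study, loci) {
  k <- length(loci)
  if (!k %in% 2:3) stop("k must be 2 or 3", call. = FALSE)
  check_two_groups(study)
  if (anyNA(study$genotypes[, loci]))
    stop("impute missing genotypes before MDR labelling", call. = FALSE)
  cells <- cell_index(study$genotypes, loci)
  is_case <- study$phenotype == "case"
  ncells <- 3L^k
  case_counts <- tabulate(cells[is_case], ncells)
  ctrl_counts <- tabulate(cells[!is_case], ncells)
  threshold <- sum(is_case) / sum(!is_case)
  labels <- cell_labels_from_counts(case_counts, ctrl_counts, threshold)
  list(cell_labels = labels, threshold_T = threshold,
       case_counts = case_counts, control_counts = ctrl_counts,
       loci = loci)
}

cell_labels_from_counts <- function(case_counts, ctrl_counts, threshold) {
  total <- case_counts + ctrl_counts
  labels <- rep("low_risk", length(total))
  high <- (ctrl_counts == 0L & case_counts > 0L) |
    (ctrl_counts > 0L & case_counts / ctrl_counts >= threshold)
  labels[high] <- "high_risk"
  labels[total == 0L] <- "empty"
  labels
}

#' Balanced accuracy of an MDR cell labelling
#'
#' Classifies each evaluation subject by their cell's label (high-risk
#' cells predict case, low-risk predict control); subjects falling in
#' cells labelled `empty` are excluded from the evaluation. Returns
#' `(sensitivity + specificity) / 2`.
#'
#' @param cell_labels Labels from [label_cells()].
#' @param cells Per-subject cell index (from the same locus order).
#' @param is_case Logical per-subject case indicator.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(cell_labels, cells, is_case) {
  lab <- cell_labels[cells]
  eval_ok <- lab != "empty"
  if (!any(eval_ok)) stop("no evaluable subjects", call. = FALSE)
  pred_case <- lab == "high_risk"
  n_case <- sum(is_case & eval_ok)
  n_ctrl <- sum(!is_case & eval_ok)
  if (n_case == 0L || n_ctrl == 0L)
    stop("evaluation set lacks one phenotype class", call. = FALSE)
  sens <- sum(pred_case & is_case & eval_ok) / n_case
  spec <- sum(!pred_case & !is_case & eval_ok) / n_ctrl
  (sens + spec) / 2
}

# ---- internal exhaustive CV engine ---------------------------------------

# Precompute, per chunk of k-subsets, the flattened cell/subject vectors
# used by the fold loop, so a permutation rerun costs one tabulate() per
# fold. combos: k x P matrix of column indices into g.
build_mdr_chunks <- function(g, combos, ncells, fold_of, n_folds,
                             chunk_size = 5000L) {
  P <- ncol(combos)
  starts <- seq(1L, P, by = chunk_size)
  lapply(starts, function(s) {
    idx <- s:min(s + chunk_size - 1L, P)
    Pc <- length(idx)
    cellmat <- matrix(0L, nrow(g), Pc)
    for (jj in seq_along(idx))
      cellmat[, jj] <- cell_index(g, combos[, idx[jj]])
    offs <- rep.int((seq_len(Pc) - 1L) * ncells, rep(nrow(g), Pc))
    v_all <- as.vector(cellmat) + offs
    r_all <- rep.int(seq_len(nrow(g)), Pc)
    folds <- lapply(seq_len(n_folds), function(f) {
      tr <- fold_of[r_all] != f
      list(tr_v = v_all[tr], tr_r = r_all[tr],
           tot_tr = tabulate(v_all[tr], ncells * Pc))
    })
    list(idx = idx, Pc = Pc, cellmat = cellmat, folds = folds)
  })
}

# One CV evaluation (observed or permuted phenotype). Returns per-fold
# winner combo id and its training/testing balanced accuracy.
mdr_cv_eval <- function(chunks, is_case, fold_of, n_folds, ncells,
                        threshold_by_fold) {
  win_id <- integer(n_folds)
  win_train <- numeric(n_folds)
  win_test <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    best_ba <- -Inf; best_global <- NA_integer_
    best_chunk <- NULL; best_col <- NA_integer_
    for (ch in chunks) {
      fd <- ch$folds[[f]]
      caseC <- tabulate(fd$tr_v[is_case[fd$tr_r]], ncells * ch$Pc)
      ctrlC <- fd$tot_tr - caseC
      Cm <- matrix(caseC, ncells, ch$Pc)
      Dm <- matrix(ctrlC, ncells, ch$Pc)
      high <- (Dm == 0 & Cm > 0) | (Dm > 0 & Cm / pmax(Dm, 1L) >=
                                      threshold_by_fold[f] & Dm > 0)
      sens <- colSums(Cm * high) / colSums(Cm)
      spec <- colSums(Dm * !high) / colSums(Dm)
      ba <- (sens + spec) / 2
      j <- which.max(ba)
      if (length(j) && ba[j] > best_ba) {
        best_ba <- ba[j]
        best_global <- ch$idx[j]
        best_chunk <- ch
        best_col <- j
      }
    }
    win_id[f] <- best_global
    win_train[f] <- best_ba
    # test BA for the winner only
    te <- fold_of == f
    cells_w <- best_chunk$cellmat[, best_col]
    caseTr <- tabulate(cells_w[!te & is_case], ncells)
    ctrlTr <- tabulate(cells_w[!te & !is_case], ncells)
    labs <- cell_labels_from_counts(caseTr, ctrlTr, threshold_by_fold[f])
    win_test[f] <- tryCatch(
      balanced_accuracy(labs, cells_w[te], is_case[te]),
      error = function(e) NA_real_)
  }
  list(win_id = win_id, win_train = win_train, win_test = win_test)
}

# Aggregate fold winners into a ranked model table; the permutation
# statistic is the top model's mean testing balanced accuracy.
rank_fold_winners <- function(ev) {
  ids <- unique(ev$win_id)
  cvc <- vapply(ids, function(i) sum(ev$win_id == i), integer(1))
  mtr <- vapply(ids, function(i) mean(ev$win_train[ev$win_id == i]),
                numeric(1))
  mte <- vapply(ids, function(i)
    mean(ev$win_test[ev$win_id == i], na.rm = TRUE), numeric(1))
  ord <- order(-cvc, -mte, ids)
  list(ids = ids[ord], cvc = cvc[ord], mean_train = mtr[ord],
       mean_test = mte[ord])
}

#' Exhaustive multifactor dimensionality reduction with cross-validation
#'
#' Runs the classical MDR search: for each of `n_folds` stratified CV
#' folds, every k-subset of the candidate SNPs is reduced to a
#' high/low-risk attribute on the training portion and the fold winner
#' is the subset with the best training balanced accuracy. Models are
#' ranked by cross-validation consistency (number of folds selecting the
#' same locus set), ties broken by mean testing balanced accuracy.
#' Significance of the top model's mean testing balanced accuracy comes
#' from full phenotype-permutation reruns of the whole search.
#'
#' @param study An imputed [genotype_study()] (see [impute_missing()]).
#' @param k Model order, 2 or 3.
#' @param n_folds Cross-validation folds (default 10).
#' @param n_perm Phenotype permutations for the significance test
#'   (default 1000; 0 skips the test).
#' @param seed Integer seed (fold assignment and permutations).
#' @param candidate_loci Optional SNP identifiers restricting the search.
#' @param min_cvc,min_train_ba Reporting thresholds: models are flagged
#'   `reported` when `cvc >= min_cvc` (default 2) and mean training
#'   balanced accuracy exceeds `min_train_ba` (default 0.5).
#' @param max_k3_panel Refuse exhaustive 3-locus search above this many
#'   SNPs (default 150); supply `candidate_loci` instead.
#' @return An object of class `mdr_fit`: `models` (ranked data.frame),
#'   `best` (full-data refit of the top model: cell labels, threshold,
#'   distilled high-risk [genotype_combination()], odds ratio), and
#'   `p_perm`.
#' @export
run_mdr <- function(study, k = 2, n_folds = 10, n_perm = 1000, seed = 1L,
                    candidate_loci = NULL, min_cvc = 2,
                    min_train_ba = 0.5, max_k3_panel = 150L) {
  if (!k %in% 2:3) stop("k must be 2 or 3", call. = FALSE)
  check_two_groups(study)
  if (anyNA(study$genotypes))
    stop("impute missing genotypes first (impute_missing)", call. = FALSE)
  snps <- if (is.null(candidate_loci)) study$snp_ids else {
    miss <- setdiff(candidate_loci, study$snp_ids)
    if (length(miss)) stop("unknown candidate loci: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    candidate_loci
  }
  m <- length(snps)
  if (m < k) stop("fewer SNPs than k", call. = FALSE)
  if (k == 3 && m > max_k3_panel)
    stop("exhaustive 3-locus search over ", m, " SNPs is not desk-",
         "tractable; restrict with candidate_loci or a pathway subset",
         call. = FALSE)
  n <- nrow(study$genotypes)
  ncells <- 3L^k
  if (n < 5L * ncells)
    warning("sparse design: ", n, " subjects for ", ncells,
            " genotype cells; testing accuracies will be unstable")

  set.seed(as.integer(seed))
  is_case <- study$phenotype == "case"
  fold_of <- integer(n)
  for (grp in list(which(is_case), which(!is_case))) {
    shuffled <- grp[sample.int(length(grp))]
    fold_of[shuffled] <- rep_len(seq_len(n_folds), length(shuffled))
  }
  threshold_by_fold <- vapply(seq_len(n_folds), function(f)
    sum(is_case & fold_of != f) / sum(!is_case & fold_of != f), numeric(1))

  cols <- match(snps, study$snp_ids)
  combos <- utils::combn(cols, k)
  chunks <- build_mdr_chunks(study$genotypes, combos, ncells, fold_of,
                             n_folds)
  ev <- mdr_cv_eval(chunks, is_case, fold_of, n_folds, ncells,
                    threshold_by_fold)
  ranked <- rank_fold_winners(ev)
  combo_names <- function(id)
    paste(study$snp_ids[combos[, id]], collapse = "/")
  models <- data.frame(
    loci = vapply(ranked$ids, combo_names, ""),
    cvc = ranked$cvc,
    mean_train_ba = ranked$mean_train,
    mean_test_ba = ranked$mean_test,
    stringsAsFactors = FALSE)
  models$reported <- models$cvc >= min_cvc &
    models$mean_train_ba > min_train_ba
  obs_stat <- ranked$mean_test[1L]

  p_perm <- NA_real_
  if (n_perm > 0) {
    b <- 0L
    for (r in seq_len(n_perm)) {
      perm_case <- is_case[sample.int(n)]
      thr <- vapply(seq_len(n_folds), function(f)
        sum(perm_case & fold_of != f) / sum(!perm_case & fold_of != f),
        numeric(1))
      ev_p <- mdr_cv_eval(chunks, perm_case, fold_of, n_folds, ncells, thr)
      if (rank_fold_winners(ev_p)$mean_test[1L] >= obs_stat - 1e-12)
        b <- b + 1L
    }
    p_perm <- (b + 1) / (n_perm + 1)
  }

  best_loci <- study$snp_ids[combos[, ranked$ids[1L]]]
  full <- label_cells(study, best_loci)
  full_cells <- cell_index(study$genotypes, best_loci)
  best <- list(
    loci = best_loci,
    cell_labels = full$cell_labels,
    threshold_T = full$threshold_T,
    case_counts = full$case_counts,
    control_counts = full$control_counts,
    train_ba = balanced_accuracy(full$cell_labels, full_cells, is_case),
    combination = distill_combination(best_loci, full$cell_labels, k))
  best$odds_ratio <- tryCatch(
    combination_odds_ratio(study, best$combination),
    error = function(e) NULL)

  structure(list(models = models, best = best, p_perm = p_perm, k = k,
                 n_folds = n_folds, n_perm = n_perm, seed = seed,
                 n_snps = m, n_subjects = n),
            class = "mdr_fit")
}

# Compact the high-risk cells into a genotype_combination: when the
# high-risk set is the Cartesian product of per-locus code sets, emit
# per-locus carrier-style conditions; otherwise keep the explicit cells.
distill_combination <- function(loci, cell_labels, k) {
  high <- which(cell_labels == "high_risk")
  if (!length(high)) return(NULL)
  # cell_index makes the first locus vary slowest: decode accordingly
  decode <- matrix(0L, length(high), k)
  rest <- high - 1L
  for (i in k:1) {
    decode[, i] <- rest %% 3L
    rest <- rest %/% 3L
  }
  sets <- lapply(seq_len(k), function(i) sort(unique(decode[, i])))
  n_product <- prod(lengths(sets))
  if (n_product == length(high))
    genotype_combination(loci, conditions = sets)
  else
    genotype_combination(loci, cells = lapply(seq_len(nrow(decode)),
                                              function(r) decode[r, ]))
}

#' @export
print.mdr_fit <- function(x, ...) {
  cat("mdr_fit: exhaustive ", x$k, "-locus MDR over ", x$n_snps,
      " SNPs, ", x$n_folds, "-fold CV\n", sep = "")
  cat("best model:", paste(x$best$loci, collapse = "/"),
      sprintf("(CVC %d/%d, test BA %.3f)", x$models$cvc[1L], x$n_folds,
              x$models$mean_test_ba[1L]), "\n")
  if (!is.na(x$p_perm))
    cat(sprintf("permutation p (mean test BA, %d perms): %.4g\n",
                x$n_perm, x$p_perm))
  if (!is.null(x$best$combination))
    cat("high-risk combination:", x$best$combination$label, "\n")
  invisible(x)
}

#' @export
summary.mdr_fit <- function(object, ...) {
  cat("ranked models (fold winners):\n")
  print(object$models, digits = 4)
  cat(sprintf("\noverall case:control threshold T = %.3f\n",
              object$best$threshold_T))
  or <- object$best$odds_ratio
  if (!is.null(or))
    cat(sprintf("high-risk carrier OR %.2f (95%% CI %.2f-%.2f)\n",
                or$or, or$ci[1L], or$ci[2L]))
  invisible(object)
}

#' Predict risk class from a fitted MDR model
#'
#' @param object An `mdr_fit`.
#' @param newdata A [genotype_study()] containing the model's loci
#'   (imputed).
#' @param ... Unused.
#' @return Factor of `high_risk`/`low_risk` per subject (`NA` for cells
#'   empty at fit time).
#' @export
predict.mdr_fit <- function(object, newdata, ...) {
  cells <- cell_index(newdata$genotypes, object$best$loci)
  lab <- object$best$cell_labels[cells]
  lab[lab == "empty"] <- NA
  factor(lab, levels = c("low_risk", "high_risk"))
}

#' Entropy-based interaction graph statistics
#'
#' For a set of loci, expresses each SNP's main effect and each pair's
#' interaction information as percentages of the phenotype entropy (the
#' MDR interaction-graph convention: positive pairwise values mark
#' synergy, negative values redundancy), and builds an average-linkage
#' dendrogram on the distance `max(syn) - syn`.
#'
#' @param study An imputed [genotype_study()].
#' @param loci Two or more SNP identifiers.
#' @param base Logarithm base (default 2).
#' @return An object of class `entropy_graph` with `main_effect_pct`,
#'   `pairwise_pct` (data.frame snp1/snp2/pct) and `dendrogram` (an
#'   `hclust`).
#' @export
entropy_graph <- function(study, loci, base = 2) {
  if (length(loci) < 2L) stop("need at least two loci", call. = FALSE)
  check_two_groups(study)
  is_case <- study$phenotype == "case"
  h_ph <- entropy(c(sum(is_case), sum(!is_case)), base = base)
  g <- study$genotypes
  main <- vapply(loci, function(s)
    100 * information_gain(g[, s], study$phenotype, base = base) / h_ph,
    numeric(1))
  prs <- t(utils::combn(length(loci), 2L))
  pct <- syn_bits <- numeric(nrow(prs))
  for (i in seq_len(nrow(prs))) {
    d <- synergy(g[, loci[prs[i, 1L]]], g[, loci[prs[i, 2L]]],
                 study$phenotype, base = base, min_n = 2)
    syn_bits[i] <- d$syn
    pct[i] <- 100 * d$syn / h_ph
  }
  dmat <- matrix(0, length(loci), length(loci),
                 dimnames = list(loci, loci))
  dval <- max(syn_bits) - syn_bits
  for (i in seq_len(nrow(prs))) {
    dmat[prs[i, 1L], prs[i, 2L]] <- dval[i]
    dmat[prs[i, 2L], prs[i, 1L]] <- dval[i]
  }
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  structure(list(main_effect_pct = main,
                 pairwise_pct = data.frame(
                   snp1 = loci[prs[, 1L]], snp2 = loci[prs[, 2L]],
                   pct = pct, syn_bits = syn_bits,
                   stringsAsFactors = FALSE),
                 dendrogram = hc, h_phenotype = h_ph),
            class = "entropy_graph")
}

#' @export
print.entropy_graph <- function(x, ...) {
  cat("entropy_graph over", length(x$main_effect_pct), "loci\n")
  cat("main effects (% of phenotype entropy):\n")
  print(round(x$main_effect_pct, 3))
  cat("pairwise interaction information (% of phenotype entropy):\n")
  print(x$pairwise_pct[order(-x$pairwise_pct$pct), c(1, 2, 3)],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.entropy_graph <- function(x, ...) {
  plot(x$dendrogram, main = "MDR interaction dendrogram",
       xlab = "", sub = "", ...)
  invisible(x)
}

#' Export an interaction dendrogram as Newick
#'
#' @param graph An `entropy_graph`.
#' @param path Output path.
#' @export
write_dendrogram <- function(graph, path) {
  ape::write.tree(ape::as.phylo(graph$dendrogram), file = path)
  invisible(path)
}

#' Carrier odds ratio of a genotype combination
#'
#' Cross-product odds ratio of the carrier/noncarrier by case/control
#' 2x2 table (identical to the univariate logistic-regression estimate
#' for a binary carrier covariate), with the Woolf log-scale 95%
#' confidence interval. Zero cells receive the Haldane 0.5 continuity
#' correction, with a warning.
#'
#' @param study A [genotype_study()].
#' @param combination A [genotype_combination()].
#' @return List with `or`, `ci` (length-2), the 2x2 `table`, and
#'   `n_excluded` (undecidable subjects).
#' @export
combination_odds_ratio <- function(study, combination) {
  carrier <- matches_combination(study, combination)
  ok <- !is.na(carrier)
  if (!any(ok)) stop("combination undecidable for every subject",
                     call. = FALSE)
  is_case <- study$phenotype == "case"
  a <- sum(carrier[ok] & is_case[ok])      # carrier cases
  b <- sum(carrier[ok] & !is_case[ok])     # carrier controls
  cc <- sum(!carrier[ok] & is_case[ok])
  d <- sum(!carrier[ok] & !is_case[ok])
  tab <- matrix(c(a, b, cc, d), 2, 2,
                dimnames = list(c("carrier", "noncarrier"),
                                c("case", "control")))
  if (any(tab == 0)) {
    warning("zero cell in carrier table; Haldane 0.5 correction applied")
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(or = or, ci = ci, table = tab, n_excluded = sum(!ok))
}
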