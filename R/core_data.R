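#' episyn: pathway-based SNP-SNP interaction analysis
#'
#' Detects epistatic interactions between SNPs in candidate-gene
#' case-control panels (long-lived cases vs middle-aged controls) and
#' follows candidate genotype combinations into survival in the case
#' cohort. The pipeline stages are marker QC ([apply_marker_qc()]), an
#' information-theoretic synergy screen ([screen_pairs()]), multifactor
#' dimensionality reduction ([run_mdr()]), and sex-stratified survival
#' follow-up ([survival_screen()]); [simulate_study()] generates
#' pathway-structured synthetic studies for testing and power work, and
#' [run_pipeline()] composes the stages end to end.
#'
#' @keywords internal
#' @aliases episyn-package
"_PACKAGE"

# Tokens treated as missing genotypes on input. The internal sentinel is
# NA_integer_, never 0: mapping missing to 0 would silently inflate
# reference homozygotes.
MISSING_TOKENS <- c("NA", "", "-9", ".")

DEFAULT_PATHWAYS <- c("IIS", "pro_antioxidant", "DNA_repair")

#' Construct a case-control genotype study
#'
#' The container consumed by every pipeline stage: a subjects-by-SNPs
#' matrix of minor-allele counts (0/1/2, `NA` = missing) plus per-subject
#' phenotype, sex, and optional follow-up fields for the case group.
#'
#' @param genotypes Integer matrix, subjects in rows, SNPs in columns;
#'   values in `{0, 1, 2, NA}`. Column names are the SNP identifiers.
#' @param phenotype Character/factor vector, one of `"case"` (long-lived)
#'   or `"control"` per subject.
#' @param subject_ids Unique subject identifiers; defaults to rownames of
#'   `genotypes` or `S1..Sn`.
#' @param sex Per-subject `"male"`, `"female"` or `"unknown"`.
#' @param months Optional non-negative follow-up months (cases; `NA`
#'   elsewhere).
#' @param event Optional event indicator (1 = death observed,
#'   0 = censored); must be present exactly when `months` is.
#' @return An object of class `genotype_study`.
#' @export
genotype_study <- function(genotypes, phenotype, subject_ids = NULL,
                           sex = NULL, months = NULL, event = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(genotypes)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n))
  }
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) {
    dup <- subject_ids[duplicated(subject_ids)][1L]
    stop("duplicate subject id: '", dup, "'", call. = FALSE)
  }
  if (length(phenotype) != n)
    stop("phenotype length does not match number of subjects", call. = FALSE)
  phenotype <- as.character(phenotype)
  bad_ph <- setdiff(unique(phenotype), c("case", "control"))
  if (length(bad_ph))
    stop("phenotype labels must be 'case'/'control'; found: ",
         paste(bad_ph, collapse = ", "), call. = FALSE)
  if (is.null(sex)) sex <- rep("unknown", n)
  sex <- as.character(sex)
  sex[is.na(sex)] <- "unknown"
  bad_sex <- setdiff(unique(sex), c("male", "female", "unknown"))
  if (length(bad_sex))
    stop("sex labels must be male/female/unknown; found: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  if (xor(is.null(months), is.null(event)))
    stop("survival months and event indicator must be supplied together",
         call. = FALSE)
  if (!is.null(months)) {
    months <- as.numeric(months)
    event <- as.integer(event)
    if (any(months < 0, na.rm = TRUE))
      stop("negative follow-up months", call. = FALSE)
    if (any(is.na(months) != is.na(event)))
      stop("months and event must share a missingness pattern", call. = FALSE)
    if (any(!(event[!is.na(event)] %in% c(0L, 1L))))
      stop("event indicator must be 0 (censored) or 1 (death)", call. = FALSE)
  }
  bad <- which(!(genotypes %in% c(0L, 1L, 2L)) & !is.na(genotypes))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(genotypes))
    stop("genotype value out of range at subject '", subject_ids[rc[1L]],
         "', SNP '", colnames(genotypes)[rc[2L]], "': ",
         genotypes[bad[1L]], call. = FALSE)
  }
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  rownames(genotypes) <- subject_ids
  structure(list(genotypes = genotypes,
                 subject_ids = subject_ids,
                 snp_ids = colnames(genotypes),
                 phenotype = phenotype,
                 sex = sex,
                 months = months,
                 event = event),
            class = "genotype_study")
}

#' @export
print.genotype_study <- function(x, ...) {
  n_case <- sum(x$phenotype == "case")
  cat("genotype_study: ", length(x$subject_ids), " subjects (",
      n_case, " cases, ", length(x$subject_ids) - n_case, " controls), ",
      length(x$snp_ids), " SNPs\n", sep = "")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotypes: %.2f%%", 100 * miss))
  if (!is.null(x$months))
    cat("; survival follow-up on ", sum(!is.na(x$months)), " subjects",
        sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.genotype_study <- function(x) dim(x$genotypes)

n_cases <- function(study) sum(study$phenotype == "case")
n_controls <- function(study) sum(study$phenotype == "control")

check_two_groups <- function(study) {
  if (n_cases(study) < 1L || n_controls(study) < 1L)
    stop("association analysis needs at least one case and one control",
         call. = FALSE)
  invisible(TRUE)
}

parse_genotype_tokens <- function(values, snp, ids) {
  values <- trimws(as.character(values))
  values[values %in% MISSING_TOKENS] <- NA_character_
  out <- suppressWarnings(as.integer(values))
  bad <- which((!is.na(values) & is.na(out)) |
                 (!is.na(out) & !(out %in% 0:2)))
  if (length(bad))
    stop("invalid genotype '", values[bad[1L]], "' for subject '",
         ids[bad[1L]], "', SNP '", snp, "'", call. = FALSE)
  out
}

#' Read a genotype table
#'
#' Reads a case-control genotype matrix in one of two plain-text
#' dialects. `"tsv"` expects a header
#' `subject_id phenotype sex months event <snp> ...` with phenotype
#' coded `case`/`control`; `"plink_raw"` expects the PLINK `.raw`
#' additive layout `FID IID PAT MAT SEX PHENOTYPE <snp>_<allele> ...`
#' with phenotype 1 = control, 2 = case and sex 1 = male, 2 = female.
#' Genotypes are minor-allele counts; the tokens `NA`, `""`, `-9` and
#' `.` are read as missing.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @return A [genotype_study()].
#' @export
read_genotype_table <- function(path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  if (dialect == "tsv") {
    need <- c("subject_id", "phenotype", "sex", "months", "event")
    if (!all(need %in% names(tab)))
      stop("tsv dialect requires columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    snp_cols <- setdiff(names(tab), need)
    ids <- tab$subject_id
    phen <- tab$phenotype
    sex <- tab$sex
    months <- suppressWarnings(as.numeric(
      replace(tab$months, tab$months %in% MISSING_TOKENS, NA)))
    event <- suppressWarnings(as.integer(
      replace(tab$event, tab$event %in% MISSING_TOKENS, NA)))
  } else {
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% names(tab)))
      stop("plink_raw dialect requires columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    snp_cols <- setdiff(names(tab), need)
    ids <- tab$IID
    ph_code <- tab$PHENOTYPE
    bad <- setdiff(unique(ph_code), c("1", "2"))
    if (length(bad))
      stop("plink_raw phenotype must be 1 (control) or 2 (case); found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    phen <- ifelse(ph_code == "2", "case", "control")
    sex <- c("1" = "male", "2" = "female")[tab$SEX]
    sex[is.na(sex)] <- "unknown"
    months <- NULL
    event <- NULL
    # strip the _<counted allele> suffix PLINK appends to marker names
    snp_ids <- sub("_[ACGT]$", "", snp_cols)
  }
  if (!length(snp_cols)) stop("no SNP columns found", call. = FALSE)
  if (length(unique(phen)) < 2L)
    stop("file contains a single phenotype group; need cases and controls",
         call. = FALSE)
  geno <- matrix(NA_integer_, nrow(tab), length(snp_cols))
  for (j in seq_along(snp_cols))
    geno[, j] <- parse_genotype_tokens(tab[[snp_cols[j]]], snp_cols[j], ids)
  colnames(geno) <- if (dialect == "plink_raw") snp_ids else snp_cols
  if (dialect == "plink_raw")
    genotype_study(geno, phen, subject_ids = ids, sex = sex)
  else
    genotype_study(geno, phen, subject_ids = ids, sex = sex,
                   months = months, event = event)
}

#' Write a genotype study to a plain-text table
#'
#' Inverse of [read_genotype_table()]; round-trips the matrix, the
#' phenotype and the missingness pattern exactly in either dialect.
#'
#' @param study A [genotype_study()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"plink_raw"` (the latter drops survival
#'   columns, which the format has no slot for).
#' @export
write_genotype_table <- function(study, path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  g <- study$genotypes
  if (dialect == "tsv") {
    months <- if (is.null(study$months)) rep(NA_real_, nrow(g)) else study$months
    event <- if (is.null(study$event)) rep(NA_integer_, nrow(g)) else study$event
    out <- data.frame(subject_id = study$subject_ids,
                      phenotype = study$phenotype,
                      sex = study$sex,
                      months = months, event = event,
                      check.names = FALSE, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(g, check.names = FALSE))
  } else {
    out <- data.frame(FID = study$subject_ids, IID = study$subject_ids,
                      PAT = 0L, MAT = 0L,
                      SEX = c(male = 1L, female = 2L, unknown = 0L)[study$sex],
                      PHENOTYPE = ifelse(study$phenotype == "case", 2L, 1L),
                      check.names = FALSE, stringsAsFactors = FALSE)
    gg <- g
    colnames(gg) <- paste0(colnames(g), "_A")
    out <- cbind(out, as.data.frame(gg, check.names = FALSE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a SNP annotation table
#'
#' Expects a TSV with columns `snp_id`, `gene`, `pathway`, `chromosome`,
#' `position` (1-based). Pathway labels are validated against the
#' declared set.
#'
#' @param path Path to the annotation TSV.
#' @param pathways Allowed pathway labels.
#' @return A data.frame of class `snp_annotation`.
#' @export
read_annotation <- function(path, pathways = DEFAULT_PATHWAYS) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    warning("empty annotation file: ", path)
    return(snp_annotation(character(), character(), character(),
                          character(), integer(), pathways = pathways))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "")
  need <- c("snp_id", "gene", "pathway", "chromosome", "position")
  if (!all(need %in% names(tab)))
    stop("annotation requires columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  snp_annotation(tab$snp_id, tab$gene, tab$pathway, tab$chromosome,
                 as.integer(tab$position), pathways = pathways)
}

#' Construct a validated SNP annotation table
#'
#' @param snp_id,gene,pathway,chromosome,position Per-SNP columns.
#' @param pathways Allowed pathway labels.
#' @return A data.frame of class `snp_annotation`.
#' @export
snp_annotation <- function(snp_id, gene, pathway, chromosome, position,
                           pathways = DEFAULT_PATHWAYS) {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id))
    stop("duplicate snp_id in annotation: '",
         snp_id[duplicated(snp_id)][1L], "'", call. = FALSE)
  pathway <- as.character(pathway)
  bad <- setdiff(unique(pathway), pathways)
  if (length(bad))
    stop("unknown pathway label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(pathways, collapse = ", "), call. = FALSE)
  position <- as.integer(position)
  if (any(!is.na(position) & position < 1L))
    stop("positions are 1-based and must be >= 1", call. = FALSE)
  ann <- data.frame(snp_id = snp_id, gene = as.character(gene),
                    pathway = pathway, chromosome = as.character(chromosome),
                    position = position, stringsAsFactors = FALSE)
  attr(ann, "pathways") <- pathways
  class(ann) <- c("snp_annotation", "data.frame")
  ann
}

#' Restrict a study to SNPs annotated to given pathways
#'
#' @param study A [genotype_study()].
#' @param ann A [snp_annotation()] table.
#' @param pathways Pathway labels to keep.
#' @return A [genotype_study()] with the same subjects and only the
#'   annotated SNPs (original column order preserved).
#' @export
subset_by_pathway <- function(study, ann, pathways) {
  allowed <- attr(ann, "pathways")
  if (is.null(allowed)) allowed <- unique(ann$pathway)
  bad <- setdiff(pathways, allowed)
  if (length(bad))
    stop("pathway(s) not in declared set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  keep_snps <- ann$snp_id[ann$pathway %in% pathways]
  keep <- study$snp_ids %in% keep_snps
  if (!any(keep))
    stop("no SNPs left after pathway restriction", call. = FALSE)
  subset_snps(study, study$snp_ids[keep])
}

# Internal: keep named SNP columns (order of `snps` as given).
subset_snps <- function(study, snps) {
  stopifnot(all(snps %in% study$snp_ids))
  study$genotypes <- study$genotypes[, snps, drop = FALSE]
  study$snp_ids <- snps
  study
}

# Internal: keep a subject subset (logical or index).
subset_subjects <- function(study, idx) {
  study$genotypes <- study$genotypes[idx, , drop = FALSE]
  study$subject_ids <- study$subject_ids[idx]
  study$phenotype <- study$phenotype[idx]
  study$sex <- study$sex[idx]
  if (!is.null(study$months)) {
    study$months <- study$months[idx]
    study$event <- study$event[idx]
  }
  study
}

#' Describe a multilocus genotype condition
#'
#' A genotype combination is a conjunction of per-SNP conditions, each an
#' allowed set of minor-allele counts: an exact genotype (`2` for minor
#' homozygote), or a carrier condition (`c(1, 2)` = at least one minor
#' allele; `c(0, 1)` = at least one major allele). A subject matches when
#' every locus condition holds; subjects missing any involved genotype
#' are undecidable.
#'
#' @param snp_ids SNP identifiers, one per locus (no repeats).
#' @param conditions List of integer vectors of allowed codes, parallel
#'   to `snp_ids`. Ignored when `cells` is given.
#' @param label Human-readable label, e.g. `"rs1-GG/rs2-G carriers"`.
#' @param cells Optional explicit list of matching multilocus genotypes
#'   (each an integer vector parallel to `snp_ids`), for risk sets that
#'   are not a per-locus product.
#' @return An object of class `genotype_combination`.
#' @export
genotype_combination <- function(snp_ids, conditions = NULL, label = NULL,
                                 cells = NULL) {
  snp_ids <- as.character(snp_ids)
  if (!length(snp_ids)) stop("combination needs at least one locus",
                             call. = FALSE)
  if (anyDuplicated(snp_ids))
    stop("each snp_id may appear once in a combination", call. = FALSE)
  if (is.null(conditions) && is.null(cells))
    stop("supply per-locus conditions or an explicit cell list",
         call. = FALSE)
  if (!is.null(cells)) {
    cells <- lapply(cells, function(cc) {
      cc <- as.integer(cc)
      if (length(cc) != length(snp_ids) || any(!cc %in% 0:2))
        stop("each cell must give one genotype code per locus",
             call. = FALSE)
      cc
    })
    conditions <- NULL
  } else {
    conditions <- lapply(conditions, function(cc) {
      cc <- sort(unique(as.integer(cc)))
      if (!length(cc) || any(!cc %in% 0:2))
        stop("conditions are non-empty subsets of {0,1,2}", call. = FALSE)
      cc
    })
    if (length(conditions) != length(snp_ids))
      stop("one condition per locus required", call. = FALSE)
  }
  if (is.null(label)) {
    if (is.null(conditions)) {
      label <- paste0(paste(snp_ids, collapse = "/"), " cells {",
                      paste(vapply(cells, paste, "", collapse = ""),
                            collapse = ","), "}")
    } else {
      label <- paste(paste0(snp_ids, "-",
                            vapply(conditions, condition_word, "")),
                     collapse = "/")
    }
  }
  structure(list(snp_ids = snp_ids, conditions = conditions,
                 cells = cells, label = label),
            class = "genotype_combination")
}

# name a per-locus allowed-code set in carrier vocabulary
condition_word <- function(cc) {
  key <- paste(cc, collapse = "")
  switch(key,
         "0" = "hom-major", "1" = "het", "2" = "hom-minor",
         "01" = "major-carrier", "12" = "minor-carrier",
         "02" = "hom", "012" = "any", paste0("{", key, "}"))
}

#' @export
print.genotype_combination <- function(x, ...) {
  cat("genotype_combination:", x$label, "\n")
  invisible(x)
}

# Internal: per-subject match of a combination. TRUE/FALSE, NA when any
# involved genotype is missing.
matches_combination <- function(study, combination) {
  miss <- setdiff(combination$snp_ids, study$snp_ids)
  if (length(miss))
    stop("combination refers to SNPs absent from the study: ",
         paste(miss, collapse = ", "), call. = FALSE)
  gm <- study$genotypes[, combination$snp_ids, drop = FALSE]
  undecidable <- rowSums(is.na(gm)) > 0L
  if (is.null(combination$conditions)) {
    key <- apply(gm, 1L, paste, collapse = ",")
    allowed <- vapply(combination$cells, paste, "", collapse = ",")
    ok <- key %in% allowed
  } else {
    ok <- rep(TRUE, nrow(gm))
    for (i in seq_along(combination$snp_ids))
      ok <- ok & (gm[, i] %in% combination$conditions[[i]])
  }
  ok[undecidable] <- NA
  ok
}
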