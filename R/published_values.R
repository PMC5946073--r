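#' Published synergy decompositions for worked-example checks
#'
#' Loads the bundled table of top-ranked SNP-pair synergy decompositions
#' (Syn, I, I1, I2 with gene/pathway labels) reported by a published
#' candidate-gene study of human longevity in Danish nonagenarians.
#' These rows serve as worked examples of the additive decomposition
#' `Syn = I - I1 - I2`; the underlying genotypes are not public, so the
#' values check the identity, not the estimator.
#'
#' @return Data.frame with columns `syn`, `i`, `i1`, `i2` and pair
#'   labels.
#' @export
published_synergy_rows <- function() {
  path <- system.file("extdata", "published_synergy_rows.tsv",
                      package = "episyn", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
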