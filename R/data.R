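#' Published Uyghur 26-locus allele frequencies
#'
#' Per-locus allele frequency tables for a published sample of 100
#' unrelated Uyghur males typed at 26 Y-STR loci, shipped as plain-text
#' package data (`inst/extdata/uyghur26y_frequencies.csv`). Counts were
#' reconstructed from the printed 4-decimal frequencies: 100 allele copies
#' at ordinary loci, 101 at DYS19 and DYS449 (one duplication carrier
#' each), 186 at the multi-copy DYS385ab (100 males minus anomalies, two
#' copies each). Null allele classes at DYS448 and DYS643 are retained as
#' the `"null"` key. `n_samples` is 100 throughout, which is the n entering
#' the gene-diversity formula.
#'
#' @return named list of `freq_table`, one per locus.
#' @examples
#' ft <- uyghur26y_frequencies()
#' round(gene_diversity(ft$DYS388), 4)  # 0.3665
#' @export
uyghur26y_frequencies <- function() {
  path <- system.file("extdata", "uyghur26y_frequencies.csv",
                      package = "ystrkit", mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "numeric", "integer"))
  out <- lapply(split(df, factor(df$locus, levels = unique(df$locus))),
                function(d) {
    frequency_table(d$locus[1], stats::setNames(d$count, d$allele),
                    n_samples = 100L)
  })
  out
}
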