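#' Reference read counts at E. coli RNase III cleavage sites
#'
#' A small built-in table of per-site read counts from a wild-type vs
#' rnc-deletion comparison in E. coli (genome NC_000913.3): genomic
#' location, site name, raw mutant read count, the raw wild-type counts in
#' replicates A and B (positions with zero reads appear as the 0.01
#' pseudocount, as conventionally reported), and the integer-rounded
#' mutant/WT ratios for both replicates. Known processing sites and
#' newly identified candidate sites are distinguished by `site_class`.
#'
#' Used to validate the package's pseudocounted ratio arithmetic and
#' display rounding against an independent reference.
#'
#' @return A data frame with columns `location`, `site_name`,
#'   `ratio1_printed`, `ratio2_printed`, `wt_reads_a`, `wt_reads_b`,
#'   `mutant_reads`, `site_class`.
#' @examples
#' head(reference_site_counts())
#' @export
reference_site_counts <- function() {
  path <- system.file("extdata", "ecoli_rnc_site_readcounts.tsv",
                      package = "cleaverate", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
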