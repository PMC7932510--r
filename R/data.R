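# Bundled reference data accessors.

#' Reference hit list of SIH-associated DGRP loci
#'
#' The curated list of 23 SNPs/indels significantly associated with
#' starvation-induced hyperactivity across DGRP lines (nominal
#' P < 1e-5), with minor/major/reference alleles, minor-allele frequency,
#' minor-allele effect size, association p-value, nominated gene and site
#' class. Used for desk-scale checks of the significance filter and the
#' grouped site-class distribution.
#'
#' @return Data frame with one row per locus; `chrom`, `pos` and `type`
#'   are parsed from the `variant_id` (`chrom_pos_type`).
#' @export
dgrp_sih_hits <- function() {
  path <- system.file("extdata", "dgrp_sih_hits.tsv", package = "flysih")
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(maf = "numeric",
                                        effect = "numeric",
                                        p_value = "numeric"))
  parts <- strsplit(d$variant_id, "_", fixed = TRUE)
  d$chrom <- vapply(parts, `[`, "", 1L)
  d$pos <- as.integer(vapply(parts, `[`, "", 2L))
  d$type <- vapply(parts, `[`, "", 3L)
  d
}
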