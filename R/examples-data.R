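#' Curated examples of trait-associated SNPs in the miRNA regulome
#'
#' A small literature-reported reference set of trait-associated SNPs
#' in the miRNA regulome whose LD blocks lack competing nonsynonymous or
#' transcriptional annotations: one pre-miRNA TAS, three miRNA-promoter
#' TASs and six 3'-UTR target-site TASs, with the super-population the
#' GWAS cohort was matched to and the minor allele frequency (percent)
#' in that population.
#'
#' @return data.frame with columns `trait`, `snp`, `maf_percent`,
#'   `population`, `mirna`, `element`, `gene`.
#' @export
selected_tas_examples <- function() {
  path <- system.file("extdata", "selected_tas.tsv", package = "mirtas",
                      mustWork = TRUE)
  read_tsv(path, na.strings = "NA")
}
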