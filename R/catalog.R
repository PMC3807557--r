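## GWAS-catalog ingestion: p-value and multi-SNP haplotype filters.

#' Default GWAS catalog column mapping
#'
#' Column names follow the NHGRI catalog export; override any entry to
#' adapt to other dialects.
#' @export
catalog_columns <- function(snp = "SNPS", p = "P-VALUE",
                            trait = "DISEASE/TRAIT", pubmed = "PUBMEDID",
                            ancestry = "INITIAL SAMPLE SIZE") {
  c(snp = snp, p = p, trait = trait, pubmed = pubmed, ancestry = ancestry)
}

#' Parse a GWAS-catalog-style association table
#'
#' Reads a TSV of reported associations and applies two filters: the
#' association p-value must be strictly below `p_threshold`, and the SNP
#' field must name exactly one rsID (rows encoding multi-SNP haplotypes,
#' i.e. more than one rsID token, are dropped, as are rows with no rsID).
#' Malformed p-values are tolerated (they parse to NA and fail the strict
#' threshold). Drop counts are logged to stderr.
#'
#' @param path path to a tab-delimited association table with a header.
#' @param p_threshold keep rows with p strictly below this (default 1e-5).
#' @param columns named mapping from roles to column names; see
#'   [catalog_columns()].
#' @return data.frame with columns `index_snp`, `trait`, `ancestry_text`,
#'   `p_value`, `pubmed_id`, `source_row`, one row per retained
#'   association.
#' @export
parse_catalog <- function(path, p_threshold = 1e-5,
                          columns = catalog_columns()) {
  if (!file.exists(path)) config_error("catalog file not found: %s", path)
  raw <- read_tsv(path)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols)) {
    config_error("catalog is missing required column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  snp_field <- as.character(raw[[columns[["snp"]]]])
  pvals <- suppressWarnings(as.numeric(raw[[columns[["p"]]]]))

  rs_tokens <- regmatches(snp_field, gregexpr("rs[0-9]+", snp_field))
  n_rs <- lengths(rs_tokens)
  multi <- n_rs > 1L
  no_snp <- n_rs == 0L
  fails_p <- is.na(pvals) | pvals >= p_threshold

  keep <- !multi & !no_snp & !fails_p
  log_msg("catalog %s: %d rows; dropped %d multi-SNP haplotype, %d without an rsID, %d with p >= %.3g or unparsable; kept %d",
          basename(path), nrow(raw), sum(multi), sum(no_snp & !multi),
          sum(fails_p & !multi & !no_snp), p_threshold, sum(keep))

  data.frame(
    index_snp = vapply(rs_tokens[keep], `[[`, character(1), 1L),
    trait = as.character(raw[[columns[["trait"]]]])[keep],
    ancestry_text = as.character(raw[[columns[["ancestry"]]]])[keep],
    p_value = pvals[keep],
    pubmed_id = as.character(raw[[columns[["pubmed"]]]])[keep],
    source_row = which(keep),
    stringsAsFactors = FALSE
  )
}
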