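## Competing-annotation flags per LD block and tier assignment for
## TAS x element records.

#' Default per-element disqualification policy
#'
#' Pre-miRNA and promoter TASs are top-tier only when their LD block
#' contains no known exonic variant; 3'-UTR target-site TASs are
#' top-tier only when the block contains neither a nonsynonymous nor a
#' transcriptional-regulatory SNP. eQTL hits annotate but never
#' disqualify.
#'
#' @return named list: element kind -> character vector of disqualifying
#'   flag names.
#' @export
default_tier_policy <- function() {
  list(pre_mirna = "has_exonic",
       promoter = "has_exonic",
       utr3 = c("has_nonsynonymous", "has_transcriptional"))
}

#' Annotate an LD block with competing functional explanations
#'
#' Each flag is TRUE iff any block member hits the respective annotation
#' set: positional overlap for interval sets (exons), rsID membership
#' for SNP lists (nonsynonymous, transcriptional/RegulomeDB-style,
#' eQTL). `tarbase_support` lists validated (miRNA, gene) pairs that
#' match a predicted target-site pair in the block.
#'
#' @param block an `ld_block`.
#' @param exons GRanges of coding exons (may be empty/NULL).
#' @param nonsyn_ids character vector of nonsynonymous SNP rsIDs.
#' @param transcriptional_ids character vector of transcriptional SNP
#'   rsIDs.
#' @param eqtl_ids character vector of eQTL rsIDs.
#' @param tarbase data.frame of validated pairs (`mirna`, `gene`), may
#'   have zero rows.
#' @param predicted_pairs data.frame (`mirna`, `gene`) of target-site
#'   predictions attributed to this block's SNPs.
#' @param strong_ld r-squared above which a member counts as very strong
#'   LD (default 0.9, strict inequality).
#' @return object of class `block_annotation`: flags, strong-LD members
#'   (r2 > `strong_ld` or the index SNP), and supported pairs.
#' @export
annotate_block <- function(block, exons = NULL,
                           nonsyn_ids = character(0),
                           transcriptional_ids = character(0),
                           eqtl_ids = character(0),
                           tarbase = NULL, predicted_pairs = NULL,
                           strong_ld = 0.9) {
  m <- block$members
  has_exonic <- FALSE
  if (!is.null(exons) && length(exons) && nrow(m)) {
    snp_gr <- GenomicRanges::GRanges(
      seqnames = m$chrom, ranges = IRanges::IRanges(start = m$pos, width = 1L))
    has_exonic <- length(suppressWarnings(GenomicRanges::findOverlaps(
      snp_gr, exons, ignore.strand = TRUE))) > 0L
  }
  tarbase_support <- data.frame(mirna = character(0), gene = character(0),
                                stringsAsFactors = FALSE)
  if (!is.null(tarbase) && nrow(tarbase) && !is.null(predicted_pairs) &&
      nrow(predicted_pairs)) {
    pk <- unique(paste(predicted_pairs$mirna, predicted_pairs$gene,
                       sep = "\t"))
    tk <- paste(tarbase$mirna, tarbase$gene, sep = "\t")
    tarbase_support <- unique(tarbase[tk %in% pk, c("mirna", "gene"),
                                      drop = FALSE])
    rownames(tarbase_support) <- NULL
  }
  structure(list(
    index_snp = block$index_snp,
    has_exonic = has_exonic,
    has_nonsynonymous = any(m$snp %in% nonsyn_ids),
    has_transcriptional = any(m$snp %in% transcriptional_ids),
    has_eqtl = any(m$snp %in% eqtl_ids),
    tarbase_support = tarbase_support,
    strong_ld_members = m$snp[m$r2 > strong_ld | m$snp == block$index_snp]
  ), class = "block_annotation")
}

#' Assign a priority tier to a TAS x element record
#'
#' `top` if none of the disqualifying flags configured for the record's
#' element kind is set on its block annotation; otherwise `supported` if
#' the block carries validated miRNA:gene support or the record's SNP is
#' in very strong LD with the index SNP (r2 > 0.9) or is the index SNP
#' itself; otherwise `other`. Adding annotations can only demote a
#' record, never promote it.
#'
#' @param record one-row data.frame (or list) with at least `snp` and
#'   `kind`.
#' @param annotation a `block_annotation` for the record's LD block.
#' @param policy per-element disqualifying flags; see
#'   [default_tier_policy()].
#' @return the record with `tier` plus the annotation flags appended.
#' @export
assign_tier <- function(record, annotation, policy = default_tier_policy()) {
  kind <- as.character(record$kind)
  if (!kind %in% names(policy)) {
    config_error("no tier policy for element kind '%s'", kind)
  }
  flags <- c(has_exonic = annotation$has_exonic,
             has_nonsynonymous = annotation$has_nonsynonymous,
             has_transcriptional = annotation$has_transcriptional,
             has_eqtl = annotation$has_eqtl)
  disq <- policy[[kind]]
  bad <- setdiff(disq, names(flags))
  if (length(bad)) {
    config_error("unknown disqualifying flag(s) in policy: %s",
                 paste(bad, collapse = ", "))
  }
  tier <- if (!any(flags[disq])) {
    "top"
  } else if (nrow(annotation$tarbase_support) > 0L ||
             record$snp %in% annotation$strong_ld_members) {
    "supported"
  } else {
    "other"
  }
  out <- as.data.frame(record, stringsAsFactors = FALSE)
  out$has_exonic <- flags[["has_exonic"]]
  out$has_nonsynonymous <- flags[["has_nonsynonymous"]]
  out$has_transcriptional <- flags[["has_transcriptional"]]
  out$has_eqtl <- flags[["has_eqtl"]]
  out$tier <- tier
  out
}

#' Prioritize a TAS x element table against block annotations
#'
#' Applies [assign_tier()] row-wise using each record's index SNP to
#' locate its block annotation.
#'
#' @param tas_elements table from [intersect_tas()].
#' @param annotations named list (index_snp -> `block_annotation`).
#' @param policy see [default_tier_policy()].
#' @return the table with flags and `tier` columns appended.
#' @export
prioritize_table <- function(tas_elements, annotations,
                             policy = default_tier_policy()) {
  if (nrow(tas_elements) == 0L) {
    out <- tas_elements
    out$has_exonic <- logical(0); out$has_nonsynonymous <- logical(0)
    out$has_transcriptional <- logical(0); out$has_eqtl <- logical(0)
    out$tier <- character(0)
    return(out)
  }
  rows <- lapply(seq_len(nrow(tas_elements)), function(i) {
    rec <- tas_elements[i, , drop = FALSE]
    ann <- annotations[[rec$index_snp]]
    if (is.null(ann)) {
      config_error("no block annotation for index SNP '%s'", rec$index_snp)
    }
    assign_tier(rec, ann, policy)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a nonsynonymous SNP list from a dbSNP-style VCF
#'
#' Returns the rsIDs of records passing an optional INFO-flag predicate
#' (e.g. keep records whose INFO contains `NSM`/`NSN`); by default every
#' record's id is returned (assume upstream filtering).
#'
#' @param path VCF path.
#' @param info_flag optional INFO key; records lacking it are skipped.
#' @return character vector of rsIDs.
#' @export
read_nonsyn_vcf <- function(path, info_flag = NULL) {
  if (!file.exists(path)) config_error("nonsynonymous VCF not found: %s", path)
  vcf <- VariantAnnotation::readVcf(path)
  ids <- names(SummarizedExperiment::rowRanges(vcf))
  if (!is.null(info_flag)) {
    info <- VariantAnnotation::info(vcf)
    if (!info_flag %in% names(info)) {
      config_error("INFO field '%s' absent from %s", info_flag, path)
    }
    keep <- info[[info_flag]]
    if (is.logical(keep)) ids <- ids[keep %in% TRUE]
  }
  ids
}

#' Read a single-column rsID set from a TSV
#'
#' For RegulomeDB-style transcriptional SNP lists and eQTL lists: the
#' column named `snp` (or the first column) is taken as the rsID set;
#' other columns are ignored for tiering.
#'
#' @param path TSV path.
#' @return character vector of rsIDs.
#' @export
read_snp_set <- function(path) {
  if (!file.exists(path)) config_error("SNP set file not found: %s", path)
  df <- read_tsv(path)
  col <- if ("snp" %in% names(df)) "snp" else names(df)[1L]
  unique(as.character(df[[col]]))
}

#' Read validated miRNA:gene pairs (TarBase dialect)
#'
#' @param path TSV with columns `mirna` and `gene`.
#' @return data.frame with `mirna`, `gene`.
#' @export
read_tarbase <- function(path) {
  if (!file.exists(path)) config_error("TarBase file not found: %s", path)
  df <- read_tsv(path)
  if (!all(c("mirna", "gene") %in% names(df))) {
    config_error("TarBase table must have columns: mirna, gene")
  }
  df[, c("mirna", "gene")]
}
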