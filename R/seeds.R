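## Seed-based miRNA target-site prediction (7mer-1a, 7mer-m8, 8mer-1a)
## and alignment-free cross-species conservation numbering.

#' Site types in order of increasing efficacy
#' @export
SITE_TYPES <- c("7mer-1a", "7mer-m8", "8mer-1a")

#' mRNA-sense seed-match patterns of a miRNA
#'
#' Derives the three canonical seed-site patterns from a mature miRNA
#' sequence (5'->3'). With positions numbered from the miRNA 5' end:
#' the 7mer-m8 pattern is the reverse complement of positions 2-8, the
#' 8mer-1a pattern is that 7mer followed by an A (opposite position 1),
#' and the 7mer-1a pattern is the reverse complement of positions 2-7
#' followed by an A. Patterns are returned in the RNA alphabet on the
#' mRNA sense strand, 5'->3'.
#'
#' @param mature_sequence mature miRNA sequence, length >= 8, over
#'   \{A,C,G,U/T\} (U and T equivalent).
#' @return named character vector with elements `8mer-1a`, `7mer-m8`,
#'   `7mer-1a`.
#' @examples
#' seed_patterns("UGAGGUAGUAGGUUGUAUAGUU")  # let-7a
#' @export
seed_patterns <- function(mature_sequence) {
  s <- normalize_rna(mature_sequence)
  if (nchar(s) < 8L) {
    data_error("mature miRNA sequence must be at least 8 nt (got %d)",
               nchar(s))
  }
  core7 <- substr(s, 2L, 8L)
  core6 <- substr(s, 2L, 7L)
  m8 <- revcomp_rna(core7)
  c(`8mer-1a` = paste0(m8, "A"),
    `7mer-m8` = m8,
    `7mer-1a` = paste0(revcomp_rna(core6), "A"))
}

## All (possibly overlapping) exact occurrences of `pattern` in the
## normalized RNA string `subject`; returns 0-based start offsets.
## Biostrings::matchPattern reports overlapping occurrences; N in the
## subject never matches (fixed matching).
.match_starts0 <- function(pattern, subject_rna) {
  if (nchar(subject_rna) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::RNAString(pattern),
                                Biostrings::RNAString(subject_rna),
                                fixed = TRUE)
  BiocGenerics::start(m) - 1L
}

#' Predict seed-match target sites in a 3'-UTR sequence
#'
#' Scans a UTR (sense strand, 5'->3') for exact occurrences of each
#' miRNA's seed patterns. Overlapping matches for the same miRNA at the
#' same seed location are collapsed to the single strongest type
#' (8mer-1a > 7mer-m8 > 7mer-1a): an 8mer-1a at offset i implies, and
#' suppresses, the 7mer-m8 at i and the 7mer-1a at i+1. Offsets are
#' 0-based on the UTR sense strand; `N` never matches.
#'
#' @param utr_sequence UTR sequence over \{A,C,G,T,U,N\}; DNA and RNA
#'   alphabets give identical predictions.
#' @param mirnas data.frame with columns `name` and `mature_sequence`.
#' @param gene_symbol optional gene label carried into the result.
#' @return data.frame with columns `mirna`, `gene_symbol`, `utr_offset`
#'   (0-based), `site_type`, `site_length` (7 or 8), sorted by
#'   (mirna, utr_offset).
#' @export
find_sites <- function(utr_sequence, mirnas, gene_symbol = NA_character_) {
  stopifnot(is.data.frame(mirnas),
            all(c("name", "mature_sequence") %in% names(mirnas)))
  utr <- normalize_rna(utr_sequence)
  out <- vector("list", nrow(mirnas))
  for (i in seq_len(nrow(mirnas))) {
    pats <- seed_patterns(mirnas$mature_sequence[i])
    s8 <- .match_starts0(pats[["8mer-1a"]], utr)
    s7m8 <- setdiff(.match_starts0(pats[["7mer-m8"]], utr), s8)
    s7a1 <- .match_starts0(pats[["7mer-1a"]], utr)
    s7a1 <- s7a1[!(s7a1 - 1L) %in% s8]
    offs <- c(s8, s7m8, s7a1)
    if (!length(offs)) next
    types <- c(rep("8mer-1a", length(s8)), rep("7mer-m8", length(s7m8)),
               rep("7mer-1a", length(s7a1)))
    out[[i]] <- data.frame(
      mirna = mirnas$name[i], gene_symbol = gene_symbol,
      utr_offset = offs, site_type = types,
      site_length = ifelse(types == "8mer-1a", 8L, 7L),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(mirna = character(0), gene_symbol = character(0),
                      utr_offset = integer(0), site_type = character(0),
                      site_length = integer(0), stringsAsFactors = FALSE)
  }
  res <- res[order(res$mirna, res$utr_offset, res$site_type), ]
  rownames(res) <- NULL
  res
}

#' Cross-species conservation number of predicted sites
#'
#' For each predicted human site, counts the species among
#' \{mouse, rat, dog, chicken\} whose orthologous UTR contains a site of
#' the same type for the same miRNA anywhere in the sequence
#' (alignment-free presence), and adds 1 for human. A missing ortholog
#' UTR counts as absent. Range 1-5; 1 means human-only.
#'
#' @param sites data.frame from [find_sites()] on the human UTR.
#' @param ortholog_utrs named list (species -> UTR sequence) for any of
#'   mouse, rat, dog, chicken; missing entries count as absent.
#' @param mirnas data.frame with `name`, `mature_sequence` (must cover
#'   the miRNAs in `sites`).
#' @return `sites` with an added integer column `conservation`.
#' @export
annotate_conservation <- function(sites, ortholog_utrs, mirnas) {
  if (nrow(sites) == 0L) {
    sites$conservation <- integer(0)
    return(sites)
  }
  species <- intersect(names(ortholog_utrs),
                       c("mouse", "rat", "dog", "chicken"))
  ## per species: set of "mirna\ttype" present anywhere in the ortholog UTR
  present <- lapply(species, function(sp) {
    os <- find_sites(ortholog_utrs[[sp]],
                     mirnas[mirnas$name %in% unique(sites$mirna), ,
                            drop = FALSE])
    unique(paste(os$mirna, os$site_type, sep = "\t"))
  })
  key <- paste(sites$mirna, sites$site_type, sep = "\t")
  cons <- rep(1L, nrow(sites))
  for (p in present) cons <- cons + as.integer(key %in% p)
  sites$conservation <- cons
  sites
}

#' Conservation number of a single site
#'
#' Convenience scalar wrapper around [annotate_conservation()].
#'
#' @param mirna miRNA name.
#' @param site_type one of `r toString(SITE_TYPES)`.
#' @param ortholog_utrs named list species -> sequence.
#' @param mirnas miRNA table covering `mirna`.
#' @return integer in 1..5.
#' @export
conservation_number <- function(mirna, site_type, ortholog_utrs, mirnas) {
  fake <- data.frame(mirna = mirna, gene_symbol = NA_character_,
                     utr_offset = 0L, site_type = site_type,
                     site_length = 7L, stringsAsFactors = FALSE)
  annotate_conservation(fake, ortholog_utrs, mirnas)$conservation
}
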