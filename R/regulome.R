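## miRNA regulome element sets: precursor GFF3, promoter/exon BED,
## 3'-UTR tables with genomic mappings, UTR admission filters, and
## TAS x element intersection.

ELEMENT_KINDS <- c("pre_mirna", "promoter", "utr3")

#' Read miRNA precursor intervals from a miRBase-dialect GFF3
#'
#' Keeps `miRNA_primary_transcript` features and labels each with the
#' miRNA name (the `Name` attribute, falling back to `ID`).
#'
#' @param path GFF3 path.
#' @param source dataset label carried into the elements.
#' @return GRanges with metadata columns `kind` ("pre_mirna"), `owner`,
#'   `source`.
#' @export
read_mirna_gff <- function(path, source = basename(path)) {
  if (!file.exists(path)) config_error("miRNA GFF3 not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "miRNA_primary_transcript"]
  owner <- as.character(gr$Name)
  if (!length(owner) || all(is.na(owner))) owner <- as.character(gr$ID)
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    kind = "pre_mirna", owner = owner, source = source)
  out
}

#' Read BED6 intervals as regulome or annotation elements
#'
#' @param path BED path (0-based half-open starts, per BED).
#' @param kind element kind label (e.g. "promoter"); for plain
#'   annotation intervals (exons) the kind is carried but unused.
#' @param source dataset label.
#' @return GRanges with metadata columns `kind`, `owner` (BED name
#'   field), `source`.
#' @export
read_bed_elements <- function(path, kind, source = basename(path)) {
  if (!file.exists(path)) config_error("BED file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bed")
  owner <- if (!is.null(gr$name)) as.character(gr$name) else
    rep(NA_character_, length(gr))
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    kind = kind, owner = owner, source = source)
  out
}

#' Read mature miRNA sequences from FASTA
#'
#' @param path FASTA of mature miRNA sequences (RNA or DNA alphabet).
#' @return data.frame with columns `name`, `mature_sequence` (RNA
#'   alphabet).
#' @export
read_mirna_fasta <- function(path) {
  if (!file.exists(path)) config_error("miRNA FASTA not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  data.frame(
    name = sub("\\s.*$", "", names(ss)),
    mature_sequence = normalize_rna(as.character(ss)),
    stringsAsFactors = FALSE
  )
}

#' Read a 3'-UTR sequence table
#'
#' Tab-delimited dialect mirroring a TargetScan UTR download: columns
#' `id` (RefSeq-style identifier), `species` (human, mouse, rat, dog,
#' chicken) and `sequence`. An optional two-column lookup table converts
#' RefSeq-style ids to official gene symbols; unmapped ids keep the
#' original id with a warning.
#'
#' @param path UTR table TSV.
#' @param symbol_map optional data.frame with columns `id`, `symbol`,
#'   or a path to such a TSV.
#' @return data.frame with columns `id`, `gene_symbol`, `species`,
#'   `sequence`.
#' @export
read_utr_table <- function(path, symbol_map = NULL) {
  if (!file.exists(path)) config_error("UTR table not found: %s", path)
  df <- read_tsv(path)
  need <- c("id", "species", "sequence")
  if (!all(need %in% names(df))) {
    config_error("UTR table must have columns: %s",
                 paste(need, collapse = ", "))
  }
  bad_sp <- setdiff(unique(df$species),
                    c("human", "mouse", "rat", "dog", "chicken"))
  if (length(bad_sp)) {
    data_error("unknown species tag(s) in UTR table: %s",
               paste(bad_sp, collapse = ", "))
  }
  gene_symbol <- df$id
  if (!is.null(symbol_map)) {
    if (is.character(symbol_map)) symbol_map <- read_tsv(symbol_map)
    m <- match(df$id, symbol_map$id)
    unmapped <- unique(df$id[is.na(m)])
    if (length(unmapped)) {
      warning(length(unmapped),
              " UTR id(s) missing from the symbol map keep their RefSeq-style id: ",
              paste(utils::head(unmapped, 5L), collapse = ", "))
    }
    gene_symbol <- ifelse(is.na(m), df$id, symbol_map$symbol[m])
  }
  data.frame(id = df$id, gene_symbol = gene_symbol, species = df$species,
             sequence = toupper(df$sequence), stringsAsFactors = FALSE)
}

#' Read candidate genomic mappings of human UTRs
#'
#' TSV with one row per aligned segment: columns `id`, `mapping`
#' (candidate-mapping index within the id), `chrom`, `strand`, `start`,
#' `end` (1-based closed). A mapping with more than one segment row is a
#' spliced alignment.
#'
#' @param path mappings TSV.
#' @return data.frame as described.
#' @export
read_utr_mappings <- function(path) {
  if (!file.exists(path)) config_error("UTR mappings file not found: %s", path)
  df <- read_tsv(path)
  need <- c("id", "mapping", "chrom", "strand", "start", "end")
  if (!all(need %in% names(df))) {
    config_error("UTR mappings must have columns: %s",
                 paste(need, collapse = ", "))
  }
  df
}

#' Apply the UTR admission filters
#'
#' A human UTR record is admitted only if it is at least 20 nt long and
#' has exactly one perfect, unspliced (single-segment) genomic mapping.
#' Rejection reasons, checked in this order, are: `multi_mapped` (more
#' than one candidate mapping), `spliced` (any candidate mapping with
#' more than one aligned segment), `too_short` (sequence < 20 nt),
#' `unmapped` (no candidate mapping). Admitted and rejected records
#' partition the input.
#'
#' @param utrs human UTR records (data.frame with `id`, `gene_symbol`,
#'   `sequence`).
#' @param mappings candidate mappings from [read_utr_mappings()].
#' @return list with `admitted` (UTR rows plus `chrom`, `start`, `end`,
#'   `strand` of the unique mapping) and `rejected` (UTR rows plus
#'   `reason`).
#' @export
filter_utr_mappings <- function(utrs, mappings) {
  reasons <- character(nrow(utrs))
  adm <- vector("list", nrow(utrs))
  for (i in seq_len(nrow(utrs))) {
    m <- mappings[mappings$id == utrs$id[i], , drop = FALSE]
    n_map <- length(unique(m$mapping))
    segs_per_map <- if (n_map) table(m$mapping) else integer(0)
    if (n_map > 1L) {
      reasons[i] <- "multi_mapped"
    } else if (n_map == 1L && any(segs_per_map > 1L)) {
      reasons[i] <- "spliced"
    } else if (nchar(utrs$sequence[i]) < 20L) {
      reasons[i] <- "too_short"
    } else if (n_map == 0L) {
      reasons[i] <- "unmapped"
    } else {
      adm[[i]] <- m[1L, c("chrom", "start", "end", "strand")]
    }
  }
  keep <- reasons == ""
  admitted <- utrs[keep, , drop = FALSE]
  if (nrow(admitted)) {
    admitted <- cbind(admitted, do.call(rbind, adm[keep]))
  } else {
    admitted <- cbind(admitted,
                      data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0), strand = character(0)))
  }
  rejected <- utrs[!keep, , drop = FALSE]
  rejected$reason <- reasons[!keep]
  rownames(admitted) <- rownames(rejected) <- NULL
  list(admitted = admitted, rejected = rejected)
}

#' Exact-match mapper for synthetic genomes
#'
#' Stand-in for a genome aligner at fixture scale: reports every exact
#' occurrence of the sequence on either strand of the genome, each as a
#' single-segment candidate mapping. Not suitable for real genomes.
#'
#' @param sequence query sequence (DNA alphabet).
#' @param genome a named `DNAStringSet` (or FASTA path).
#' @return data.frame with columns `mapping`, `chrom`, `strand`, `start`,
#'   `end` (1-based closed); zero rows if absent.
#' @export
naive_map_utr <- function(sequence, genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  query <- Biostrings::DNAString(chartr("Uu", "Tt", sequence))
  hits <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    fwd <- Biostrings::matchPattern(query, subj, fixed = TRUE)
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(query),
                                    subj, fixed = TRUE)
    if (length(fwd)) {
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, strand = "+",
        start = BiocGenerics::start(fwd), end = BiocGenerics::end(fwd),
        stringsAsFactors = FALSE)
    }
    if (length(rev)) {
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, strand = "-",
        start = BiocGenerics::start(rev), end = BiocGenerics::end(rev),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  out <- cbind(mapping = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Assemble admitted UTRs into regulome elements
#'
#' @param admitted_utrs `admitted` table from [filter_utr_mappings()].
#' @param source dataset label.
#' @return GRanges with `kind` = "utr3", `owner` = gene symbol.
#' @export
utr_elements <- function(admitted_utrs, source = "utr_table") {
  if (nrow(admitted_utrs) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      kind = character(0), owner = character(0), source = character(0))
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = admitted_utrs$chrom,
    ranges = IRanges::IRanges(start = admitted_utrs$start,
                              end = admitted_utrs$end),
    strand = admitted_utrs$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = "utr3", owner = admitted_utrs$gene_symbol, source = source)
  gr
}

#' Intersect TAS LD blocks with regulome elements
#'
#' Emits one row for every (block member SNP, element) pair where the SNP
#' position falls inside the element interval. A SNP overlapping elements
#' of several kinds yields one row per element. Output is stable-sorted
#' by (chrom, pos, kind, owner). A chromosome naming mismatch between
#' SNPs and elements triggers a warning with per-chromosome counts.
#'
#' @param blocks list of `ld_block` objects (or a flattened table from
#'   [ld_blocks_table()]).
#' @param elements GRanges with metadata `kind`, `owner`, `source`
#'   (concatenate precursor, promoter and UTR elements).
#' @return data.frame: tas columns (snp, index_snp, trait, population,
#'   chrom, pos, r2, minor_allele, maf) plus element columns (kind,
#'   owner, element_start, element_end, element_strand, source).
#' @export
intersect_tas <- function(blocks, elements) {
  tas <- if (is.data.frame(blocks)) blocks else ld_blocks_table(blocks)
  empty <- data.frame(snp = character(0), index_snp = character(0),
                      trait = character(0), population = character(0),
                      chrom = character(0), pos = integer(0),
                      r2 = numeric(0), minor_allele = character(0),
                      maf = numeric(0), kind = character(0),
                      owner = character(0), element_start = integer(0),
                      element_end = integer(0),
                      element_strand = character(0), source = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(tas) == 0L || length(elements) == 0L) return(empty)
  shared <- intersect(unique(tas$chrom),
                      as.character(GenomicRanges::seqnames(elements)))
  if (length(shared) == 0L) {
    tas_counts <- table(tas$chrom)
    el_counts <- table(as.character(GenomicRanges::seqnames(elements)))
    warning("no chromosome shared between SNPs (",
            paste(sprintf("%s:%d", names(tas_counts), as.integer(tas_counts)),
                  collapse = ", "),
            ") and elements (",
            paste(sprintf("%s:%d", names(el_counts), as.integer(el_counts)),
                  collapse = ", "), ")")
    return(empty)
  }
  snp_gr <- GenomicRanges::GRanges(
    seqnames = tas$chrom,
    ranges = IRanges::IRanges(start = tas$pos, width = 1L))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(
    snp_gr, elements, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  out <- cbind(
    tas[qi, c("member_snp", "index_snp", "trait", "population", "chrom",
              "pos", "r2", "minor_allele", "maf"), drop = FALSE],
    data.frame(
      kind = elements$kind[si], owner = elements$owner[si],
      element_start = BiocGenerics::start(elements)[si],
      element_end = BiocGenerics::end(elements)[si],
      element_strand = as.character(GenomicRanges::strand(elements))[si],
      source = elements$source[si], stringsAsFactors = FALSE)
  )
  names(out)[names(out) == "member_snp"] <- "snp"
  out <- out[order(out$chrom, out$pos, out$kind, out$owner, out$snp), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
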