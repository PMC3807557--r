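## Allelic-complement UTR sequences: SNP clustering, haplotype
## enumeration, and created/abolished site calls.

#' Cluster UTR SNPs by transitive proximity
#'
#' SNPs are chained into one cluster whenever two positions are within
#' `max_gap` nt of each other (transitively), so that allele combinations
#' of SNPs that can co-occupy one seed-site span are enumerated jointly.
#'
#' @param positions integer vector of SNP positions (1-based within the
#'   UTR).
#' @param max_gap chaining distance in nt (default 7, the widest 7mer
#'   span).
#' @return integer vector of cluster ids (1, 2, ...) parallel to
#'   `positions`, in increasing position order of cluster founders.
#' @export
cluster_snps <- function(positions, max_gap = 7L) {
  if (!length(positions)) return(integer(0))
  ord <- order(positions)
  p <- positions[ord]
  cl <- integer(length(p))
  cl[1L] <- 1L
  for (i in seq_along(p)[-1L]) {
    cl[i] <- if (p[i] - p[i - 1L] <= max_gap) cl[i - 1L] else cl[i - 1L] + 1L
  }
  out <- integer(length(p))
  out[ord] <- cl
  out
}

#' Enumerate alternate (allelic-complement) UTR sequences
#'
#' Groups the supplied bi-allelic SNPs into proximity clusters
#' ([cluster_snps()]); each cluster of size k yields all 2^k - 1
#' non-reference allele combinations (e.g. two A/T SNPs in one cluster
#' yield the AT, TA and TT haplotypes). Clusters vary independently:
#' while one cluster is enumerated, every other position carries the
#' reference allele. Alleles must already be on the transcript sense
#' strand (see [map_snps_to_utr()] for genomic VCF input).
#'
#' @param utr_sequence reference UTR sequence (sense strand).
#' @param snps data.frame with columns `id`, `utr_pos` (1-based position
#'   within the UTR), `ref`, `alt` (single bases, sense strand).
#' @param max_cluster cluster size cap (default 10, i.e. at most 1,023
#'   combinations); larger clusters raise a data error.
#' @return data.frame with one row per alternate sequence: `label`
#'   (e.g. "rs1:A>U+rs2:G>C"), `cluster`, `snps` (comma-joined rsIDs set
#'   to their alternate allele), `sequence`. Sequences are in the RNA
#'   alphabet and have the same length as the reference.
#' @export
enumerate_alternate_sequences <- function(utr_sequence, snps,
                                          max_cluster = 10L) {
  ref <- normalize_rna(utr_sequence)
  if (nrow(snps) == 0L) {
    return(data.frame(label = character(0), cluster = integer(0),
                      snps = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("id", "utr_pos", "ref", "alt") %in% names(snps)))
  if (any(snps$utr_pos < 1L | snps$utr_pos > nchar(ref))) {
    data_error("SNP position outside the UTR: %s",
               paste(snps$id[snps$utr_pos < 1L | snps$utr_pos > nchar(ref)],
                     collapse = ", "))
  }
  ref_allele <- normalize_rna(snps$ref)
  alt_allele <- normalize_rna(snps$alt)
  have <- substring(ref, snps$utr_pos, snps$utr_pos)
  bad <- have != ref_allele
  if (any(bad)) {
    data_error("reference allele mismatch at SNP %s (UTR has %s, SNP says %s)",
               snps$id[bad][1L], have[bad][1L], ref_allele[bad][1L])
  }
  cl <- cluster_snps(snps$utr_pos)
  chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  out <- list()
  for (c_id in sort(unique(cl))) {
    idx <- which(cl == c_id)
    k <- length(idx)
    if (k > max_cluster) {
      data_error("SNP cluster of size %d exceeds the cap of %d (SNPs: %s)",
                 k, max_cluster, paste(snps$id[idx], collapse = ", "))
    }
    for (mask in seq_len(2^k - 1L)) {
      on <- idx[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
      seq_chars <- chars
      seq_chars[snps$utr_pos[on]] <- alt_allele[on]
      out[[length(out) + 1L]] <- data.frame(
        label = paste(sprintf("%s:%s>%s", snps$id[on], ref_allele[on],
                              alt_allele[on]), collapse = "+"),
        cluster = c_id,
        snps = paste(snps$id[on], collapse = ","),
        sequence = paste(seq_chars, collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map genomic SNPs onto UTR (transcript sense-strand) coordinates
#'
#' Converts VCF-style genomic SNVs to 1-based positions within a UTR
#' given its genomic mapping; for minus-strand genes the position is
#' flipped and the alleles are complemented, so that substitutions are
#' always performed on the sense-strand sequence.
#'
#' @param snps data.frame with `chrom`, `pos` (1-based genomic), `id`,
#'   `ref`, `alt`.
#' @param mapping list or one-row data.frame with `chrom`, `start`, `end`
#'   (1-based closed genomic interval), `strand` ("+" or "-").
#' @return data.frame with columns `id`, `utr_pos`, `ref`, `alt`
#'   restricted to SNPs inside the mapping.
#' @export
map_snps_to_utr <- function(snps, mapping) {
  keep <- snps$chrom == mapping$chrom &
    snps$pos >= mapping$start & snps$pos <= mapping$end
  s <- snps[keep, , drop = FALSE]
  if (identical(mapping$strand, "-")) {
    data.frame(id = s$id,
               utr_pos = mapping$end - s$pos + 1L,
               ref = comp_dna(s$ref), alt = comp_dna(s$alt),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = s$id,
               utr_pos = s$pos - mapping$start + 1L,
               ref = s$ref, alt = s$alt, stringsAsFactors = FALSE)
  }
}

#' Created/abolished sites between reference and alternate predictions
#'
#' Site identity is (miRNA, offset, type), offsets in reference
#' coordinates (alternates never change length; bi-allelic SNVs only).
#' A site present only in the alternate context is `created`; present
#' only in the reference, `abolished`. A type change at one location is
#' reported as one abolished plus one created. A site identical in both
#' contexts never appears.
#'
#' @param reference_sites,alternate_sites data.frames from
#'   [find_sites()] over the same UTR and miRNA set.
#' @param haplotype_label label of the alternate haplotype.
#' @param snps comma-joined rsIDs producing the alternate.
#' @return data.frame with `direction` (created/abolished), the site
#'   columns, `haplotype` and `snps`.
#' @export
diff_sites <- function(reference_sites, alternate_sites,
                       haplotype_label = NA_character_,
                       snps = NA_character_) {
  key <- function(s) paste(s$mirna, s$utr_offset, s$site_type, sep = "\r")
  rk <- key(reference_sites); ak <- key(alternate_sites)
  created <- alternate_sites[!ak %in% rk, , drop = FALSE]
  abolished <- reference_sites[!rk %in% ak, , drop = FALSE]
  add_dir <- function(df, dir) {
    if (nrow(df) == 0L) return(NULL)
    df$direction <- dir
    df$haplotype <- haplotype_label
    df$snps <- snps
    df
  }
  out <- rbind(add_dir(abolished, "abolished"), add_dir(created, "created"))
  if (is.null(out)) {
    out <- data.frame(mirna = character(0), gene_symbol = character(0),
                      utr_offset = integer(0), site_type = character(0),
                      site_length = integer(0), direction = character(0),
                      haplotype = character(0), snps = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Site differences induced by all alternate haplotypes of a UTR
#'
#' Convenience driver: predicts sites on the reference UTR and on every
#' alternate sequence from [enumerate_alternate_sequences()], and
#' accumulates the created/abolished calls.
#'
#' @param utr_sequence reference UTR sequence.
#' @param snps UTR-coordinate SNP table (see
#'   [enumerate_alternate_sequences()]).
#' @param mirnas miRNA table (`name`, `mature_sequence`).
#' @param gene_symbol gene label carried through.
#' @return data.frame of site differences across all alternates.
#' @export
utr_site_diffs <- function(utr_sequence, snps, mirnas,
                           gene_symbol = NA_character_) {
  ref_sites <- find_sites(utr_sequence, mirnas, gene_symbol)
  alts <- enumerate_alternate_sequences(utr_sequence, snps)
  out <- lapply(seq_len(nrow(alts)), function(i) {
    alt_sites <- find_sites(alts$sequence[i], mirnas, gene_symbol)
    diff_sites(ref_sites, alt_sites, alts$label[i], alts$snps[i])
  })
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) {
    return(diff_sites(ref_sites, ref_sites))
  }
  rownames(res) <- NULL
  res
}
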