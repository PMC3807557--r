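## Phased haplotype panels: construction, VCF / plain-text readers,
## r-squared, MAF, and LD-block expansion.

#' Construct a phased haplotype panel
#'
#' A panel holds an ordered table of bi-allelic SNPs and a haplotype x SNP
#' binary allele matrix (0 = reference, 1 = alternate, NA = missing). It
#' is the source of all pairwise r-squared and minor-allele-frequency
#' computations for one super-population.
#'
#' @param snps data.frame with columns `chrom`, `pos` (1-based), `id`
#'   (rsID), `ref`, `alt` (single bases).
#' @param haplotypes integer/numeric matrix, rows = haplotypes, columns =
#'   SNPs in the order of `snps`; entries in \{0, 1, NA\}.
#' @param population one of EUR, AFR, AMR, ASN.
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(snps, haplotypes, population = "EUR") {
  stopifnot(is.data.frame(snps),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(snps)))
  population <- match.arg(population, SUPERPOPULATIONS)
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) != nrow(snps)) {
    data_error("haplotype matrix has %d columns but %d SNPs were given",
               ncol(haplotypes), nrow(snps))
  }
  vals <- haplotypes[!is.na(haplotypes)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    data_error("haplotype matrix entries must be 0, 1 or NA")
  }
  if (nrow(haplotypes) %% 2L != 0L) {
    warning("haplotype count is odd (", nrow(haplotypes),
            "); expected an even count from diploid phasing")
  }
  if (anyDuplicated(snps$id)) {
    data_error("duplicated SNP ids in panel: %s",
               paste(unique(snps$id[duplicated(snps$id)]), collapse = ", "))
  }
  colnames(haplotypes) <- snps$id
  structure(list(snps = snps, haplotypes = haplotypes,
                 population = population),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Phased haplotype panel (%s): %d haplotypes x %d bi-allelic SNPs on %d contig(s)\n",
              x$population, nrow(x$haplotypes), nrow(x$snps),
              length(unique(x$snps$chrom))))
  invisible(x)
}

#' Read a phased haplotype panel from a VCF
#'
#' Loads phased GT fields from a VCF and builds a [haplotype_panel()].
#' Multi-allelic records and non-SNV records are dropped with a warning
#' (the panel models each bi-allelic polymorphic locus); missing alleles
#' (".") become NA and are excluded pairwise downstream.
#'
#' @param path VCF path (plain or bgzipped).
#' @param population super-population label of the panel.
#' @return a `haplotype_panel`.
#' @export
read_haplotype_vcf <- function(path, population = "EUR") {
  if (!file.exists(path)) config_error("haplotype VCF not found: %s", path)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- lengths(altl)
  alt1 <- vapply(as.list(altl), function(x) {
    if (length(x)) as.character(x[1L]) else NA_character_
  }, character(1))
  biallelic <- n_alt == 1L
  snv <- biallelic & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L
  if (any(!snv)) {
    warning(sum(!snv), " multi-allelic or non-SNV record(s) dropped from ",
            basename(path))
  }
  gt <- VariantAnnotation::geno(vcf)$GT[snv, , drop = FALSE]
  ids <- names(rr)[snv]
  ## variants x samples of "a|b" -> (2*samples) x variants of 0/1
  parse_gt <- function(g) {
    parts <- strsplit(g, "[|/]")
    a <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
    b <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
    rbind(a, b)
  }
  hap <- matrix(NA_integer_, nrow = 2L * ncol(gt), ncol = nrow(gt))
  for (j in seq_len(nrow(gt))) {
    ab <- parse_gt(gt[j, ])
    hap[, j] <- as.vector(ab)
  }
  hap[!is.na(hap) & hap > 1L] <- NA_integer_  # defensive: treat as missing
  snps <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[snv],
    pos = GenomicRanges::start(rr)[snv],
    id = ids, ref = ref[snv], alt = alt1[snv],
    stringsAsFactors = FALSE
  )
  haplotype_panel(snps, hap, population)
}

#' Read a haplotype panel from a two-file plain-text dialect
#'
#' Alternative to VCF input: a SNP metadata TSV (columns chrom, pos, id,
#' ref, alt; positions 1-based) plus a whitespace-separated 0/1 matrix,
#' one row per haplotype, one column per SNP ("." = missing).
#'
#' @param meta_path SNP metadata TSV.
#' @param matrix_path haplotype allele matrix file.
#' @param population super-population label.
#' @return a `haplotype_panel`.
#' @export
read_haplotype_matrix <- function(meta_path, matrix_path,
                                  population = "EUR") {
  snps <- read_tsv(meta_path)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(snps))) {
    config_error("haplotype metadata must have columns: %s",
                 paste(need, collapse = ", "))
  }
  rows <- readLines(matrix_path)
  rows <- rows[nzchar(trimws(rows))]
  cells <- strsplit(trimws(rows), "[ \t]+")
  if (length(unique(lengths(cells))) != 1L) {
    data_error("ragged haplotype matrix in %s", matrix_path)
  }
  m <- do.call(rbind, lapply(cells, function(v) {
    v[v == "."] <- NA
    as.integer(v)
  }))
  haplotype_panel(snps, m, population)
}

.panel_col <- function(panel, id) {
  j <- match(id, panel$snps$id)
  if (is.na(j)) lookup_error("SNP '%s' not present in the haplotype panel", id)
  panel$haplotypes[, j]
}

#' Pairwise r-squared between two panel SNPs
#'
#' Computes the squared allelic correlation r^2 = D^2 / (pA(1-pA)pB(1-pB))
#' with D = pAB - pA*pB, from phased haplotype frequencies. Haplotypes
#' missing an allele at either SNP are excluded pairwise. If either SNP is
#' monomorphic among the compared haplotypes the denominator is zero and
#' the function returns 0. Symmetric in its arguments; the result is
#' clamped to [0, 1] against floating-point drift.
#'
#' @param panel a [haplotype_panel()].
#' @param snp_a,snp_b rsIDs present in the panel.
#' @return r-squared in [0, 1].
#' @export
compute_r2 <- function(panel, snp_a, snp_b) {
  a <- .panel_col(panel, snp_a)
  b <- .panel_col(panel, snp_b)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L) return(0)
  pA <- mean(a); pB <- mean(b)
  ## grouped so the result is bit-identical under argument swap
  den <- (pA * (1 - pA)) * (pB * (1 - pB))
  if (den <= 0) return(0)
  pAB <- mean(a == 1L & b == 1L)
  D <- pAB - pA * pB
  min(1, max(0, D * D / den))
}

#' Minor allele identity and frequency of a panel SNP
#'
#' @param panel a [haplotype_panel()].
#' @param snp rsID present in the panel.
#' @return list with `minor_allele` (the base) and `maf` in [0, 0.5]. At
#'   frequency exactly 0.5 the alternate allele is reported as minor
#'   (deterministic tie-break).
#' @export
compute_maf <- function(panel, snp) {
  x <- .panel_col(panel, snp)
  j <- match(snp, panel$snps$id)
  p_alt <- mean(x, na.rm = TRUE)
  if (is.nan(p_alt)) p_alt <- 0
  if (p_alt <= 0.5) {
    list(minor_allele = panel$snps$alt[j], maf = p_alt)
  } else {
    list(minor_allele = panel$snps$ref[j], maf = 1 - p_alt)
  }
}

#' Expand a GWAS index SNP into its LD block
#'
#' Collects every panel SNP within `window_bp` of the index SNP (same
#' chromosome) whose r-squared with the index exceeds `r2_threshold`
#' strictly, plus the index SNP itself (carried with r^2 = 1). Each
#' member carries its r-squared, minor allele and MAF in the panel's
#' population. If the index SNP is absent from the panel the association
#' is skipped with a warning and an empty block flagged `unresolved` is
#' returned.
#'
#' @param index_snp rsID of the GWAS index SNP.
#' @param panel a [haplotype_panel()].
#' @param r2_threshold strict lower bound on member r-squared
#'   (default 0.6).
#' @param window_bp half-width of the search window around the index SNP
#'   (default 1e6).
#' @param trait optional trait label carried through to outputs.
#' @return object of class `ld_block` with fields `index_snp`, `trait`,
#'   `population`, `unresolved`, and `members` (data.frame: snp, chrom,
#'   pos, r2, minor_allele, maf).
#' @export
expand_ld_block <- function(index_snp, panel, r2_threshold = 0.6,
                            window_bp = 1e6L, trait = NA_character_) {
  stopifnot(r2_threshold >= 0, r2_threshold <= 1)
  empty <- data.frame(snp = character(0), chrom = character(0),
                      pos = integer(0), r2 = numeric(0),
                      minor_allele = character(0), maf = numeric(0),
                      stringsAsFactors = FALSE)
  j <- match(index_snp, panel$snps$id)
  if (is.na(j)) {
    warning("index SNP ", index_snp,
            " absent from the haplotype panel; association skipped")
    return(structure(list(index_snp = index_snp, trait = trait,
                          population = panel$population,
                          unresolved = TRUE, members = empty),
                     class = "ld_block"))
  }
  chrom <- panel$snps$chrom[j]
  pos <- panel$snps$pos[j]
  cand <- which(panel$snps$chrom == chrom &
                  abs(panel$snps$pos - pos) <= window_bp &
                  seq_len(nrow(panel$snps)) != j)
  r2 <- vapply(panel$snps$id[cand], function(id)
    compute_r2(panel, index_snp, id), numeric(1))
  keep <- cand[r2 > r2_threshold]
  members_idx <- c(j, keep)
  r2_all <- c(1.0, r2[r2 > r2_threshold])
  mafs <- lapply(panel$snps$id[members_idx], function(id)
    compute_maf(panel, id))
  members <- data.frame(
    snp = panel$snps$id[members_idx],
    chrom = panel$snps$chrom[members_idx],
    pos = panel$snps$pos[members_idx],
    r2 = r2_all,
    minor_allele = vapply(mafs, `[[`, character(1), "minor_allele"),
    maf = vapply(mafs, `[[`, numeric(1), "maf"),
    stringsAsFactors = FALSE
  )
  members <- members[order(members$chrom, members$pos, members$snp), ]
  rownames(members) <- NULL
  structure(list(index_snp = index_snp, trait = trait,
                 population = panel$population, unresolved = FALSE,
                 members = members),
            class = "ld_block")
}

#' @export
print.ld_block <- function(x, ...) {
  if (x$unresolved) {
    cat(sprintf("LD block for %s (%s): unresolved (index SNP not in panel)\n",
                x$index_snp, x$population))
  } else {
    cat(sprintf("LD block for %s (%s): %d member SNP(s), r2 range [%.3f, 1]\n",
                x$index_snp, x$population, nrow(x$members),
                min(x$members$r2)))
  }
  invisible(x)
}

#' Write LD blocks to a TSV
#'
#' One row per block member: index_snp, trait, population, member_snp,
#' chrom, pos, r2, minor_allele, maf. Unresolved blocks contribute no
#' rows.
#'
#' @param blocks list of `ld_block` objects.
#' @param path output TSV path.
#' @return the flattened data.frame, invisibly.
#' @export
write_ld_blocks <- function(blocks, path) {
  df <- ld_blocks_table(blocks)
  write_tsv(df, path)
  invisible(df)
}

#' Flatten LD blocks into one table
#' @param blocks list of `ld_block` objects.
#' @return data.frame, one row per (block, member).
#' @export
ld_blocks_table <- function(blocks) {
  rows <- lapply(blocks, function(b) {
    if (b$unresolved || nrow(b$members) == 0L) return(NULL)
    cbind(data.frame(index_snp = b$index_snp, trait = b$trait,
                     population = b$population, stringsAsFactors = FALSE),
          stats::setNames(b$members,
                          c("member_snp", "chrom", "pos", "r2",
                            "minor_allele", "maf")))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(index_snp = character(0), trait = character(0),
                      population = character(0), member_snp = character(0),
                      chrom = character(0), pos = integer(0),
                      r2 = numeric(0), minor_allele = character(0),
                      maf = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
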