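## Deterministic synthetic-fixture generators. Every input the pipeline
## consumes (phased VCF, miRBase-style GFF3, BED, FASTA, UTR tables,
## GWAS catalog, annotation sets) is emitted as real files in the same
## formats the pipeline reads, with a manifest of planted ground truth.

#' Specification of a synthetic fixture set
#'
#' Defaults describe a small but complete world: a 200-haplotype
#' EUR panel, six miRNAs with promoters and precursors, sixty genes with
#' 3'-UTRs (and four-species ortholog UTRs), planted created/abolished
#' target sites, planted promoter/precursor TASs, an engineered
#' r-squared = 0.6 boundary pair, decoy catalog rows, and a planted
#' regulatory hub (one miRNA with conserved sites in 40% of one trait's
#' genes vs 5% of background genes). Identical spec + seed regenerate
#' byte-identical files.
#'
#' @param rng_seed integer seed driving all generation.
#' @param n_haplotypes haplotype count (even; must be divisible by 8 so
#'   the r-squared = 0.6 pair can be engineered by pattern replication).
#' @param n_snps number of background (ungrouped) panel SNPs.
#' @param ld_block_length spacer length in nt between planted loci.
#' @param n_mirnas number of miRNAs (>= 5; the first five have planted
#'   roles).
#' @param n_genes number of genes with UTRs (>= 55).
#' @param utr_length_range min/max UTR length in nt.
#' @param hub_mirna name of the planted hub miRNA.
#' @param target_fraction fraction of the hub trait's genes carrying a
#'   conserved site for the hub miRNA (default 0.4).
#' @param background_fraction carrier fraction among non-trait genes
#'   (default 0.05).
#' @param trait_size genes per trait list (default 15).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(rng_seed = 1L, n_haplotypes = 200L, n_snps = 60L,
                         ld_block_length = 150L, n_mirnas = 6L,
                         n_genes = 60L, utr_length_range = c(180L, 320L),
                         hub_mirna = "mir-3", target_fraction = 0.4,
                         background_fraction = 0.05, trait_size = 15L) {
  if (n_haplotypes %% 8L != 0L) {
    data_error("n_haplotypes must be divisible by 8 to engineer the r2 = 0.6 pair (got %d)",
               n_haplotypes)
  }
  if (n_mirnas < 5L) data_error("n_mirnas must be >= 5 (got %d)", n_mirnas)
  if (n_genes < 55L) data_error("n_genes must be >= 55 (got %d)", n_genes)
  stopifnot(n_snps > 0L, ld_block_length > 0L,
            length(utr_length_range) == 2L,
            utr_length_range[1] >= 100L,
            utr_length_range[2] >= utr_length_range[1],
            target_fraction > 0, target_fraction <= 1,
            background_fraction >= 0, background_fraction < target_fraction,
            trait_size >= 5L)
  structure(list(rng_seed = as.integer(rng_seed),
                 n_haplotypes = as.integer(n_haplotypes),
                 n_snps = as.integer(n_snps),
                 ld_block_length = as.integer(ld_block_length),
                 n_mirnas = as.integer(n_mirnas),
                 n_genes = as.integer(n_genes),
                 utr_length_range = as.integer(utr_length_range),
                 hub_mirna = hub_mirna,
                 target_fraction = target_fraction,
                 background_fraction = background_fraction,
                 trait_size = as.integer(trait_size)),
            class = "fixture_spec")
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp_dna <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.pat_dna <- function(mature, type) {
  chartr("U", "T", seed_patterns(mature)[[type]])
}

.sub_str <- function(s, at, repl) {
  ## replace substring of s starting at 1-based `at` with repl
  paste0(substr(s, 1L, at - 1L), repl,
         substr(s, at + nchar(repl), nchar(s)))
}

## remove every occurrence of (mirna, any type) from seq except an
## optional protected 0-based offset; mutate one base inside each stray
## occurrence until clean.
.ensure_only_site <- function(seq, mirna_row, keep_offset0 = NULL,
                              keep_type = NULL, max_iter = 100L) {
  for (it in seq_len(max_iter)) {
    sites <- find_sites(seq, mirna_row)
    if (!is.null(keep_offset0)) {
      stray <- sites[!(sites$utr_offset == keep_offset0 &
                         sites$site_type == keep_type), , drop = FALSE]
    } else {
      stray <- sites
    }
    if (nrow(stray) == 0L) return(seq)
    at <- stray$utr_offset[1L] + 2L  # mutate 2nd base of the stray site
    cur <- substr(seq, at, at)
    repl <- setdiff(c("A", "C", "G", "T"), chartr("U", "T", cur))[1L]
    seq <- .sub_str(seq, at, repl)
  }
  data_error("could not scrub stray %s sites from a fixture UTR", mirna_row$name)
}

## verify a planted single-SNP substitution yields exactly the intended
## site difference against the full miRNA set; returns TRUE/FALSE.
.clean_single_diff <- function(utr, snp_df, mirnas, direction, mirna, offset0,
                               type) {
  d <- utr_site_diffs(utr, snp_df, mirnas)
  nrow(d) == 1L && d$direction == direction && d$mirna == mirna &&
    d$utr_offset == offset0 && d$site_type == type
}

.write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Generate the synthetic miRNA regulome
#'
#' Builds a one-chromosome genome embedding miRNA promoters, precursors
#' and gene 3'-UTRs; plants an abolishable 8mer-1a site (conservation 3:
#' human + mouse + rat), a creatable 7mer-1a site on a minus-strand gene,
#' a decoy UTR site in a block that will carry competing annotations,
#' and conserved hub-miRNA sites in a fraction of the hub trait's genes.
#' Emits genome FASTA, mature-miRNA FASTA, miRBase-dialect GFF3,
#' promoter BED, UTR table (human + four ortholog species), UTR genomic
#' mappings (including multi-mapped/spliced/too-short/unmapped rejection
#' exercisers) and a RefSeq-to-symbol map.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list with file paths, layout tables and planted truths
#'   (consumed by [make_haplotype_panel()] and [make_gwas_catalog()]).
#' @export
make_regulome <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(spec$rng_seed, {
    ## --- miRNAs with mutually distinct seed patterns
    repeat {
      mirnas <- data.frame(
        name = sprintf("mir-%d", seq_len(spec$n_mirnas)),
        mature_sequence = vapply(seq_len(spec$n_mirnas), function(i)
          chartr("T", "U", .random_dna(22L)), character(1)),
        stringsAsFactors = FALSE)
      pats <- unlist(lapply(mirnas$mature_sequence, seed_patterns))
      if (!anyDuplicated(substr(mirnas$mature_sequence, 2L, 8L)) &&
          !anyDuplicated(pats)) break
    }

    ## --- genome layout (cursor-based)
    segs <- character(0)
    cursor <- 1L
    put <- function(seqtxt) {
      segs[[length(segs) + 1L]] <<- seqtxt
      start <- cursor
      cursor <<- cursor + nchar(seqtxt)
      c(start = start, end = cursor - 1L)
    }
    gap_positions <- integer(0)  # free positions usable for index SNPs
    put_gap <- function(len) {
      iv <- put(.random_dna(len))
      gap_positions <<- c(gap_positions, iv[["start"]]:iv[["end"]])
      iv
    }

    promoters <- hairpins <- vector("list", spec$n_mirnas)
    for (i in seq_len(spec$n_mirnas)) {
      put_gap(spec$ld_block_length)
      promoters[[i]] <- put(.random_dna(200L))
      put_gap(40L)
      hp <- .random_dna(80L)
      hp <- .sub_str(hp, 10L, chartr("U", "T", mirnas$mature_sequence[i]))
      hairpins[[i]] <- put(hp)
    }

    ## --- gene UTRs (sense-strand sequences; planted later)
    n_g <- spec$n_genes
    lens <- sample(seq(spec$utr_length_range[1], spec$utr_length_range[2]),
                   n_g, replace = TRUE)
    strands <- ifelse(seq_len(n_g) %% 5L == 2L, "-", "+")
    utr_seq <- vapply(lens, .random_dna, character(1))

    ## planted gene roles
    trait_genes <- sprintf("GENE%d", 41:(40 + spec$trait_size))
    n_carriers <- ceiling(spec$target_fraction * spec$trait_size)
    carriers <- trait_genes[seq_len(n_carriers)]
    n_bg <- ceiling(spec$background_fraction * (n_g - spec$trait_size))
    bg_carriers <- sprintf("GENE%d", 30 + seq_len(n_bg))
    null_genes <- sprintf("GENE%d", 16:(15 + spec$trait_size))
    gene_names <- sprintf("GENE%d", seq_len(n_g))

    hub_i <- match(spec$hub_mirna, mirnas$name)
    if (is.na(hub_i)) data_error("hub miRNA %s not among fixture miRNAs",
                                 spec$hub_mirna)
    pat_hub <- .pat_dna(mirnas$mature_sequence[hub_i], "8mer-1a")
    pat_ab <- .pat_dna(mirnas$mature_sequence[1L], "8mer-1a")
    pat_cr_full <- .pat_dna(mirnas$mature_sequence[2L], "7mer-1a")

    plant_site <- function(g, pattern, offset0, mirna_row, type) {
      s <- .sub_str(utr_seq[g], offset0 + 1L, pattern)
      .ensure_only_site(s, mirna_row, offset0, type)
    }
    ## abolishable site in GENE1, decoy site in GENE3
    utr_seq[1L] <- plant_site(1L, pat_ab, 40L, mirnas[1L, ], "8mer-1a")
    utr_seq[3L] <- plant_site(3L, pat_ab, 60L, mirnas[1L, ], "8mer-1a")
    ## hub carrier sites (conserved in all five species)
    for (g in match(c(carriers, bg_carriers), gene_names)) {
      utr_seq[g] <- plant_site(g, pat_hub, 30L, mirnas[hub_i, ], "8mer-1a")
    }

    ## creatable site in GENE2: plant the 7mer-1a pattern with one
    ## mismatched base; search (offset, mismatch position, allele) until
    ## the reference carries no mir-2 site and repairing the mismatch is
    ## the one and only site change
    base_seq2 <- .ensure_only_site(utr_seq[2L], mirnas[2L, ])
    create_plant <- NULL
    offsets <- c(50L, 70L, 90L, 20L, 110L)
    for (create_off0 in offsets) {
      for (mm in seq_len(nchar(pat_cr_full))) {
        for (mm_base in setdiff(c("A", "C", "G", "T"),
                                substr(pat_cr_full, mm, mm))) {
          broken <- .sub_str(pat_cr_full, mm, mm_base)
          cand <- .sub_str(base_seq2, create_off0 + 1L, broken)
          if (nrow(find_sites(cand, mirnas[2L, ]))) next
          snp_df <- data.frame(id = "rs201", utr_pos = create_off0 + mm,
                               ref = mm_base,
                               alt = substr(pat_cr_full, mm, mm),
                               stringsAsFactors = FALSE)
          if (.clean_single_diff(cand, snp_df, mirnas, "created", "mir-2",
                                 create_off0, "7mer-1a")) {
            create_plant <- list(seq = cand, snp = snp_df,
                                 off0 = create_off0)
            break
          }
        }
        if (!is.null(create_plant)) break
      }
      if (!is.null(create_plant)) break
    }
    if (is.null(create_plant)) {
      data_error("could not engineer a clean created-site SNP in the fixture")
    }
    utr_seq[2L] <- create_plant$seq
    create_off0 <- create_plant$off0

    ## abolishing SNPs: search (position within site, allele)
    find_abolish_snp <- function(g, id, offset0) {
      for (k in 1:8) {
        pos <- offset0 + k
        ref <- substr(utr_seq[g], pos, pos)
        for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
          snp_df <- data.frame(id = id, utr_pos = pos, ref = ref, alt = alt,
                               stringsAsFactors = FALSE)
          if (.clean_single_diff(utr_seq[g], snp_df, mirnas, "abolished",
                                 "mir-1", offset0, "8mer-1a")) {
            return(snp_df)
          }
        }
      }
      data_error("could not engineer a clean abolishing SNP in GENE%d", g)
    }
    abol_snp <- find_abolish_snp(1L, "rs101", 40L)
    decoy_snp <- find_abolish_snp(3L, "rs701", 60L)

    ## --- place UTRs in the genome
    gene_iv <- vector("list", n_g)
    for (g in seq_len(n_g)) {
      put_gap(120L)
      gseq <- if (strands[g] == "-") .revcomp_dna(utr_seq[g]) else utr_seq[g]
      gene_iv[[g]] <- put(gseq)
    }
    put_gap(spec$ld_block_length)
    genome <- paste(segs, collapse = "")
    genome_len <- nchar(genome)

    ## --- ortholog UTRs with controlled conservation
    species4 <- c("mouse", "rat", "dog", "chicken")
    ensure_absent <- function(s, mirna_row, type) {
      for (it in 1:100) {
        hit <- find_sites(s, mirna_row)
        hit <- hit[hit$site_type == type, , drop = FALSE]
        if (nrow(hit) == 0L) return(s)
        at <- hit$utr_offset[1L] + 3L
        repl <- setdiff(c("A", "C", "G", "T"), substr(s, at, at))[1L]
        s <- .sub_str(s, at, repl)
      }
      data_error("could not scrub an ortholog site in the fixture")
    }
    ortho <- list()  # gene -> species -> sequence
    cons_plan <- list(
      GENE1 = list(mirna = 1L, type = "8mer-1a", pat = pat_ab,
                   present = c("mouse", "rat"))
    )
    for (g in c(carriers, bg_carriers)) {
      cons_plan[[g]] <- list(mirna = hub_i, type = "8mer-1a", pat = pat_hub,
                             present = species4)
    }
    for (g in seq_len(n_g)) {
      nm <- gene_names[g]
      plan <- cons_plan[[nm]]
      per_sp <- list()
      for (sp in species4) {
        s <- .random_dna(lens[g])
        if (!is.null(plan)) {
          if (sp %in% plan$present) {
            s <- .sub_str(s, 26L, plan$pat)
            s <- .ensure_only_site(s, mirnas[plan$mirna, ], 25L, plan$type)
          } else {
            s <- ensure_absent(s, mirnas[plan$mirna, ], plan$type)
          }
        }
        per_sp[[sp]] <- s
      }
      ortho[[nm]] <- per_sp
    }

    ## --- planted SNP/index genomic coordinates
    utr_genomic <- function(g, utr_pos) {
      iv <- gene_iv[[g]]
      if (strands[g] == "-") iv[["end"]] - utr_pos + 1L
      else iv[["start"]] + utr_pos - 1L
    }
    genomic_allele <- function(g, allele) {
      if (strands[g] == "-") comp_dna(allele) else allele
    }
    base_at <- function(pos) substr(genome, pos, pos)

    ## index SNPs / annotation SNPs live in inter-element gaps
    gap_positions <- setdiff(gap_positions, integer(0))
    take_gap <- local({
      i <- 0L
      function() {
        i <<- i + 37L  # stride to spread index SNPs across gaps
        gap_positions[[i]]
      }
    })
    planted <- list(
      list(id = "rs100", role = "index", group = "abolish",
           pos = take_gap()),
      list(id = "rs101", role = "tas_utr3", group = "abolish",
           gene = "GENE1",
           pos = utr_genomic(1L, abol_snp$utr_pos),
           alt = genomic_allele(1L, abol_snp$alt)),
      list(id = "rs200", role = "index", group = "create",
           pos = take_gap()),
      list(id = "rs201", role = "tas_utr3", group = "create",
           gene = "GENE2",
           pos = utr_genomic(2L, create_plant$snp$utr_pos),
           alt = genomic_allele(2L, create_plant$snp$alt)),
      list(id = "rs300", role = "index", group = "promoter",
           pos = take_gap()),
      list(id = "rs301", role = "tas_promoter", group = "promoter",
           mirna = "mir-4",
           pos = promoters[[4L]][["start"]] + 57L),
      list(id = "rs400", role = "index", group = "premirna",
           pos = take_gap()),
      list(id = "rs401", role = "tas_premirna", group = "premirna",
           mirna = "mir-5",
           pos = hairpins[[5L]][["start"]] + 41L),
      list(id = "rs700", role = "index", group = "decoy_annot",
           pos = take_gap()),
      list(id = "rs701", role = "tas_utr3", group = "decoy_annot",
           gene = "GENE3",
           pos = utr_genomic(3L, decoy_snp$utr_pos),
           alt = genomic_allele(3L, decoy_snp$alt)),
      list(id = "rs702", role = "nonsyn", group = "decoy_annot",
           pos = take_gap()),
      list(id = "rs900", role = "index", group = "boundary",
           pos = take_gap()),
      list(id = "rs901", role = "boundary_partner", group = "boundary",
           pos = take_gap()),
      list(id = "rs800", role = "maf_tie", group = "tie",
           pos = take_gap())
    )
    planted_df <- do.call(rbind, lapply(planted, function(p) {
      data.frame(id = p$id, role = p$role, group = p$group,
                 chrom = "chr1", pos = p$pos,
                 ref = base_at(p$pos),
                 alt = p$alt %||% NA_character_,
                 gene = p$gene %||% NA_character_,
                 mirna = p$mirna %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
    need_alt <- is.na(planted_df$alt)
    planted_df$alt[need_alt] <- vapply(planted_df$ref[need_alt], function(r)
      setdiff(c("A", "C", "G", "T"), r)[1L], character(1))
    if (anyDuplicated(planted_df$pos)) {
      data_error("fixture layout collision among planted SNP positions")
    }

    ## --- write files
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      mirna_fasta = file.path(dir, "mirna_mature.fa"),
      mirna_gff = file.path(dir, "mirna.gff3"),
      promoter_bed = file.path(dir, "promoters.bed"),
      exon_bed = file.path(dir, "exons.bed"),
      utr_table = file.path(dir, "utrs.tsv"),
      utr_mappings = file.path(dir, "utr_mappings.tsv"),
      symbol_map = file.path(dir, "refseq_symbols.tsv")
    )
    .write_fasta(list(chr1 = genome), paths$genome)
    .write_fasta(stats::setNames(as.list(mirnas$mature_sequence),
                                 mirnas$name), paths$mirna_fasta)

    gff <- c("##gff-version 3", sprintf("##sequence-region chr1 1 %d",
                                        genome_len))
    for (i in seq_len(spec$n_mirnas)) {
      hp <- hairpins[[i]]
      gff <- c(gff,
               sprintf("chr1\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t+\t.\tID=MI%07d;Alias=MI%07d;Name=%s",
                       hp[["start"]], hp[["end"]], i, i, mirnas$name[i]),
               sprintf("chr1\t.\tmiRNA\t%d\t%d\t.\t+\t.\tID=MIMAT%07d;Name=%s;Derives_from=MI%07d",
                       hp[["start"]] + 9L, hp[["start"]] + 30L, i,
                       mirnas$name[i], i))
    }
    writeLines(gff, paths$mirna_gff)

    bed_line <- function(start, end, name) {
      sprintf("chr1\t%d\t%d\t%s\t0\t+", start - 1L, end, name)
    }
    writeLines(vapply(seq_len(spec$n_mirnas), function(i)
      bed_line(promoters[[i]][["start"]], promoters[[i]][["end"]],
               mirnas$name[i]), character(1)), paths$promoter_bed)
    exon_center <- planted_df$pos[planted_df$id == "rs700"]
    writeLines(bed_line(exon_center - 10L, exon_center + 10L, "EXON1"),
               paths$exon_bed)

    ## UTR table: human + orthologs + rejection exercisers
    utr_rows <- list()
    add_utr <- function(id, species, sequence) {
      utr_rows[[length(utr_rows) + 1L]] <<- data.frame(
        id = id, species = species, sequence = sequence,
        stringsAsFactors = FALSE)
    }
    nm_ids <- sprintf("NM_%04d", seq_len(n_g))
    for (g in seq_len(n_g)) {
      add_utr(nm_ids[g], "human", utr_seq[g])
      for (sp in species4) add_utr(nm_ids[g], sp, ortho[[gene_names[g]]][[sp]])
    }
    add_utr("NM_BAD_MULTI", "human", .random_dna(100L))
    add_utr("NM_BAD_SPLICED", "human", .random_dna(100L))
    add_utr("NM_BAD_SHORT", "human", .random_dna(15L))
    add_utr("NM_BAD_UNMAPPED", "human", .random_dna(50L))
    write_tsv(do.call(rbind, utr_rows), paths$utr_table)

    map_rows <- lapply(seq_len(n_g), function(g) {
      iv <- gene_iv[[g]]
      data.frame(id = nm_ids[g], mapping = 1L, chrom = "chr1",
                 strand = strands[g], start = iv[["start"]],
                 end = iv[["end"]], stringsAsFactors = FALSE)
    })
    map_rows[[length(map_rows) + 1L]] <- data.frame(
      id = rep("NM_BAD_MULTI", 2L), mapping = 1:2, chrom = "chr1",
      strand = "+", start = c(11L, 501L), end = c(110L, 600L),
      stringsAsFactors = FALSE)
    map_rows[[length(map_rows) + 1L]] <- data.frame(
      id = rep("NM_BAD_SPLICED", 2L), mapping = 1L, chrom = "chr1",
      strand = "+", start = c(11L, 301L), end = c(60L, 350L),
      stringsAsFactors = FALSE)
    map_rows[[length(map_rows) + 1L]] <- data.frame(
      id = "NM_BAD_SHORT", mapping = 1L, chrom = "chr1", strand = "+",
      start = 11L, end = 25L, stringsAsFactors = FALSE)
    write_tsv(do.call(rbind, map_rows), paths$utr_mappings)

    write_tsv(data.frame(
      id = c(nm_ids, "NM_BAD_MULTI", "NM_BAD_SPLICED", "NM_BAD_SHORT"),
      symbol = c(gene_names, "BADMULTI", "BADSPLICED", "BADSHORT"),
      stringsAsFactors = FALSE), paths$symbol_map)

    list(
      paths = paths, mirnas = mirnas, gene_names = gene_names,
      nm_ids = nm_ids, strands = strands, utr_seq = utr_seq,
      utr_lengths = stats::setNames(lens, gene_names),
      gene_iv = gene_iv, promoters = promoters, hairpins = hairpins,
      genome = genome, genome_len = genome_len,
      planted = planted_df,
      trait_genes = trait_genes, null_genes = null_genes,
      carriers = carriers, bg_carriers = bg_carriers,
      planted_sites = list(
        abolish = list(gene = "GENE1", mirna = "mir-1", offset0 = 40L,
                       type = "8mer-1a", snp = "rs101", conservation = 3L),
        create = list(gene = "GENE2", mirna = "mir-2",
                      offset0 = create_off0, type = "7mer-1a",
                      snp = "rs201"),
        decoy = list(gene = "GENE3", mirna = "mir-1", offset0 = 60L,
                     type = "8mer-1a", snp = "rs701"),
        hub = list(mirna = spec$hub_mirna, type = "8mer-1a", offset0 = 30L,
                   carriers = carriers, bg_carriers = bg_carriers)
      )
    )
  })
}

#' Generate the phased haplotype panel fixture
#'
#' Builds the panel around planted LD groups: every planted TAS SNP is a
#' duplicated column of its index SNP (r-squared = 1), the
#' boundary pair rs900/rs901 replicates the 8-haplotype worked pattern
#' (r-squared exactly 0.6), rs800 is an exact 50/50 MAF tie, and
#' background SNPs are mutually independent columns (between-group
#' r-squared approximately 0). Written as a phased VCF (including one
#' multi-allelic record the loader must drop).
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @param regulome output of [make_regulome()] (optional: without it a
#'   free-standing panel with the engineered pairs and background SNPs
#'   is generated on a synthetic coordinate grid).
#' @return list with `panel` (a [haplotype_panel()]), `vcf` path and the
#'   SNP table.
#' @export
make_haplotype_panel <- function(spec, dir, regulome = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$n_haplotypes
  .with_seed(spec$rng_seed + 1L, {
    rand_col <- function() {
      repeat {
        p <- stats::runif(1, 0.2, 0.4)
        col <- as.integer(stats::runif(n) < p)
        if (sum(col) > 0L && sum(col) < n) return(col)
      }
    }
    snps <- list(); cols <- list()
    add_snp <- function(id, chrom, pos, ref, alt, col) {
      snps[[length(snps) + 1L]] <<- data.frame(
        chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
      cols[[length(cols) + 1L]] <<- col
    }

    if (!is.null(regulome)) {
      pl <- regulome$planted
      for (grp in unique(pl$group[pl$group != "boundary" &
                                    pl$group != "tie"])) {
        rows <- pl[pl$group == grp, , drop = FALSE]
        col <- rand_col()
        for (r in seq_len(nrow(rows))) {
          add_snp(rows$id[r], rows$chrom[r], rows$pos[r], rows$ref[r],
                  rows$alt[r], col)
        }
      }
      brow <- pl[pl$group == "boundary", , drop = FALSE]
      add_snp(brow$id[1L], brow$chrom[1L], brow$pos[1L], brow$ref[1L],
              brow$alt[1L], rep(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), n / 8L))
      add_snp(brow$id[2L], brow$chrom[2L], brow$pos[2L], brow$ref[2L],
              brow$alt[2L], rep(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), n / 8L))
      trow <- pl[pl$group == "tie", , drop = FALSE]
      add_snp(trow$id[1L], trow$chrom[1L], trow$pos[1L], trow$ref[1L],
              trow$alt[1L], rep_len(c(1L, 0L), n))
      used <- pl$pos
      genome_len <- regulome$genome_len
      base_at <- function(pos) substr(regulome$genome, pos, pos)
    } else {
      add_snp("rs900", "chr1", 1000L, "A", "G",
              rep(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), n / 8L))
      add_snp("rs901", "chr1", 1040L, "C", "T",
              rep(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), n / 8L))
      add_snp("rs800", "chr1", 1080L, "G", "A", rep_len(c(1L, 0L), n))
      used <- c(1000L, 1040L, 1080L)
      genome_len <- 100000L
      base_at <- function(pos) "A"
    }

    bg_pos <- sort(sample(setdiff(seq_len(genome_len), used), spec$n_snps))
    for (i in seq_along(bg_pos)) {
      ref <- base_at(bg_pos[i])
      alt <- setdiff(c("A", "C", "G", "T"), ref)[
        1L + (bg_pos[i] %% 3L)]
      add_snp(sprintf("rs%d", 5000L + i), "chr1", bg_pos[i], ref, alt,
              rand_col())
    }

    snp_df <- do.call(rbind, snps)
    mat <- do.call(cbind, cols)
    ord <- order(snp_df$pos)
    snp_df <- snp_df[ord, , drop = FALSE]
    mat <- mat[, ord, drop = FALSE]
    rownames(snp_df) <- NULL
    panel <- haplotype_panel(snp_df, mat, "EUR")

    vcf_path <- file.path(dir, "panel.vcf")
    .write_phased_vcf(panel, vcf_path, genome_len,
                      extra_multiallelic = !is.null(regulome))
    list(panel = panel, vcf = vcf_path, snps = snp_df)
  })
}

## write a haplotype_panel as a phased VCF; optionally append one
## multi-allelic record that readers must drop.
.write_phased_vcf <- function(panel, path, contig_len,
                              extra_multiallelic = FALSE) {
  n_hap <- nrow(panel$haplotypes)
  n_samp <- n_hap %/% 2L
  samples <- sprintf("S%03d", seq_len(n_samp))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chr1,length=%d>", contig_len),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(panel$snps)), function(j) {
    col <- panel$haplotypes[, j]
    gt <- paste(col[seq(1L, n_hap, by = 2L)], col[seq(2L, n_hap, by = 2L)],
                sep = "|")
    gt[is.na(col[seq(1L, n_hap, by = 2L)]) |
         is.na(col[seq(2L, n_hap, by = 2L)])] <- ".|."
    paste(c(panel$snps$chrom[j], panel$snps$pos[j], panel$snps$id[j],
            panel$snps$ref[j], panel$snps$alt[j], ".", "PASS", ".", "GT",
            gt), collapse = "\t")
  }, character(1))
  if (extra_multiallelic) {
    gt <- rep("0|0", n_samp)
    body <- c(body, paste(c("chr1", "3", "rs899", "A", "C,G", ".", "PASS",
                            ".", "GT", gt), collapse = "\t"))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate the GWAS catalog and companion annotation fixtures
#'
#' Emits a catalog TSV whose planted rows put the planted TASs inside
#' their index SNPs' LD blocks (ancestry strings drawn from the
#' super-population keyword vocabulary), plus decoy rows exercising the
#' filters: a row at p = 2e-5 (above threshold), a multi-SNP haplotype
#' row, and a row whose index SNP is absent from the panel. Also writes
#' trait gene lists, the nonsynonymous VCF, transcriptional and eQTL
#' SNP sets, and validated miRNA:gene pairs.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @param regulome output of [make_regulome()].
#' @return list of file paths.
#' @export
make_gwas_catalog <- function(spec, dir, regulome) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(spec$rng_seed + 2L, {
    rows <- data.frame(
      SNPS = c("rs100", "rs200", "rs300", "rs400", "rs700", "rs900",
               "rs999", "rs910 x rs911", "rs100"),
      `P-VALUE` = c("3e-8", "1e-9", "5e-12", "1e-7", "1e-8", "1e-8",
                    "1e-8", "1e-9", "2e-5"),
      `DISEASE/TRAIT` = c("trait_abolish", "trait_create", "trait_promoter",
                          "trait_premirna", "trait_nonsyn", "trait_boundary",
                          "trait_unresolved", "trait_multisnp",
                          "trait_decoy_p"),
      PUBMEDID = sprintf("900%02d", 1:9),
      `INITIAL SAMPLE SIZE` = c(
        "2,000 Norwegian individuals", "Utah residents (CEPH)",
        "1,200 individuals from England", "Finnish cohort",
        "German cases and controls", "French population sample",
        "Icelandic individuals", "Scottish twins", "Swiss cohort"),
      check.names = FALSE, stringsAsFactors = FALSE)
    paths <- list(
      catalog = file.path(dir, "catalog.tsv"),
      trait_genes = file.path(dir, "trait_genes.tsv"),
      nonsyn_vcf = file.path(dir, "nonsyn.vcf"),
      transcriptional = file.path(dir, "transcriptional.tsv"),
      eqtl = file.path(dir, "eqtl.tsv"),
      tarbase = file.path(dir, "tarbase.tsv")
    )
    write_tsv(rows, paths$catalog)

    write_tsv(data.frame(
      trait = c(rep("trait_promoter", length(regulome$trait_genes)),
                rep("trait_abolish", length(regulome$null_genes))),
      gene = c(regulome$trait_genes, regulome$null_genes),
      stringsAsFactors = FALSE), paths$trait_genes)

    ns <- regulome$planted[regulome$planted$role == "nonsyn", , drop = FALSE]
    writeLines(c(
      "##fileformat=VCFv4.2",
      sprintf("##contig=<ID=chr1,length=%d>", regulome$genome_len),
      '##INFO=<ID=NSM,Number=0,Type=Flag,Description="Missense">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO"), collapse = "\t"),
      sprintf("chr1\t%d\t%s\t%s\t%s\t.\tPASS\tNSM", ns$pos, ns$id, ns$ref,
              ns$alt)
    ), paths$nonsyn_vcf)

    write_tsv(data.frame(snp = ns$id, category = "2b",
                         stringsAsFactors = FALSE), paths$transcriptional)
    write_tsv(data.frame(snp = "rs101", gene = "GENE1", tissue = "LCL",
                         stringsAsFactors = FALSE), paths$eqtl)
    write_tsv(data.frame(mirna = "mir-1", gene = "GENE3",
                         support = "reporter_assay",
                         stringsAsFactors = FALSE), paths$tarbase)
    paths
  })
}

#' Generate a complete fixture set with a planted-truth manifest
#'
#' Runs [make_regulome()], [make_haplotype_panel()] and
#' [make_gwas_catalog()] into one directory and writes
#' `fixture_manifest.json` recording every planted truth (expected LD
#' blocks, TAS x element hits, site diffs, tiers, hub enrichment and
#' decoys) for end-to-end verification.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return object of class `mirtas_fixture`: list with `spec`, `paths`,
#'   `manifest`, `regulome`, `panel`.
#' @export
make_fixture_set <- function(spec = fixture_spec(), dir) {
  reg <- make_regulome(spec, dir)
  pan <- make_haplotype_panel(spec, dir, reg)
  cat_paths <- make_gwas_catalog(spec, dir, reg)

  manifest <- list(
    rng_seed = spec$rng_seed,
    expected = list(
      associations_kept = 7L,
      associations_dropped = list(p_filter = 1L, multi_snp = 1L),
      blocks_resolved = 6L, blocks_unresolved = 1L,
      unique_tas = 12L,
      tas_per_element = list(pre_mirna = 1L, promoter = 1L, utr3 = 3L),
      diffs = list(created = 1L, abolished = 2L),
      tiers = list(top = 4L, supported = 1L, other = 0L),
      top_tas = c("rs101", "rs201", "rs301", "rs401"),
      supported_tas = "rs701",
      hub = list(mirna = spec$hub_mirna, trait = "trait_promoter"),
      boundary = list(index = "rs900", excluded_partner = "rs901",
                      r2 = 0.6)
    ),
    planted_sites = reg$planted_sites,
    decoys = list(p_filter_trait = "trait_decoy_p",
                  multi_snp_trait = "trait_multisnp",
                  unresolved_index = "rs999"),
    planted_snps = reg$planted
  )
  manifest_path <- file.path(dir, "fixture_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  paths <- c(reg$paths, list(panel_vcf = pan$vcf), cat_paths,
             list(manifest = manifest_path))
  structure(list(spec = spec, paths = paths, manifest = manifest,
                 regulome = reg, panel = pan$panel),
            class = "mirtas_fixture")
}

#' @export
print.mirtas_fixture <- function(x, ...) {
  cat(sprintf("Synthetic fixture set (seed %d): %d miRNAs, %d genes, %d haplotypes, %d files in %s\n",
              x$spec$rng_seed, x$spec$n_mirnas, x$spec$n_genes,
              x$spec$n_haplotypes, length(x$paths),
              dirname(x$paths$genome)))
  invisible(x)
}
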