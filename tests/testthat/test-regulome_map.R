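test_that("UTR admission filters reject by reason and partition the input", {
  utrs <- data.frame(
    id = c("ok", "multi", "spliced", "short", "unmapped"),
    gene_symbol = c("G1", "G2", "G3", "G4", "G5"),
    species = "human",
    sequence = c(strrep("A", 120), strrep("C", 50), strrep("G", 50),
                 strrep("A", 19), strrep("T", 40)),
    stringsAsFactors = FALSE)
  mappings <- rbind(
    data.frame(id = "ok", mapping = 1L, chrom = "chr1", strand = "+",
               start = 1001L, end = 1120L),
    data.frame(id = "multi", mapping = 1:2, chrom = "chr1", strand = "+",
               start = c(1L, 5001L), end = c(50L, 5050L)),
    data.frame(id = "spliced", mapping = 1L, chrom = "chr1", strand = "+",
               start = c(1L, 2001L), end = c(25L, 2025L)),
    data.frame(id = "short", mapping = 1L, chrom = "chr1", strand = "+",
               start = 1L, end = 19L))
  fl <- filter_utr_mappings(utrs, mappings)
  expect_identical(fl$admitted$id, "ok")
  expect_identical(fl$admitted$start, 1001L)
  got <- setNames(fl$rejected$reason, fl$rejected$id)
  expect_identical(got[["multi"]], "multi_mapped")
  expect_identical(got[["spliced"]], "spliced")
  expect_identical(got[["short"]], "too_short")
  expect_identical(got[["unmapped"]], "unmapped")
  # partition: nothing lost or duplicated
  expect_setequal(c(fl$admitted$id, fl$rejected$id), utrs$id)
  expect_identical(nrow(fl$admitted) + nrow(fl$rejected), nrow(utrs))
})

test_that("the naive exact mapper reports strand-aware single-segment hits", {
  genome <- Biostrings::DNAStringSet(c(
    chrA = "TTTTTCAGGACCAGTTTTT",
    chrB = "AAAGGTCCTGAAA"))
  # present once on + strand of chrA
  one <- naive_map_utr("AGGACCAG", genome)
  expect_identical(nrow(one), 1L)
  expect_identical(one$strand, "+")
  expect_identical(one$start, 7L)
  expect_identical(one$end, 14L)
  # present forward on chrA and as reverse complement on chrB
  both <- naive_map_utr("CAGGACC", genome)
  expect_identical(nrow(both), 2L)
  expect_setequal(both$strand, c("+", "-"))
  # absent
  expect_identical(nrow(naive_map_utr("ACGTACGTA", genome)), 0L)
})

test_that("TAS x element intersection emits one pair per containment", {
  members <- data.frame(
    index_snp = "rsI", trait = "t", population = "EUR",
    member_snp = c("rs1", "rs2", "rs3"), chrom = "chr1",
    pos = c(100L, 205L, 900L), r2 = 1, minor_allele = "G", maf = 0.2,
    stringsAsFactors = FALSE)
  elements <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(90L, 200L, 201L), end = c(120L, 250L, 240L)),
    strand = "+",
    kind = c("pre_mirna", "promoter", "utr3"),
    owner = c("mir-9", "mir-9", "GENEX"), source = "test")
  out <- intersect_tas(members, elements)
  # rs1 in the precursor; rs2 in both the promoter and the overlapping UTR
  expect_identical(nrow(out), 3L)
  expect_identical(out$snp, c("rs1", "rs2", "rs2"))
  expect_identical(sort(out$kind[out$snp == "rs2"]), c("promoter", "utr3"))
  # rs3 outside all elements contributes nothing
  expect_false("rs3" %in% out$snp)
})

test_that("intersection agrees with a brute-force containment scan", {
  set.seed(21)
  n_snp <- 60L; n_el <- 25L
  members <- data.frame(
    index_snp = "rsI", trait = "t", population = "EUR",
    member_snp = sprintf("rs%d", seq_len(n_snp)),
    chrom = sample(c("chr1", "chr2"), n_snp, TRUE),
    pos = sample.int(5000L, n_snp), r2 = 1, minor_allele = "G",
    maf = 0.1, stringsAsFactors = FALSE)
  st <- sample.int(4800L, n_el)
  el_chrom <- sample(c("chr1", "chr2"), n_el, TRUE)
  elements <- GenomicRanges::GRanges(
    el_chrom, IRanges::IRanges(start = st, end = st + sample.int(400L, n_el)),
    kind = sample(c("pre_mirna", "promoter", "utr3"), n_el, TRUE),
    owner = sprintf("own%d", seq_len(n_el)), source = "test")
  got <- intersect_tas(members, elements)
  want <- oracle_containment(members$pos, members$chrom, st,
                             st + (GenomicRanges::width(elements) - 1L),
                             el_chrom)
  expect_identical(nrow(got), nrow(want))
  want_keys <- sort(paste(members$member_snp[want[, 1]],
                          sprintf("own%d", want[, 2])))
  expect_identical(sort(paste(got$snp, got$owner)), want_keys)
  # stable sort contract
  expect_false(is.unsorted(order(got$chrom, got$pos, got$kind)))
})

test_that("chromosome naming mismatches warn with per-chromosome counts", {
  members <- data.frame(index_snp = "rsI", trait = "t", population = "EUR",
                        member_snp = "rs1", chrom = "1", pos = 100L,
                        r2 = 1, minor_allele = "G", maf = 0.2)
  elements <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 120),
                                     kind = "utr3", owner = "G",
                                     source = "s")
  expect_warning(out <- intersect_tas(members, elements),
                 "no chromosome shared")
  expect_identical(nrow(out), 0L)
})

test_that("GFF3 and BED element readers preserve coordinates and owners", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tmiRNA_primary_transcript\t101\t180\t.\t+\t.\tID=MI0000001;Name=mir-x",
    "chr1\t.\tmiRNA\t110\t131\t.\t+\t.\tID=MIMAT0001;Name=mir-x;Derives_from=MI0000001"),
    gff)
  pre <- read_mirna_gff(gff)
  expect_identical(length(pre), 1L)    # mature record is not an element
  expect_identical(BiocGenerics::start(pre), 101L)
  expect_identical(BiocGenerics::end(pre), 180L)
  expect_identical(pre$owner, "mir-x")
  expect_identical(pre$kind, "pre_mirna")

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t180\tmir-x\t0\t+", bed)  # BED: 0-based half-open
  prom <- read_bed_elements(bed, "promoter")
  expect_identical(BiocGenerics::start(prom), 101L)
  expect_identical(BiocGenerics::end(prom), 180L)
  expect_identical(prom$owner, "mir-x")
})

test_that("UTR table reading maps symbols and flags unknown ids", {
  tab <- tempfile(fileext = ".tsv")
  write.table(data.frame(id = c("NM_1", "NM_1", "NM_2"),
                         species = c("human", "mouse", "human"),
                         sequence = c("ACGT", "ACGT", "GGGG")),
              tab, sep = "\t", quote = FALSE, row.names = FALSE)
  smap <- data.frame(id = "NM_1", symbol = "GENEA")
  expect_warning(utrs <- read_utr_table(tab, smap), "NM_2")
  expect_identical(utrs$gene_symbol, c("GENEA", "GENEA", "NM_2"))
  # unknown species tag is a data error
  bad <- tempfile(fileext = ".tsv")
  write.table(data.frame(id = "NM_1", species = "zebrafish",
                         sequence = "ACGT"),
              bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_utr_table(bad), class = "mirtas_data_error")
})
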