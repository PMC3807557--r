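test_that("catalog parsing applies the strict p-value and multi-SNP filters", {
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(
    SNPS = c("rs1", "rs1 x rs2", "rs3", "rs4", "haplotype", "rs6"),
    `P-VALUE` = c("2e-6", "1e-9", "1.0e-5", "4e-8", "1e-9", "oops"),
    `DISEASE/TRAIT` = paste0("t", 1:6),
    PUBMEDID = as.character(1:6),
    `INITIAL SAMPLE SIZE` = rep("Norwegian", 6),
    check.names = FALSE)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- suppressMessages(parse_catalog(tmp))
  # rs1 kept; multi-SNP dropped; p == 1e-5 dropped (strict <); rs4 kept;
  # no-rsID row dropped; malformed p tolerated but dropped
  expect_identical(out$index_snp, c("rs1", "rs4"))
  expect_identical(out$source_row, c(1L, 4L))
  expect_true(all(out$p_value < 1e-5))
})

test_that("catalog parsing names missing columns in its error", {
  tmp <- tempfile(fileext = ".tsv")
  write.table(data.frame(SNPS = "rs1"), tmp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(parse_catalog(tmp), "P-VALUE",
               class = "mirtas_config_error")
})

test_that("super-population assignment follows keyword rows with EUR fallback", {
  expect_identical(assign_superpopulation("Norwegian"), "EUR")
  expect_identical(assign_superpopulation("Japanese individuals from Tokyo"),
                   "ASN")
  expect_identical(assign_superpopulation("Brazilian"), "EUR")
  expect_identical(assign_superpopulation("Yoruba in Ibadan, Nigeria"), "AFR")
  expect_identical(assign_superpopulation("Mexican-American families"), "AMR")
  # row order resolves conflicts: EUR row checked before ASN ("India" vs "Asia")
  expect_identical(assign_superpopulation("Indian subjects from South Asia"),
                   "EUR")
  # " UK " only matches as a token
  expect_identical(assign_superpopulation("UK residents"), "EUR")
  expect_identical(assign_superpopulation(""), "EUR")
})

test_that("super-population assignment is total over arbitrary strings", {
  set.seed(42)
  junk <- vapply(1:200, function(i) {
    paste(sample(c(letters, LETTERS, " ", ",", "0"), 30, TRUE),
          collapse = "")
  }, character(1))
  out <- assign_superpopulation(junk)
  expect_true(all(out %in% SUPERPOPULATIONS))
  expect_length(out, 200L)
})

test_that("r-squared matches hand-counted and degenerate cases", {
  a <- c(1, 1, 1, 1, 0, 0, 0, 0)
  b <- c(1, 1, 1, 0, 0, 0, 0, 0)
  p <- make_test_panel(8, list(a = a, b = b, same = a,
                               flip = 1 - a, mono = rep(0, 8)))
  # hand count: pA=0.5, pB=0.375, pAB=0.375, D=0.1875 -> r2 = 0.6 exactly
  expect_identical(compute_r2(p, "a", "b"), 0.6)
  expect_identical(compute_r2(p, "a", "same"), 1)
  # allele relabeling leaves r2 invariant
  expect_identical(compute_r2(p, "a", "flip"), 1)
  expect_identical(compute_r2(p, "a", "mono"), 0)
  expect_error(compute_r2(p, "a", "nope"), class = "mirtas_lookup_error")
})

test_that("r-squared is symmetric and agrees with the 2x2-table oracle", {
  set.seed(7)
  cols <- lapply(1:12, function(i) as.integer(runif(60) < runif(1, .1, .9)))
  # sprinkle missing alleles to exercise pairwise exclusion
  cols[[3]][c(2, 9)] <- NA
  names(cols) <- sprintf("s%02d", 1:12)
  p <- suppressWarnings(make_test_panel(60, cols))
  for (i in 1:11) for (j in (i + 1):12) {
    ida <- sprintf("s%02d", i); idb <- sprintf("s%02d", j)
    r <- compute_r2(p, ida, idb)
    expect_identical(r, compute_r2(p, idb, ida))
    expect_equal(r, oracle_r2(cols[[i]], cols[[j]]), tolerance = 1e-12)
    expect_true(r >= 0 && r <= 1)
  }
})

test_that("MAF reports the minor allele with the alt tie-break", {
  p <- make_test_panel(8, list(
    zero = rep(0L, 8), tie = c(1, 1, 1, 1, 0, 0, 0, 0),
    three = c(1, 1, 1, 0, 0, 0, 0, 0), seven = c(1, 1, 1, 1, 1, 1, 1, 0)))
  expect_identical(compute_maf(p, "zero"), list(minor_allele = "G", maf = 0))
  expect_identical(compute_maf(p, "tie"), list(minor_allele = "G", maf = 0.5))
  expect_identical(compute_maf(p, "three"),
                   list(minor_allele = "G", maf = 0.375))
  # majority alt: the reference becomes the minor allele
  got <- compute_maf(p, "seven")
  expect_identical(got$minor_allele, "A")
  expect_equal(got$maf, 0.125)
})

test_that("LD-block expansion honors the strict threshold, window and membership invariants", {
  a <- c(1, 1, 1, 1, 0, 0, 0, 0)
  b <- c(1, 1, 1, 0, 0, 0, 0, 0)
  p <- make_test_panel(8, list(idx = a, boundary = b, dup = a,
                               far = a, indep = c(0, 1, 0, 1, 1, 0, 1, 0)),
                       pos = c(1000L, 1050L, 1100L, 900000L, 1200L))
  blk <- expand_ld_block("idx", p, r2_threshold = 0.6, window_bp = 10000L)
  # boundary partner at exactly r2 = 0.6 is excluded (strict >)
  expect_false("boundary" %in% blk$members$snp)
  # perfect-LD duplicate included with r2 = 1; index always present at r2 = 1
  expect_true(all(c("idx", "dup") %in% blk$members$snp))
  expect_identical(blk$members$r2[blk$members$snp == "idx"], 1)
  expect_identical(blk$members$r2[blk$members$snp == "dup"], 1)
  # perfect-LD SNP outside the window is excluded
  expect_false("far" %in% blk$members$snp)
  expect_true(all(blk$members$r2[blk$members$snp != "idx"] > 0.6))
  expect_true(all(blk$members$maf <= 0.5 & blk$members$maf >= 0))

  # widening the window admits the distant perfect-LD SNP
  blk2 <- expand_ld_block("idx", p, window_bp = 1e6L)
  expect_true("far" %in% blk2$members$snp)
})

test_that("an index SNP absent from the panel yields an unresolved block", {
  p <- make_test_panel(8, list(a = c(1, 1, 0, 0, 1, 0, 1, 0)))
  expect_warning(blk <- expand_ld_block("rs_missing", p), "absent")
  expect_true(blk$unresolved)
  expect_identical(nrow(blk$members), 0L)
  expect_identical(nrow(ld_blocks_table(list(blk))), 0L)
})

test_that("phased VCF and matrix-dialect readers reconstruct the panel", {
  set.seed(11)
  snps <- data.frame(chrom = "chr1", pos = c(500L, 700L, 900L),
                     id = c("rs1", "rs2", "rs3"),
                     ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                     stringsAsFactors = FALSE)
  hap <- cbind(c(1L, 0L, 1L, 0L), c(0L, 0L, 1L, 1L), c(NA, NA, 0L, 1L))
  vcf <- tempfile(fileext = ".vcf")
  write_test_vcf(vcf, snps, hap)
  panel <- read_haplotype_vcf(vcf)
  expect_identical(panel$snps$id, snps$id)
  expect_identical(panel$snps$pos, snps$pos)
  expect_identical(unname(panel$haplotypes[, "rs2"]), c(0L, 0L, 1L, 1L))
  expect_true(all(is.na(panel$haplotypes[1:2, "rs3"])))

  meta <- tempfile(fileext = ".tsv"); mat <- tempfile(fileext = ".txt")
  write.table(snps, meta, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("1 0 .", "0 0 .", "1 1 0", "0 1 1"), mat)
  panel2 <- read_haplotype_matrix(meta, mat)
  expect_identical(panel2$haplotypes[!is.na(panel2$haplotypes)],
                   panel$haplotypes[!is.na(panel$haplotypes)])
})

test_that("multi-allelic records are dropped and odd haplotype counts warn", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t10\trsA\tA\tG\t.\tPASS\t.\tGT\t0|1",
    "chr1\t20\trsB\tA\tC,G\t.\tPASS\t.\tGT\t0|0",
    "chr1\t30\trsC\tAT\tA\t.\tPASS\t.\tGT\t0|0"), vcf)
  expect_warning(panel <- read_haplotype_vcf(vcf), "multi-allelic")
  expect_identical(panel$snps$id, "rsA")

  expect_warning(
    haplotype_panel(data.frame(chrom = "chr1", pos = 1L, id = "x",
                               ref = "A", alt = "G"),
                    matrix(c(0L, 1L, 0L), ncol = 1), "EUR"),
    "odd")
})
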