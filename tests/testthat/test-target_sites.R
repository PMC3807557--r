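let7a <- data.frame(name = "let-7a",
                    mature_sequence = "UGAGGUAGUAGGUUGUAUAGUU",
                    stringsAsFactors = FALSE)

test_that("seed patterns are the mRNA-sense reverse complements with A anchors", {
  pats <- seed_patterns(let7a$mature_sequence)
  expect_identical(pats[["8mer-1a"]], "CUACCUCA")
  expect_identical(pats[["7mer-m8"]], "CUACCUC")
  expect_identical(pats[["7mer-1a"]], "UACCUCA")
  # DNA input is equivalent
  expect_identical(seed_patterns("TGAGGTAGTAGGTTGTATAGTT"), pats)
  expect_error(seed_patterns("UGAGGUA"), class = "mirtas_data_error")
})

test_that("find_sites reports each example site with strongest-type collapse", {
  s1 <- find_sites("AACUACCUCAGG", let7a)
  expect_identical(nrow(s1), 1L)
  expect_identical(s1$site_type, "8mer-1a")
  expect_identical(s1$utr_offset, 2L)

  s2 <- find_sites("AACUACCUCGG", let7a)
  expect_identical(s2$site_type, "7mer-m8")

  expect_identical(nrow(find_sites("GGGGGGGG", let7a)), 0L)
  # N never matches
  expect_identical(nrow(find_sites("AACUACCNCAGG", let7a)), 0L)
})

test_that("DNA and RNA alphabets give identical predictions", {
  set.seed(5)
  for (i in 1:20) {
    mir <- rand_mirna_table(1)
    utr_rna <- rand_rna(80)
    utr_dna <- chartr("U", "T", utr_rna)
    expect_identical(find_sites(utr_rna, mir), find_sites(utr_dna, mir))
  }
})

test_that("find_sites agrees with the brute-force complementarity oracle", {
  set.seed(99)
  for (i in 1:150) {
    mir <- rand_mirna_table(1)
    # seed-enriched sequences so matches actually occur
    utr <- rand_rna(70)
    if (i %% 2 == 0) {
      pat <- seed_patterns(mir$mature_sequence)[[sample(3, 1)]]
      at <- sample(60, 1)
      utr <- paste0(substr(utr, 1, at - 1), pat,
                    substr(utr, at + nchar(pat), nchar(utr)))
    }
    got <- find_sites(utr, mir)
    want <- oracle_find_sites(utr, mir$name, mir$mature_sequence)
    expect_identical(got[, c("mirna", "utr_offset", "site_type")],
                     want, label = sprintf("case %d", i))
  }
})

test_that("every 8mer-1a implies the collapsed 7mer matches at its location", {
  set.seed(17)
  checked <- 0L
  for (i in 1:60) {
    mir <- rand_mirna_table(1)
    pats <- seed_patterns(mir$mature_sequence)
    utr <- paste0(rand_rna(20), pats[["8mer-1a"]], rand_rna(20))
    sites <- find_sites(utr, mir)
    e8 <- sites[sites$site_type == "8mer-1a", , drop = FALSE]
    for (off in e8$utr_offset) {
      # uncollapsed, the same offset satisfies 7mer-m8 and offset+1 the 7mer-1a
      expect_identical(substr(utr, off + 1, off + 7), pats[["7mer-m8"]])
      expect_identical(substr(utr, off + 2, off + 8), pats[["7mer-1a"]])
      # and the collapse removed them
      expect_false(any(sites$site_type == "7mer-m8" &
                         sites$utr_offset == off))
      expect_false(any(sites$site_type == "7mer-1a" &
                         sites$utr_offset == off + 1))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 50L)
})

test_that("conservation counts same-type presence across ortholog UTRs", {
  mir <- let7a
  site_utr <- "AACUACCUCAGG"
  none <- list(mouse = "GGGG", rat = "CCCC", dog = "AAAA",
               chicken = "UUUU")
  expect_identical(conservation_number("let-7a", "8mer-1a", none, mir), 1L)
  all4 <- lapply(none, function(x) paste0(x, site_utr))
  expect_identical(conservation_number("let-7a", "8mer-1a", all4, mir), 5L)
  two <- none; two$mouse <- site_utr; two$rat <- site_utr
  expect_identical(conservation_number("let-7a", "8mer-1a", two, mir), 3L)
  # a different site type elsewhere does not count
  m8only <- none; m8only$dog <- "AACUACCUCGG"
  expect_identical(conservation_number("let-7a", "8mer-1a", m8only, mir), 1L)
  # missing species count as absent
  expect_identical(conservation_number("let-7a", "8mer-1a",
                                       list(mouse = site_utr), mir), 2L)
})

test_that("alternate enumeration yields 2^k - 1 combinations per cluster", {
  utr <- paste0(strrep("C", 30), "A", "GG", "A", strrep("C", 30))
  # two A/T SNPs 3 nt apart: AT, TA and TT haplotypes
  snps <- data.frame(id = c("rs1", "rs2"), utr_pos = c(31L, 34L),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  alts <- enumerate_alternate_sequences(utr, snps)
  expect_identical(nrow(alts), 3L)
  hap <- vapply(alts$sequence, function(s)
    paste0(substr(s, 31, 31), substr(s, 34, 34)), character(1),
    USE.NAMES = FALSE)
  expect_setequal(hap, c("UA", "AU", "UU"))
  expect_true(all(nchar(alts$sequence) == nchar(utr)))

  # one SNP: exactly one alternate differing at one position
  one <- enumerate_alternate_sequences(utr, snps[1, ])
  expect_identical(nrow(one), 1L)
  ref_chars <- strsplit(normalize_rna(utr), "")[[1]]
  alt_chars <- strsplit(one$sequence, "")[[1]]
  expect_identical(which(ref_chars != alt_chars), 31L)

  # 50 nt apart: two independent clusters, one alternate each
  far <- data.frame(id = c("rs1", "rs2"), utr_pos = c(5L, 55L),
                    ref = c("C", "C"), alt = c("G", "G"))
  two <- enumerate_alternate_sequences(utr, far)
  expect_identical(nrow(two), 2L)
  expect_identical(sort(unique(two$cluster)), c(1L, 2L))
})

test_that("cluster chaining is transitive at <= 7 nt and 2^k - 1 holds to k = 4", {
  # positions 1, 8, 15, 22 chain pairwise at exactly 7 nt into one cluster
  expect_identical(cluster_snps(c(1L, 8L, 15L, 22L)), rep(1L, 4))
  expect_identical(cluster_snps(c(1L, 9L)), c(1L, 2L))
  for (k in 1:4) {
    utr <- strrep("C", 60)
    snps <- data.frame(id = sprintf("rs%d", 1:k),
                       utr_pos = seq(10L, by = 4L, length.out = k),
                       ref = "C", alt = "A", stringsAsFactors = FALSE)
    expect_identical(nrow(enumerate_alternate_sequences(utr, snps)),
                     as.integer(2^k - 1))
  }
})

test_that("alternate enumeration validates alleles and caps cluster size", {
  utr <- strrep("C", 80)
  bad <- data.frame(id = "rsX", utr_pos = 10L, ref = "A", alt = "G")
  expect_error(enumerate_alternate_sequences(utr, bad), "rsX",
               class = "mirtas_data_error")
  big <- data.frame(id = sprintf("rs%d", 1:11),
                    utr_pos = seq(2L, by = 2L, length.out = 11),
                    ref = "C", alt = "A")
  expect_error(enumerate_alternate_sequences(utr, big),
               class = "mirtas_data_error")
})

test_that("site diffs report created/abolished with type changes as both", {
  ref <- find_sites("AACUACCUCAGG", let7a)   # 8mer-1a
  alt <- find_sites("AACUACCUCGGG", let7a)   # 7mer-m8 at same offset
  d <- diff_sites(ref, alt, "h1", "rs1")
  expect_setequal(d$direction, c("abolished", "created"))
  expect_identical(d$site_type[d$direction == "abolished"], "8mer-1a")
  expect_identical(d$site_type[d$direction == "created"], "7mer-m8")

  # diff of a site list with itself is empty
  expect_identical(nrow(diff_sites(ref, ref)), 0L)
  # created and abolished keys are disjoint
  key <- paste(d$mirna, d$utr_offset, d$site_type)
  expect_identical(anyDuplicated(key), 0L)
})

test_that("utr_site_diffs finds planted abolish/create events and nothing else", {
  set.seed(3)
  mir <- rand_mirna_table(2)
  pat <- chartr("U", "T", seed_patterns(mir$mature_sequence[1])[["8mer-1a"]])
  utr <- paste0(strrep("C", 25), pat, strrep("C", 25))
  ref_sites <- find_sites(utr, mir)
  expect_true(any(ref_sites$site_type == "8mer-1a"))
  # break the third base of the site
  pos <- 28L
  refb <- substr(utr, pos, pos)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  d <- utr_site_diffs(utr, data.frame(id = "rsZ", utr_pos = pos,
                                      ref = refb, alt = altb), mir)
  expect_true(any(d$direction == "abolished" & d$mirna == mir$name[1] &
                    d$utr_offset == 25L))
  # a SNP outside the planted span leaves the planted site untouched
  d2 <- utr_site_diffs(utr, data.frame(id = "rsQ", utr_pos = 2L,
                                       ref = "C", alt = "G"), mir)
  expect_false(any(d2$mirna == mir$name[1] & d2$utr_offset == 25L))
})

test_that("genomic SNPs map onto minus-strand UTRs with complemented alleles", {
  mapping <- list(chrom = "chr1", start = 101L, end = 130L, strand = "-")
  snps <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     pos = c(130L, 101L, 110L), id = c("a", "b", "c"),
                     ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                     stringsAsFactors = FALSE)
  m <- map_snps_to_utr(snps, mapping)
  expect_identical(m$id, c("a", "b"))     # off-chromosome SNP dropped
  expect_identical(m$utr_pos, c(1L, 30L)) # genomic end is sense position 1
  expect_identical(m$ref, c("T", "G"))    # complemented
  expect_identical(m$alt, c("C", "A"))

  plus <- map_snps_to_utr(snps, within(as.list(mapping), strand <- "+"))
  expect_identical(plus$utr_pos, c(30L, 1L))
  expect_identical(plus$ref, c("A", "C"))
})
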