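## Shared fixture/run cache so expensive generation happens once per
## test run.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(seed = 1L) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), sprintf("mirtas_fx_%d", seed))
    .fixture_cache[[key]] <- suppressWarnings(suppressMessages(
      mirtas::make_fixture_set(mirtas::fixture_spec(rng_seed = seed), dir)))
  }
  .fixture_cache[[key]]
}

fixture_config <- function(fx, reps = 200L, seed = 7L) {
  mirtas::pipeline_config(
    catalog = fx$paths$catalog,
    panels = list(EUR = fx$paths$panel_vcf),
    mirna_gff = fx$paths$mirna_gff, mirna_fasta = fx$paths$mirna_fasta,
    promoter_bed = fx$paths$promoter_bed, utr_table = fx$paths$utr_table,
    utr_mappings = fx$paths$utr_mappings, symbol_map = fx$paths$symbol_map,
    exon_bed = fx$paths$exon_bed, nonsyn_vcf = fx$paths$nonsyn_vcf,
    transcriptional = fx$paths$transcriptional, eqtl = fx$paths$eqtl,
    tarbase = fx$paths$tarbase, trait_genes = fx$paths$trait_genes,
    reps = reps, seed = seed)
}

get_run <- function() {
  if (is.null(.fixture_cache$run)) {
    fx <- get_fixture(1L)
    out <- file.path(tempdir(), "mirtas_run_shared")
    .fixture_cache$run <- suppressWarnings(suppressMessages(
      mirtas::run_pipeline(fixture_config(fx), out)))
  }
  .fixture_cache$run
}

## minimal phased VCF writer, independent of the package's writer
write_test_vcf <- function(path, snps, hap) {
  n_hap <- nrow(hap)
  samples <- sprintf("S%d", seq_len(n_hap %/% 2L))
  gt <- vapply(seq_len(ncol(hap)), function(j) {
    a <- hap[seq(1, n_hap, 2), j]; b <- hap[seq(2, n_hap, 2), j]
    g <- paste(a, b, sep = "|")
    g[is.na(a) | is.na(b)] <- ".|."
    paste(g, collapse = "\t")
  }, character(1))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
            snps$chrom, snps$pos, snps$id, snps$ref, snps$alt, gt))
  writeLines(lines, path)
  path
}
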