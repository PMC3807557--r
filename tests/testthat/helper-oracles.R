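## Independent oracles used to cross-check the package's own engines.
## These deliberately re-derive results from first principles (explicit
## Watson-Crick pairing, 2x2 haplotype tables, O(n*m) containment scans)
## rather than reusing any package code path.

## --- brute-force seed-site scanner -----------------------------------
.wc <- c(A = "U", U = "A", G = "C", C = "G")

oracle_find_sites <- function(utr, mirna_name, mature) {
  s <- strsplit(toupper(chartr("Tt", "Uu", utr)), "")[[1]]
  m <- strsplit(toupper(chartr("Tt", "Uu", mature)), "")[[1]]
  n <- length(s)
  pair_ok <- function(ui, mj) {
    a <- s[ui]
    a %in% names(.wc) && .wc[[a]] == m[mj]
  }
  hits <- list()
  add <- function(off0, type) {
    hits[[length(hits) + 1L]] <<- data.frame(
      mirna = mirna_name, utr_offset = off0, site_type = type,
      stringsAsFactors = FALSE)
  }
  for (i in 0:(n - 7L)) {
    ## 7mer-m8: utr[i+k] pairs miRNA position 9-k, k = 1..7
    if (all(vapply(1:7, function(k) pair_ok(i + k, 9L - k), logical(1)))) {
      if (i + 8L <= n && s[i + 8L] == "A") add(i, "8mer-1a")
      else add(i, "7mer-m8")
    }
    ## 7mer-1a: utr[i+k] pairs position 8-k (k = 1..6), then an A
    if (i + 7L <= n && s[i + 7L] == "A" &&
        all(vapply(1:6, function(k) pair_ok(i + k, 8L - k), logical(1)))) {
      ## suppressed when an 8mer covers it (8mer at i-1)
      covered <- i >= 1L && i + 6L <= n &&
        all(vapply(1:7, function(k) pair_ok(i - 1L + k, 9L - k),
                   logical(1))) && s[i + 6L + 1L] == "A"
      if (!covered) add(i, "7mer-1a")
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(mirna = character(0), utr_offset = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE)
  }
  out[order(out$utr_offset, out$site_type), , drop = FALSE]
}

## --- 2x2 haplotype-table r-squared ------------------------------------
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  nA1 <- n11 + n10; nA0 <- n01 + n00
  nB1 <- n11 + n01; nB0 <- n10 + n00
  den <- as.numeric(nA1) * nA0 * nB1 * nB0
  if (den == 0) return(0)
  num <- (as.numeric(n11) * n00 - as.numeric(n10) * n01)^2
  num / den
}

## --- O(n*m) interval containment scan ---------------------------------
oracle_containment <- function(snp_pos, snp_chrom, el_start, el_end,
                               el_chrom) {
  out <- list()
  for (i in seq_along(snp_pos)) {
    for (j in seq_along(el_start)) {
      if (snp_chrom[i] == el_chrom[j] && snp_pos[i] >= el_start[j] &&
          snp_pos[i] <= el_end[j]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

## --- small generators --------------------------------------------------
rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

rand_mirna_table <- function(k, len = 22L) {
  data.frame(name = sprintf("syn-mir-%d", seq_len(k)),
             mature_sequence = vapply(seq_len(k), function(i) rand_rna(len),
                                      character(1)),
             stringsAsFactors = FALSE)
}

make_test_panel <- function(n_hap, cols, pos = NULL, chrom = "chr1") {
  m <- do.call(cbind, cols)
  k <- ncol(m)
  if (is.null(pos)) pos <- seq(100L, by = 50L, length.out = k)
  snps <- data.frame(chrom = chrom, pos = pos,
                     id = names(cols) %||% sprintf("rs%d", seq_len(k)),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  if (!is.null(names(cols))) snps$id <- names(cols)
  mirtas::haplotype_panel(snps, m, "EUR")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
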