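## Shared helpers: sequence alphabet handling, classed error conditions,
## stderr logging. Internal only.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Condition constructors. The CLI maps mirtas_config_error -> exit 2 and
## mirtas_data_error -> exit 3.
config_error <- function(msg, ...) {
  stop(structure(
    class = c("mirtas_config_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

data_error <- function(msg, ...) {
  stop(structure(
    class = c("mirtas_data_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

lookup_error <- function(msg, ...) {
  stop(structure(
    class = c("mirtas_lookup_error", "mirtas_data_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

log_msg <- function(fmt, ...) {
  message(sprintf(paste0("[mirtas] ", fmt), ...))
}

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases and converts T to U. `N` is preserved (it never matches a
#' seed pattern). Any other character is a data error.
#'
#' @param x character vector of sequences over \{A,C,G,T,U,N\} (case
#'   insensitive).
#' @return character vector over \{A,C,G,U,N\}.
#' @export
normalize_rna <- function(x) {
  y <- chartr("t", "u", toupper(x))
  y <- chartr("T", "U", y)
  bad <- grepl("[^ACGUN]", y)
  if (any(bad)) {
    data_error("sequence contains characters outside {A,C,G,T,U,N}: %s",
               substr(y[bad][1L], 1L, 40L))
  }
  y
}

#' Reverse complement in the RNA alphabet
#'
#' @param x character vector over \{A,C,G,U,N\}.
#' @return reverse complements, 5'->3'.
#' @export
revcomp_rna <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## DNA single-base complement (used when flipping VCF alleles onto the
## transcript strand of minus-strand genes).
comp_dna <- function(x) chartr("ACGTN", "TGCAN", toupper(x))

## Stable write of a data.frame as TSV (no quoting, no row names).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, ...)
}
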