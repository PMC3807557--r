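## Super-population assignment from free-text cohort ancestry.

#' Super-population codes
#'
#' The four continental 1000 Genomes phase I super-populations used for
#' population-matched LD lookup. EUR is the fallback for unrecognized
#' ancestry text.
#' @export
SUPERPOPULATIONS <- c("EUR", "AFR", "AMR", "ASN")

## Keyword rows, checked in order; first row with any case-insensitive
## substring match wins. Keywords with flanking spaces (" UK ", "Kinh ")
## are matched against the space-padded text so they only hit as
## standalone tokens.
.superpop_keywords <- list(
  EUR = c("Indian", "India", "Europe", "Canadian", "Canada", "Caucasian",
          "White", "Framingham", "Norwegian", "Norway", "French", "France",
          "Iceland", "German", "Germany", "Scandanavia", "Finnish",
          "Finland", " UK ", "Welsh", "Wales", "Irish", "Ireland",
          "Scottish", "Scotland", "Spanish", "Spain", "Iberia", "Toscani",
          "Tuscan", "Utah", "CEPH", "England", "English", "Swiss",
          "Switzerland", "Australia", "Turkish", "Turkey", "Saami",
          "Belgium", "Belgian", "Russia", "Polish", "Poland"),
  AFR = c("Africa", "Ghani", "Malawi", "Yoruba", "Esan", "Mende", "Sierra",
          "Leone", "Gambia", "Kenya", "Luhya"),
  AMR = c("Mexico", "Mexican", "Hispanic", "Peru", "Puerto", "Rico",
          "Rican", "Colombia", "Medellin", "Lima"),
  ASN = c("Asia", "Chin", "Japan", "Thai", "Korea", "Bangladesh", "Taiwan",
          "Indonesia", "Vietnam", "Hong Kong", "Kosrae", "Micronesia",
          "Papua New Guinea", "Han", "Dai", "Kinh ", "Tokyo",
          "Xishuangbanna", "Beijing")
)

#' Assign a GWAS cohort to a 1000 Genomes super-population
#'
#' Maps free-text case--control cohort ancestry to one of EUR, AFR, AMR,
#' ASN by case-insensitive keyword substring matching. Rows are checked
#' in the order EUR, AFR, AMR, ASN and the first row with any matching
#' keyword wins; text matching no keyword maps to EUR. The function is
#' total: every string (including "") yields a code.
#'
#' @param ancestry_text character vector of free-text ancestry
#'   descriptions.
#' @return character vector of super-population codes.
#' @examples
#' assign_superpopulation(c("Norwegian", "Japanese individuals from Tokyo",
#'                          "Brazilian"))
#' @export
assign_superpopulation <- function(ancestry_text) {
  if (length(ancestry_text) == 0L) return(character(0))
  ancestry_text[is.na(ancestry_text)] <- ""
  padded <- paste0(" ", tolower(ancestry_text), " ")
  out <- rep("EUR", length(padded))
  assigned <- logical(length(padded))
  for (code in names(.superpop_keywords)) {
    kws <- tolower(.superpop_keywords[[code]])
    hit <- rep(FALSE, length(padded))
    for (kw in kws) hit <- hit | grepl(kw, padded, fixed = TRUE)
    take <- hit & !assigned
    out[take] <- code
    assigned <- assigned | hit
  }
  out
}
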