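#' Load a genetic code by preset name
#'
#' Presets map to NCBI translation tables: `standard` -> 1,
#' `prokaryotes` -> 11, `yeasts` -> 12, `mycoplasma` -> 4,
#' `mitochondria` -> 2 (vertebrate mitochondrial).  The table itself comes
#' from [Biostrings::getGeneticCode()].
#'
#' @param name One of `"standard"`, `"prokaryotes"`, `"yeasts"`,
#'   `"mycoplasma"`, `"mitochondria"`.
#' @return A list with class `"genetic_code"`: `name`, `ncbi_id`,
#'   `table` (named character, 64 codons -> one-letter amino acid, `*` for
#'   stop), `start_codons`, `stop_codons`.
#' @examples
#' gc <- load_genetic_code("standard")
#' gc$table[["ATG"]]
#' load_genetic_code("mycoplasma")$table[["TGA"]]  # "W", not stop
#' @export
load_genetic_code <- function(name = "standard") {
  ids <- c(standard = "1", prokaryotes = "11", yeasts = "12",
           mycoplasma = "4", mitochondria = "2")
  if (!name %in% names(ids)) {
    stop("unknown genetic code '", name, "'; valid names: ",
         paste(names(ids), collapse = ", "))
  }
  tab <- Biostrings::getGeneticCode(ids[[name]])
  structure(list(
    name = name,
    ncbi_id = unname(ids[[name]]),
    table = tab,
    start_codons = unique(c("ATG", attr(tab, "alt_init_codons"))),
    stop_codons = names(tab)[tab == "*"]
  ), class = "genetic_code")
}

## Three-letter amino acid name for a codon under a genetic_code.
## Stops report "Ter".
aa3_of <- function(codon, code) {
  aa <- unname(code$table[codon])
  ifelse(aa == "*", "Ter", unname(Biostrings::AMINO_ACID_CODE[aa]))
}

is_stop_codon <- function(codon, code) codon %in% code$stop_codons

## --- small sequence utilities used throughout -----------------------------

str_rev <- function(x) {
  vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""), "")
}

revcomp <- function(x) {
  out <- character(length(x))
  nz <- nzchar(x)
  out[nz] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x[nz])))
  out
}

complement_base <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(map[x])
}

## IUPAC symbol covering a set of bases (single base -> itself).
iupac_symbol <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  key <- paste(bases, collapse = "")
  map <- Biostrings::IUPAC_CODE_MAP
  hit <- names(map)[map == key]
  if (length(hit) == 0L) stop("no IUPAC symbol for base set ", key)
  hit[[1L]]
}

## Expand a single IUPAC ambiguity symbol to its base set.
iupac_expand <- function(symbol) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!symbol %in% names(map)) stop("not an IUPAC symbol: ", symbol)
  strsplit(unname(map[symbol]), NULL)[[1L]]
}
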