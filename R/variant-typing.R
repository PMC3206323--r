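## Ordered from least to most complex; with several alternative alleles the
## most complex per-allele type is reported.
TYPE_COMPLEXITY <- c("SNP", "MNP", "INVERSION", "INDEL")

#' Classify a single ref/alt allele pair
#'
#' * different lengths -> `INDEL`
#' * both length 1 -> `SNP`
#' * equal length > 1 and the alternative allele is the inversion of the
#'   reference allele -> `INVERSION`
#' * otherwise -> `MNP`
#'
#' "Inversion" means plain character reversal by default (e.g. reference
#' `TTAG` vs alternative `GATT`), not reverse complement; `inversion =
#' "revcomp"` switches to the biological reverse-complement reading.
#'
#' @param ref_allele,alt_allele Allele strings (`""` is the gap allele).
#' @param inversion `"reverse"` (default) or `"revcomp"`.
#' @return One of `"SNP"`, `"MNP"`, `"INVERSION"`, `"INDEL"`.
#' @examples
#' classify_type("G", "C")       # SNP
#' classify_type("TTAG", "GATT") # INVERSION
#' classify_type("CA", "")       # INDEL
#' classify_type("AC", "GT")     # MNP
#' @export
classify_type <- function(ref_allele, alt_allele,
                          inversion = c("reverse", "revcomp")) {
  inversion <- match.arg(inversion)
  ref <- toupper(ref_allele); alt <- toupper(alt_allele)
  if (identical(ref, alt)) stop("reference and alternative allele coincide")
  if (nchar(ref) != nchar(alt)) return("INDEL")
  if (nchar(ref) == 1L) return("SNP")
  inv <- if (inversion == "reverse") str_rev(ref) else revcomp(ref)
  if (alt == inv) "INVERSION" else "MNP"
}

#' Overall type of a variant record
#'
#' Each alternative allele is typed against the reference allele
#' (alternatives identical to the reference, as produced by IUPAC
#' expansion of heterozygous reference/alternative calls, are ignored);
#' the most complex type is reported
#' (`INDEL > INVERSION > MNP > SNP`).
#'
#' @param record A [variant_record()].
#' @param inversion See [classify_type()].
#' @return A single type string.
#' @export
variant_type <- function(record, inversion = c("reverse", "revcomp")) {
  inversion <- match.arg(inversion)
  alts <- setdiff(record$alt_alleles, record$ref_allele)
  types <- vapply(alts, classify_type, "", ref_allele = record$ref_allele,
                  inversion = inversion)
  TYPE_COMPLEXITY[max(match(types, TYPE_COMPLEXITY))]
}
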