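## Known-variant store and KNOWN/NOVEL/ALTERNATIVE status resolution.
##
## Substitutions are indexed by (chromosome, start, end); indels are
## canonicalized first so that redundant records annotating the same event
## at different placements in a repeat tract collapse onto one index entry.

#' Load a known-variants file
#'
#' @param path VCF with an ID column (e.g. a dbSNP extract).
#' @param genome A [reference_genome()]; records whose reference allele
#'   does not match the genome are skipped with a warning, and indels are
#'   left-normalized against it.
#' @param ref_offset Chromosomal offset of the VCF's coordinate system
#'   (default 1 = VCF positions are chromosomal).
#' @return An object of class `"known_variant_db"`.
#' @export
load_known <- function(path, genome, ref_offset = 1) {
  records <- parse_vcf(path)
  subst <- new.env(parent = emptyenv())
  indel_seq <- new.env(parent = emptyenv())   # key incl. sequence -> ids
  indel_pos <- new.env(parent = emptyenv())   # positional key -> ids
  n_skip <- 0L
  add <- function(env, key, ids) {
    assign(key, unique(c(if (exists(key, envir = env)) get(key, envir = env),
                         ids)), envir = env)
  }
  for (rec in records) {
    cs <- chrom_pos(rec$rel_start, ref_offset)
    ce <- chrom_pos(rec$rel_end, ref_offset)
    ok <- tryCatch(
      verify_ref(genome, rec$chromosome, cs, ce, rec$ref_allele)$matched,
      error = function(e) FALSE)
    if (!isTRUE(ok)) { n_skip <- n_skip + 1L; next }
    for (alt in rec$alt_alleles) {
      if (nchar(alt) == nchar(rec$ref_allele)) {
        key <- paste(rec$chromosome, cs, ce, sep = "|")
        add(subst, key, rec$name)
        add(subst, paste0(key, "|", alt), rec$name)
      } else {
        ci <- tryCatch(
          canonicalize(genome, rec$chromosome, cs, rec$ref_allele, alt),
          error = function(e) NULL)
        if (is.null(ci)) { n_skip <- n_skip + 1L; next }
        add(indel_seq, canonical_key(ci), rec$name)
        add(indel_pos, paste(ci$chromosome, ci$op, ci$canonical_pos,
                             sep = "|"), rec$name)
      }
    }
  }
  if (n_skip > 0L) {
    warning(n_skip, " known-variant record(s) mismatching the reference ",
            "genome were skipped", call. = FALSE)
  }
  structure(list(subst = subst, indel_seq = indel_seq,
                 indel_pos = indel_pos, n = length(records)),
            class = "known_variant_db")
}

#' @export
print.known_variant_db <- function(x, ...) {
  cat(sprintf("known_variant_db: %d record(s)\n", x$n))
  invisible(x)
}

get0_env <- function(env, key) {
  if (exists(key, envir = env)) get(key, envir = env) else NULL
}

#' Resolve KNOWN / NOVEL / ALTERNATIVE status
#'
#' A variant is KNOWN when a known variant shares its coordinates and at
#' least one of its alternative alleles (indels: when the canonical forms
#' coincide); ALTERNATIVE when coordinates collide but no allele matches;
#' NOVEL otherwise.  KNOWN reports every matching identifier,
#' ALTERNATIVE the colliding ones.
#'
#' @param db A [load_known()] store (or `NULL`: everything is NOVEL).
#' @param genome A [reference_genome()] (for indel canonicalization).
#' @param chromosome,start,end Chromosomal coordinates of the variant.
#' @param ref_allele,alt_alleles Allele strings.
#' @return List with `status` and `ids` (character vector, empty for
#'   NOVEL).
#' @export
status_of <- function(db, genome, chromosome, start, end, ref_allele,
                      alt_alleles) {
  if (is.null(db)) return(list(status = "NOVEL", ids = character()))
  known_ids <- character(); collide_ids <- character()
  for (alt in setdiff(alt_alleles, ref_allele)) {
    if (nchar(alt) == nchar(ref_allele)) {
      key <- paste(chromosome, start, end, sep = "|")
      hit <- get0_env(db$subst, paste0(key, "|", alt))
      if (!is.null(hit)) {
        known_ids <- c(known_ids, hit)
      } else {
        collide_ids <- c(collide_ids, get0_env(db$subst, key))
      }
    } else {
      ci <- tryCatch(canonicalize(genome, chromosome, start, ref_allele, alt),
                     error = function(e) NULL)
      if (is.null(ci)) next
      hit <- get0_env(db$indel_seq, canonical_key(ci))
      if (!is.null(hit)) {
        known_ids <- c(known_ids, hit)
      } else {
        collide_ids <- c(collide_ids, get0_env(
          db$indel_pos, paste(ci$chromosome, ci$op, ci$canonical_pos,
                              sep = "|")))
      }
    }
  }
  if (length(known_ids)) {
    list(status = "KNOWN", ids = unique(known_ids))
  } else if (length(collide_ids)) {
    list(status = "ALTERNATIVE", ids = unique(collide_ids))
  } else {
    list(status = "NOVEL", ids = character())
  }
}
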