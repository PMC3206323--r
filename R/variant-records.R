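#' Construct a variant record
#'
#' Coordinates are 1-based with inclusive ends; an SNP has
#' `rel_start == rel_end`.  Deletions carry the deleted bases in
#' `ref_allele` and the empty string as (one of the) alternative allele(s);
#' insertions carry `ref_allele = ""` with the inserted bases as
#' alternative allele, placed between `rel_start - 1` and `rel_start`
#' (`rel_end == rel_start`).
#'
#' @param name Variant identifier chosen by the user.
#' @param chromosome Chromosome name.
#' @param rel_start,rel_end 1-based inclusive positions in the reference
#'   sequence's relative coordinate system.
#' @param alt_alleles Character vector of 1-3 alternative alleles (`""` is
#'   the gap allele).
#' @param ref_allele Reference allele (possibly `""` for insertions).
#' @return A list of class `"variant_record"`.
#' @export
variant_record <- function(name, chromosome, rel_start, rel_end,
                           alt_alleles, ref_allele) {
  rel_start <- as.numeric(rel_start); rel_end <- as.numeric(rel_end)
  alt_alleles <- toupper(as.character(alt_alleles))
  ref_allele <- toupper(as.character(ref_allele))
  if (is.na(rel_start) || is.na(rel_end)) stop("non-numeric position")
  if (rel_start > rel_end) stop("rel_start > rel_end")
  if (length(alt_alleles) < 1L) stop("at least one alt allele required")
  if (length(alt_alleles) > 3L) stop("at most three alt alleles supported")
  if (!is.na(ref_allele) && all(alt_alleles == ref_allele)) {
    stop("all alternative alleles equal the reference allele")
  }
  structure(list(name = as.character(name),
                 chromosome = as.character(chromosome),
                 rel_start = rel_start, rel_end = rel_end,
                 alt_alleles = alt_alleles, ref_allele = ref_allele),
            class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("variant_record %s %s:%g-%g %s>%s\n", x$name, x$chromosome,
              x$rel_start, x$rel_end,
              if (nzchar(x$ref_allele)) x$ref_allele else "-",
              paste(ifelse(nzchar(x$alt_alleles), x$alt_alleles, "-"),
                    collapse = "/")))
  invisible(x)
}

## Parse an AltAlleles cell: "X/Y" splits, a single IUPAC ambiguity symbol
## expands to its bases, and the gap markers "-", "—" map to "".
parse_allele_field <- function(x) {
  x <- toupper(trimws(x))
  if (x %in% c("-", "—", ".", "")) return("")
  parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
  parts[parts %in% c("-", "—", ".")] <- ""
  if (length(parts) == 1L && nchar(parts) == 1L &&
      !parts %in% c("A", "C", "G", "T", "N", "")) {
    parts <- iupac_expand(parts)
  }
  bad <- nzchar(parts) & grepl("[^ACGTN]", parts)
  if (any(bad)) stop("invalid allele string: ", x)
  parts
}

parse_ref_field <- function(x) {
  x <- toupper(trimws(x))
  if (x %in% c("-", "—", ".", "")) return("")
  if (grepl("[^ACGTN]", x)) stop("invalid reference allele: ", x)
  x
}

skipped_frame <- function() {
  data.frame(line = integer(), name = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Parse a six-column variant table
#'
#' Columns: Name, Chromosome, RelStart, RelEnd, AltAlleles, RefAllele,
#' tab- or whitespace-separated.  Heterozygous alternative alleles may be
#' given slash-separated (`A/G`, up to three) or as a single IUPAC
#' ambiguity symbol (`R` = `A/G`); `-` (or an em-dash) is the gap allele.
#' Whether a header line is present is auto-detected by testing whether the
#' third column of the first line is numeric.
#'
#' Malformed lines are skipped with a warning; the skipped lines are kept
#' in the `"skipped"` attribute (data frame with `line`, `name`, `reason`)
#' so that downstream output can retain one row per input line.
#'
#' @param text Path to a file, or a character vector of lines (a single
#'   string containing newlines is split).
#' @param has_header `TRUE`, `FALSE`, or `NA` to auto-detect.
#' @return List of [variant_record()]s with attribute `"skipped"`.
#' @export
parse_variant_table <- function(text, has_header = NA) {
  lines <- if (length(text) == 1L && file.exists(text)) {
    readLines(text, warn = FALSE)
  } else if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    text
  }
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(structure(list(), skipped = skipped_frame()))
  }
  first_fields <- strsplit(trimws(lines[idx[1L]]), "[\t ]+")[[1L]]
  if (is.na(has_header)) {
    has_header <- length(first_fields) >= 3L &&
      is.na(suppressWarnings(as.numeric(first_fields[[3L]])))
  }
  if (has_header) idx <- idx[-1L]
  records <- list()
  skipped <- skipped_frame()
  for (i in idx) {
    fields <- strsplit(trimws(lines[[i]]), "[\t ]+")[[1L]]
    rec <- tryCatch({
      if (length(fields) != 6L) {
        stop("expected 6 columns, found ", length(fields))
      }
      variant_record(fields[[1L]], fields[[2L]], fields[[3L]], fields[[4L]],
                     parse_allele_field(fields[[5L]]),
                     parse_ref_field(fields[[6L]]))
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      warning(sprintf("line %d skipped: %s", i, conditionMessage(rec)),
              call. = FALSE)
      skipped <- rbind(skipped, data.frame(
        line = i,
        name = if (length(fields) >= 1L) fields[[1L]] else NA_character_,
        reason = conditionMessage(rec), stringsAsFactors = FALSE))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  structure(records, skipped = skipped)
}

## Strip the shared leading base(s) of a VCF REF/ALT pair, moving pos right.
## Returns list(pos, ref, alts).
strip_vcf_anchor <- function(pos, ref, alts) {
  repeat {
    if (!nzchar(ref) || any(!nzchar(alts))) break
    heads <- substr(c(ref, alts), 1L, 1L)
    if (length(unique(heads)) != 1L) break
    ref <- substr(ref, 2L, nchar(ref))
    alts <- substr(alts, 2L, nchar(alts))
    pos <- pos + 1
  }
  list(pos = pos, ref = ref, alts = alts)
}

#' Parse a VCF file into variant records
#'
#' VCF-style anchored indels are converted to the gap convention used
#' throughout: a deletion record keeps the deleted bases as reference
#' allele with an empty alternative allele; an insertion keeps the inserted
#' bases as alternative allele with an empty reference allele.
#' Multi-allelic ALT cells are split into separate alternative alleles.
#'
#' @param path VCF 4.x file (plain text or gzipped).
#' @return List of [variant_record()]s with a `"skipped"` attribute (see
#'   [parse_variant_table()]); record names come from the ID column, or
#'   `chrom:pos` when ID is `.`.
#' @export
parse_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  records <- list()
  skipped <- skipped_frame()
  for (i in seq_len(nrow(fix))) {
    rec <- tryCatch({
      pos <- as.numeric(fix[i, "POS"])
      ref <- toupper(fix[i, "REF"])
      alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]])
      alts <- alts[alts != "*" & !grepl("[<>\\[\\]]", alts)]
      if (length(alts) == 0L) stop("no sequence-resolved ALT allele")
      st <- strip_vcf_anchor(pos, ref, alts)
      id <- fix[i, "ID"]
      nm <- if (is.na(id) || id == ".") {
        paste0(fix[i, "CHROM"], ":", fix[i, "POS"])
      } else id
      rel_end <- if (nzchar(st$ref)) st$pos + nchar(st$ref) - 1 else st$pos
      variant_record(nm, fix[i, "CHROM"], st$pos, rel_end, st$alts, st$ref)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      warning(sprintf("VCF record %d skipped: %s", i,
                      conditionMessage(rec)), call. = FALSE)
      skipped <- rbind(skipped, data.frame(
        line = i, name = fix[i, "ID"], reason = conditionMessage(rec),
        stringsAsFactors = FALSE))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  structure(records, skipped = skipped)
}

#' Parse a Personal Genome SNP (pgSnp) track
#'
#' pgSnp is BED-based: chrom, chromStart (0-based), chromEnd, name (the
#' observed alleles, slash-separated), alleleCount, alleleFreq, alleleScores.
#' The format carries no reference allele; `ref_allele` is left `NA` and is
#' filled from the reference genome during annotation (alleles equal to the
#' reference are then dropped from the alternative set).
#'
#' @param path pgSnp file.
#' @return List of [variant_record()]s with a `"skipped"` attribute.
#' @export
parse_pgsnp <- function(path) {
  if (!file.exists(path)) stop("pgSnp file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines))
  records <- list()
  skipped <- skipped_frame()
  for (i in keep) {
    fields <- strsplit(trimws(lines[[i]]), "[\t ]+")[[1L]]
    rec <- tryCatch({
      if (length(fields) < 4L) stop("expected >= 4 columns")
      start0 <- as.numeric(fields[[2L]]); end <- as.numeric(fields[[3L]])
      alleles <- parse_allele_field(fields[[4L]])
      r <- variant_record(paste0(fields[[1L]], ":", fields[[2L]]),
                          fields[[1L]], start0 + 1, max(end, start0 + 1),
                          alleles, "N")
      r$ref_allele <- NA_character_  # resolved against the genome later
      r
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      warning(sprintf("pgSnp line %d skipped: %s", i,
                      conditionMessage(rec)), call. = FALSE)
      skipped <- rbind(skipped, data.frame(
        line = i, name = fields[[1L]], reason = conditionMessage(rec),
        stringsAsFactors = FALSE))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  structure(records, skipped = skipped)
}

#' Write variant records as a six-column table
#'
#' Inverse of [parse_variant_table()]: writing and re-parsing reproduces
#' the records.
#'
#' @param records List of [variant_record()]s.
#' @param path Output path.
#' @export
write_variant_table <- function(records, path) {
  header <- paste(c("Name", "Chromosome", "RelStart", "RelEnd",
                    "AltAlleles", "RefAllele"), collapse = "\t")
  rows <- vapply(records, function(r) {
    alts <- ifelse(nzchar(r$alt_alleles), r$alt_alleles, "-")
    paste(c(r$name, r$chromosome, format(r$rel_start, scientific = FALSE),
            format(r$rel_end, scientific = FALSE),
            paste(alts, collapse = "/"),
            if (nzchar(r$ref_allele)) r$ref_allele else "-"),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
}
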